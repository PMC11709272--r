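---
title: "Order-based DAG learning for equal-variance linear SEMs: methods and design choices"
author: "semdag package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Order-based DAG learning: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semdag)
```

## The model and why an ordering identifies it

`semdag` learns a directed acyclic graph $G = (V, E)$ from an
$n \times p$ data matrix under the linear structural equation model

$$ Y_j \;=\; \sum_{k \in pa(j)} \beta_{jk}\, Y_k + U_j,
   \qquad U_j \sim N(0, \sigma^2) \text{ i.i.d.}, $$

with *one common error variance* $\sigma^2$. Without constraints on the
errors, observational data identify only a Markov equivalence class of
graphs. The equal-variance assumption is what buys exact identifiability:
it induces an asymmetry along the causal direction that a node ordering
can exploit. Concretely, the precision matrix
$\Omega = \Sigma^{-1}$ has diagonal entries
$\omega_{jj} = 1/\mathrm{var}(Y_j \mid Y_{-j})$, and under the model a
*sink* attains the maximal full conditional variance
$\mathrm{var}(Y_j \mid Y_{-j}) = \sigma^2$, while any node with children
has strictly smaller conditional variance (each child subtracts at least
$\beta^2/\sigma^{-2}$-worth of precision). Peeling the minimum-precision
node, removing its column, and repeating therefore reconstructs a
reversed topological order of the true DAG — this is the *bottom-up*
(BU) ordering. Once an ordering is fixed, estimating the graph reduces
to $p$ independent sparse regressions, which is what makes the approach
fast in high dimensions.

The package implements both stages:

1. **Ordering** — from a prior knowledge graph (topological vertex order
   `TO`, or the unique topological *layer* partition `TL` computed by
   iterative leaf removal), or data-driven bottom-up via the graphical
   lasso.
2. **Parent selection** — a weighted LASSO of every node on its
   candidate ancestors, with optional protection (zero penalty) for
   edges of the prior graph, followed by thresholding of
   $|\hat\beta_{jk}|$.

## Stage 1a: knowledge-based orderings

A raw knowledge graph (e.g. a signalling pathway) may contain cycles and
self-loops; `graphToDAG()` removes self-loops and then deletes the back
edges found by a depth-first traversal started from each node in
ascending label order, with neighbours visited in label order. The
traversal rule is our own deterministic stand-in — how the upstream
ecosystem breaks cycles is not documented — and it guarantees that the
same input always yields the same DAG.

`layerDecomposition()` computes the partition
$L(G) = (L_0, \dots, L_d)$: $L_0$ is the source set and $L_j$ the
sources of the subgraph left after removing $L_0, \dots, L_{j-1}$.
Operationally the package forms the transpose of the DAG and strips its
leaves (out-degree-zero nodes, i.e. the sources of $G$) iteratively,
which realizes the same partition top-down. Unlike a topological vertex
sort, the layer partition is *unique*, and any node's parents lie in
strictly upper layers, so regressions restricted to earlier layers can
never create a cycle. The test-suite checks the implementation against
an independent brute-force source-peeling oracle written directly on the
adjacency matrix.

All tie-breaking (root order in the vertex sort, listing order within a
layer) is by ascending node label, so results are bit-reproducible.

## Stage 1b: bottom-up ordering via the graphical lasso

The precision matrix of the remaining variables is re-estimated at every
peel from

$$ \hat\Omega \in \arg\min_{\Omega \succ 0}\;
   \mathrm{tr}(\Omega S) - \log\det(\Omega)
   + \lambda \sum_{j \neq k} |\omega_{jk}|, $$

with the penalty on off-diagonal entries only, so that $\lambda \to 0$
recovers the MLE $S^{-1}$. No sparse-inverse-covariance package is part
of the supported dependency set, so the solver is implemented in-package
as the classic block coordinate descent over columns of the working
covariance, warm-started across sweeps. It is validated three ways: a
dense-inverse oracle at tiny $\lambda$, the decoupled
$\mathrm{diag}(1/s_{jj})$ limit at huge $\lambda$, and a frozen
reference solution computed once with an independent implementation
(scikit-learn's graphical lasso, tolerance $10^{-10}$) on a fixed
$4 \times 4$ fixture.

**Covariance, not correlation.** The input $S$ is the centered
cross-product matrix $(Y^\top Y)/n$; standardizing columns to unit
variance is available behind a flag but is *off* by default. This is a
deliberate design decision: the equal-variance identification argument
lives on the covariance scale. On the chain
$Y_1 \to Y_2 \to Y_3$ ($\beta = 0.8$, $\sigma = 1$) the
covariance-precision diagonal is $(1.64, 1.64, 1.00)$ — minimum at the
sink $Y_3$, as the theory demands — whereas the correlation-precision
diagonal is $(1.64, 2.69, 2.05)$, whose minimum is the *source*: a
correlation-scaled bottom-up loop would walk the chain backwards.
Standardization interacts badly with equal error variances because
dividing by $\mathrm{sd}(Y_j)$ re-weights exactly the signal the method
keys on. For expression data whose columns arrive on wildly different
scales the flag exists, with this caveat.

**Penalty default.** $\lambda = 0.001$ when $n > p$ and
$\sqrt{\log(p)/n}$ when $n \le p$. The flat rate $\log(p)/n$ is kept
selectable; the square-root reading is the default because it is the
rate the graphical-lasso theory prescribes, while the flat value is
vanishingly small exactly in the high-dimensional regime where a strong
penalty is needed (0.046 at $n = p = 100$).

**Vertex vs layer peeling.** Vertex mode removes the single
minimum-precision node per iteration (ties to the smallest label); layer
mode removes the whole set
$\{j : \hat\omega_{jj} \le \min(\hat\omega) + \eta\}$. The default
$\eta = 0.05$ follows the documented interface; with `eta = NULL` (or
`"adaptive"`) and $n > 100$, $\eta$ is estimated from the data as the
mean absolute difference between the precision diagonals of two half
samples — a direct estimate of how far two diagonal entries can drift
apart by sampling noise alone. The published description of the adaptive
rule stops at "half of the sample data", so this split-half statistic is
our documented stand-in. The split is the deterministic first/second
half (a seeded random split is available): determinism means repeated
designs give exactly zero, and no hidden RNG state leaks into results.

## Stage 2: weighted LASSO parent selection

Given the ordering, each node $Y_j$ is regressed on its candidate
ancestors $S_j$ (strictly earlier vertices, or the union of strictly
earlier layers — same-layer edges are never considered):

$$ \hat\beta \in \arg\min_\beta\;
   \tfrac{1}{2n}\,\|Y_j - \textstyle\sum_{k \in S_j} \beta_{jk} Y_k\|^2
   + \lambda_j \sum_{k \in S_j} w_{jk} |\beta_{jk}|. $$

Data are centered (no intercepts), predictors are standardized inside
each regression for penalty comparability, and coefficients are
reported on the original scale. In knowledge-based mode the candidate
set is *all* ordering-preceding nodes, not just known parents — known
edges get $w = 0$ (never shrunk, always retained) and everything else
$w = 1$, which is what makes newly discovered connections (`dagNew`)
possible alongside preserved ones (`dagOld`). Vertex mode fits exactly
$p - 1$ regressions; layer mode fits $p - |L_0|$ (one per node outside
the top layer — the constructive count, which we assert in tests).

**Choosing $\lambda_j$.** Four rules are exposed: 10-fold
cross-validation (default for $p \le 100$), BIC
($n \log(\mathrm{RSS}/n) + \log(n)\,\mathrm{df}$, default above 100),
the tuning-free normal-quantile formula
$\lambda_j = z\!\left(1 - \alpha / [2p(j-1)]\right)/n$, and a
user-supplied candidate vector scored per node by CV. Fold assignments
are seeded, so runs are reproducible. The CV rule returns the
**one-standard-error** penalty, not the CV minimizer. This is a
deliberate deviation worth spelling out: the CV minimizer is tuned for
prediction and is well known to overselect when the goal is support
recovery. In this package's own equal-variance simulations
($p = 20$, $n = 5000$) the CV-min rule drove the edge false-discovery
rate to about 0.70 (at true-positive rate 1.0), while the one-SE rule
achieved about 0.03 at the same true-positive rate. The divisor of the
tuning-free formula is $n$ as documented upstream; a
$\sqrt{n}$-variant from the penalized-regression literature is
selectable.

**Thresholding.** An edge is kept iff $|\hat\beta_{jk}| >$ `beta`
(strict), so the default `beta = 0` removes exact zeros only. One purely
numerical guard: penalized coefficients below $10^{-10}$ in magnitude
are snapped to zero, because the path solver can park inactive
coefficients at $\sim 10^{-17}$ — values that are numerically zero but
would otherwise count as edges under a strict-positivity test.
Unpenalized ($w = 0$) columns are exempt from the snap so the
always-included contract holds exactly.

## The synthetic generator: what it emulates and what it does not

`randomDAG()` draws a uniform node permutation and includes each forward
pair with probability `edgeProb`; `drawWeights()` draws
$|\beta| \sim U[0.5, 1]$ with fair random signs and sets $\sigma = 1$;
`simulateSEM()` generates nodes in topological order. These defaults are
the stated world of the package's tests: coefficient magnitudes bounded
away from zero keep every edge identifiable at desk-scale $n$, sign
balance prevents variance blow-up along long paths, and the common
$\sigma = 1$ is precisely the regime the method assumes (a per-node
$\sigma$ override exists solely to demonstrate what breaks without it).
`populationCovariance()` gives the closed form
$\Sigma = (I - B^\top)^{-1} D (I - B^\top)^{-\top}$ used as the exact
input oracle.

A green test suite therefore establishes that the implementation is
faithful to the model *it assumes*. It does not establish performance on
real expression data, which are non-Gaussian, measured with error,
subject to latent confounding and batch structure, and certainly not
equal-variance; nor does it validate the correlation-scale variant, the
behaviour under model misspecification, or any biological claim.

## Evaluation choices

Structural Hamming distance counts differing entries of the directed
adjacency matrices, so a reversed edge costs 2; equivalence-class-aware
variants are out of scope. The normalized SHD divides by $p(p-1)$
(ordered pairs) by default because division by $p$ alone can exceed 1
on dense graphs, contradicting a $[0,1]$ range; the $p$ divisor remains
selectable. MCC uses the standard degenerate-margin convention
(zero denominator $\Rightarrow$ 0). Path coefficients are the per-node
OLS (Gaussian MLE) on the fitted parent sets, and score prediction
$\hat Y = Y_c \hat B$ centers new data with the *training* means only —
no information from the test rows enters the transform.

## Known limitations

* The bottom-up loop inverts/estimates a $p \times p$ precision matrix
  per peel; the pure-R solver is comfortable to a few hundred nodes but
  is not engineered for $p$ in the thousands.
* Equal error variance is an assumption, not a conclusion: on data whose
  noise scales differ systematically along the causal order the BU
  ordering can be systematically wrong, and nothing in the output warns
  about it.
* `graphToDAG()`'s cycle-breaking is a documented heuristic; different
  but equally defensible rules yield different DAGs from the same cyclic
  prior.
* The adaptive $\eta$ is a stand-in for an upstream procedure documented
  only by intent.
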