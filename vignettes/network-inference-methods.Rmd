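---
title: "Permutation-stabilised lasso network inference: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Permutation-stabilised lasso network inference: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plnet)
```

## The inference problem

Given an expression matrix of `n` samples by `p` genes, plnet infers an
undirected network whose edges represent the main pairwise associations
among genes. Estimating the full conditional-independence structure via
the inverse covariance matrix is unstable when `p` approaches or exceeds
`n`; plnet instead follows the neighbourhood-selection strategy: each gene
in turn is treated as the response and regressed on all remaining genes,
and the network is assembled from the per-gene selections. Linearity is
assumed only locally — gene by gene — which is a far weaker assumption
than global linearity of the whole system.

Each per-gene regression is an intercept-free lasso,

$$
\hat\beta^{(i)} = \arg\min_\beta \; \frac{1}{2n}\,\lVert y_i - X_{-i}\beta\rVert_2^2
  + \lambda\,\lVert\beta\rVert_1 ,
$$

where `y_i` is the (standardized) expression of response gene `i`,
`X_{-i}` holds the remaining genes and the response gene is never among
its own predictors, so no self-interactions can arise. The one-norm
penalty shrinks most coefficients exactly to zero and yields a sparse
neighbour set. Because the lasso fits no intercept, the data are
standardized once, globally, before any fit: every gene column is centred
and scaled to unit population standard deviation (denominator `n`). With
this convention `max_j |x_j^T y|/n` is exactly the smallest penalty with
an all-zero solution, which anchors the cross-validation grid.

## Estimating the shrinkage factor once

Cross-validating the penalty for every response would dominate the run
time, so the shrinkage factor is estimated once and shared by every
response gene and every permutation refit. `estimate_lambda()` draws
`ceiling(0.10 p)` response genes (at least one), runs 3-fold
cross-validation over a 100-point log-spaced grid from that response's
`lambda_max` down to `0.001 * lambda_max`, records the per-response
minimiser of mean held-out squared error, and returns the median across
responses. The median was chosen over the mean because single responses
with a degenerate cross-validation curve (for example a gene that is
almost perfectly predictable) would otherwise drag the shared penalty
towards zero. Ties along the grid resolve towards the larger penalty,
i.e. the sparser model.

## The permutation stability stage

The step-1 neighbour sets are unstable in exactly the settings that
motivate the method: strongly correlated predictor groups, from which the
lasso picks one member essentially at random. The second stage quantifies
that instability. First the non-zero step-1 coefficients are ranked by
absolute value and the best 80% are kept as candidates
(`best_fraction`). Then the response is permuted `B` times; each permuted
response is refit at the same shared penalty, and a counter per candidate
records how often it is re-selected. Permutation destroys any genuine
response-predictor association, so a candidate that keeps being
re-selected owes its selection to the predictor-side correlation
structure, not to the response: candidates with *small* counters are the
stable, response-specific ones. The `fanout` smallest-counter candidates
(default 1) become the selected neighbours; ties on the counter fall back
to the larger step-1 coefficient, then to the smaller gene index, so the
output is fully deterministic.

### The empirical-null significance gate

When many candidates are swapped in and out with similar frequency — the
collinear-group pathology — the counters are nearly uniform and the
"smallest" counter is meaningless. For `B >= 20` (below that the
empirical distribution has too little support, a threshold this package
chooses explicitly) an optional gate tests the smallest counter against
the empirical distribution of the *other* candidates' counters: its
p-value is the fraction of the other counters that are less than or equal
to it, and the entire selection is emptied when the p-value exceeds
`significance_level` (default 0.05). A uniquely smallest counter gets
p = 0 and survives regardless of the candidate-set size; uniform counters
get p = 1 and are always rejected; `k` candidates tied at the minimum
among `m` give `(k-1)/(m-1)`. The leave-one-out form matters: including
the tested counter in its own null caps the attainable p-value at `1/m`
from below, and with the candidate-set sizes the pipeline actually
produces (typically 3-15 at the shared penalty) a gate of that form can
never pass at conventional levels — it would silently empty every
selection. A single candidate passes trivially (p = 0): the pathology the
gate targets requires at least two competitors. The gate removes the
whole selection rather than individual genes because it tests the
best-supported neighbour; if even that one is indistinguishable from the
null, the response provides no reliable neighbour at all.

## Assembly and symmetrisation

The directed adjacency matrix sets `A[i, j] = 1` when gene `j` is a
selected neighbour of response `i`; the counter matrix is kept alongside
as a weighted diagnostic view. Neighbourhood selection is not symmetric,
so the matrix is symmetrised before use. The default OR rule declares an
undirected edge when at least one direction was selected, which matches
the goal of detecting generic association while ignoring magnitude and
direction; AND requires both directions, and the mean/max/min rules
(which operate on weights and binarise at strictly positive weight) are
provided for completeness of the standard symmetrisation menu.
Binarising before symmetrisation is an internal choice without effect for
OR and AND, the two rules that matter here.

## Evaluation against a gold standard

Predictions are scored over all `p(p-1)/2` unordered gene pairs:
confusion counts, true/false positive rate, precision, and the Matthews
correlation coefficient

$$
\mathrm{MCC} = \frac{TP\cdot TN - FP\cdot FN}
 {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}},
$$

with any zero denominator factor giving 0 — in particular the empty
network scores 0 rather than profiting from the abundant true negatives
of sparse graphs. Global topology conservation is measured by the Pearson
correlation between per-gene degree vectors and between per-gene
betweenness-centrality vectors of the predicted and gold networks.
Betweenness is left unnormalised (Pearson correlation is scale-invariant,
so normalisation would not change the statistic); pairs without a
connecting path contribute nothing, so isolated genes score 0. Spearman
correlation is available behind a flag; Pearson is the default.
Evaluation is undirected-only: a directed gold standard is OR-symmetrised
first, and explicit zero-weight rows in gold-standard files are dropped
from the edge set (every non-edge pair already counts as a negative).

## The synthetic benchmark generator

`generate_gold_network()` draws a connected scale-free network by
preferential attachment; with one attachment edge per node (the
benchmark default) the gold network is a spanning tree with hubs, whose
degree distribution is right-skewed like curated regulatory networks.
`simulate_expression()` replaces kinetic simulation with a linear
structural-equation model: an acyclic orientation is drawn from a random
node ordering, root genes are standard normal, and every other gene is a
signed-coefficient combination of its parents plus Gaussian noise. This
is the correct null ecosystem for a method whose own working assumption
is local linearity — it tests parameter recovery, not model
misspecification. Defaults: coefficients drawn uniformly from
±[0.5, 1.5] (random sign, so both activation- and inhibition-like
effects occur), `noise_sd = 0.1`, `n = 100` samples — a strong but not
trivial signal at the benchmark network sizes. An optional multicollinear
block appends genes that are `collinear_rho`-correlated copies of random
existing genes, reproducing the correlated-group pathology that motivates
the permutation stage.

What the generator does *not* emulate: nonlinear and saturating kinetics,
time-series structure, measurement-specific noise models, and directed
feedback loops. Passing benchmarks here therefore demonstrates correct
recovery under the method's own assumptions, not performance on real
microarray data. One consequence deserves emphasis: with small noise the
linear model produces near-deterministic chains in which a gene's
grandparent is almost as correlated with it as its parent, which makes
exact neighbour identification *harder* than in kinetic simulators.  On
the 50-gene tree benchmark (n = 100, noise 0.1, 500 permutations, 5
seeds) the test suite measures median degree correlation around 0.7 and
median betweenness correlation around 0.5 between predicted and gold
networks — clear topology conservation, though below the strongest values
reported for kinetic-simulator benchmarks of the same size, which the
acceptance suite records accordingly.

## Determinism and parallelism

Every operation is a pure function of its inputs and one integer seed.
The per-response permutation stream is seeded from
`(seed, response_index)`, so results are independent of the order in
which responses are processed: running with 1 or 4 workers produces
byte-identical edge lists. The per-gene loop parallelises with fork-based
workers (`workers` in the configuration); the permutation refits inside
one response are the hot loop and run in compiled code against a Gram
matrix computed once per response.

## Numerical choices

* Lasso solver: covariance-form updates on `G = X^T X / n`. An exact
  active-set solve (restricted linear system; drop the worst
  sign-inconsistent coordinate, add the worst subgradient violator, one
  exchange per iteration) is attempted first and terminates at a verified
  KKT point, i.e. with exact zeros; on singular restricted systems
  (exactly collinear columns) or cycling it falls back to cyclic
  coordinate descent with tolerance 1e-7 on coefficient updates and
  periodic KKT polishing. The test suite cross-checks solutions against
  glmnet and closed forms.
* Permutation refits warm-start from the previous permutation's support,
  which leaves the (unique) solution unchanged but cuts the exchange
  count.
* `B = 0` disables the permutation stage and the gate: the network is
  then built purely from step-1 fanout truncation by coefficient
  magnitude.
* Zero-variance genes are rejected at standardization with the offending
  gene named; a zero-variance predictor column inside a fit is pinned at
  coefficient 0.
* Degenerate correlations (constant centrality vectors, e.g. an empty
  predicted network) return NaN with a warning instead of failing.

## Problem sizes in the shipped suites

The test and acceptance suites run the full pipeline at the benchmark
scale the method targets on a desk machine: 50-gene networks with 100
samples and up to 500 permutations, with medians over 5-10 seeded
replicates; module tests use 3-20-gene instances. These sizes were chosen
so that each suite completes in minutes while still exercising the
benchmark conditions; the method itself has no hard size limit, and the
permutation count remains the dominant cost driver at larger `p`.

## Known limitations

* Edge direction and sign (activation vs inhibition) are not estimated.
* The shared shrinkage factor trades per-response optimality for speed; a
  too-restrictive shared penalty can exclude true neighbours of
  weakly-coupled genes before the permutation stage can assess them.
* `fanout` caps each response's neighbour count, so the degree of strong
  hubs is recovered only through the selections of their many partners.
* The elastic-net generalisation of the penalty is out of scope, as is
  integrating heterogeneous data sources.
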