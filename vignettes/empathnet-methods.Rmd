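---
title: "Methods: longitudinal Ising networks from questionnaire items"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal Ising networks from questionnaire items}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(empathnet)
```

## The model and the pipeline

`empathnet` estimates psychometric *symptom networks*: each questionnaire
item is a binary node ("present"/"absent"), and edges are direct pairwise
dependencies under a \{0,1\} Ising model,

$$P(x) \propto \exp\Big(\sum_i \tau_i x_i + \sum_{i<j} \beta_{ij} x_i x_j\Big),$$

so that the conditional distribution of each node given all others is a
logistic regression with intercept $\tau_i$ and coefficients $\beta_{ij}$.
The pipeline, aimed at two-occasion (pre/post intervention) designs, runs:

1. **Binarization** of multi-instrument Likert responses (DASS-21,
   EQ-short, JSE-S, EES) by each instrument's published dichotomization.
2. **Item filtering**: only items whose *both* response categories occur
   in at least 30% of participants at *both* occasions become nodes, so
   the two networks share one node set.
3. **eLasso estimation**: one $\ell_1$-penalized logistic regression per
   node with extended-BIC penalty selection, symmetrized by the AND rule.
4. **Graph analysis** of the absolute-weight network: strength,
   betweenness, closeness, Onnela clustering, rank-based hubs, two-level
   map-equation communities, and all-pairs shortest paths.
5. **Longitudinal inference**: a permutation test of the pre/post change
   in a regional measure against refitted pseudo-networks.

## Binarization rules and an asymmetry worth knowing

For an ordinary item, score $\ge c$ codes 1 (DASS-21 $c=1$, EQ-short
$c=2$, JSE-S $c=4$, EES $c=3$). For a *reverse-keyed* item the rule is the
exact complement: score $< c$ codes 1. For instruments whose cut does not
sit at the scale midpoint (JSE-S on 1–7, EES on 1–5) this is *not* the
mirror image of the ordinary rule about the midpoint — the published
dichotomizations put the boundary at the same raw score for both keyings
(JSE-S: 1–3 vs 4–7 in both directions; EES: 1–2 vs 3–5). The package
follows the published ranges; the test suite pins each instrument's ranges
explicitly.

Scale *totals* (used for the paired $t$-tests of overall change) follow
each instrument's published scoring instead: reverse-keyed JSE-S and EES
items are reverse-scored ($\min + \max - s$) before summing, while DASS-21
and EQ-short totals sum raw scores. Binarization and total scoring are
deliberately independent code paths.

## Estimation choices

* **Coding.** Nodes are coded \{0,1\} (not ±1), matching the binarization
  and making the nodewise model an ordinary logistic regression.
* **Penalty path.** Per node, 100 log-spaced $\lambda$ values from
  $\lambda_{\max} = \max_j |x_j^\top (y-\bar y)|/n$ (the smallest penalty
  with an all-zero solution) down to $0.01\,\lambda_{\max}$.
* **Solver.** Iteratively reweighted least squares with cyclic coordinate
  descent on each quadratic approximation, warm starts along the path,
  convergence tolerance $10^{-6}$ on the penalized objective and a final
  polishing pass at a tight inner tolerance. The solver is deterministic.
  Tests verify it against glmnet and against a generic bound-constrained
  optimizer on the positive/negative-part parameterization.
* **Model selection.** EBIC
  $= -2\ell + k\log n + 2\gamma k \log(p-1)$ with $\gamma = 0.25$ (the
  established default for this estimator); ties break toward the sparser
  model. $\gamma$ is configurable; sparsity is monotone in $\gamma$ (a
  property test checks this).
* **Symmetrization.** The default AND rule keeps an edge only when both
  nodewise regressions select it and averages the two directed
  coefficients; OR mode averages with the unselected direction as 0. AND
  output is always a subset of OR output.
* **Near-separation.** With $n = 40$ and strongly associated items,
  selected coefficients can grow large; any $|\hat\beta| > 10$ triggers a
  warning rather than a hard cap — the $\ell_1$ penalty already bounds the
  solution for $\lambda > 0$.

## Graph measures

All distance-based measures use the absolute-weight network and the length
transform $L_{ij} = 1/w_{ij}$ (strong connections are short), the standard
convention of the brain-connectivity toolchain this mirrors; distances come
from Floyd–Warshall. Betweenness counts unordered endpoint-excluded pairs
(Brandes). Closeness uses the component-scaled convention
$(r/(n-1))\cdot(r/\sum d)$ so disconnected networks degrade gracefully.
Clustering is the Onnela geometric-mean triangle intensity on
globally max-normalized weights. Hubs are nodes ranked in the top
`round(0.2 p)` (five ranks for 24 nodes) on at least two of
strength/betweenness/closeness, with competition ranking; ties that
overfill the top set are all admitted, with a warning, since the ranking
convention for ties is not otherwise determined. When several geodesics
tie, reported paths are the lexicographically smallest node sequence, so
path reports are reproducible.

## Communities: the two-level map equation

With stationary visit rates $p_i = s_i/2W$ and module exit rates
$q_m = \mathrm{cut}(m)/2W$, the expected per-step description length of a
random walk under a two-level code is

$$L(M) = \Big(\sum_m q_m\Big) H(Q) + \sum_m p_m^\circlearrowright H(P^m),$$

minimized over partitions by seeded local search: single-node moves to
neighboring modules, then whole-module merges, alternating until no move
improves $L$ by more than $10^{-10}$, best of 10 random restarts. Only the
two-level (non-hierarchical) formulation is implemented. For up to 10
nodes, `enumerate_optimal_partition()` provides the exact minimizer by
Bell-number enumeration; the optimizer matches it on ≥95% of random
test graphs and never beats it. No teleportation is used: the
strength-proportional stationary distribution is exact for undirected
networks. Note that merging two modules with zero cut between them can
*increase* $L$ (two disconnected triangles: one module costs $\log_2 6$
bits, two modules $\log_2 3$), which is exactly why the map equation can
detect disconnected or weakly connected modules; the optimizer is locally
optimal under both node moves and module merges.

## The permutation null for pre/post change

The observed statistic is the post-minus-pre difference of a regional
measure (default: clustering) computed from two independently refitted
networks. The null distribution refits networks on random splits of the
pooled $2N$ participant–occasion records into two pseudo-groups of size
$N$ — unrestricted by participant, following the pooled-records design;
a within-participant label-flip mode (`paired = TRUE`) is available. The
two-sided p-value uses the add-one estimator
$p = (1 + \#\{|d_0| \ge |d_{obs}|\})/(1 + B)$, so $p \ge 1/(B+1) > 0$.
Splits that leave any node constant in a pseudo-group are redrawn and
counted. Production default is $B = 5000$ permutations; exploratory and
test runs use a few hundred. No multiple-testing correction is applied by
default (mirroring a fixed per-node significance screen, default
$\alpha = 0.015$); Benjamini–Hochberg across nodes is available in
`permutation_scan()`.

Because refitted clustering on small pseudo-groups has a point mass at
zero (sparse refits lose triangles), the p-value distribution under the
null is discrete and conservative rather than uniform; the calibration
suite therefore checks that the empirical type-I error at $\alpha = 0.05$
stays within a band around the nominal level rather than testing
uniformity.

## The synthetic-data generator

Raw item-level responses for this kind of study are typically not
deposited, so validation runs on synthetic data with known ground truth:

* `random_ising_model()` draws Erdős–Rényi supports with uniform signed
  weights and thresholds.
* `gibbs_sample()` is a sequential-scan Gibbs sampler (C++), default 1000
  burn-in sweeps and thinning 10; for ≤12 nodes tests verify the sampled
  joint distribution against exact state enumeration (χ² and
  total-variation checks).
* `calibrate_marginals()` adjusts thresholds (couplings fixed) until
  sampled presence frequencies match target counts — by damped logit
  updates on exact marginals for ≤12 nodes, by stochastic approximation
  above. The damping step decays because cooperative couplings amplify
  simultaneous threshold moves and a constant step oscillates. The default
  targets are the published per-item presence counts of a 40-participant,
  24-item pre/post empathy-training study
  (`reference_presence_counts()`), giving a "study-scale" scenario.
* `likert_expand()` inverts the binarization by drawing uniformly from
  each binary value's preimage, so `binarize_table()` recovers the binary
  table exactly; this exercises all four instruments' rules end to end.
* `simulate_demo_study()` builds a 10-item two-occasion dataset over real
  item labels. Its ground-truth model gives a quarter of the edges a
  negative sign, mirroring the mixed-polarity couplings of real symptom
  networks — an all-positive model of comparable strength is
  ferromagnetic and collapses onto all-present/all-absent response
  patterns that the prevalence filter would (correctly) discard.
* `generate_paired_dataset()` draws the two occasions *independently*
  (optionally with a planted change such as removing one node's edges).
  Real pre/post data have within-participant dependence that this does not
  emulate; passing tests therefore validate the estimator and test
  machinery, not longitudinal dependence structure. The unrestricted
  permutation design is exact under exchangeability, which independent
  draws satisfy by construction.

## Problem sizes used in the validation suites

Chosen as the package's standard validation scale: chain recovery uses a
6-node chain ($\beta = 1$, $\tau = -0.5$, $n = 1000$, 20 seeds); metric
oracles use 50 random graphs with up to 12 nodes; map-equation optimality
uses 50 random graphs with up to 8 nodes (exhaustive enumeration);
permutation calibration uses a 5-node complete null model
($\beta = 0.6$, marginals $1/2$), $N = 40$ per group — the reference
study's size — with 200 permutations × 200 replicates; planted-change
recovery uses a strong triangle (β = 2) whose focal node loses its edges,
$N = 200$ per group, 50 seeds. The planted triangle is strong so that
pseudo-group mixtures (which halve the effective association) still retain
the triangle's edges; weak planted effects are simply not detectable at
these sample sizes.

## Known limitations

* Independent occasions in the generator (above): no within-person
  carry-over.
* The AND/OR rule, $\gamma$, and the λ path are conventions of the cited
  estimator, not estimated from data; all are configurable and logged in
  the run manifest.
* Closeness and betweenness discard edge sign (absolute weights); edge
  polarity is preserved separately in the signed network outputs.
* Joint (non-nodewise) Ising maximum likelihood, Gaussian/mixed graphical
  models, hierarchical map equations, and edge-level network comparison
  statistics are out of scope.

## A worked run

```{r, eval = FALSE}
demo <- simulate_demo_study(N = 40, seed = 1)
input <- tempfile(fileext = ".csv")
write.csv(demo$likert, input, row.names = FALSE)
cfg <- pipeline_config(input = input, output_dir = "results_demo",
                       n_permutations = 200, seed = 1)
res <- run_pipeline(cfg)
res$hubs$union
res$permutation
```
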