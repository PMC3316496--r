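---
title: "Methods behind mirsignet: paired differential expression, conditional forest importance, and weighted correlation networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind mirsignet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

mirsignet implements a discovery pipeline for candidate driver miRNAs from
matched tumour/normal expression profiles: two independent per-feature
rankings (a paired t-test and a random-forest permutation importance) are
intersected into a tissue-specific signature, the signature is turned into a
significance-filtered weighted Spearman correlation network whose centrality
and robustness structure points at the organising nodes, and qPCR-style
relative quantification statistics support an independent validation cohort.
This vignette records the modelling choices, the defaults and their
rationale, and what the accompanying synthetic-data generator does and does
not establish.

## The paired expression model and the synthetic generator

All expression values are treated as already normalised on the log2 scale
(RMA-style output); normalisation itself is out of scope. The generator
(`generator_config()`, `generate_paired_cohort()`) draws

    value = baseline_mean + subject effect + tissue effect
            + module factor + noise

with a per-(feature, subject) Gaussian subject effect (SD `baseline_sd`,
shared by the two tissues of a pair — this is what makes the design paired),
a tumour-only shift of `sign(fc) * log2(|fc|)` for each planted fold-change
`fc`, and i.i.d. Gaussian within-pair noise (SD `noise_sd`). Because a
tumour-minus-normal difference carries independent noise from both tissues,
its SD is `sqrt(2) * noise_sd`.

Correlated modules are driven by a shared per-sample standard-normal factor:
module members replace their subject-effect-plus-noise component with
`sigma * (sqrt(rho) * f + sqrt(1 - rho) * z)`, where
`sigma^2 = baseline_sd^2 + noise_sd^2` keeps the marginal variance of module
members equal to that of every other feature. Pearson correlation between
members is then exactly `rho` in expectation; the realised *Spearman*
correlation of bivariate Gaussians is `(6 / pi) * asin(rho / 2)`, about 0.79
for `rho = 0.8`, which is what network edges actually see. Negative target
correlations are handled by alternating loading signs (only pairs of
opposite-sign members attain `-|rho|`; a mutually negative equicorrelated
set of more than two variables does not exist). Modules may not overlap.

Defaults — `baseline_mean = 7`, `baseline_sd = 1`, `noise_sd = 0.25` log2
units — are in the range typical of normalised miRNA array data (inter-subject
spread near one log2 unit, technical spread a quarter of that). The original
study does not report its within-pair variance, so these are free choices of
the package, fixed once.

One global integer seed drives everything; per-stage sub-seeds are derived
deterministically from it, so any pipeline run is bit-reproducible.

What the generator does **not** emulate: probe-level effects, batch
structure, missing values, heavy-tailed noise, and correlation between the
tissue effect and the module factor. Passing recovery tests therefore
demonstrates that the pipeline recovers the structure it assumes, not that
real cohorts satisfy those assumptions.

## Paired differential expression

`paired_t_test()` tests the mean of the within-pair log2 differences against
the t distribution with `n_pairs - 1` degrees of freedom, two-sided.
Features whose differences have zero variance are *flagged* rather than
dropped or zero-filled: an identical tumour/normal pair of columns is the
well-defined boundary case `t = 0, p = 1`, while a constant nonzero
difference has an undefined t statistic and is reported as `NA` with
`zero_variance = TRUE`.

False-discovery-rate control uses Benjamini–Hochberg step-up adjustment
(`bh_fdr()`, delegating to `stats::p.adjust`), the default reading of "FDR
control" in microarray practice.

The tumour/normal `ratio` is the geometric-mean ratio
`2^mean(log2 T - log2 N)` by default — the natural summary for log-scale
input — with a linear-scale arithmetic alternative
(`scale = "arithmetic"`). The reported `fold_change` follows the signed
convention used in the field's tables: `ratio` itself when at least 1,
`-1/ratio` otherwise, so down-regulation appears as a negative fold-change
and `|fold_change|` is always at least 1. Ranking is by ascending p-value
with ties broken by descending `|fold_change|`, then feature id.

## Random forest and conditional permutation importance

`fit_forest()` grows CART trees (Gini splits, grown to purity, no pruning)
on the sample-by-feature matrix, labelling samples tumour or normal from the
pairing map. Following the bias-avoiding recommendations for permutation
importance, the per-tree learning sets are drawn **without** replacement at
fraction 0.632 of the observations (`replace = TRUE` restores classic
bagging). `mtry` defaults to `floor(sqrt(m))`. The out-of-bag (OOB) error is
the misclassification rate of the majority vote over the trees for which a
sample was held out; ties resolve to the normal class deterministically.

`conditional_mda()` implements conditional permutation importance: for each
feature *j* and tree, the OOB values of *j* are permuted **within the strata
carved out by the split points that the tree places on covariates correlated
with j** (absolute Spearman correlation above
`conditional_corr_threshold`, default 0.2, computed once on the full data).
The importance is the mean over trees of the increase in per-tree OOB error.
An empty conditioning set — or a threshold of 1 or more — reduces exactly to
the classical unconditional permutation importance. The conditioning is what
prevents a feature from inheriting importance merely through correlation
with a truly predictive one; the test suite checks this directly by cloning
an informative feature.

Two estimator properties worth knowing:

* Raw (unscaled) MDA of a pure-noise feature is not exactly centred on zero
  in small samples: overfit noise splits anti-generalise, producing a small
  offset (about −0.004 error-fraction units at 40 samples). The reference
  implementation (`randomForest`, unscaled `type = 1` importance) shows the
  same offset on identical data; tests assert equivalence with it and
  negligibility against real signal rather than exact centring.
* MDA values may legitimately be negative; ranks are assigned by descending
  MDA with feature-id tie-breaks.

`proximity_matrix()` counts, for each sample pair, the fraction of trees in
which both fall in the same leaf, by default restricted to trees where both
are out of sample (the less optimistic variant; `all_trees = TRUE` gives the
classic one, and is the right choice when the OOB variant leaves
never-jointly-out pairs missing). `mds_embedding()` applies classical
(Torgerson) scaling to `1 - proximity`; dimensions with null eigenvalues
come back as zero coordinates, and asking for at least as many dimensions as
samples is rejected.

The forest core is compiled (Rcpp) for speed, but all randomness flows
through R's RNG, so `set.seed()` semantics — and bit-reproducibility — are
preserved.

## Signature: merging the two rankings

`merge_rankings()` intersects `{p < p_threshold}` from the t-test table with
`{MDA > mda_threshold}` from the importance table, ordered by ascending p.
Both thresholds are study decisions (published analyses used cuts such as
p below 0.001 with the top MDA tier) and therefore have **no defaults**; an
empty signature is valid but warned about. Relaxing either threshold can
only grow the signature (tested as a monotonicity property).

## The correlation network and its metrics

`build_network()` computes all pairwise Spearman correlations among
signature features, by default across the tumour samples (the network is
meant to describe tumour biology; `tissue` exposes the alternatives since
pooling tumour and normal samples would let the common tissue shift induce
correlations). An edge exists when the two-sided, unadjusted p-value is
below `alpha` (default 0.05); exact p-values are used for ten or fewer
untied samples and the t-approximation otherwise (`stats::cor.test`).
Constant features keep their node but contribute no edges.

Edge weights and signs: metrics use `|rho|` as the working weight
(`raw_abs`, default) because the clustering formulas presume nonnegative
weights; the sign is kept as an edge attribute for reporting. An
`inverse_abs` mode (`w = 1/|rho|`) is provided because some published degree
values exceed what weights bounded by 1 permit, suggesting an inverse
convention in the original tooling; neither printed value is reproducible
from the text, so the mode is a user choice.

* **Path length** is the sum of *inverse* weights along a path, so strongly
  correlated neighbours are close; distances are minimised over paths
  (Dijkstra) and all minimum-length paths are counted with a relative tie
  tolerance of 1e-9 — floating-point sums that differ by less are the same
  length. The hand-rolled implementation exists precisely because this tie
  tolerance is part of the contract; `igraph::distances` serves as an
  independent cross-check in the tests.
* **Weighted degree** is the sum of incident weights.
* **Betweenness** of `v` is the fraction of shortest paths over unordered
  pairs `{s, t}` (endpoints excluded) passing through `v`, normalised by
  `(n-1)(n-2)/2` so it lies in [0, 1]; unreachable pairs contribute zero,
  and networks with fewer than three nodes score zero. It is invariant to
  rescaling all weights by a positive constant.
* **Zhang–Horvath clustering** of `v` is
  `sum_{j != k} w_vj w_jk w_kv / ((sum_j w_vj)^2 - sum_j w_vj^2)`, the
  weighted triangle density of the neighbourhood; with unit weights it
  reduces to the unweighted local clustering coefficient. Nodes with fewer
  than two neighbours score zero.
* **Average weighted clustering (AWCC)** follows the Schank–Wagner form
  `sum_v c_w(v) w(v) / sum_v w(v)` with a selectable node weight function.
  The default is the **unit** weight — the plain mean of the Zhang–Horvath
  coefficients over all nodes. The degree-weighted alternative
  (`node_weight = "degree"`) is provided, but it has a perverse property for
  robustness ranking: a cohesive node that also carries a weak spurious
  pendant edge contributes a *diluted* coefficient with a *large* weight, so
  removing it can raise the average, masking exactly the nodes the ranking
  is meant to expose. In planted-clique simulations the unit average ranks
  all clique members lowest in 20/20 seeded runs, the degree-weighted
  average in only 12/20; the unit form is therefore the default. (Under
  degree weights, removing an isolated node leaves the average strictly
  unchanged; under unit weights it yields the remaining network's mean.)
* **Robustness ranking** removes each node in turn and reports the AWCC of
  the remainder, ascending — the nodes whose removal hurts cohesion most
  first.
* **Maximal cliques** are enumerated on adjacency alone (igraph); the
  four-node clique of correlated drivers planted by the generator is the
  canonical recovery target.

`write_network_graphml()` exports the graph with all centralities as node
attributes and `rho`, p-value and sign as edge attributes.

## qPCR validation statistics

`relative_quantification()` implements comparative-Ct quantification:
`dCt = Ct_target - Ct_reference` per tissue,
`ddCt = dCt_tumor - dCt_normal`, `RQ = 2^-ddCt`. It is invariant to
per-subject additive Ct offsets, and subjects with incomplete measurements
are excluded with a warning.

`wilcoxon_vs_unity()` tests RQ values against the null value 1 on the
symmetric scale — `log2(RQ)` against 0 — because RQ is log-normal under
Gaussian Ct noise and a signed-rank test wants a symmetric null. Exact
values equal to 1 are dropped (the classical treatment of zeros) and at
least five informative values are required; p-values are exact for 25 or
fewer untied differences, normal-approximated with continuity correction
otherwise.

`power_simulation()` estimates the power of this test by Monte Carlo over
synthetic Ct tables. The Ct noise SD behind published power statements is
never reported, so `ct_sd` is an explicit parameter rather than a hidden
constant; at `ct_sd = 0.5` cycles per measurement (so the per-subject ddCt
noise SD is `2 * ct_sd = 1`), a 14-subject cohort reaches ~91% power for a
2-fold effect at two-sided alpha 0.05, consistent with the 14-subject /
90%-power design convention. The validation report (`qpcr_report()`) emits
both the median with quartiles and the mean, since published tables are
ambiguous about which they show.

## Numerical and interface conventions

* Degenerate inputs fail loudly: zero-variance features are flagged, empty
  signatures warn, mismatched feature universes and unknown nodes are
  errors, negative `ct_sd` is rejected (zero is the legitimate noise-free
  case).
* Tie-breaks are always deterministic (feature id as the final key; majority
  vote ties to the normal class).
* The pipeline (`run_pipeline()`) writes every stage table as TSV plus a
  JSON manifest (versions, seed, parameters, per-stage status); a failing
  stage is recorded in the manifest before the run aborts, and partial
  outputs are retained. A thin Rscript wrapper over the same functions lives
  in `inst/scripts/run_pipeline.R`.

## Problem sizes used by the test suite

The checks are sized for a desk machine: recovery simulations use 50
subject pairs, 60 features (10 planted effects at 3–4 fold, one 4-feature
module at `rho = 0.8`) and 1000-tree forests over 20 seeds — 1000 trees
stand in for the 100 000 a full study would use, which only narrows the
Monte-Carlo spread of OOB error and importances; graph oracles enumerate
all simple paths and all subsets on 500 random graphs of up to 8 nodes;
Wilcoxon exact p-values are verified against full sign-assignment
enumeration up to n = 12; the power simulation uses 2000 replicates.

## Known limitations

* Spearman edge p-values are unadjusted (matching the published p < 0.05
  convention); at signature sizes of tens of nodes a handful of spurious
  edges is expected and visible in the robustness analysis.
* The forest does not implement class weighting or regression targets, and
  numerical equality with the `randomForest` RNG stream is not a goal —
  statistical equivalence is tested instead.
* Amplification-efficiency correction (Pfaffl-type) and multiple reference
  genes are out of scope for the qPCR module.
* The printed degree and AWCC magnitudes of the original networks are not
  reproducible from any weight convention bounded by `|rho| <= 1`; both
  weight modes are provided, neither is asserted against those values.
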