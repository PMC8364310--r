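---
title: "Methods: iterative tau-white-matter pathway searching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: iterative tau-white-matter pathway searching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical machinery: the
model behind the pathway search, the parameters that matter, what the
synthetic-cohort generator does and does not emulate, the numerical choices
made where the design was genuinely open, and the limitations a user should
keep in mind.

## The model

The package asks a chained association question on a structural brain graph:
does tau burden in a gray-matter region co-vary with the microstructural
state of a white-matter tract leaving it, and does that tract's state in turn
co-vary with tau burden in the region at the other end? Both links are
ordinary least-squares models with an intercept, adjusted for age and sex:

* model (a): `metric_edge = b0 + b1 * tau_up + g1 * age + g2 * sex + e`
* model (b): `tau_down = a0 + a1 * metric_edge + g1' * age + g2' * sex + e'`

A connection is accepted as an *association pathway* iff the two-sided
t-tests on `b1` and `a1` are both below `alpha`. OLS with Gaussian errors is
the right reading of this design: both responses are continuous, the
reported effect summaries (adjusted R-squared and its increment) are
OLS-native, and the directionality of the two models is what lets the
covariates sit on the right-hand side of both equations. The conjunction of
two tests at level `alpha` gives a per-connection false-positive rate near
`alpha^2` under the global null (the two statistics share only the edge
metric and are approximately independent when nothing is associated), which
is what the null-calibration test checks empirically.

The search is seed-propagating: regions whose tau-positivity prevalence
exceeds a threshold start the search; accepted destination regions join the
seed set; iterations continue until one finds nothing. Three structural
rules shape the candidate set at each iteration:

1. connections between two current seeds are never tested (no circulation);
2. each directed connection is tested at most once per run — identical data
   would give an identical p-value, so re-testing can only waste time or
   loop;
3. hemispheres are searched independently by default (`hemisphere_mode =
   "separate"`), so inter-hemispheric backbone edges are not candidates.

Iteration labels are per-hemisphere and contiguous from 1. The per-pathway
headline effect size, `r2_diff`, is the adjusted R-squared of model (b)
minus that of the age+sex-only model fitted on the same subjects; model (a)'s
analogue is stored alongside (`r2_diff_up`). Note that adjusted R-squared of
the covariates-only model can be negative in small samples, in which case
`r2_diff` can exceed the full model's adjusted R-squared; the identity
`r2_diff = adj_r2_full - adj_r2_covariates_only` is the defined quantity.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `positivity_cutoff` | 1.23 | SUVR | conventional flortaucipir tau-positivity cutoff; 20 centiloid is a reasonable choice for the amyloid variant |
| `positivity_comparator` | `>` (strict) | — | the boundary has measure zero for a continuous signal; configurable to `>=` |
| `seed_prevalence` | 0.80 | fraction | strict `>`; balances seed count against off-target contamination |
| `backbone_fraction` | 0.10 | fraction of max mean connectivity | liberal cut that removes noise connections while keeping valid ones; sweep 0.04–0.11 provided |
| `alpha` | 0.05 | — | per-model significance; the dual test makes the effective per-connection level ~`alpha^2` |
| `covariates` | age, sex | years; 0/1 | the standard confounders of both tau burden and diffusion metrics |
| `min_n` | 5 | subjects | smallest complete-case sample a model may be fitted on |
| `p_adjust` | `"none"` | — | no correction inside the search; the bootstrap is the stability check. A per-iteration BH option exists |
| `size_correction` | `"mean"` | — | ROI-size denominator `mean(size_i, size_j)`; `"sum"` and `"none"` available |

Predictors are not standardized (p-values are invariant; coefficients stay in
natural units), and sex is a 0/1 indicator. Sign agreement between models
(a) and (b) is recorded but not required for acceptance.

## Numerical and design choices

* **Backbone comparator.** Edges are kept at `mean >= fraction * max`
  (inclusive), so the maximal edge always survives and the backbone is
  invariant to uniform rescaling of all subjects' matrices. The threshold is
  relative to the *group-mean* matrix, not per-subject maxima, and the
  backbone is built once on the full sample.
* **Degenerate fits.** A constant predictor, a rank-deficient design, or
  fewer than `min_n` complete cases abort only the affected connection
  (logged with a reason in `tested_connections`), never the run.
* **Missing edge metrics** are handled by listwise deletion per connection;
  node signals must be complete and the loader enforces it.
* **Determinism.** The search itself has no randomness. Simulation and
  bootstrap take explicit integer seeds; bootstrap replicate `r` uses seed
  `rng_seed + r`, so the stability map is a pure function of (cohort,
  config, `n_boot`, `rng_seed`) and independent of execution order.
* **Bootstrap scope.** Each replicate re-runs positivity, prevalence, seed
  selection and the search; the backbone is *not* rebuilt by default (it is
  a one-time structural construction), and `resample_backbone = TRUE`
  enables full rebuilds for sensitivity analysis.
* **Voting identity** is directed (up -> down) and ignores iteration labels,
  which legitimately vary across resamples; an undirected aggregation is
  available for display.
* **ROI identity** is the pair (name, hemisphere); integer ids are assigned
  from parcellation row order on load, so files with different orderings
  produce identical analyses.
* **Off-target regions** (basal ganglia: pallidum, caudate, putamen,
  thalamus in the 84-region layout) are eligible seeds and are treated
  exactly like every other region; they function as built-in negative
  controls rather than exclusions.

## The synthetic-cohort generator

The generator exists so that every stage of the pipeline can be tested
against known ground truth. It emulates:

* a two-hemisphere parcellation graph (connected random geometric per
  hemisphere plus a few homotopic bridges; optionally the 84-region
  Desikan-Killiany name layout with lognormal ROI sizes, meanlog
  `log(3000)`, sdlog 0.4);
* planted node -> edge -> node chains: effects are specified on the
  correlation scale (`beta1` tau -> metric, `alpha1` metric -> tau per
  link). Every planted variable is built from a unit-variance signal part,
  so the partial correlation of adjacent variables given the covariates
  equals the stated effect and power is directly interpretable in `n`;
* a tau-severity gradient: chain roots and off-target regions receive
  `1.0 + Gamma(shape 3, scale 0.2)` SUVR (mean severity 0.6, giving ~90%
  positivity prevalence at cutoff 1.23, comfortably above the 80% seed
  threshold), downstream chain regions sit near the cutoff (mean 1.12, SD
  0.15), and background regions below it (mean 1.05, SD 0.10);
* age/sex confounding of both tau and every diffusion channel (age ~
  Normal(70, 8) years, sex ~ Bernoulli(0.5); tau gains 0.004 SUVR/year and
  0.03 SUVR for male sex; each metric gains 0.01 channel-SD/year and 0.2
  channel-SD for sex);
* streamline counts: negative-binomial (dispersion 50) around per-edge mean
  counts uniform on [200, 400] scaled by mean endpoint size — so true edges
  agree within a factor of two after normalization and all survive the 10%
  cut — plus spurious counts (mean 6) on a random 8% of non-edges per
  subject, two orders of magnitude below true edges;
* six metric channels at natural scales (MD 0.85 ± 0.06 in 1e-3 mm²/s units,
  FA 0.45 ± 0.05, and so on) with the planted signal injected into the
  configured channel only, in the direction degeneration moves it (MD/Da/Dr
  up, FA/ICVF down); the other channels are confound-plus-noise, mirroring
  per-metric independent runs.

It deliberately does **not** emulate: spatial autocorrelation between
neighboring ROIs, realistic tractography failure modes (crossing-fiber
dropouts, distance bias), site or scanner effects, non-Gaussian metric
noise, correlated metric channels (an option exists but defaults off), or
longitudinal change. Passing tests on these cohorts therefore demonstrates
the *algorithmic* correctness and statistical calibration of the pipeline,
not that a particular clinical dataset would yield any specific pattern.

Null cohorts keep the severity gradient (so seeds are still selected and
connections still tested) but set both effect sizes to zero — the right
negative control for calibration, since the number of tested candidates
matches the planted case.

## Problem sizes in the tests

The test-suite and acceptance scales were chosen to make the statistical
properties sharp at desk scale: 100 random small designs for the OLS oracle;
50 random cohorts of at most 8 regions for equivalence with the brute-force
fixed-point reference; 100 replicates of a 6-node chain at standardized
effects 0.5 with n = 200 for recovery; 100 null cohorts of n = 100 for
calibration; 200 bootstrap replicates at effects 0.7, n = 150 for stability
separation. The analysis scripts use the study-scale configuration: 62
subjects, 84 regions, effects 0.5, 1000 bootstrap replicates.

## Known limitations

* **Greedy seeding interacts with shortcuts.** If the graph contains an edge
  that skips ahead along a chain and that edge shows a chance association,
  the skipped-to region is seeded early and the true incoming link becomes a
  seed-seed connection that is never tested. On resampled data this
  occasionally suppresses a genuine pathway; it is faithful behavior of the
  seed-propagation rules, and the bootstrap frequency table is where it
  shows up. The same mechanism means alpha-nesting of the *directed*
  pathway set is not strictly guaranteed: a shortcut accepted only at the
  larger alpha can flip the direction in which a chain link is traversed,
  so a directed pair present at the smaller alpha may appear reversed at
  the larger one. Undirected nesting is the robust property in practice.
* **No causal claim.** The two regressions impose a direction of
  interpretation, not a causal direction; the method finds association
  structure on a fixed graph from cross-sectional data.
* **No multiple-testing correction inside the search** by design; with many
  seeds and a dense backbone the number of candidates grows, and the
  `alpha^2` per-connection level plus bootstrap stability is the intended
  control. The BH option is available for sensitivity analyses.
* **Sample-size floor.** With fewer than ~30 subjects the dual test is
  underpowered at moderate effects, and bootstrap replicates begin to lose
  seeds to prevalence fluctuation; the generator makes such regimes easy to
  explore before committing to a design.
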