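---
title: "Models and methods: valence-asymmetric social learning of self-perception"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: valence-asymmetric social learning of self-perception}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sociallearn)
```

## The task and the two learning models

The package analyses a social feedback task in which a participant, after
giving a stressful speech, works through trials of the following form: an
evaluative cue ("I was convincing", "I looked anxious") is rated on a
visual analogue scale (VAS, coded 0–1), judges' feedback is shown on the
same scale, and the participant then rates their state self-esteem. After
a delay every cue is re-rated (T2). Two quantities drive all analyses:

* the **feedback mismatch** `dEval = feedback - self-evaluation(T1)`,
  computed on a *favorability* scale (ratings of negatively worded cues
  are recoded as `1 - rating`), so positive `dEval` always means "the
  judges saw me more favorably than I saw myself"; and
* the **valence of feedback** `V`, the recoded feedback value itself, on
  the same 0–1 scale as self-esteem.

Two models capture how people learn from this information.

**Valence-split feedback learning.** The T2 re-evaluation moves from T1 in
proportion to the mismatch, with separate slopes by mismatch sign:

$$\mathrm{SelfEval}(T2) = \mathrm{SelfEval}(T1) +
\begin{cases}\beta_{pos}\,\Delta Eval & \Delta Eval > 0\\
\beta_{neg}\,\Delta Eval & \Delta Eval < 0\end{cases}$$

`fit_valence_betas()` estimates this by OLS of the T2−T1 change on the two
sign-masked mismatch regressors. The printed model fixes the T1
coefficient at one and has no intercept, so none is fitted by default; an
`include_intercept` flag exists because multi-level formulations sometimes
add one. Trials with a mismatch of exactly zero carry no valence
information and are excluded. The difference `beta_pos - beta_neg` is the
**social influence bias**.

**Asymmetric Rescorla–Wagner affective updating.** State self-esteem
`F(t)` follows

$$F(t) = F(t-1) + \alpha \,\mathrm{APE}, \qquad
\mathrm{APE} = V(t) - F(t-1),$$

with `alpha = alpha_pos` for positive affective prediction errors and
`alpha_neg` for negative ones; `F(0)` is the free prior. Because each step
is a convex move toward a value in [0, 1], the trajectory is bounded for
any rates in the unit interval — the simulator relies on this, and a
property test asserts it. The difference `alpha_pos - alpha_neg` is the
**affective updating bias**.

`fit_rw()` minimizes the sum of squared errors between the observed and
modeled time course, with all parameters bound to [0, 1]. The first
self-esteem rating is compared against the model's post-update value for
trial 1: the prior is the pre-task state and the equation indexes
self-esteem from the feedback of the same trial. A rating of exactly the
previous state (APE = 0) updates nothing under either branch. Missing
ratings are dropped from the error term while the recursion still
advances on their feedback, since the latent state must evolve.

### Numerical choices

Local optima are real for the asymmetric model (the two rates exchange
roles as the trajectory crosses the feedback), so the fit launches
bound-constrained L-BFGS-B searches from the grid `{0.1, 0.5, 0.9}` per
free parameter (27 starts for two rates, 9 for one) and keeps the best
SSE. The objective is evaluated at the projection of the proposal onto
the unit box because numerical gradients probe a step beyond active
bounds. Tests verify that the multi-start solution never loses to an
exhaustive 0.02-step grid on small instances.

Model comparison uses the Gaussian least-squares form of the BIC,

$$\mathrm{BIC} = n\,\ln(\mathrm{SSE}/n) + k\,\ln n,$$

with `k = 2` (prior + shared rate) or `k = 3` (prior + two rates). The
profiled-out error variance is excluded identically from both variants,
so only the comparison is meaningful — which is all it is used for. A
perfect fit returns `-Inf` with a `perfect_fit` flag. `cohort_rw()`
reports the per-subject preference and the summed-BIC comparison, since
either aggregation is defensible.

## The synthetic cohort generator

No public data accompany this design, so the package ships a generator
(`generate_cohort()`) whose defaults *are* the study conditions the
analyses assume: 52 trials, two groups of 21 (SAD-like) and 23
(control-like) subjects, half the cues positively worded, feedback drawn
around the participant's own rating with SD 0.15 VAS, and rating /
esteem / T2 noise of 0.05 VAS. Each subject's ground-truth parameters are
drawn from per-group Gaussians clipped to [0, 1]. The group means are
configuration, not estimates: the SAD-like group gets a lower prior
(0.40 vs 0.55), `alpha_neg > alpha_pos` (0.35/0.25) and
`beta_neg > beta_pos` (0.55/0.40), the control-like group the mirror
image — magnitudes chosen once to produce group effects of the size this
literature reports (standardized differences around 0.7–0.9) while
keeping all parameters comfortably inside the unit interval.

Design details worth knowing:

* **Mismatch signs are stratified.** The analysis assumes roughly half
  positive and half negative mismatches per subject. Under iid Gaussian
  draws the per-subject count fluctuates with SD ≈ 3.6 at 52 trials, so
  the simulator instead assigns exactly half the trials (shuffled) a
  positive sign and draws half-normal magnitudes — the marginal mismatch
  distribution is the same zero-mean Gaussian, but the sign count is
  balanced by construction. The plain Gaussian draw is still available as
  `draw_feedback()`. Mismatches that land on exactly zero after clipping
  at the scale bounds are redrawn once, then reflected inward, so every
  trial is sign-classifiable.
* **Clipping applies to data, not models.** Generated ratings are clipped
  to the VAS bounds; the fitted models mirror the printed equations and
  are never clipped.
* **Mediators.** Each of `n_regions` synthetic regions emits per trial
  `M_r = a_r z(dEval) + noise` (standardized units), and the T2 outcome
  gains `mediator_outcome_scale` VAS units per unit of the b-weighted
  mediator sum. The default four regions span the cells a mediation
  analysis must distinguish: both paths, a-only, b-only, neither. Because
  the mediator term enters through within-subject z-scored mismatch, its
  centering offsets the valence-split betas; exact-recovery checks
  therefore switch the coupling off (`mediator_outcome_scale = 0`) along
  with the noise terms.
* **Reproducibility.** One master seed; each subject simulates on an
  independent substream drawn from it, so cohorts are identical no matter
  how subject-level work is scheduled.

What the generator does *not* emulate: within-person coupling between the
two biases (parameters are drawn independently within group, so the
pooled bias inter-correlation in a default cohort comes from the group
difference alone and the partial correlation controlling for group is
near zero); serial dependence in T1 ratings; cue-specific difficulty;
missing trials; and anything about BOLD physiology — region "amplitudes"
are abstract standardized signals. Passing tests therefore show that the
estimators recover the generating process under the stated noise, not
that they would survive every pathology of real behavioral data.

## Group-level inference

`welch_t()` (Welch–Satterthwaite df) serves group comparisons and
`paired_t()` within-group valence comparisons, both two-sided. Effect
sizes follow the conversions that reproduce the printed literature
values at these sample sizes: `d = t * sqrt(1/n1 + 1/n2)` for
independent samples and `d_z = |t| / sqrt(n)` for paired ones. A few
published (t, d) pairs in this literature deviate from these conversions
by 0.01–0.02 (consistent with d computed from raw SDs, which the t
statistic alone cannot recover); the conversions are the package
convention. `partial_correlation()` residualizes both variables on the
covariate and refers `r` to a t distribution with `n - 3` df; a variable
fully explained by the covariate yields r = 0 by definition rather than
the arbitrary correlation of numerically-zero residuals.
`robust_regression()` delegates the IRLS machinery to `MASS::rlm`
(Huber, k = 1.345, MAD scale re-estimated per iteration, 50 iterations,
bisquare by flag) behind a stable result container.

## Multilevel mediation

`subject_paths()` decomposes one subject's trial series into path `a`
(mediator on mismatch), `b` and the direct effect `c'` (outcome on
mediator and mismatch jointly), total effect `c`, and indirect effect
`ab = a*b`; variables are z-scored within subject by default so paths are
comparable across subjects (a raw-scale option remains). The OLS identity
`c = c' + ab` holds to machine precision per subject and is asserted. A
mediator perfectly collinear with the predictor aliases the direct path,
which the pivoted-QR solver maps to zero — the full-mediation limit.

`group_mediation()` is a deliberately transparent summary-statistics
second level: one-sample t-tests across subjects on each path, plus a
bias-corrected percentile bootstrap (default 5,000 subject resamples) for
the mean indirect effect, whose product-term distribution is non-normal.
A significant mean `ab` opposing the sign of the mean total effect is
classified as **suppression**, mirroring the interpretation of
protective activity. `conjunction()` returns the regions significant on
`a`, `b` and `ab` simultaneously. This is simpler than weighted
multilevel mediation estimators; calibration tests (type-I error of the
`ab` test within [0.03, 0.07] under a null b path, ≥90% CI coverage of
the analytically derived standardized indirect effect) bound what the
simplification costs under the generator's conditions.

## Network-mask similarity

`mask_similarity()` scores a subject's contrast vector against a binary
network mask as the Pearson correlation with the 0/1 indicator,
Fisher-z transformed — equivalent, up to a monotone transform, to the
standardized in-mask versus out-of-mask mean difference. The default
abstract grid is 1,000 parcels with 20% in-network, matching the
coverage of canonical frontoparietal parcellations; the operation is
agnostic to whether the vector indexes parcels or voxels.
`group_network_test()` wires the similarities into the same Welch and
Spearman machinery used for the behavioral biases.

## The pipeline

`run_pipeline()` chains the stages — generate, write, valence betas, RW
fits, group statistics, per-region mediation, network similarity,
report — under one master seed with per-stage substreams, and is
idempotent: re-running a configuration reproduces every output file
byte-for-byte. `validate_config()` accepts YAML (see
`inst/extdata/default_config.yaml`) and reports *all* violations at
once rather than failing on the first. The markdown report is rendered
exclusively from the serialized CSV/JSON intermediates, so every number
in it traces to a file. The network stage adds between-subject signal
noise (SD 1 in parcel-noise units) on top of a group offset (0.8) and a
bias-linked slope (0.5): without it the similarity score would be an
almost deterministic function of the learning bias, which no
between-subject imaging measure is.

## Problem sizes used in the shipped checks

The test-suite simulations use the sizes at which the statistical claims
are stated: 100 subjects for parameter recovery and BIC selection, 500
small cohorts (40 subjects) for the null-mediation error rate, 100
cohorts for CI coverage, suppression and conjunction power, 10,000
replicates for t-test calibration, and 100 default-size cohorts for the
group-by-valence design check. These sizes make the Monte-Carlo error
small relative to each stated bound while keeping a full run in the low
minutes on one core.

## Known limitations

* Learning rates and betas are estimated per subject and aggregated
  (summary statistics), not shrunk hierarchically; with 52 trials per
  subject the per-subject estimates are stable, but small-trial uses
  would benefit from partial pooling, which is out of scope.
* The BIC form assumes iid Gaussian residuals; autocorrelated esteem
  noise would favor the larger model slightly.
* The bootstrap CI resamples subjects only; trial-level uncertainty
  enters through the per-subject path estimates.
* The mediation second level weights subjects equally rather than by
  first-level precision.
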