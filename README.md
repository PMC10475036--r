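# sociallearn

Valence-asymmetric social learning of self-perception: simulation and
analysis of a speech-feedback task in which participants rate their own
performance (VAS, 0–1), receive judges' feedback drawn around their own
rating, track trial-wise state self-esteem, and re-rate every item after
a delay. The design targets the question at the heart of computational
work on social anxiety: do people update their self-image more from
negative than from positive social feedback, and is that asymmetry larger
in socially anxious individuals?

Two models carry the analysis. The T2 re-evaluation follows a
valence-split feedback-learning rule,

    SelfEval(T2) = SelfEval(T1) + β_pos·ΔEval   (ΔEval > 0)
    SelfEval(T2) = SelfEval(T1) + β_neg·ΔEval   (ΔEval < 0)

where ΔEval is the judge-minus-self mismatch on a favorability scale;
`β_pos − β_neg` is the *social influence bias*. State self-esteem follows
an asymmetric Rescorla–Wagner recursion,

    F(t) = F(t−1) + α·APE,   APE = V_feedback(t) − F(t−1)

with separate learning rates `α_pos`/`α_neg` for positive and negative
affective prediction errors (all parameters bound to [0, 1], fitted by
multi-start constrained least squares, 1- vs 2-rate variants compared by
BIC); `α_pos − α_neg` is the *affective updating bias*.

Around these sit the rest of the pipeline: group inference (paired and
Welch t-tests with the effect-size conversions `d = t·√(1/n1+1/n2)` and
`d_z = |t|/√n`, Pearson/Spearman/partial correlations, Fisher z, robust
Huber regression), trial-level multilevel mediation (paths a, b, ab with
a bias-corrected bootstrap and suppression/conjunction logic),
network-mask similarity scoring, and a seeded synthetic-cohort generator
with known ground truth — the study's raw data are not deposited, so
every analysis is exercised against cohorts whose generating parameters
are known exactly.

## Worked example

```r
library(sociallearn)

co <- generate_cohort(generator_config(seed = 1))
co
#> Synthetic feedback-task cohort
#>   44 subjects (HC n=23, SAD n=21), 52 trials each
#>   4 mediator regions, master seed 1

# per-subject valence-split learning betas, then the group-by-valence test
b <- cohort_betas(co)
welch_t(b$bias[b$group == "HC"], b$bias[b$group == "SAD"])
#> welch t-test: t(39.1) = 4.03, p = 0.0002531, Cohen's d = 1.22

# asymmetric Rescorla-Wagner fit for one subject
s <- split_subjects(co)[["hc_22"]]
fit_rw(s$self_esteem, s$v_feedback, n_rates = 2)
#> Asymmetric RW fit (2-rate, 52 observed trials)
#>   prior = 0.5475, alpha_pos = 0.4505, alpha_neg = 0.2163
#>   SSE = 0.12742, BIC = -300.745
```

The Welch test above compares the per-subject social influence bias
between groups: the control-like group (generated with a positive-bias
mean) sits about 1.2 pooled standard deviations above the SAD-like group
(generated with a negative-bias mean), and the fitted subject shows the
control-typical pattern of updating self-esteem roughly twice as strongly
from positive as from negative prediction errors. Effect-size conversion
from a published statistic is a one-liner:

```r
cohen_d_from_welch_t(2.15, 21, 23)
#> [1] 0.6489201
```

The full pipeline — generate, fit both models, group statistics,
per-region mediation, network similarity, markdown report — runs from a
single seeded configuration (YAML or in-code):

```r
run_pipeline(default_run_config(seed = 1), "out/")
```

## Package layout

- `R/generator.R` — synthetic cohort generator (`generate_cohort`,
  `simulate_subject`, `draw_feedback`, cohort I/O)
- `R/feedback_learning.R` — valence-split betas (`fit_valence_betas`,
  `cohort_betas`)
- `R/affective_updating.R` — asymmetric RW model (`predict_trajectory`,
  `fit_rw`, `bic_sse`, `updating_bias`, `cohort_rw`)
- `R/inference_stats.R` — t-tests, correlations, Fisher z, robust
  regression
- `R/mediation.R` — per-subject paths, group mediation, conjunction
- `R/network_similarity.R` — mask similarity and group network tests
- `R/pipeline.R` — YAML config validation and the end-to-end run
- `vignettes/sociallearn-methods.Rmd` — models, assumptions, design
  decisions and limitations
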