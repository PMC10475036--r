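# Shared fixture builders: everything is generated in code at test time.

# Small cohort for fast structural tests.
small_config <- function(seed = 1, ...) {
  generator_config(n_trials = 12, n_subjects_per_group = c(SAD = 2, HC = 2),
                   seed = seed, ...)
}

# All stochastic terms and the mediator->outcome coupling off, so both
# models are exactly identifiable from the simulated data.
zero_noise_config <- function(seed = 1, ...) {
  generator_config(rating_noise_sd = 0, esteem_noise_sd = 0, t2_noise_sd = 0,
                   mediator_outcome_scale = 0, seed = seed, ...)
}

# One-group config with identical parameter distributions for both labels
# (handy for null calibrations).
flat_group_params <- function(beta_pos = 0.5, beta_neg = 0.5, prior = 0.5,
                              alpha_pos = 0.3, alpha_neg = 0.3,
                              trait = 0.5, sd = 0) {
  g <- list(beta_pos = c(beta_pos, sd), beta_neg = c(beta_neg, sd),
            prior = c(prior, sd), alpha_pos = c(alpha_pos, sd),
            alpha_neg = c(alpha_neg, sd), trait_eval_mean = c(trait, 0.05))
  list(SAD = g, HC = g)
}

# Deterministic subject parameter list.
subject_params <- function(beta_pos = 0.5, beta_neg = 0.5, prior = 0.5,
                           alpha_pos = 0.3, alpha_neg = 0.3, trait = 0.5,
                           id = "s01", group = "HC") {
  list(subject_id = id, group = group, beta_pos = beta_pos,
       beta_neg = beta_neg, prior = prior, alpha_pos = alpha_pos,
       alpha_neg = alpha_neg, trait_eval_mean = trait)
}
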