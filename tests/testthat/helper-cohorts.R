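# Shared desk-scale configurations. The "midrange" settings move the
# post-operative mean away from the 48-point ceiling so that the analysis
# model's linearity holds essentially exactly and generative parameters are
# recoverable; the default configuration keeps the survey-like ceiling spike.

cfg_midrange <- function(...) {
  cohort_config(mean_postop = 28, sigma_eps = 7,
                miss = miss_config(enabled = FALSE), ...)
}

# MAR on the outcome only: response driven by length of stay (observed,
# outcome-correlated), everything else observed
miss_mar_q2 <- function(eta0 = 1.2, los = -0.12) {
  miss_config(r1 = list(eta0 = 20, los = 0, wait = 0, private = 0,
                        teaching = 0, log_volume = 0, sd_phi = 0),
              r2 = list(eta0 = eta0, los = los, wait = 0, previous = 0,
                        preadmission = 0, assisted = 0, lives_alone = 0,
                        sd_phi = 0, delta = 0),
              covariate_mcar = c(ethnicity = 0, duration = 0))
}

# MNAR on the outcome only: response depends directly on the post-op total
miss_mnar_q2 <- function(delta, eta0 = 0.6, sd_phi = 0.3) {
  miss_config(r1 = list(eta0 = 20, los = 0, wait = 0, private = 0,
                        teaching = 0, log_volume = 0, sd_phi = 0),
              r2 = list(eta0 = eta0, los = 0, wait = 0, previous = 0,
                        preadmission = 0, assisted = 0, lives_alone = 0,
                        sd_phi = sd_phi, delta = delta),
              covariate_mcar = c(ethnicity = 0, duration = 0))
}

small_complete_cohort <- function(seed = 5, n_providers = 12, volume = 80) {
  generate_cohort(cfg_midrange(n_providers = n_providers,
                               volume_mean = volume, seed = seed))
}
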