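test_that("same seed reproduces the cohort bit for bit", {
  a <- generate_cohort(cohort_config(n_providers = 8, volume_mean = 40, seed = 9))
  b <- generate_cohort(cohort_config(n_providers = 8, volume_mean = 40, seed = 9))
  expect_identical(a$patients, b$patients)
  expect_identical(a$truth, b$truth)
  expect_identical(a$providers, b$providers)
})

test_that("with missingness off the patients equal the truth", {
  co <- small_complete_cohort()
  expect_true(all(co$patients$R1 == 1L))
  expect_true(all(co$patients$R2 == 1L))
  tr <- co$truth
  tr$casemix_mean <- NULL
  expect_identical(co$patients, tr)
})

test_that("questionnaire hierarchy and block deletion hold", {
  co <- generate_cohort(cohort_config(n_providers = 15, volume_mean = 60, seed = 2))
  p <- co$patients
  expect_true(all(p$R2 <= p$R1))              # Q2 observed => Q1 observed
  q1 <- as.matrix(p[, paste0("q1_item_", 1:12)])
  q2 <- as.matrix(p[, paste0("q2_item_", 1:12)])
  expect_true(all(is.na(q1[p$R1 == 0, ])))
  expect_true(all(is.na(q2[p$R2 == 0, ])))
  expect_true(all(!is.na(q2[p$R2 == 1, ])))   # no item non-response by default
  obs <- !is.na(q1)
  expect_true(all(q1[obs] %in% 0:4))
})

test_that("no provider effect and tiny noise pins provider means to case mix", {
  co <- generate_cohort(cfg_midrange(n_providers = 10, volume_mean = 300,
                                     sigma_u = 0, sigma_eps = 0.01, seed = 21))
  tr <- co$truth
  dev <- tapply(tr$y2_total - tr$casemix_mean, tr$provider_id, mean)
  n_j <- tapply(tr$y2_total, tr$provider_id, length)
  # per-provider averaging leaves only categorisation noise (sd below ~6)
  expect_true(all(abs(dev) < 4 * 6 / sqrt(n_j)))
  expect_lt(abs(mean(tr$y2_total - tr$casemix_mean)), 0.2)
})

test_that("cohort pre-op mean matches a direct simulation of the threshold model", {
  cfg <- cohort_config(n_providers = 50, volume_mean = 200,
                       miss = miss_config(enabled = FALSE), seed = 31)
  co <- generate_cohort(cfg)

  # independent oracle: straight-line simulation of the generative equations
  set.seed(99)
  n <- 5e5
  xb <- numeric(n)
  for (nm in names(cfg$covariate_probs)) {
    p <- cfg$covariate_probs[[nm]]
    xb <- xb + cfg$beta1[[nm]][sample.int(length(p), n, TRUE, prob = p)]
  }
  mean_xb <- sum(vapply(names(cfg$covariate_probs), function(nm)
    sum(cfg$covariate_probs[[nm]] * cfg$beta1[[nm]]), numeric(1)))
  eta <- cfg$mean_preop - mean_xb + xb + stats::rnorm(n, 0, cfg$sigma_1)
  mu <- total_inverse(cfg$thresholds)(pmin(pmax(eta, 0.1), 47.9))
  tot <- numeric(n)
  for (k in 1:12) {
    tot <- tot + latent_to_category(mu + stats::rnorm(n), cfg$thresholds[k, ])
  }
  oracle_mean <- mean(tot)

  mc_se <- sd(co$truth$y1_total) / sqrt(nrow(co$truth))
  expect_lt(abs(mean(co$truth$y1_total) - oracle_mean), 3 * mc_se + 0.05)
})

test_that("selection model collapses to the stated marginal rates", {
  co <- small_complete_cohort(seed = 13, n_providers = 20, volume = 100)
  null_miss <- miss_config(
    r1 = list(eta0 = 20, los = 0, wait = 0, private = 0, teaching = 0,
              log_volume = 0, sd_phi = 0),
    r2 = list(eta0 = 0, los = 0, wait = 0, previous = 0, preadmission = 0,
              assisted = 0, lives_alone = 0, sd_phi = 0, delta = 0),
    covariate_mcar = c(ethnicity = 0, duration = 0))
  co$providers$phi1_true <- co$providers$phi2_true <- 0
  p <- apply_missingness(co$truth, co$providers, null_miss, seed = 3)
  # logit^{-1}(0) = 0.5 for Q2; saturated link forces Q1 on
  expect_true(all(p$R1 == 1L))
  n <- nrow(p)
  expect_lt(abs(mean(p$R2) - 0.5), 3 * sqrt(0.25 / n))

  sat <- miss_config(
    r1 = list(eta0 = 20, los = 0, wait = 0, private = 0, teaching = 0,
              log_volume = 0, sd_phi = 0),
    r2 = list(eta0 = 20, los = 0, wait = 0, previous = 0, preadmission = 0,
              assisted = 0, lives_alone = 0, sd_phi = 0, delta = 0),
    covariate_mcar = c(ethnicity = 0, duration = 0))
  p2 <- apply_missingness(co$truth, co$providers, sat, seed = 4)
  expect_true(all(p2$R2 == 1L))
  expect_identical(p2$y2_total, co$truth$y2_total)
})

test_that("MCAR missingness leaves responders and non-responders exchangeable", {
  set.seed(77)
  pvals <- replicate(6, {
    co <- generate_cohort(cohort_config(
      n_providers = 15, volume_mean = 100,
      miss = miss_mnar_q2(delta = 0, eta0 = 0, sd_phi = 0),
      seed = sample.int(1e6, 1)))
    p <- co$patients
    suppressWarnings(stats::chisq.test(table(p$age_band, p$R2))$p.value)
  })
  # nominal-level behaviour: not systematically small
  expect_gt(mean(pvals), 0.2)
  expect_gt(max(pvals), 0.1)
})

test_that("outcome-dependent selection orders responder and non-responder outcomes", {
  co <- generate_cohort(cohort_config(n_providers = 20, volume_mean = 150,
                                      miss = miss_mnar_q2(delta = 0.1),
                                      seed = 17))
  p <- co$patients
  y_true <- co$truth$y2_total
  expect_gt(mean(y_true[p$R2 == 1]), mean(y_true[p$R2 == 0]))
})

test_that("configuration validation rejects bad inputs", {
  expect_error(cohort_config(nonsense = 1), "unknown")
  expect_error(generate_cohort(cohort_config(
    thresholds = matrix(c(1, 0.5, 0.2, 0.1), 1))), "strictly increasing")
  bad <- cohort_config()
  bad$covariate_probs$sex <- c(0.7, 0.6)
  expect_error(generate_cohort(bad), "sum to 1")
})
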