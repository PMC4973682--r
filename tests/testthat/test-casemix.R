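test_that("analysis model recovers the generative parameters at scale", {
  co <- generate_cohort(cfg_midrange(n_providers = 50, volume_mean = 200,
                                     seed = 7))
  fit <- fit_analysis_model(co$truth)
  se <- sqrt(diag(as.matrix(stats::vcov(fit$model))))
  expect_lt(abs(fit$gamma - 0.45), 3 * se["y1_total"])
  expect_lt(abs(unname(fit$beta["ethnicitynonwhite"]) - (-1.5)),
            3 * se["ethnicitynonwhite"])
  expect_lt(abs(unname(fit$beta["comorbidity2+"]) - (-2.5)),
            3 * se["comorbidity2+"])
  # sigma_u: MC error ~ sigma_u / sqrt(2 (J - 1))
  expect_lt(abs(fit$sigma_u - 1.5), 3 * 1.5 / sqrt(2 * 49))
  expect_gt(fit$sigma_eps, 7)   # configured residual plus categorisation noise
})

test_that("null provider effect estimates at the boundary", {
  co <- generate_cohort(cfg_midrange(n_providers = 30, volume_mean = 100,
                                     sigma_u = 0, seed = 8))
  fit <- fit_analysis_model(co$truth)
  expect_lt(fit$sigma_u, 0.4)
  expect_lt(max(abs(fit$u_hat)), 1)
})

test_that("adding a constant shifts only the intercept", {
  co <- small_complete_cohort(seed = 9, n_providers = 10, volume = 50)
  d <- co$truth
  f0 <- fit_analysis_model(d)
  d2 <- d
  d2$y2_total <- d2$y2_total + 5
  f1 <- fit_analysis_model(d2)
  expect_equal(f1$alpha, f0$alpha + 5, tolerance = 1e-6)
  expect_equal(f1$beta, f0$beta, tolerance = 1e-6)
  expect_equal(f1$gamma, f0$gamma, tolerance = 1e-6)
  expect_equal(f1$sigma_u, f0$sigma_u, tolerance = 1e-5)
  expect_equal(f1$sigma_eps, f0$sigma_eps, tolerance = 1e-5)
})

test_that("singular designs are rejected with the offending column named", {
  co <- small_complete_cohort(seed = 10, n_providers = 5, volume = 30)
  d <- co$truth
  d$duration <- d$ethnicity   # perfectly collinear factor copy
  levels(d$duration) <- c("<1y", "1-5y", ">5y")[c(1, 2)]
  expect_error(fit_analysis_model(d), "collinear")
  expect_error(fit_analysis_model(d[0, ]), "at least 2 providers|completed")
})

test_that("indirect standardisation matches hand evaluation", {
  d <- data.frame(provider_id = c("A", "A"), y2_total = c(30, 45))
  fake_fit <- structure(list(model = NULL), class = "analysis_fit")
  est <- standardize_providers(d, fake_fit, yhat = c(30, 30))
  # ratios 1.0 and 1.5 -> rho = 1.25; national mean 37.5 -> y_tilde = 46.875
  expect_equal(est$rho, 1.25)
  expect_equal(est$y_tilde, 1.25 * mean(d$y2_total))
  expect_equal(attr(est, "ybar2"), 37.5)

  # identity standardisation: observed equals expected
  d2 <- data.frame(provider_id = rep("B", 3), y2_total = c(20, 30, 40))
  est2 <- standardize_providers(d2, fake_fit, yhat = c(20, 30, 40))
  expect_equal(est2$rho, 1)
  expect_equal(est2$y_tilde, mean(d2$y2_total))

  # a provider 10% above expectation lands at 1.1 x national mean
  d3 <- data.frame(provider_id = rep("C", 4), y2_total = 1.1 * c(20, 25, 30, 35))
  est3 <- standardize_providers(d3, fake_fit, yhat = c(20, 25, 30, 35))
  expect_equal(est3$rho, 1.1, tolerance = 1e-12)
  expect_equal(est3$y_tilde, 1.1 * mean(d3$y2_total), tolerance = 1e-12)

  expect_error(standardize_providers(d, fake_fit, yhat = c(-1, 30)),
               "non-positive")
})

test_that("volume-weighted mean standardisation factor is ~1 on real fits", {
  co <- small_complete_cohort(seed = 12, n_providers = 15, volume = 60)
  fit <- fit_analysis_model(co$truth)
  est <- standardize_providers(co$truth, fit)
  expect_equal(sum(est$rho * est$n) / sum(est$n), 1, tolerance = 0.01)
  expect_equal(est$y_tilde, est$rho * attr(est, "ybar2"))
})

test_that("Rubin pooling matches hand evaluation", {
  p <- pool_rubin(c(1, 3), c(1, 1))
  expect_equal(p$estimate, 2)
  expect_equal(p$V_W, 1)
  expect_equal(p$V_B, 2)
  expect_equal(p$total, 1 + 1.5 * 2)

  same <- pool_rubin(rep(4.2, 6), rep(0.3, 6))
  expect_equal(same$V_B, 0)
  expect_equal(same$total, same$V_W)

  single <- pool_rubin(5, 2)
  expect_equal(single$estimate, 5)
  expect_equal(single$total, 2)
  expect_equal(single$V_B, 0)

  expect_error(pool_rubin(numeric(0), numeric(0)), "no estimates")
  expect_error(pool_rubin(c(1, 2), c(1, -1)), "non-negative")
  # pooled total variance never below the within component
  set.seed(4)
  for (i in 1:10) {
    est <- stats::rnorm(7); v <- stats::runif(7)
    pr <- pool_rubin(est, v)
    expect_gte(pr$total, pr$V_W)
  }
})

test_that("complete-case filter drops exactly the incomplete records", {
  co <- generate_cohort(cohort_config(n_providers = 10, volume_mean = 50,
                                      seed = 14))
  cc <- complete_cases(co$patients)
  expect_false(anyNA(cc[, c(paste0("q1_item_", 1:12), paste0("q2_item_", 1:12),
                            "ethnicity", "duration")]))
  expect_true(all(cc$R2 == 1))
  # nothing complete was dropped
  n_complete <- sum(stats::complete.cases(
    co$patients[, c(paste0("q1_item_", 1:12), paste0("q2_item_", 1:12),
                    "age_band", "sex", "ethnicity", "comorbidity",
                    "deprivation", "duration")]))
  expect_identical(nrow(cc), n_complete)
})
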