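test_that("control limits follow the z * sigma / sqrt(n) formula", {
  lim <- control_limits(38, 9.5, volumes = 100)
  tab <- lim$table
  expect_equal(tab$lower_0.95, 38 - 1.959964 * 9.5 / 10, tolerance = 1e-6)
  expect_equal(tab$upper_0.95, 38 + 1.959964 * 9.5 / 10, tolerance = 1e-6)
  expect_equal(round(tab$lower_0.95, 3), 36.138)
  expect_equal(round(tab$upper_0.95, 3), 39.862)

  # nested bands at every volume, converging to the mean
  lim2 <- control_limits(38, 9.5, volumes = c(10, 50, 200, 1e6))
  t2 <- lim2$table
  expect_true(all(t2$lower_0.998 <= t2$lower_0.95))
  expect_true(all(t2$upper_0.95 <= t2$upper_0.998))
  expect_true(all(diff(t2$lower_0.95) > 0))    # widths shrink with volume
  expect_lt(t2$upper_0.998[4] - 38, 0.03)

  ex <- control_limits(38, 9.5, volumes = 100, exact_multipliers = TRUE)
  expect_equal(ex$z, c(2, 3))
  expect_error(control_limits(38, 0, volumes = 10), "positive")
  expect_error(control_limits(38, 9.5, volumes = 0), ">= 1")
})

test_that("classification matches an interval-membership oracle", {
  lim <- control_limits(40, 8)
  n <- 64
  sweep <- seq(34, 46, by = 0.05)
  got <- classify_providers(sweep, rep(n, length(sweep)), lim)

  oracle <- vapply(sweep, function(y) {
    lo95 <- 40 - 1.959964 * 8 / sqrt(n); hi95 <- 40 + 1.959964 * 8 / sqrt(n)
    lo998 <- 40 - 3.090232 * 8 / sqrt(n); hi998 <- 40 + 3.090232 * 8 / sqrt(n)
    if (y < lo998) "negative_alarm"
    else if (y > hi998) "positive_alarm"
    else if (y < lo95) "negative_alert"
    else if (y > hi95) "positive_alert"
    else "in_control"
  }, character(1))
  expect_identical(as.character(got), oracle)
  # ordered traversal: alarm -> alert -> in control -> alert -> alarm
  expect_identical(rle(as.character(got))$values,
                   c("negative_alarm", "negative_alert", "in_control",
                     "positive_alert", "positive_alarm"))
})

test_that("centre and exact-limit points are inside", {
  lim <- control_limits(40, 8)
  expect_identical(as.character(classify_providers(40, 100, lim)), "in_control")
  # boundary convention checked around a zero mean so the limit values are
  # exactly representable: a point on a limit is inside it
  lim0 <- control_limits(0, 8)
  on_inner <- lim0$z[1] * 8 / sqrt(100)
  on_outer <- -lim0$z[2] * 8 / sqrt(100)
  expect_identical(as.character(classify_providers(on_inner, 100, lim0)),
                   "in_control")
  expect_identical(as.character(classify_providers(on_outer, 100, lim0)),
                   "negative_alert")
  expect_identical(as.character(classify_providers(-8, 100, lim0)),
                   "negative_alarm")
})

test_that("status is invariant to affine rescaling", {
  set.seed(6)
  y <- stats::rnorm(50, 40, 2)
  n <- sample(20:500, 50, replace = TRUE)
  lim <- control_limits(40, 8)
  s1 <- classify_providers(y, n, lim)
  a <- 2.5; b <- -7
  lim2 <- control_limits(a * 40 + b, a * 8)
  s2 <- classify_providers(a * y + b, n, lim2)
  expect_identical(s1, s2)
})

test_that("growing volume never widens the band around a provider", {
  lim <- control_limits(40, 8)
  y <- 41.2
  stat_small <- classify_providers(y, 50, lim)
  stat_big <- classify_providers(y, 800, lim)
  # with more volume the same deviation can only look as or more extreme
  expect_gte(as.integer(stat_big), as.integer(stat_small))
  widths <- 2 * 1.959964 * 8 / sqrt(c(50, 100, 400, 800))
  expect_true(all(diff(widths) < 0))
})

test_that("tariff eligibility needs both performance and collection", {
  expect_true(bpt_eligibility(factor("in_control", levels = promperf:::status_levels), 0.60))
  expect_false(bpt_eligibility(factor("negative_alarm", levels = promperf:::status_levels), 0.90))
  expect_false(bpt_eligibility(factor("positive_alarm", levels = promperf:::status_levels), 0.40))
  # threshold is exclusive
  expect_false(bpt_eligibility(factor("in_control", levels = promperf:::status_levels), 0.5))
  expect_error(bpt_eligibility(factor("in_control"), 1.2), "0, 1", fixed = TRUE)
})

test_that("assess_providers partitions every provider into one status", {
  set.seed(8)
  est <- data.frame(provider_id = sprintf("P%02d", 1:40),
                    y_tilde = stats::rnorm(40, 38, 1.5),
                    n = sample(30:400, 40, TRUE),
                    response_rate = stats::runif(40, 0.3, 0.95))
  a <- assess_providers(est, mean = 38, sigma_pop = 9.5)
  expect_identical(sum(a$status_table$n), 40L)
  expect_identical(nrow(a$assessments), 40L)
  expect_equal(sum(a$status_table$pct), 100, tolerance = 0.3)
  expect_false(anyNA(a$assessments$status))
  neg <- a$assessments$status == "negative_alarm"
  expect_true(all(!a$assessments$bpt_eligible[neg]))
  low <- a$assessments$response_rate <= 0.5
  expect_true(all(!a$assessments$bpt_eligible[low]))

  one <- assess_providers(est[3, ], mean = 38, sigma_pop = 9.5)
  expect_identical(sum(one$status_table$n), 1L)
})
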