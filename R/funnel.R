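status_levels <- c("negative_alarm", "negative_alert", "in_control",
                   "positive_alert", "positive_alarm")

#' Funnel-plot control limits
#'
#' Control limits around the national mean narrow with provider volume as
#' `mean +/- z * sigma_pop / sqrt(n)`. The conventional funnel levels are
#' 95% (nominal `z = 1.959964`, often described as "2 standard deviations")
#' and 99.8% (`z = 3.090232`, "3 standard deviations"); set
#' `exact_multipliers = TRUE` to use literal 2 and 3. No over-dispersion
#' adjustment is applied.
#'
#' @param mean national mean of the standardised outcome.
#' @param sigma_pop between-patient SD of the standardised outcome.
#' @param volumes provider volumes at which to tabulate the limits.
#' @param levels coverage levels of the inner and outer bands.
#' @param exact_multipliers use z = 2 and 3 instead of the nominal normal
#'   quantiles.
#' @return a `funnel_limits` object; its `table` element has one row per
#'   volume with lower/upper bounds per level.
#' @export
control_limits <- function(mean, sigma_pop, volumes = NULL,
                           levels = c(0.95, 0.998), exact_multipliers = FALSE) {
  if (sigma_pop <= 0) stop("sigma_pop must be positive")
  levels <- sort(levels)
  z <- if (exact_multipliers && identical(sort(levels), c(0.95, 0.998))) {
    c(2, 3)
  } else {
    stats::qnorm(1 - (1 - levels) / 2)
  }
  obj <- structure(list(mean = mean, sigma_pop = sigma_pop,
                        levels = levels, z = z),
                   class = "funnel_limits")
  if (!is.null(volumes)) {
    if (any(volumes < 1)) stop("volumes must be >= 1")
    tab <- data.frame(n = volumes)
    half <- outer(sigma_pop / sqrt(volumes), z)
    for (l in seq_along(levels)) {
      tab[[sprintf("lower_%s", format(levels[l]))]] <- mean - half[, l]
      tab[[sprintf("upper_%s", format(levels[l]))]] <- mean + half[, l]
    }
    obj$table <- tab
  }
  obj
}

#' @export
print.funnel_limits <- function(x, ...) {
  cat(sprintf("Funnel limits: mean %.3f, sigma_pop %.3f, levels %s (z = %s)\n",
              x$mean, x$sigma_pop, paste(x$levels, collapse = "/"),
              paste(round(x$z, 3), collapse = "/")))
  invisible(x)
}

#' Classify providers against funnel control limits
#'
#' A provider strictly outside the outer band is an alarm, strictly outside
#' the inner band (but within the outer) an alert, otherwise in control;
#' the sign follows the side of the mean. A point exactly on a limit is
#' inside it.
#'
#' @param y_tilde standardised provider outcomes.
#' @param n provider volumes.
#' @param limits a [control_limits()] object.
#' @return factor with levels `negative_alarm`, `negative_alert`,
#'   `in_control`, `positive_alert`, `positive_alarm`.
#' @export
classify_providers <- function(y_tilde, n, limits) {
  stopifnot(length(y_tilde) == length(n))
  half_inner <- limits$z[1] * limits$sigma_pop / sqrt(n)
  half_outer <- limits$z[2] * limits$sigma_pop / sqrt(n)
  dev <- y_tilde - limits$mean
  status <- ifelse(dev > half_outer, "positive_alarm",
            ifelse(dev > half_inner, "positive_alert",
            ifelse(dev < -half_outer, "negative_alarm",
            ifelse(dev < -half_inner, "negative_alert", "in_control"))))
  factor(status, levels = status_levels)
}

#' Best-practice tariff eligibility
#'
#' Providers qualify for the bonus iff they are not performing statistically
#' significantly below the benchmark (no negative alarm status) and they
#' collected PROMs for more than the required share of eligible patients
#' (over 50% by default).
#'
#' @param status a status factor from [classify_providers()].
#' @param response_rate per-provider PROM collection rate in `[0, 1]`.
#' @param threshold minimum collection rate (exclusive).
#' @return logical vector.
#' @export
bpt_eligibility <- function(status, response_rate, threshold = 0.5) {
  if (any(response_rate < 0 | response_rate > 1, na.rm = TRUE)) {
    stop("response_rate must lie in [0, 1]")
  }
  status != "negative_alarm" & response_rate > threshold
}

#' Assess all providers and tabulate funnel status
#'
#' Builds limits from the (pooled) national mean and population SD,
#' classifies every provider at its volume, applies the best-practice
#' tariff rule, and returns the five-category status frequency table. Under
#' a complete-case analysis the volumes are the complete-case counts; under
#' multiple imputation they are the full eligible counts (the funnel "volume
#' effect").
#'
#' @param estimates data frame with `provider_id`, `y_tilde`, `n`, and
#'   optionally `response_rate`.
#' @param mean,sigma_pop national mean and population SD of the
#'   standardised outcome.
#' @param mode label recorded on the output (`"cca"`, `"mi"`, `"mnar"`).
#' @param bpt_threshold collection-rate threshold for the tariff rule.
#' @param exact_multipliers see [control_limits()].
#' @return a `provider_assessment` list: `assessments` (per-provider data
#'   frame with `status` and `bpt_eligible`), `status_table` (counts and
#'   percentages), and the `limits` used.
#' @export
assess_providers <- function(estimates, mean, sigma_pop, mode = "mi",
                             bpt_threshold = 0.5, exact_multipliers = FALSE) {
  limits <- control_limits(mean, sigma_pop, exact_multipliers = exact_multipliers)
  status <- classify_providers(estimates$y_tilde, estimates$n, limits)
  rr <- if ("response_rate" %in% names(estimates)) estimates$response_rate else NA_real_
  ass <- data.frame(provider_id = estimates$provider_id,
                    y_tilde = estimates$y_tilde,
                    n = estimates$n,
                    response_rate = rr,
                    status = status,
                    stringsAsFactors = FALSE)
  ass$bpt_eligible <- ifelse(is.na(ass$response_rate), NA,
                             bpt_eligibility(status, ass$response_rate,
                                             bpt_threshold))
  ass$mode <- mode
  structure(list(assessments = ass,
                 status_table = status_table(status, mode = mode),
                 limits = limits),
            class = "provider_assessment")
}

#' Five-category status frequency table
#'
#' @param status a status factor.
#' @param mode label column.
#' @return data frame with counts and percentages per status.
#' @export
status_table <- function(status, mode = NA_character_) {
  counts <- table(factor(status, levels = status_levels))
  data.frame(mode = mode,
             status = factor(status_levels, levels = status_levels),
             n = as.integer(counts),
             pct = round(100 * as.integer(counts) / max(sum(counts), 1), 1),
             row.names = NULL)
}

#' @export
print.provider_assessment <- function(x, ...) {
  cat("Provider assessment (", x$assessments$mode[1], " mode, ",
      nrow(x$assessments), " providers)\n", sep = "")
  print(x$status_table)
  invisible(x)
}

#' Funnel coordinates for plotting
#'
#' Tabulates provider points and smooth control-limit curves over the
#' observed volume range, ready for export or plotting with any graphics
#' system.
#'
#' @param assessment a [assess_providers()] result.
#' @param n_grid number of volumes at which to evaluate the limit curves.
#' @return list of data frames `points` and `limits`.
#' @export
funnel_coordinates <- function(assessment, n_grid = 200) {
  lim <- assessment$limits
  nr <- range(assessment$assessments$n)
  grid <- unique(round(exp(seq(log(max(nr[1], 1)), log(nr[2]), length.out = n_grid))))
  list(points = assessment$assessments,
       limits = control_limits(lim$mean, lim$sigma_pop, volumes = grid,
                               levels = lim$levels)$table)
}
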