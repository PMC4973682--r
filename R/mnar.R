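#' Importance weights for imputations under an MNAR selection model
#'
#' Under a logistic selection model in which `delta` is the log-odds of
#' observing the outcome per unit of the (possibly unobserved) outcome, the
#' MAR imputations can be re-weighted towards the implied MNAR mechanism
#' with `w_m proportional to exp(-delta * S_m)`, where `S_m` is the sum of
#' imputation `m`'s imputed outcomes over the patients whose outcome was
#' missing. For `delta > 0` (better outcomes more likely observed) this
#' up-weights the imputations whose imputed values are small. Computed in
#' log space (the sums are in the thousands, so raw exponentials would
#' under- or overflow); adding any constant to all sums leaves the weights
#' unchanged.
#'
#' @param imputed_sums numeric vector `S_1..S_M` of per-imputation sums of
#'   imputed outcomes over the missing-outcome patients.
#' @param delta MNAR sensitivity parameter; `delta = 0` gives equal weights.
#' @return normalised weights summing to 1.
#' @export
imputation_weights <- function(imputed_sums, delta) {
  if (!length(imputed_sums)) stop("no imputations")
  if (any(!is.finite(imputed_sums))) stop("imputed sums must be finite")
  lw <- -delta * imputed_sums
  lw <- lw - max(lw)
  w <- exp(lw)
  w / sum(w)
}

#' Effective sample size of importance weights
#'
#' `1 / sum(w^2)`, between 1 (degenerate) and M (equal weights); a
#' diagnostic for weight degeneracy as `delta` moves away from 0.
#'
#' @param weights normalised weights.
#' @return scalar effective sample size.
#' @export
effective_sample_size <- function(weights) 1 / sum(weights^2)

#' Weighted Rubin's-rules pooling
#'
#' Re-weighted combination of the per-imputation estimates:
#' estimate `= sum w_m theta_m`, within variance `= sum w_m sigma_m^2`,
#' between variance `= sum w_m (theta_m - estimate)^2`, total
#' `= V_W + (1 + 1/M) V_B`. Note the between variance uses the weighted
#' (`1/M`-style) dispersion; at `delta = 0` it is therefore a factor
#' `(M-1)/M` smaller than the classical Rubin between variance, while the
#' pooled estimate coincides exactly.
#'
#' @param estimates,variances per-imputation estimates and squared standard
#'   errors.
#' @param weights normalised weights from [imputation_weights()].
#' @return a `pooled_estimate` (see [pool_rubin()]) with an `ess` element.
#' @export
pool_weighted <- function(estimates, variances, weights) {
  M <- length(estimates)
  if (length(variances) != M || length(weights) != M) stop("length mismatch")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8) {
    stop("weights must be non-negative and sum to 1")
  }
  est <- sum(weights * estimates)
  V_W <- sum(weights * variances)
  V_B <- sum(weights * (estimates - est)^2)
  ess <- effective_sample_size(weights)
  if (ess < 1.5 && M > 1) {
    warning("importance weights nearly degenerate (effective sample size ",
            round(ess, 2), ")", call. = FALSE)
  }
  structure(list(estimate = est, V_W = V_W, V_B = V_B,
                 total = V_W + (1 + 1 / M) * V_B, M = M, ess = ess),
            class = "pooled_estimate")
}

#' Sensitivity sweep over a grid of MNAR departures
#'
#' For each `delta` in the grid: weights are computed from the imputed
#' post-operative totals of the missing-outcome patients (globally, shared
#' by all providers), every provider's standardised outcome is re-pooled
#' with [pool_weighted()], the funnel limits are rebuilt from the weighted
#' national mean and population SD, and the providers are reclassified,
#' yielding one status frequency table per `delta`. `delta = 0` reproduces
#' the MAR (equal-weight) analysis.
#'
#' @param estimates_by_m list of M `provider_estimates` data frames (one per
#'   completed dataset, from [standardize_providers()]).
#' @param imputed_sums per-imputation sums of imputed post-operative totals
#'   over missing-outcome patients.
#' @param volumes data frame `provider_id`, `n` giving the funnel volumes
#'   (full eligible counts under MI).
#' @param grid ordered vector of `delta` values; must contain 0.
#' @param response_rates optional data frame `provider_id`,
#'   `response_rate` for the tariff rule.
#' @param ess_floor attach a warning flag to any `delta` whose weight
#'   effective sample size falls below this.
#' @param exact_multipliers see [control_limits()].
#' @return a `sensitivity_result`: `table` (per-delta status counts and
#'   percentages), `weights` (M x n_delta matrix), `ess`, `national_mean`
#'   per delta, and per-delta `assessments`.
#' @export
delta_sweep <- function(estimates_by_m, imputed_sums, volumes, grid,
                        response_rates = NULL, ess_floor = 2,
                        exact_multipliers = FALSE) {
  grid <- sort(grid)
  grid[abs(grid) < 1e-12] <- 0   # seq() artefacts
  if (!any(grid == 0)) stop("delta grid must contain 0")
  M <- length(estimates_by_m)
  if (length(imputed_sums) != M) stop("need one imputed sum per imputation")

  ids <- estimates_by_m[[1]]$provider_id
  est_mat <- vapply(estimates_by_m, function(d) d$y_tilde[match(ids, d$provider_id)],
                    numeric(length(ids)))
  var_mat <- vapply(estimates_by_m, function(d) d$se[match(ids, d$provider_id)]^2,
                    numeric(length(ids)))
  ybar_m <- vapply(estimates_by_m, attr, numeric(1), "ybar2")
  sigma_m <- vapply(estimates_by_m, attr, numeric(1), "sigma_pop")
  vol <- volumes$n[match(ids, volumes$provider_id)]
  rr <- if (!is.null(response_rates)) {
    response_rates$response_rate[match(ids, response_rates$provider_id)]
  } else NULL

  tabs <- list(); assessments <- list()
  W <- matrix(NA_real_, M, length(grid), dimnames = list(NULL, format(grid)))
  ess <- national <- numeric(length(grid))
  for (g in seq_along(grid)) {
    d <- grid[g]
    w <- imputation_weights(imputed_sums, d)
    W[, g] <- w
    ess[g] <- effective_sample_size(w)
    national[g] <- sum(w * ybar_m)
    sigma_pop <- sum(w * sigma_m)
    y_pool <- as.numeric(est_mat %*% w)
    v_w <- as.numeric(var_mat %*% w)
    v_b <- as.numeric((est_mat - y_pool)^2 %*% w)
    est <- data.frame(provider_id = ids, y_tilde = y_pool, n = vol,
                      var_total = v_w + (1 + 1 / M) * v_b,
                      stringsAsFactors = FALSE)
    if (!is.null(rr)) est$response_rate <- rr
    a <- assess_providers(est, mean = national[g], sigma_pop = sigma_pop,
                          mode = if (abs(d) < 1e-12) "mi" else "mnar",
                          exact_multipliers = exact_multipliers)
    tab <- a$status_table
    tab$delta <- d
    tab$ess <- ess[g]
    tab$low_ess <- ess[g] < ess_floor
    tabs[[g]] <- tab
    assessments[[g]] <- a
  }
  structure(list(table = do.call(rbind, tabs), weights = W, ess = ess,
                 national_mean = national, grid = grid,
                 assessments = assessments),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat("MNAR sensitivity sweep over delta = ",
      paste(format(x$grid), collapse = ", "), "\n", sep = "")
  wide <- stats::reshape(x$table[, c("delta", "status", "n")],
                         idvar = "delta", timevar = "status",
                         direction = "wide")
  names(wide) <- sub("^n\\.", "", names(wide))
  print(wide, row.names = FALSE)
  invisible(x)
}
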