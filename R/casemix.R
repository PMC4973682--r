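#' Fit the case-mix analysis model to a completed dataset
#'
#' The analysis model regresses the post-operative total on the case-mix
#' covariates and the pre-operative total with a provider random intercept,
#'
#' `y2_ij = alpha + X_ij beta + y1_ij gamma + u_j + eps_ij`,
#' `u_j ~ N(0, sigma_u^2)`, `eps_ij ~ N(0, sigma_eps^2)`,
#'
#' estimated by restricted maximum likelihood (via `lme4::lmer`).
#'
#' @param data a completed patient data frame (no missing outcome,
#'   pre-operative total or covariates) with a `provider_id` column.
#' @return an `analysis_fit` with `alpha`, `beta` (named covariate
#'   coefficients), `gamma`, `sigma_u`, `sigma_eps`, `u_hat` (shrunken
#'   provider effects), the national mean `ybar2`, and the fitted `lmer`
#'   model.
#' @export
fit_analysis_model <- function(data) {
  needed <- c("y2_total", "y1_total", "age_band", "sex", "ethnicity",
              "comorbidity", "deprivation", "duration", "provider_id")
  miss <- needed[!needed %in% names(data)]
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (anyNA(data[needed])) stop("analysis model requires a completed dataset")
  if (length(unique(data$provider_id)) < 2) stop("need at least 2 providers")

  fx <- y2_total ~ age_band + sex + ethnicity + comorbidity + deprivation +
    duration + y1_total
  X <- stats::model.matrix(fx, data)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("singular design; collinear column(s): ", paste(dropped, collapse = ", "))
  }

  fit <- lme4::lmer(y2_total ~ age_band + sex + ethnicity + comorbidity +
                      deprivation + duration + y1_total + (1 | provider_id),
                    data = data, REML = TRUE,
                    control = lme4::lmerControl(calc.derivs = FALSE,
                                                check.conv.singular = "ignore"))
  fe <- lme4::fixef(fit)
  vc <- as.data.frame(lme4::VarCorr(fit))
  re <- lme4::ranef(fit)$provider_id
  u_hat <- stats::setNames(re[["(Intercept)"]], rownames(re))

  structure(list(
    alpha = unname(fe["(Intercept)"]),
    beta = fe[setdiff(names(fe), c("(Intercept)", "y1_total"))],
    gamma = unname(fe["y1_total"]),
    sigma_u = vc$sdcor[vc$grp == "provider_id"],
    sigma_eps = vc$sdcor[vc$grp == "Residual"],
    u_hat = u_hat,
    ybar2 = mean(data$y2_total),
    model = fit
  ), class = "analysis_fit")
}

#' @export
print.analysis_fit <- function(x, ...) {
  cat("Case-mix analysis model (REML)\n")
  cat(sprintf("  alpha = %.3f, gamma = %.3f, sigma_u = %.3f, sigma_eps = %.3f\n",
              x$alpha, x$gamma, x$sigma_u, x$sigma_eps))
  cat(sprintf("  national mean = %.3f over %d providers\n",
              x$ybar2, length(x$u_hat)))
  invisible(x)
}

#' Indirectly standardised provider outcomes
#'
#' For each patient the case-mix-expected outcome is the fixed part of the
#' analysis model, `yhat2 = alpha + X beta + y1 gamma` (the provider effect
#' is deliberately excluded: indirect standardisation compares observed
#' outcomes with what case mix alone predicts). Each provider's
#' standardisation factor is the mean observed/expected ratio over its
#' patients, `rho_j = mean(y2 / yhat2)`, and its standardised outcome is
#' `y_tilde_j = rho_j * ybar2`, the national mean scaled by that factor. The
#' within-dataset standard error is the delta-method plug-in
#' `ybar2 * sd(ratio) / sqrt(n_j)`.
#'
#' @param data completed patient data frame.
#' @param fit an [fit_analysis_model()] result for the same dataset.
#' @param yhat optional vector of case-mix-expected outcomes overriding the
#'   fixed-part predictions of `fit` (one per row of `data`).
#' @return a `provider_estimates` data frame: `provider_id`, `n`, `rho`,
#'   `y_tilde`, `se`; with attributes `ybar2` and `sigma_pop` (the
#'   between-patient SD of the standardised outcome, `ybar2 * sd(ratio)`).
#' @export
standardize_providers <- function(data, fit, yhat = NULL) {
  if (is.null(yhat)) yhat <- stats::predict(fit$model, newdata = data, re.form = NA)
  if (length(yhat) != nrow(data)) stop("yhat length must match data rows")
  if (any(yhat <= 0)) {
    stop("non-positive case-mix-expected outcome; ratio standardisation undefined")
  }
  ratio <- data$y2_total / yhat
  ybar2 <- mean(data$y2_total)
  agg <- split(ratio, data$provider_id)
  agg <- agg[lengths(agg) > 0]
  out <- data.frame(
    provider_id = names(agg),
    n = as.integer(lengths(agg)),
    rho = vapply(agg, mean, numeric(1)),
    stringsAsFactors = FALSE
  )
  out$y_tilde <- out$rho * ybar2
  sds <- vapply(agg, stats::sd, numeric(1))
  out$se <- ybar2 * sds / sqrt(out$n)
  rownames(out) <- NULL
  attr(out, "ybar2") <- ybar2
  attr(out, "sigma_pop") <- ybar2 * stats::sd(ratio)
  class(out) <- c("provider_estimates", "data.frame")
  out
}

#' Pool estimates across imputations by Rubin's rules
#'
#' The pooled estimate is the mean of the per-imputation estimates, the
#' within variance the mean of the per-imputation variances, the between
#' variance the sample variance of the estimates, and the total variance
#' `V_W + (1 + 1/M) V_B`. With `M = 1` the between component is 0.
#'
#' @param estimates numeric vector of M per-imputation estimates.
#' @param variances numeric vector of M per-imputation squared standard
#'   errors (all `>= 0`).
#' @return a `pooled_estimate` list: `estimate`, `V_W`, `V_B`, `total`,
#'   `M`, and the Rubin degrees of freedom `df` (infinite when `V_B = 0`).
#' @export
pool_rubin <- function(estimates, variances) {
  M <- length(estimates)
  if (M < 1) stop("no estimates to pool")
  if (length(variances) != M) stop("estimates and variances differ in length")
  if (any(variances < 0, na.rm = TRUE)) stop("variances must be non-negative")
  est <- mean(estimates)
  V_W <- mean(variances)
  V_B <- if (M > 1) sum((estimates - est)^2) / (M - 1) else 0
  total <- V_W + (1 + 1 / M) * V_B
  df <- if (M > 1 && V_B > 0) (M - 1) * (1 + V_W / ((1 + 1 / M) * V_B))^2 else Inf
  structure(list(estimate = est, V_W = V_W, V_B = V_B, total = total,
                 M = M, df = df),
            class = "pooled_estimate")
}

#' Restrict a cohort to its complete cases
#'
#' A complete case has all 24 items observed at both occasions and complete
#' case-mix covariates; everything else is dropped, as in the official
#' complete-case assessment. Providers left with zero complete cases drop
#' out of a complete-case analysis entirely.
#'
#' @param patients patient records with `NA` for missing values.
#' @return the complete-case subset.
#' @export
complete_cases <- function(patients) {
  cols <- c(q1_items, q2_items, "age_band", "sex", "ethnicity",
            "comorbidity", "deprivation", "duration")
  keep <- stats::complete.cases(patients[, cols])
  patients[keep, , drop = FALSE]
}
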