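#' Per-provider PROM collection rates
#'
#' Fraction of each provider's eligible patients with both questionnaires
#' fully observed (all 24 items), the denominator being all eligible
#' patients. This is the collection rate the best-practice tariff rule
#' tests against its 50% threshold.
#'
#' @param patients patient records.
#' @return data frame `provider_id`, `n_eligible`, `n_complete`,
#'   `response_rate`.
#' @export
response_rates <- function(patients) {
  complete <- stats::complete.cases(patients[, c(q1_items, q2_items)])
  agg <- tapply(complete, patients$provider_id, function(x) c(length(x), sum(x)))
  ids <- names(agg)
  m <- do.call(rbind, agg)
  data.frame(provider_id = ids, n_eligible = as.integer(m[, 1]),
             n_complete = as.integer(m[, 2]),
             response_rate = m[, 2] / m[, 1],
             stringsAsFactors = FALSE, row.names = NULL)
}

provider_volumes <- function(patients) {
  tab <- table(patients$provider_id)
  data.frame(provider_id = names(tab), n = as.integer(tab),
             stringsAsFactors = FALSE)
}

#' Complete-case provider assessment
#'
#' Restricts to complete cases, fits the analysis model, standardises
#' providers, and classifies them on a funnel built from the complete-case
#' national mean and population SD at complete-case volumes.
#'
#' @param patients patient records with missing values.
#' @param response_rate data frame from [response_rates()] (computed on the
#'   full cohort; the tariff rule always uses eligible patients as the
#'   denominator).
#' @param bpt_threshold,exact_multipliers see [assess_providers()].
#' @return list with the `analysis_fit`, `provider_estimates`, and the
#'   `provider_assessment`.
#' @export
cca_analysis <- function(patients, response_rate = response_rates(patients),
                         bpt_threshold = 0.5, exact_multipliers = FALSE) {
  cc <- complete_cases(patients)
  if (!nrow(cc)) stop("no complete cases")
  fit <- fit_analysis_model(cc)
  est <- standardize_providers(cc, fit)
  est$response_rate <- response_rate$response_rate[
    match(est$provider_id, response_rate$provider_id)]
  assessment <- assess_providers(est, mean = attr(est, "ybar2"),
                                 sigma_pop = attr(est, "sigma_pop"),
                                 mode = "cca", bpt_threshold = bpt_threshold,
                                 exact_multipliers = exact_multipliers)
  list(fit = fit, estimates = est, assessment = assessment)
}

#' Multiple-imputation provider assessment
#'
#' Fits the analysis model to each completed dataset, standardises
#' providers within each, pools the per-provider standardised outcomes,
#' the national mean and the population SD across imputations by Rubin's
#' rules, and classifies every provider at its full eligible volume (the
#' funnel "volume effect").
#'
#' @param imputations an `imputation_set` of fully completed datasets.
#' @param patients the original (incomplete) patient records, used for
#'   volumes and collection rates.
#' @param bpt_threshold,exact_multipliers see [assess_providers()].
#' @return list with per-imputation `estimates_by_m` and `fits`, the pooled
#'   per-provider table `pooled`, the pooled `national_mean` and
#'   `sigma_pop`, and the `provider_assessment`.
#' @export
mi_analysis <- function(imputations, patients,
                        bpt_threshold = 0.5, exact_multipliers = FALSE) {
  fits <- lapply(imputations$datasets, fit_analysis_model)
  est_by_m <- mapply(standardize_providers, imputations$datasets, fits,
                     SIMPLIFY = FALSE)
  ids <- sort(unique(patients$provider_id))
  est_mat <- vapply(est_by_m, function(d) d$y_tilde[match(ids, d$provider_id)],
                    numeric(length(ids)))
  var_mat <- vapply(est_by_m, function(d) d$se[match(ids, d$provider_id)]^2,
                    numeric(length(ids)))
  pooled_list <- lapply(seq_along(ids), function(i)
    pool_rubin(est_mat[i, ], var_mat[i, ]))
  pooled <- data.frame(
    provider_id = ids,
    y_tilde = vapply(pooled_list, `[[`, numeric(1), "estimate"),
    var_total = vapply(pooled_list, `[[`, numeric(1), "total"),
    stringsAsFactors = FALSE
  )
  vols <- provider_volumes(patients)
  pooled$n <- vols$n[match(pooled$provider_id, vols$provider_id)]
  rr <- response_rates(patients)
  pooled$response_rate <- rr$response_rate[match(pooled$provider_id, rr$provider_id)]
  national_mean <- mean(vapply(est_by_m, attr, numeric(1), "ybar2"))
  sigma_pop <- mean(vapply(est_by_m, attr, numeric(1), "sigma_pop"))
  assessment <- assess_providers(pooled, mean = national_mean,
                                 sigma_pop = sigma_pop, mode = "mi",
                                 bpt_threshold = bpt_threshold,
                                 exact_multipliers = exact_multipliers)
  list(fits = fits, estimates_by_m = est_by_m, pooled = pooled,
       national_mean = national_mean, sigma_pop = sigma_pop,
       assessment = assessment)
}

#' Sums of imputed post-operative totals over missing-outcome patients
#'
#' The quantity `S_m` entering the MNAR importance weights: for each
#' completed dataset, the sum of the imputed post-operative totals over the
#' patients whose outcome was missing. Pre-operative imputations never
#' enter the weights.
#'
#' @param imputations an `imputation_set`.
#' @param patients the original incomplete records.
#' @return numeric vector of length M.
#' @export
imputed_outcome_sums <- function(imputations, patients) {
  idx <- which(is.na(patients$y2_total))
  vapply(imputations$datasets, function(d) sum(d$y2_total[idx]), numeric(1))
}

#' Run the end-to-end missing-data-aware profiling pipeline
#'
#' Generates (or accepts) a cohort, then runs the requested analysis modes:
#' complete-case (`cca`), multiple imputation under MAR (`mi`), and the
#' MNAR delta-reweighting sensitivity sweep (`mnar`, which requires `mi`).
#' Writes cohort, provider-estimate, funnel, status and sensitivity CSVs
#' plus a machine-readable JSON summary when `out_dir` is given. The
#' summary contains no wall-clock information, so identical inputs and seed
#' reproduce it byte for byte.
#'
#' @param cohort a `prom_cohort`, or `NULL` to generate one from `config`.
#' @param config cohort configuration used when `cohort` is `NULL`; its
#'   seed is overridden by `seed`.
#' @param modes subset of `c("cca", "mi", "mnar")`.
#' @param M,burn_in,thin imputation sampler settings.
#' @param delta_grid sensitivity grid (must contain 0).
#' @param bpt_threshold tariff collection-rate threshold.
#' @param exact_multipliers use z = 2/3 instead of 1.96/3.09.
#' @param seed master seed for generation and imputation.
#' @param out_dir optional output directory.
#' @return a `pipeline_result` list with elements per mode plus `summary`.
#' @export
run_pipeline <- function(cohort = NULL, config = cohort_config(),
                         modes = c("cca", "mi", "mnar"),
                         M = 20L, burn_in = 200L, thin = 20L,
                         delta_grid = seq(-0.3, 0.3, by = 0.1),
                         bpt_threshold = 0.5, exact_multipliers = FALSE,
                         seed = 1L, out_dir = NULL) {
  modes <- match.arg(modes, several.ok = TRUE)
  if ("mnar" %in% modes && !"mi" %in% modes) {
    stop("mnar mode requires mi mode")
  }
  if (is.null(cohort)) {
    config$seed <- seed
    cohort <- generate_cohort(config)
  }
  patients <- cohort$patients
  providers <- cohort$providers
  rr <- response_rates(patients)
  out <- list(cohort = cohort)
  summary <- list(seed = seed, modes = modes,
                  n_providers = nrow(providers), n_patients = nrow(patients),
                  schema_version = "1")

  if ("cca" %in% modes) {
    out$cca <- tryCatch(
      cca_analysis(patients, rr, bpt_threshold, exact_multipliers),
      error = function(e) e)
    if (!inherits(out$cca, "error")) {
      st <- out$cca$assessment$status_table
      summary$cca <- list(
        status_counts = stats::setNames(as.list(st$n), as.character(st$status)),
        n_assessed = sum(st$n),
        bpt_ineligible = sum(!out$cca$assessment$assessments$bpt_eligible,
                             na.rm = TRUE))
    }
  }

  if ("mi" %in% modes) {
    has_missing <- anyNA(patients[, c(q1_items, q2_items, "ethnicity", "duration")])
    imp <- if (has_missing) {
      impute_pipeline(patients, providers, M = M, burn_in = burn_in,
                      thin = thin, seed = seed + 1000L)
    } else {
      fit_and_impute(patients, providers, impute_spec("q2"), M = M,
                     burn_in = burn_in, thin = thin, seed = seed + 1000L)
    }
    out$imputations <- imp
    out$mi <- mi_analysis(imp, patients, bpt_threshold, exact_multipliers)
    st <- out$mi$assessment$status_table
    summary$mi <- list(
      status_counts = stats::setNames(as.list(st$n), as.character(st$status)),
      n_assessed = sum(st$n),
      M = M,
      bpt_ineligible = sum(!out$mi$assessment$assessments$bpt_eligible,
                           na.rm = TRUE))
  }

  if ("mnar" %in% modes) {
    sums <- imputed_outcome_sums(out$imputations, patients)
    if (all(sums == 0)) {
      summary$mnar <- list(note = "no missing outcomes; sensitivity sweep skipped")
    } else {
      out$mnar <- delta_sweep(out$mi$estimates_by_m, sums,
                              volumes = provider_volumes(patients),
                              grid = delta_grid, response_rates = rr,
                              exact_multipliers = exact_multipliers)
      tab <- out$mnar$table
      summary$mnar <- lapply(split(tab, tab$delta), function(t)
        stats::setNames(as.list(t$n), as.character(t$status)))
    }
  }

  out$summary <- summary
  class(out) <- "pipeline_result"
  if (!is.null(out_dir)) write_pipeline(out, out_dir)
  out
}

write_pipeline <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort(result$cohort, file.path(dir, "cohort"))
  if (!is.null(result$cca) && !inherits(result$cca, "error")) {
    est <- result$cca$estimates
    est$analysis_mode <- "cca"
    utils::write.csv(est, file.path(dir, "provider_estimates_cca.csv"),
                     row.names = FALSE)
    utils::write.csv(result$cca$assessment$status_table,
                     file.path(dir, "status_table_cca.csv"), row.names = FALSE)
    fc <- funnel_coordinates(result$cca$assessment)
    utils::write.csv(fc$limits, file.path(dir, "funnel_limits_cca.csv"),
                     row.names = FALSE)
  }
  if (!is.null(result$mi)) {
    pooled <- result$mi$pooled
    pooled$analysis_mode <- "mi"
    utils::write.csv(pooled, file.path(dir, "provider_estimates_mi.csv"),
                     row.names = FALSE)
    utils::write.csv(result$mi$assessment$status_table,
                     file.path(dir, "status_table_mi.csv"), row.names = FALSE)
    fc <- funnel_coordinates(result$mi$assessment)
    utils::write.csv(fc$limits, file.path(dir, "funnel_limits_mi.csv"),
                     row.names = FALSE)
  }
  if (!is.null(result$mnar)) {
    utils::write.csv(result$mnar$table, file.path(dir, "sensitivity_table.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(grid = result$mnar$grid, ess = result$mnar$ess,
           weights = apply(result$mnar$weights, 2, as.numeric, simplify = FALSE)),
      file.path(dir, "sensitivity_weights.json"), digits = NA)
  }
  jsonlite::write_json(result$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("promperf pipeline result —", x$summary$n_providers, "providers,",
      x$summary$n_patients, "patients\n")
  for (mode in c("cca", "mi")) {
    block <- x[[mode]]
    if (!is.null(block) && !inherits(block, "error")) {
      print(block$assessment$status_table)
    }
  }
  if (!is.null(x$mnar)) print(x$mnar)
  invisible(x)
}
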