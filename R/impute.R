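#' @useDynLib promperf, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

q1_items <- paste0("q1_item_", 1:12)
q2_items <- paste0("q2_item_", 1:12)

#' Imputation model specification for a missingness pattern
#'
#' The survey has two missing-data patterns, each with its own multivariate
#' latent-normal imputation model:
#'
#' * `"q1"`: the 12 pre-operative items plus the incomplete covariates
#'   (ethnicity, symptom duration) are the modelled responses; predictors are
#'   the fully observed case-mix covariates plus the pattern's auxiliary
#'   variables: length of stay, waiting time (log scale), and the
#'   provider-level private/teaching/volume characteristics. Fitted on all
#'   patients.
#' * `"q2"`: the 12 post-operative items are the responses; predictors are
#'   the (completed) case-mix covariates, the completed pre-operative total,
#'   and the patient-level auxiliaries: length of stay, waiting time,
#'   previous surgery, pre-admission questionnaire flag, assistance flag,
#'   lives-alone flag. No provider-level predictors; fitted on Q1 responders
#'   only.
#'
#' Both models carry per-component provider random intercepts.
#'
#' @param pattern `"q1"` or `"q2"`.
#' @return a list of class `impute_spec` with `pattern`, `responses`,
#'   `ncat`, and a predictor `formula`.
#' @export
impute_spec <- function(pattern = c("q2", "q1")) {
  pattern <- match.arg(pattern)
  if (pattern == "q1") {
    spec <- list(
      pattern = "q1",
      responses = c(q1_items, "ethnicity", "duration"),
      ncat = c(rep(5L, 12), 2L, 3L),
      formula = ~ age_band + sex + comorbidity + deprivation +
        log1p(length_of_stay) + log1p(waiting_time) +
        is_private + is_teaching + log_volume
    )
  } else {
    spec <- list(
      pattern = "q2",
      responses = q2_items,
      ncat = rep(5L, 12),
      formula = ~ age_band + sex + ethnicity + comorbidity + deprivation +
        duration + y1_total + log1p(length_of_stay) + log1p(waiting_time) +
        previous_surgery + pre_admission_q1 + assisted_q2 + lives_alone
    )
  }
  class(spec) <- "impute_spec"
  spec
}

# response data frame columns -> 0-based integer category matrix
encode_responses <- function(data, spec) {
  H <- matrix(NA_integer_, nrow(data), length(spec$responses))
  for (k in seq_along(spec$responses)) {
    v <- data[[spec$responses[k]]]
    H[, k] <- if (is.factor(v)) as.integer(v) - 1L else as.integer(v)
  }
  colnames(H) <- spec$responses
  H
}

init_thresholds <- function(h, ncat) {
  if (ncat == 2L) return(0)
  tab <- pmax(tabulate(h[!is.na(h)] + 1L, nbins = ncat), 0.5)
  cum <- cumsum(tab) / sum(tab)
  a <- stats::qnorm(pmin(pmax(cum[-ncat], 1e-4), 1 - 1e-4))
  a <- a - a[1]
  # guard against ties from degenerate category counts
  for (m in seq_along(a)[-1]) if (a[m] <= a[m - 1]) a[m] <- a[m - 1] + 1e-3
  a
}

build_design <- function(data, providers, spec) {
  df <- data
  pidx <- match(df$provider_id, providers$provider_id)
  df$is_private <- providers$is_private[pidx]
  df$is_teaching <- providers$is_teaching[pidx]
  df$log_volume <- log(pmax(providers$target_volume[pidx], 1))
  mf <- stats::model.frame(spec$formula, df, na.action = stats::na.fail)
  X <- stats::model.matrix(spec$formula, mf)
  # constant auxiliaries (e.g. no teaching hospital in a small cohort) carry
  # no information; drop them instead of failing the rank check
  if (ncol(X) > 1) {
    const <- c(FALSE, apply(X[, -1, drop = FALSE], 2,
                            function(v) max(v) - min(v) == 0))
    X <- X[, !const, drop = FALSE]
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("collinear predictor column(s) in ", spec$pattern,
         " imputation model: ", paste(dropped, collapse = ", "))
  }
  list(X = X, prov = pidx - 1L)
}

#' Fit one latent-normal imputation model and draw completed datasets
#'
#' Runs the Metropolis-within-Gibbs sampler for the given missingness
#' pattern: truncated-normal draws of the latent item values, conjugate
#' draws of the latent-regression coefficients and per-provider random
#' effects, inverse-gamma draws of the level-2 variances, Metropolis updates
#' of the cut-points (first cut-point fixed at 0) and of the residual
#' cross-item correlation. Every `thin`-th post-burn-in state emits a
#' completed dataset by cutting the current latent values of the missing
#' cells at the current thresholds. Observed values are never altered.
#'
#' The total chain length is `burn_in + M * thin` iterations (the survey
#' analysis used 100 imputations from 10,000 post-burn-in iterations thinned
#' every 100th).
#'
#' @param patients patient records (see [generate_cohort()]).
#' @param providers provider frame.
#' @param spec an [impute_spec()].
#' @param M number of imputations.
#' @param burn_in burn-in iterations.
#' @param thin iterations between emitted datasets.
#' @param seed optional RNG seed.
#' @param fit_subset logical vector selecting the rows the model is fitted
#'   on (default all); rows outside the subset are left untouched here.
#' @return an `imputation_set`: `datasets` (list of M completed data frames),
#'   `states` (parameter draws at each emission), and sampler metadata.
#' @export
fit_and_impute <- function(patients, providers, spec = impute_spec("q2"),
                           M = 100L, burn_in = 1000L, thin = 100L,
                           seed = NULL, fit_subset = NULL) {
  local_seed(seed)
  if (is.null(fit_subset)) fit_subset <- rep(TRUE, nrow(patients))
  fit_data <- patients[fit_subset, , drop = FALSE]
  H <- encode_responses(fit_data, spec)
  for (k in seq_along(spec$ncat)) {
    v <- H[!is.na(H[, k]), k]
    if (length(v) && (min(v) < 0L || max(v) > spec$ncat[k] - 1L)) {
      stop("response categories out of range in '", spec$responses[k], "'")
    }
  }

  if (!anyNA(H)) {
    out <- replicate(M, patients, simplify = FALSE)
    return(new_imputation_set(out, states = NULL, spec = spec, M = M,
                              burn_in = burn_in, thin = thin, seed = seed,
                              acc = NULL, note = "no missing values"))
  }

  des <- build_design(fit_data, providers, spec)
  thr0 <- lapply(seq_along(spec$ncat), function(k) init_thresholds(H[, k], spec$ncat[k]))
  res <- ordinal_gibbs_cpp(H, des$X, des$prov, J = nrow(providers),
                           ncat = spec$ncat, thr_init = thr0, rho_init = 0.2,
                           burn = as.integer(burn_in), n_keep = as.integer(M),
                           thin = as.integer(thin))
  if (length(res$imputations) < M) stop("sampler emitted fewer than M datasets")

  datasets <- lapply(res$imputations, function(Hc) {
    decode_responses(patients, fit_subset, Hc, spec)
  })
  check_mixing(res$states, spec)
  new_imputation_set(datasets, states = res$states, spec = spec, M = M,
                     burn_in = burn_in, thin = thin, seed = seed,
                     acc = list(thresholds = res$acc_thresholds, rho = res$acc_rho))
}

decode_responses <- function(patients, fit_subset, Hc, spec) {
  out <- patients
  rows <- which(fit_subset)
  for (k in seq_along(spec$responses)) {
    nm <- spec$responses[k]
    v <- out[[nm]]
    if (is.factor(v)) {
      v[rows] <- factor(levels(v)[Hc[, k] + 1L], levels = levels(v))
    } else {
      v[rows] <- as.integer(Hc[, k])
    }
    out[[nm]] <- v
  }
  if (spec$pattern == "q1") out$y1_total <- ohs_total(out[, q1_items])
  if (spec$pattern == "q2") out$y2_total <- ohs_total(out[, q2_items])
  out
}

# crude split-chain drift heuristic on the emitted regression draws
check_mixing <- function(states, spec, bound = 1.2) {
  if (is.null(states) || length(states) < 6) return(invisible(NULL))
  b <- vapply(states, function(s) mean(s$B[1, ]), numeric(1))
  h <- length(b) %/% 2
  first <- b[seq_len(h)]; second <- b[(h + 1):length(b)]
  pooled_sd <- stats::sd(b)
  if (pooled_sd > 0 &&
      abs(mean(first) - mean(second)) / (pooled_sd / sqrt(h)) > 6 * bound) {
    warning("imputation sampler for pattern '", spec$pattern,
            "' shows between-half drift; consider a longer burn-in",
            call. = FALSE)
  }
  invisible(NULL)
}

new_imputation_set <- function(datasets, states, spec, M, burn_in, thin,
                               seed, acc, note = NULL) {
  structure(list(datasets = datasets, states = states, M = M,
                 meta = list(pattern = spec$pattern, burn_in = burn_in,
                             thin = thin, seed = seed, acceptance = acc,
                             note = note)),
            class = "imputation_set")
}

#' @export
print.imputation_set <- function(x, ...) {
  cat("Imputation set:", x$M, "completed dataset(s), pattern",
      x$meta$pattern %||% "joint", "\n")
  if (!is.null(x$meta$note)) cat("  note:", x$meta$note, "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# predictive item draw for patients outside the fitted subset
predict_items <- function(state, X, prov_idx, ncat) {
  K <- ncol(state$B)
  n <- nrow(X)
  mu <- X %*% state$B + state$u[prov_idx, , drop = FALSE]
  Z <- mu + cs_noise(n, K, state$rho)
  out <- matrix(NA_integer_, n, K)
  for (k in seq_len(K)) {
    out[, k] <- latent_to_category(Z[, k], sort(state$thresholds[[k]]))
  }
  out
}

#' Two-stage multiple imputation of the full cohort
#'
#' Chains the two pattern-specific models into M jointly completed datasets:
#'
#' 1. the Q1-pattern model imputes pre-operative items and the incomplete
#'    covariates (ethnicity, symptom duration) for all patients;
#' 2. per completed dataset, the Q2-pattern model is fitted on Q1 responders
#'    and imputes their missing post-operative items in-chain; patients whose
#'    Q1 was itself imputed receive post-operative items from the model's
#'    posterior-predictive draw at the emitted parameter state.
#'
#' Stage 2 is re-fitted per imputation because its predictors (completed
#' pre-operative total, ethnicity, duration) differ across stage-1
#' completions; each refit is an independent short chain. When stage 1 has
#' nothing to impute the Q2 model runs as a single chain emitting all M
#' datasets.
#'
#' @param patients,providers cohort components (see [generate_cohort()]).
#' @param M number of imputations (the survey analysis used 100).
#' @param burn_in stage-1 burn-in and stage-2 single-chain burn-in.
#' @param thin thinning interval between emissions.
#' @param burn_in_stage2 burn-in of each per-imputation stage-2 refit.
#' @param seed optional RNG seed; fixes the entire imputation set.
#' @return an `imputation_set` whose datasets are complete in all 24 items,
#'   ethnicity, symptom duration and both totals for every patient.
#' @export
impute_pipeline <- function(patients, providers, M = 100L, burn_in = 1000L,
                            thin = 100L, burn_in_stage2 = burn_in, seed = NULL) {
  local_seed(seed)
  spec1 <- impute_spec("q1")
  spec2 <- impute_spec("q2")

  stage1_missing <- anyNA(encode_responses(patients, spec1))
  if (stage1_missing) {
    set1 <- fit_and_impute(patients, providers, spec1, M = M,
                           burn_in = burn_in, thin = thin)
  } else {
    set1 <- NULL
  }

  r1 <- patients$R1 == 1L
  if (!stage1_missing) {
    # single-chain fast path: stage-2 predictors identical across m
    out <- fit_and_impute(patients, providers, spec2, M = M,
                          burn_in = burn_in, thin = thin, fit_subset = r1)
    if (any(!r1)) stop("Q1 marked unobserved but no stage-1 missingness found")
    out$meta$pattern <- "q1+q2"
    return(out)
  }

  datasets <- vector("list", M)
  states <- vector("list", M)
  for (m in seq_len(M)) {
    completed <- set1$datasets[[m]]
    one <- fit_and_impute(completed, providers, spec2, M = 1L,
                          burn_in = burn_in_stage2, thin = 1L,
                          fit_subset = r1)
    dm <- one$datasets[[1]]
    if (any(!r1)) {
      st <- one$states[[1]]
      des <- build_design(dm, providers, spec2)
      rows <- which(!r1)
      imp <- predict_items(st, des$X[rows, , drop = FALSE],
                           des$prov[rows] + 1L, spec2$ncat)
      dm[rows, q2_items] <- imp
      dm$y2_total <- ohs_total(dm[, q2_items])
      states[[m]] <- st
    } else {
      states[[m]] <- one$states[[1]]
    }
    datasets[[m]] <- dm
  }
  set <- new_imputation_set(datasets, states = states, spec = list(pattern = "q1+q2"),
                            M = M, burn_in = burn_in, thin = thin, seed = seed,
                            acc = NULL)
  set
}

#' Write an imputation set to CSV files plus a JSON manifest
#'
#' @param set an `imputation_set`.
#' @param dir output directory.
#' @param long also write a single long-format CSV with a `dataset_id`
#'   column for downstream pooling.
#' @return `dir`, invisibly.
#' @export
write_imputations <- function(set, dir, long = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (m in seq_len(set$M)) {
    utils::write.csv(set$datasets[[m]],
                     file.path(dir, sprintf("imputation_%03d.csv", m)),
                     row.names = FALSE)
  }
  if (long) {
    longdf <- do.call(rbind, lapply(seq_len(set$M), function(m) {
      cbind(dataset_id = m, set$datasets[[m]])
    }))
    utils::write.csv(longdf, file.path(dir, "imputations_long.csv"), row.names = FALSE)
  }
  jsonlite::write_json(
    list(M = set$M, pattern = set$meta$pattern, burn_in = set$meta$burn_in,
         thin = set$meta$thin, seed = set$meta$seed),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
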