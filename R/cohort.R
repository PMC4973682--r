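#' Configuration for a synthetic PROM cohort
#'
#' Builds the full parameter set for [generate_cohort()]: a patients-in-
#' providers cohort with ordinal questionnaire items generated from a
#' latent-normal threshold model, a post-operative outcome following the
#' case-mix analysis model (intercept + covariates + pre-op score + provider
#' random effect + residual, all on the 0-48 total-score scale), and
#' missingness following logistic selection models for the pre-operative (Q1)
#' and post-operative (Q2) questionnaires.
#'
#' Category probabilities and auxiliary-variable distributions default to
#' values typical of the English hip-replacement PROM survey (most patients
#' female, over 55, white, 0-1 comorbidities; pre-op total around 17.5,
#' post-op around 38 with SD near 9.5; about 61% of patients returning Q1 and
#' 52% both questionnaires). The default cohort is a desk-scale 50 providers
#' with mean volume 200.
#'
#' The post-operative selection model is
#' `logit P(R2 = 1) = eta0 + W eta1 + Z eta2 + phi_j + delta * (y2 - delta_center)`
#' with patient auxiliaries `W`, provider auxiliaries `Z`, a provider random
#' intercept `phi_j`, and `delta` the log-odds of response per unit of the
#' (possibly unobserved) post-operative total. `delta = 0` is MAR;
#' `delta_center` merely reparameterises the intercept so that `eta0` keeps
#' controlling the marginal response rate as `delta` moves. Q1 has its own
#' selection model (provider-level predictors, no outcome term by default),
#' and Q2 is only ever sent to Q1 responders, so `R1 = 0` forces `R2 = 0`.
#'
#' @param ... overrides for any configuration element; unknown names error.
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(...) {
  cfg <- list(
    n_providers   = 50L,
    volume_mean   = 200,
    volume_size   = 1.5,    # negative-binomial dispersion of provider volume
    volume_min    = 5L,
    prob_private  = 0.49,
    prob_teaching = 0.11,
    covariate_probs = list(
      age_band    = c(0.12, 0.22, 0.35, 0.31),
      sex         = c(0.60, 0.40),              # female, male
      ethnicity   = c(0.87, 0.13),              # white, nonwhite
      comorbidity = c(0.72, 0.21, 0.07),
      deprivation = c(0.13, 0.17, 0.23, 0.26, 0.21),  # most -> least deprived
      duration    = c(0.14, 0.67, 0.19)
    ),
    # per-level additive effects on the total-score scale
    beta1 = list(                                # pre-operative score
      age_band    = c(0, -0.3, -0.6, -1.0),
      sex         = c(0, 0.5),
      ethnicity   = c(0, -1.0),
      comorbidity = c(0, -1.0, -2.0),
      deprivation = c(0, 0.3, 0.6, 0.9, 1.2),
      duration    = c(0, -1.0, -2.0)
    ),
    beta2 = list(                                # post-operative score
      age_band    = c(0, 0.8, 1.2, 0.4),
      sex         = c(0, 0.3),
      ethnicity   = c(0, -1.5),
      comorbidity = c(0, -1.2, -2.5),
      deprivation = c(0, 0.4, 0.8, 1.2, 1.6),
      duration    = c(0, -0.8, -1.6)
    ),
    gamma       = 0.45,    # pre-op total coefficient in the analysis model
    mean_preop  = 17.5,    # target E[pre-op total]; fixes the pre-op intercept
    mean_postop = 38,      # target E[post-op total]; fixes alpha
    sigma_1     = 6.5,     # pre-op residual SD (total-score scale)
    sigma_u     = 1.5,     # provider effect SD (total-score scale)
    sigma_eps   = 8,       # post-op residual SD (total-score scale)
    rho         = 0.2,     # residual cross-item latent correlation
    thresholds  = ohs_thresholds(),
    # auxiliary variables; length of stay loads negatively on the post-op
    # residual (complications lengthen stay and depress recovery)
    aux = list(
      los_meanlog = log(4.5), los_sdlog = 0.8,
      los_comorb = 0.15, los_outcome = -0.35,
      wait_shape = 2.1, wait_scale = 42,
      prob_previous = 0.89, prob_preadmission = 0.82,
      prob_assisted = 0.94, prob_lives_alone = 0.26
    ),
    miss = miss_config(),
    seed = 1L
  )
  apply_overrides(cfg, list(...), "cohort_config")
}

#' Missingness configuration
#'
#' Parameters of the two logistic selection models (Q1, Q2), covariate
#' missingness, and optional per-item non-response. `delta` in the `r2` block
#' is the MNAR sensitivity parameter (log-odds of response per post-op score
#' unit); the `r1` block has an analogous `delta` acting on the pre-op total,
#' 0 by default. Covariate missingness is MCAR at the given rates (ethnicity
#' 11%, symptom duration 39% by default, mirroring the survey's observed
#' proportions).
#'
#' @param ... overrides for any element; unknown names error.
#' @return a list of class `miss_config`.
#' @export
miss_config <- function(...) {
  cfg <- list(
    enabled = TRUE,
    r1 = list(eta0 = 0.55, los = -0.02, wait = -0.001,
              private = 0.3, teaching = 0, log_volume = 0.1,
              sd_phi = 0.6, delta = 0),
    r2 = list(eta0 = 2.6, los = -0.06, wait = -0.001,
              previous = -0.2, preadmission = 0.3, assisted = -0.3,
              lives_alone = -0.4, sd_phi = 0.6, delta = 0),
    covariate_mcar = c(ethnicity = 0.11, duration = 0.39),
    item_nonresponse = 0
  )
  out <- apply_overrides(cfg, list(...), "miss_config")
  class(out) <- "miss_config"
  out
}

apply_overrides <- function(cfg, dots, what) {
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown ", what, " field(s): ", paste(bad, collapse = ", "))
    for (nm in names(dots)) {
      if (is.list(cfg[[nm]]) && is.list(dots[[nm]]) && !is.null(names(dots[[nm]]))) {
        sub <- dots[[nm]]
        badsub <- setdiff(names(sub), names(cfg[[nm]]))
        if (length(badsub)) stop("unknown ", what, "$", nm, " field(s): ",
                                 paste(badsub, collapse = ", "))
        cfg[[nm]][names(sub)] <- sub
      } else {
        cfg[[nm]] <- dots[[nm]]
      }
    }
  }
  class(cfg) <- what
  cfg
}

validate_config <- function(cfg) {
  stopifnot(cfg$n_providers >= 1, cfg$volume_min >= 1,
            cfg$sigma_u >= 0, cfg$sigma_eps >= 0, cfg$sigma_1 >= 0,
            cfg$rho > -1 / 23, cfg$rho < 1)
  check_thresholds(cfg$thresholds)
  for (nm in names(cfg$covariate_probs)) {
    p <- cfg$covariate_probs[[nm]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop("covariate probabilities for '", nm, "' must be non-negative and sum to 1")
    }
    if (length(cfg$beta1[[nm]]) != length(p) || length(cfg$beta2[[nm]]) != length(p)) {
      stop("effect vector length mismatch for covariate '", nm, "'")
    }
  }
  invisible(TRUE)
}

cov_levels <- list(
  age_band    = c("<55", "55-64", "65-74", "75+"),
  sex         = c("female", "male"),
  ethnicity   = c("white", "nonwhite"),
  comorbidity = c("0", "1", "2+"),
  deprivation = c("Q1", "Q2", "Q3", "Q4", "Q5"),
  duration    = c("<1y", "1-5y", ">5y")
)

# equicorrelated latent noise with unit marginal variance
cs_noise <- function(n, k, rho) {
  shared <- stats::rnorm(n)
  sqrt(rho) * shared + sqrt(1 - rho) * matrix(stats::rnorm(n * k), n, k)
}

categorize_items <- function(z, thresholds) {
  out <- matrix(NA_integer_, nrow(z), ncol(z))
  for (k in seq_len(ncol(z))) out[, k] <- latent_to_category(z[, k], thresholds[k, ])
  out
}

#' Generate a synthetic patients-in-providers PROM cohort
#'
#' Draws providers first (true outcome effects `u_j ~ N(0, sigma_u)`, true
#' response-propensity effects `phi_j`), then per patient: categorical
#' case-mix covariates; a pre-operative latent health level and 12 Q1 items
#' from the threshold model; a post-operative conditional mean
#' `alpha + X beta + gamma * y1 + u_j + eps` on the total-score scale mapped
#' through the inverse expected-total curve, and 12 Q2 items; auxiliary
#' variables (length of stay, waiting time, questionnaire-context flags);
#' and finally the configured missingness. Because the latent item mean is
#' placed by exact inversion of the expected-total curve, the analysis model
#' holds by construction: `E[y2 | X, y1, u] = alpha + X beta + gamma y1 + u`
#' away from the floor/ceiling.
#'
#' @param config a [cohort_config()].
#' @return a list of class `prom_cohort` with elements `providers` (one row
#'   per provider, including the true effects), `patients` (post-missingness
#'   records with `R1`/`R2` indicators and `NA` items), and `truth` (the same
#'   patients before any deletion, plus the true case-mix mean
#'   `casemix_mean = alpha + X beta + gamma y1`).
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_config(config)
  local_seed(config$seed)

  J <- config$n_providers
  providers <- data.frame(
    provider_id   = sprintf("P%03d", seq_len(J)),
    is_private    = stats::rbinom(J, 1, config$prob_private),
    is_teaching   = stats::rbinom(J, 1, config$prob_teaching),
    target_volume = pmax(config$volume_min,
                         stats::rnbinom(J, mu = config$volume_mean,
                                        size = config$volume_size)),
    u_true        = stats::rnorm(J, 0, config$sigma_u),
    phi1_true     = stats::rnorm(J, 0, config$miss$r1$sd_phi),
    phi2_true     = stats::rnorm(J, 0, config$miss$r2$sd_phi),
    stringsAsFactors = FALSE
  )

  n_j  <- providers$target_volume
  N    <- sum(n_j)
  prov <- rep(seq_len(J), n_j)

  covs <- lapply(names(cov_levels), function(nm) {
    p <- config$covariate_probs[[nm]]
    factor(cov_levels[[nm]][sample.int(length(p), N, replace = TRUE, prob = p)],
           levels = cov_levels[[nm]])
  })
  names(covs) <- names(cov_levels)

  xb <- function(effects) {
    out <- numeric(N)
    for (nm in names(cov_levels)) out <- out + effects[[nm]][as.integer(covs[[nm]])]
    out
  }
  mean_xb <- function(effects) {
    sum(vapply(names(cov_levels), function(nm)
      sum(config$covariate_probs[[nm]] * effects[[nm]]), numeric(1)))
  }

  finv <- total_inverse(config$thresholds)
  clip <- function(x) pmin(pmax(x, 0.1), 47.9)

  # pre-operative questionnaire
  alpha1 <- config$mean_preop - mean_xb(config$beta1)
  eta1   <- alpha1 + xb(config$beta1) + stats::rnorm(N, 0, config$sigma_1)
  z1     <- finv(clip(eta1)) + cs_noise(N, 12, config$rho)
  q1     <- categorize_items(z1, config$thresholds)
  y1     <- as.integer(rowSums(q1))

  # post-operative questionnaire, analysis-model mean on the total scale
  alpha2 <- config$mean_postop - mean_xb(config$beta2) -
    config$gamma * config$mean_preop
  casemix_mean <- alpha2 + xb(config$beta2) + config$gamma * y1
  eps2 <- stats::rnorm(N, 0, config$sigma_eps)
  eta2 <- casemix_mean + providers$u_true[prov] + eps2
  z2   <- finv(clip(eta2)) + cs_noise(N, 12, config$rho)
  q2   <- categorize_items(z2, config$thresholds)
  y2   <- as.integer(rowSums(q2))

  # auxiliaries; length of stay carries information about the post-op residual
  aux <- config$aux
  s2  <- if (config$sigma_eps > 0) eps2 / config$sigma_eps else numeric(N)
  comorb_idx <- as.integer(covs$comorbidity) - 1L
  los  <- round(stats::rlnorm(N, aux$los_meanlog + aux$los_comorb * comorb_idx +
                                aux$los_outcome * s2, aux$los_sdlog))
  wait <- round(stats::rgamma(N, shape = aux$wait_shape, scale = aux$wait_scale))

  truth <- data.frame(
    patient_id  = sprintf("S%06d", seq_len(N)),
    provider_id = providers$provider_id[prov],
    covs,
    length_of_stay   = pmin(los, 365),
    waiting_time     = wait,
    previous_surgery = stats::rbinom(N, 1, aux$prob_previous),
    pre_admission_q1 = stats::rbinom(N, 1, aux$prob_preadmission),
    assisted_q2      = stats::rbinom(N, 1, aux$prob_assisted),
    lives_alone      = stats::rbinom(N, 1, aux$prob_lives_alone),
    stringsAsFactors = FALSE
  )
  colnames(q1) <- paste0("q1_item_", 1:12)
  colnames(q2) <- paste0("q2_item_", 1:12)
  truth <- cbind(truth, q1, q2)
  truth$y1_total <- y1
  truth$y2_total <- y2
  truth$casemix_mean <- casemix_mean
  truth$R1 <- 1L
  truth$R2 <- 1L

  patients <- if (isTRUE(config$miss$enabled)) {
    apply_missingness(truth, providers, config$miss,
                      delta_center_q1 = config$mean_preop,
                      delta_center_q2 = config$mean_postop)
  } else {
    p <- truth
    p$casemix_mean <- NULL
    p
  }

  structure(list(providers = providers, patients = patients, truth = truth,
                 config = config),
            class = "prom_cohort")
}

#' Apply selection-model missingness to a complete cohort
#'
#' Sets the questionnaire response indicators by two logistic selection
#' models and deletes items accordingly. The Q2 indicator follows
#' `logit P(R2*=1) = eta0 + W eta1 + phi_j + delta (y2 - center)`; the Q1
#' indicator uses its own model with provider-level predictors; `R2` is
#' forced to 0 whenever `R1 = 0` (the post-operative questionnaire is only
#' sent to Q1 responders). Items are deleted as a block per questionnaire;
#' optional per-item non-response and MCAR covariate deletion follow.
#'
#' @param truth complete patient records from [generate_cohort()].
#' @param providers provider frame carrying `phi1_true`, `phi2_true` and the
#'   provider auxiliaries.
#' @param miss a [miss_config()].
#' @param delta_center_q1,delta_center_q2 centring constants for the
#'   outcome terms (reparameterise the intercepts only).
#' @param seed optional seed; by default continues the current RNG stream.
#' @return the patient frame with `R1`, `R2` set and missing values `NA`.
#' @export
apply_missingness <- function(truth, providers, miss = miss_config(),
                              delta_center_q1 = 17.5, delta_center_q2 = 38,
                              seed = NULL) {
  if (!is.null(seed)) local_seed(seed)
  p <- truth
  p$casemix_mean <- NULL
  pidx <- match(p$provider_id, providers$provider_id)
  N <- nrow(p)

  logv <- log(pmax(providers$target_volume, 1)) -
    log(pmax(mean(providers$target_volume), 1))

  m1 <- miss$r1
  lp1 <- m1$eta0 + m1$los * p$length_of_stay + m1$wait * p$waiting_time +
    m1$private * providers$is_private[pidx] +
    m1$teaching * providers$is_teaching[pidx] +
    m1$log_volume * logv[pidx] +
    providers$phi1_true[pidx] +
    m1$delta * (p$y1_total - delta_center_q1)
  R1 <- stats::rbinom(N, 1, stats::plogis(lp1))

  m2 <- miss$r2
  lp2 <- m2$eta0 + m2$los * p$length_of_stay + m2$wait * p$waiting_time +
    m2$previous * p$previous_surgery + m2$preadmission * p$pre_admission_q1 +
    m2$assisted * p$assisted_q2 + m2$lives_alone * p$lives_alone +
    providers$phi2_true[pidx] +
    m2$delta * (p$y2_total - delta_center_q2)
  R2 <- stats::rbinom(N, 1, stats::plogis(lp2)) * R1

  q1_cols <- paste0("q1_item_", 1:12)
  q2_cols <- paste0("q2_item_", 1:12)
  p[R1 == 0L, c(q1_cols, "y1_total")] <- NA
  p[R2 == 0L, c(q2_cols, "y2_total")] <- NA

  if (miss$item_nonresponse > 0) {
    for (cols in list(q1_cols, q2_cols)) {
      obs <- !is.na(p[[cols[1]]])
      drop <- matrix(stats::runif(sum(obs) * 12) < miss$item_nonresponse,
                     sum(obs), 12)
      block <- as.matrix(p[obs, cols])
      block[drop] <- NA
      p[obs, cols] <- block
    }
    p$y1_total <- ohs_total(p[, q1_cols])
    p$y2_total <- ohs_total(p[, q2_cols])
  }

  cm <- miss$covariate_mcar
  if (!is.null(cm["ethnicity"]) && cm[["ethnicity"]] > 0) {
    p$ethnicity[stats::runif(N) < cm[["ethnicity"]]] <- NA
  }
  if (!is.null(cm["duration"]) && cm[["duration"]] > 0) {
    p$duration[stats::runif(N) < cm[["duration"]]] <- NA
  }

  p$R1 <- R1
  p$R2 <- R2
  p
}

# set.seed without clobbering the caller's RNG stream
local_seed <- function(seed, envir = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  restore <- function() {
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
  do.call(on.exit, list(as.call(list(restore)), add = TRUE), envir = envir)
  set.seed(seed)
  invisible(NULL)
}

#' Write a cohort to plain-text files
#'
#' Writes `patients.csv`, `truth.csv`, `providers.csv`, the configuration as
#' YAML (`config.yml`) and a small JSON metadata file recording the seed.
#'
#' @param cohort a `prom_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$patients, file.path(dir, "patients.csv"), row.names = FALSE)
  if (!is.null(cohort$truth)) {
    utils::write.csv(cohort$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  }
  utils::write.csv(cohort$providers, file.path(dir, "providers.csv"), row.names = FALSE)
  if (!is.null(cohort$config)) {
    cfg <- cohort$config
    cfg$thresholds <- apply(cfg$thresholds, 1, paste, collapse = ",")
    if (requireNamespace("yaml", quietly = TRUE)) {
      yaml::write_yaml(unclass(cfg), file.path(dir, "config.yml"))
    }
  }
  jsonlite::write_json(list(seed = cohort$config$seed %||% NA,
                            n_patients = nrow(cohort$patients),
                            n_providers = nrow(cohort$providers)),
                       file.path(dir, "metadata.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' Restores the factor codings of the case-mix covariates; `truth.csv` is
#' optional (synthetic cohorts carry it, real extracts would not).
#'
#' @param dir directory containing `patients.csv`, `providers.csv` and
#'   optionally `truth.csv`.
#' @return a `prom_cohort` (without the generating config).
#' @export
read_cohort <- function(dir) {
  refactor <- function(d) {
    for (nm in names(cov_levels)) {
      if (nm %in% names(d)) d[[nm]] <- factor(d[[nm]], levels = cov_levels[[nm]])
    }
    d
  }
  patients <- refactor(utils::read.csv(file.path(dir, "patients.csv")))
  providers <- utils::read.csv(file.path(dir, "providers.csv"))
  out <- list(providers = providers, patients = patients)
  tp <- file.path(dir, "truth.csv")
  if (file.exists(tp)) out$truth <- refactor(utils::read.csv(tp))
  structure(out, class = "prom_cohort")
}
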