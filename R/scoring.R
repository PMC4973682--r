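#' Score the 12-item Oxford Hip Score
#'
#' The OHS total is the unweighted sum of 12 ordinal items, each scored
#' 0 (most severe symptoms) to 4 (no symptoms), giving a total between 0
#' (worst) and 48 (best). The total is only defined when all 12 items are
#' observed: item non-response is treated as missing data to be imputed at
#' item level, not pro-rated.
#'
#' @param items a length-12 vector of item scores in `{0,...,4}` (possibly
#'   `NA`), or an `n x 12` matrix/data frame of item scores, one row per
#'   questionnaire.
#' @return the integer total in `0..48`, or `NA` when any item is missing;
#'   vectorised over rows for matrix input.
#' @examples
#' ohs_total(rep(4, 12))   # 48, symptom free
#' ohs_total(rep(0, 12))   # 0, most severe
#' @export
ohs_total <- function(items) {
  if (is.data.frame(items)) items <- as.matrix(items)
  if (is.matrix(items)) {
    if (ncol(items) != 12L) stop("expected 12 item columns, got ", ncol(items))
    check_item_range(items)
    return(as.integer(rowSums(items)))  # rowSums propagates NA
  }
  if (length(items) != 12L) stop("expected 12 items, got ", length(items))
  check_item_range(items)
  if (anyNA(items)) return(NA_integer_)
  as.integer(sum(items))
}

check_item_range <- function(items) {
  bad <- !is.na(items) & (items < 0 | items > 4 | items != round(items))
  if (any(bad)) {
    stop("item scores must be integers in {0,...,4}; offending values: ",
         paste(utils::head(unique(items[bad]), 5), collapse = ", "))
  }
  invisible(TRUE)
}

#' Map latent values to ordinal categories through a threshold model
#'
#' Each ordinal item is modelled as a discretisation of a latent normal
#' variable cut at strictly increasing thresholds `alpha`: category 0 iff
#' `z <= alpha[1]`, category m iff `alpha[m] < z <= alpha[m+1]`, and the top
#' category iff `z > alpha[M-1]`. A value exactly on a cut-point belongs to
#' the lower category.
#'
#' @param z numeric vector of latent values.
#' @param thresholds strictly increasing numeric vector of `M - 1` cut-points.
#' @return integer categories in `0..(M-1)`, same length as `z`.
#' @export
latent_to_category <- function(z, thresholds) {
  check_thresholds(thresholds)
  out <- rep(NA_integer_, length(z))
  ok <- !is.na(z)
  # category = number of cut-points strictly below z (z == cut stays below)
  out[ok] <- findInterval(z[ok], thresholds, left.open = TRUE)
  out
}

check_thresholds <- function(thresholds) {
  if (anyNA(thresholds) || any(!is.finite(thresholds))) {
    stop("thresholds must be finite")
  }
  if (is.matrix(thresholds)) {
    if (any(apply(thresholds, 1L, function(r) any(diff(r) <= 0)))) {
      stop("thresholds must be strictly increasing within each item")
    }
  } else if (any(diff(thresholds) <= 0)) {
    stop("thresholds must be strictly increasing")
  }
  invisible(TRUE)
}

#' Default item thresholds for a 12-item instrument
#'
#' Returns a `n_items x 4` matrix of cut-points on the latent scale. The
#' per-item cut-points share a common shape and are staggered across items
#' (items differ in "difficulty"), so that the 48 cut-points spread roughly
#' evenly over the latent range. A spread-out cut-point set makes the
#' expected-total curve [expected_total()] close to linear over most of the
#' 0-48 range, which is the classical-test-theory behaviour of a sum score
#' with heterogeneous items.
#'
#' @param n_items number of items (12 for the OHS).
#' @param base common cut-point shape, strictly increasing length-4 vector.
#' @param spread half-range of the per-item difficulty offsets.
#' @return numeric matrix `n_items x 4`, rows strictly increasing.
#' @export
ohs_thresholds <- function(n_items = 12L,
                           base = c(-1.53, -0.51, 0.51, 1.53),
                           spread = 0.8) {
  offs <- if (n_items == 1L) 0 else seq(-spread, spread, length.out = n_items)
  thr <- outer(offs, base, `+`)
  check_thresholds(thr)
  thr
}

#' Expected total score as a function of a common latent shift
#'
#' For items generated as `Z_k = mu + e_k` with `e_k` standard normal and
#' cut-points `alpha^k`, the conditional mean of the total score is
#' `F(mu) = sum_k sum_m pnorm(mu - alpha^k_m)`, a strictly increasing map
#' from the latent scale onto (0, 48). Marginal item variances are 1, so
#' residual cross-item correlation does not change this curve.
#'
#' @param mu numeric vector of latent shifts.
#' @param thresholds `n_items x (M-1)` cut-point matrix (see
#'   [ohs_thresholds()]).
#' @return expected totals, same length as `mu`.
#' @export
expected_total <- function(mu, thresholds) {
  check_thresholds(thresholds)
  a <- as.vector(thresholds)
  vapply(mu, function(m) sum(stats::pnorm(m - a)), numeric(1))
}

#' Inverse of the expected-total curve
#'
#' Builds a fast monotone interpolator for `F^{-1}` where `F` is
#' [expected_total()]. Used by the cohort generator to place a patient's
#' latent item mean so that the expected total equals a target value on the
#' 0-48 scale.
#'
#' @param thresholds cut-point matrix as in [expected_total()].
#' @param mu_range latent range covered by the interpolation grid.
#' @return a function mapping totals (within `F(mu_range)`) to latent shifts.
#' @export
total_inverse <- function(thresholds, mu_range = c(-8, 8)) {
  grid <- seq(mu_range[1], mu_range[2], by = 0.005)
  f <- expected_total(grid, thresholds)
  stats::approxfun(f, grid, rule = 2)
}
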