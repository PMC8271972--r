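#' Penalty weights for the pairwise dissimilarity
#'
#' Non-negative weights on the three dissimilarity components: `w1` on the
#' squared Euclidean distance, `w2` on the null-series penalty, `w3` on the
#' constant-series penalty. The default (1, 1, 1) weights the components
#' equally.
#'
#' @param w1,w2,w3 non-negative reals.
#' @return a `penalty_weights` list.
#' @export
penalty_weights <- function(w1 = 1, w2 = 1, w3 = 1) {
  w <- c(w1 = w1, w2 = w2, w3 = w3)
  if (any(!is.finite(w)) || any(w < 0)) {
    stop_invalid("penalty weights must be finite and >= 0")
  }
  structure(as.list(w), class = "penalty_weights")
}

#' Total variation of a series
#'
#' Sum of absolute differences between consecutive values; 0 for constant or
#' length-1 input. This is the `diff` statistic used by the constant-series
#' penalty: a series that barely moves has small total variation, so
#' `exp(-total_variation(x))` approaches 1.
#'
#' @param values numeric vector, length >= 1, finite.
#' @return non-negative real.
#' @export
total_variation <- function(values) {
  check_finite_numeric(values, "series values")
  if (length(values) < 2) return(0)
  sum(abs(diff(values)))
}

#' Is a series null?
#'
#' A series is null when its largest absolute value does not exceed `tol`.
#' The tolerance absorbs floating-point residue left by spline resampling of
#' an all-zero channel.
#'
#' @param values numeric vector.
#' @param tol non-negative tolerance on max absolute value (default 1e-8).
#' @return logical.
#' @export
is_null_series <- function(values, tol = 1e-8) {
  length(values) == 0 || max(abs(values)) <= tol
}

#' Pairwise dissimilarity between two joint-angle series
#'
#' Computes the three components and their weighted sum:
#' `z1` the squared Euclidean distance, `z2` the null penalty (2 when either
#' series is null, else 0), `z3 = exp(-TV(x)) + exp(-TV(y))` the constant
#' penalty (TV = total variation), and `z = w1*z1 + w2*z2 + w3*z3`.
#'
#' @param ti,tj numeric vectors of equal length.
#' @param weights a [penalty_weights()] object.
#' @param null_tol tolerance for [is_null_series()].
#' @return one-row tibble with columns `z1`, `z2`, `z3`, `z`.
#' @export
pair_dissimilarity <- function(ti, tj, weights = penalty_weights(),
                               null_tol = 1e-8) {
  if (length(ti) != length(tj)) {
    stop_invalid("series must have equal length (resample the cohort first)")
  }
  check_finite_numeric(ti, "series values")
  check_finite_numeric(tj, "series values")
  z1 <- sum((ti - tj)^2)
  z2 <- if (is_null_series(ti, null_tol) || is_null_series(tj, null_tol)) 2 else 0
  z3 <- exp(-total_variation(ti)) + exp(-total_variation(tj))
  tibble(z1 = z1, z2 = z2, z3 = z3,
         z = weights$w1 * z1 + weights$w2 * z2 + weights$w3 * z3)
}

#' Dissimilarity matrix for a set of series
#'
#' Symmetric matrix with zero diagonal whose off-diagonal entries are the
#' pairwise dissimilarities. With `normalize = TRUE` the squared-distance
#' component is divided by its off-diagonal mean before the penalties are
#' added, putting it on the O(1) scale the null/constant penalties (2 and at
#' most 2) are calibrated to; raw squared distances over 1500 samples in
#' degrees are several orders of magnitude larger and would otherwise drown
#' the penalties.
#'
#' @param series list of equal-length numeric vectors (one per angle), or a
#'   cohort series tibble slice with a `values` list column.
#' @param weights a [penalty_weights()] object.
#' @param normalize divide z1 by its off-diagonal mean first (default FALSE,
#'   the raw composition).
#' @param null_tol tolerance for [is_null_series()].
#' @return `n x n` numeric matrix.
#' @export
dissimilarity_matrix <- function(series, weights = penalty_weights(),
                                 normalize = FALSE, null_tol = 1e-8) {
  if (is.data.frame(series)) series <- series$values
  n <- length(series)
  if (n < 2) stop_invalid("need at least two series")
  lens <- lengths(series)
  if (length(unique(lens)) != 1) {
    stop_invalid("all series must have equal length (resample the cohort first)")
  }
  for (v in series) check_finite_numeric(v, "series values")
  X <- do.call(rbind, series)
  z1 <- as.matrix(dist(X))^2
  if (normalize) {
    mu <- mean(z1[upper.tri(z1)])
    if (mu > 0) z1 <- z1 / mu
  }
  nullv <- map_lgl(series, is_null_series, tol = null_tol)
  ev <- exp(-map_dbl(series, total_variation))
  z2 <- (outer(nullv, nullv, `|`)) * 2
  z3 <- outer(ev, ev, `+`)
  Z <- weights$w1 * z1 + weights$w2 * z2 + weights$w3 * z3
  diag(Z) <- 0
  Z <- (Z + t(Z)) / 2  # exact symmetry against floating-point asymmetry
  rownames(Z) <- colnames(Z) <- names(series)
  Z
}

#' Write a dissimilarity matrix as CSV (diagnostic)
#'
#' @param Z square matrix from [dissimilarity_matrix()].
#' @param path output CSV file.
#' @param angle_names optional header names.
#' @return `path`, invisibly.
#' @export
write_dissimilarity_csv <- function(Z, path, angle_names = colnames(Z)) {
  df <- as.data.frame(Z)
  if (!is.null(angle_names)) names(df) <- angle_names
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}
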