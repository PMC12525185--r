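#' Determination coefficient (squared Pearson correlation)
#'
#' @param observed,predicted Numeric vectors of equal length (n >= 2).
#' @return Squared Pearson correlation between the two vectors.
#' @export
stat_r2 <- function(observed, predicted) {
  check_pair(observed, predicted, 2L)
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0)
    stop("undefined statistic: zero variance in observed or predicted")
  stats::cor(observed, predicted)^2
}

#' Lin's concordance correlation coefficient
#'
#' CCC = 2*cov(o, p) / (var(o) + var(p) + (mean(o) - mean(p))^2), a measure
#' of agreement with the identity line; 1 only when observed equals predicted
#' elementwise.
#'
#' @inheritParams stat_r2
#' @return CCC in \[-1, 1\].
#' @export
stat_ccc <- function(observed, predicted) {
  check_pair(observed, predicted, 2L)
  vo <- stats::var(observed)
  vp <- stats::var(predicted)
  if (vo == 0 && vp == 0)
    stop("undefined statistic: both vectors constant")
  2 * stats::cov(observed, predicted) /
    (vo + vp + (mean(observed) - mean(predicted))^2)
}

#' Index of ideality of correlation (IIC)
#'
#' IIC is the Pearson correlation multiplied by the ratio of the smaller to
#' the larger one-sided mean absolute error, where residuals
#' `delta = observed - predicted` are split into the negative class
#' (`delta < 0`) and the non-negative class (`delta >= 0`).  It is therefore
#' simultaneously sensitive to the strength of the correlation and to the
#' asymmetry of the residuals around the fitted line.  Conventions: if all
#' residuals are exactly zero the MAE ratio is 1 (IIC equals r); if exactly
#' one residual class is empty the ratio is 0 (maximal asymmetry).
#'
#' @inheritParams stat_r2
#' @return IIC value; satisfies `abs(iic) <= abs(r)`.
#' @examples
#' stat_iic(c(0, 1, 3), c(1, 1, 2))  # 0.47245...
#' @export
stat_iic <- function(observed, predicted) {
  check_pair(observed, predicted, 2L)
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0)
    stop("undefined statistic: zero variance in observed or predicted")
  r <- stats::cor(observed, predicted)
  r * mae_ratio(observed - predicted)
}

# min/max ratio of one-sided MAEs with the documented edge conventions
mae_ratio <- function(delta) {
  neg <- delta[delta < 0]
  pos <- delta[delta >= 0]
  if (all(delta == 0)) return(1)
  if (length(neg) == 0L || length(pos) == 0L) return(0)
  mneg <- mean(abs(neg))
  mpos <- mean(abs(pos))
  if (mneg == 0 && mpos == 0) return(1)
  min(mneg, mpos) / max(mneg, mpos)
}

#' Leave-one-out cross-validated determination coefficient
#'
#' Q2 = 1 - PRESS/TSS for the one-variable least-squares line of `endpoints`
#' on `dcw_values`, with PRESS computed by the closed leverage form
#' `e_i / (1 - h_i)` so no refitting is needed.
#'
#' @param dcw_values Numeric descriptor values (n >= 4, non-constant).
#' @param endpoints Numeric observed endpoints.
#' @return Q2; always `<=` the in-sample R2.
#' @export
stat_q2_loo <- function(dcw_values, endpoints) {
  check_pair(dcw_values, endpoints, 4L)
  x <- dcw_values
  y <- endpoints
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0)
    stop("degenerate descriptor: zero variance in dcw_values")
  b <- sum((x - mean(x)) * (y - mean(y))) / sxx
  a <- mean(y) - b * mean(x)
  e <- y - (a + b * x)
  h <- 1 / n + (x - mean(x))^2 / sxx
  press <- sum((e / (1 - h))^2)
  tss <- sum((y - mean(y))^2)
  1 - press / tss
}

#' Fischer F-ratio from a determination coefficient
#'
#' For the one-descriptor linear model, `F = r2 * (n - 2) / (1 - r2)`.
#' Published tables report it rounded to the nearest integer.
#'
#' @param r2 Determination coefficient in \[0, 1).
#' @param n Number of observations (n >= 3).
#' @return The F-ratio (not rounded).
#' @examples
#' round(f_from_r2(0.4791, 63))  # 56
#' round(f_from_r2(0.6803, 65))  # 134
#' @export
f_from_r2 <- function(r2, n) {
  if (any(r2 < 0) || any(r2 >= 1))
    stop("r2 must lie in [0, 1); r2 = 1 gives an infinite F")
  if (any(n < 3)) stop("n must be at least 3")
  r2 * (n - 2) / (1 - r2)
}

#' Root mean squared error and mean absolute error
#'
#' @inheritParams stat_r2
#' @return Named numeric vector `c(rmse = ..., mae = ...)`.
#' @export
stat_rmse_mae <- function(observed, predicted) {
  check_pair(observed, predicted, 1L)
  e <- observed - predicted
  c(rmse = sqrt(mean(e^2)), mae = mean(abs(e)))
}

#' Residual-sign cluster diagnostic
#'
#' Splits the observed-vs-predicted cloud into two clusters by residual sign
#' (`observed < predicted` versus `observed >= predicted`; ties go to the
#' high cluster) and reports the determination coefficient overall and within
#' each cluster.  Under IIC-driven optimization the per-cluster correlations
#' can be much stronger than the overall one, the signature of a population
#' mixing typical and atypical molecules.
#'
#' @inheritParams stat_r2
#' @return A list of class `"cluster_report"` with `overall_r2`,
#'   `low_cluster_r2`, `high_cluster_r2` (NA when a cluster has fewer than 3
#'   points or zero variance), and cluster sizes `n_low`, `n_high`.
#' @export
cluster_r2 <- function(observed, predicted) {
  check_pair(observed, predicted, 4L)
  delta <- observed - predicted
  low <- delta < 0
  safe_r2 <- function(o, p) {
    if (length(o) < 3L || stats::sd(o) == 0 || stats::sd(p) == 0) return(NA_real_)
    stats::cor(o, p)^2
  }
  structure(list(
    overall_r2 = safe_r2(observed, predicted),
    low_cluster_r2 = safe_r2(observed[low], predicted[low]),
    high_cluster_r2 = safe_r2(observed[!low], predicted[!low]),
    n_low = sum(low),
    n_high = sum(!low)
  ), class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf("Residual-sign clusters: overall R2 = %.4f\n", x$overall_r2))
  cat(sprintf("  low  (obs <  pred): n = %d, R2 = %s\n", x$n_low,
              format(x$low_cluster_r2, digits = 4)))
  cat(sprintf("  high (obs >= pred): n = %d, R2 = %s\n", x$n_high,
              format(x$high_cluster_r2, digits = 4)))
  invisible(x)
}

#' Full statistics bundle for one set
#'
#' Computes the standard report row for a compound set: n, R2, CCC, IIC, Q2
#' (leave-one-out on the descriptor), RMSE, MAE and F.  Q2 and F are NA when
#' the preconditions fail (for instance on a validation set of fewer than 4
#' compounds, or R2 numerically 1).
#'
#' @param observed Observed endpoints.
#' @param predicted Model predictions for the same compounds.
#' @param dcw Optional descriptor values for the Q2 computation; defaults to
#'   `predicted` (identical up to the affine calibration, so Q2 is the same).
#' @return Named list with elements `n, r2, ccc, iic, q2, rmse, mae, f`.
#' @export
stat_bundle <- function(observed, predicted, dcw = predicted) {
  rm_ <- stat_rmse_mae(observed, predicted)
  r2 <- stat_r2(observed, predicted)
  q2 <- if (length(observed) >= 4L && stats::sd(dcw) > 0)
    stat_q2_loo(dcw, observed) else NA_real_
  f <- if (r2 < 1) f_from_r2(r2, length(observed)) else NA_real_
  list(n = length(observed),
       r2 = r2,
       ccc = stat_ccc(observed, predicted),
       iic = stat_iic(observed, predicted),
       q2 = q2,
       rmse = unname(rm_["rmse"]),
       mae = unname(rm_["mae"]),
       f = f)
}

check_pair <- function(x, y, nmin) {
  if (!is.numeric(x) || !is.numeric(y)) stop("inputs must be numeric")
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (length(x) < nmin) stop("need at least ", nmin, " observations")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  invisible(TRUE)
}
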