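# Outlier screening: spectral outliers by the GH (global Mahalanobis)
# distance, laboratory outliers by the t-statistic of residuals.

#' GH distance of factor scores
#'
#' The global H statistic: the squared Mahalanobis distance of each sample's
#' score vector from the score centroid, divided by the number of factors k.
#' Under this normalization the calibration-set mean of GH is (n-1)/n, just
#' below 1, and GH > 3 is the conventional spectral-outlier cutoff.
#'
#' @param scores Numeric matrix of factor scores, samples in rows.
#' @return Numeric vector of GH distances (>= 0).
#' @export
gh_distance <- function(scores) {
  scores <- as.matrix(scores)
  k <- ncol(scores)
  if (k < 1) stop("scores must have at least one factor")
  S <- stats::cov(scores)
  ok <- tryCatch({
    d2 <- stats::mahalanobis(scores, colMeans(scores), S)
    TRUE
  }, error = function(e) FALSE)
  if (!ok || !all(is.finite(d2))) {
    stop("singular score covariance; use fewer factors for GH screening")
  }
  d2 / k
}

outlier_report <- function(sample_ids, gh = NA_real_, t_stat = NA_real_,
                           gh_cutoff = 3.0, t_cutoff = 2.5,
                           round_removed = NA_integer_) {
  df <- data.frame(sample_id = as.character(sample_ids),
                   gh = gh,
                   spectral_flag = !is.na(gh) & gh > gh_cutoff,
                   t_stat = t_stat,
                   lab_flag = !is.na(t_stat) & t_stat > t_cutoff,
                   round_removed = round_removed,
                   stringsAsFactors = FALSE)
  attr(df, "gh_cutoff") <- gh_cutoff
  attr(df, "t_cutoff") <- t_cutoff
  class(df) <- c("outlier_report", "data.frame")
  df
}

#' @export
print.outlier_report <- function(x, ...) {
  n_s <- sum(x$spectral_flag, na.rm = TRUE)
  n_l <- sum(x$lab_flag, na.rm = TRUE)
  cat("Outlier report:", nrow(x), "samples;", n_s,
      "spectral flag(s) (GH >", attr(x, "gh_cutoff"), "),", n_l,
      "lab flag(s) (t >", attr(x, "t_cutoff"), ")\n")
  flagged <- x[x$spectral_flag | x$lab_flag, , drop = FALSE]
  if (nrow(flagged)) print(as.data.frame(flagged), row.names = FALSE)
  invisible(x)
}

#' Screen spectra for population outliers
#'
#' Computes factor scores of the (preprocessed) spectra -- PLS scores when a
#' response is supplied, principal-component scores otherwise -- and flags
#' samples whose GH distance exceeds the cutoff. Screening iterates up to
#' `max_rounds`, removing flagged samples and re-deriving scores, because a
#' gross outlier inflates the covariance that shields milder ones.
#'
#' @param x An `aligned_dataset`, [spectrum_set()] or numeric matrix.
#' @param treatment Optional [math_treatment()] applied before scoring (for a
#'   `spectrum_set`/`aligned_dataset` input).
#' @param k Number of factors for the score space (default 10, capped by the
#'   data).
#' @param cutoff GH cutoff, default 3.0.
#' @param y Optional response; when given, scores come from a PLS
#'   decomposition against it.
#' @param max_rounds Maximum removal rounds (default 2).
#' @return An [outlier_report] for all input samples; `round_removed` records
#'   the round in which a sample was flagged.
#' @export
screen_spectral <- function(x, treatment = NULL, k = 10, cutoff = 3.0,
                            y = NULL, max_rounds = 2) {
  if (inherits(x, "aligned_dataset")) x <- x$spectra
  if (inherits(x, "spectrum_set")) {
    if (!is.null(treatment)) x <- apply_treatment(x, treatment)
    ids <- x$sample_ids
    X <- x$absorbance
  } else {
    X <- as.matrix(x)
    ids <- rownames(X) %||% sprintf("S%03d", seq_len(nrow(X)))
  }
  n <- nrow(X)
  keep <- rep(TRUE, n)
  gh_all <- rep(NA_real_, n)
  round_removed <- rep(NA_integer_, n)
  for (round in seq_len(max_rounds)) {
    idx <- which(keep)
    kk <- min(k, length(idx) - 2, ncol(X))
    if (kk < 1) stop("too few samples left for GH screening")
    Xi <- X[idx, , drop = FALSE]
    scores <- if (is.null(y)) {
      stats::prcomp(Xi, center = TRUE, scale. = FALSE)$x[, seq_len(kk),
                                                         drop = FALSE]
    } else {
      suppressWarnings(nipals_pls(Xi, y[idx], ncomp = kk))$scores
    }
    gh <- gh_distance(scores)
    gh_all[idx] <- gh
    flagged <- gh > cutoff
    if (all(flagged)) stop("all samples flagged as spectral outliers")
    if (!any(flagged)) break
    round_removed[idx[flagged]] <- round
    keep[idx[flagged]] <- FALSE
  }
  outlier_report(ids, gh = gh_all, gh_cutoff = cutoff,
                 round_removed = round_removed)
}

#' Screen laboratory values against model predictions
#'
#' Flags a laboratory value as an outlier when the difference between
#' predicted and observed values exceeds `cutoff` standard errors (strict
#' inequality): t = |predicted - observed| / SEC.
#'
#' @param y_obs Observed laboratory values.
#' @param y_pred Model predictions, aligned with `y_obs`.
#' @param sec Standard error of calibration (> 0), same units as `y_obs`.
#' @param cutoff t-statistic cutoff, default 2.5.
#' @param sample_ids Optional identifiers.
#' @return An [outlier_report].
#' @export
screen_lab <- function(y_obs, y_pred, sec, cutoff = 2.5,
                       sample_ids = NULL) {
  if (length(y_obs) != length(y_pred)) stop("y_obs and y_pred not aligned")
  if (!is.finite(sec) || sec <= 0) stop("sec must be > 0")
  t_stat <- abs(y_pred - y_obs) / sec
  ids <- sample_ids %||% names(y_obs) %||%
    sprintf("S%03d", seq_along(y_obs))
  outlier_report(ids, t_stat = t_stat, t_cutoff = cutoff)
}
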