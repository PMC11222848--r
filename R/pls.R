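# NIPALS PLS1 regression with cross-validated factor selection.

#' Fit a PLS1 model by NIPALS
#'
#' Extracts latent factors by successive deflation, each factor maximizing
#' covariance with the response. The predictor matrix is centered internally
#' (centering stored in the model); autoscaling is off by default, the usual
#' choice for NIR absorbance, and can be enabled with `scale = TRUE`.
#'
#' @param X Numeric matrix, samples in rows, spectral channels in columns.
#' @param y Numeric response vector, one value per row of `X`.
#' @param ncomp Number of latent factors to extract; truncated to the rank
#'   of the problem with a warning if it exceeds it.
#' @param scale Logical: divide each column by its standard deviation.
#' @param tol Convergence tolerance on the weight vector in the inner loop;
#'   PLS1 converges in one pass, the loop guards degenerate cases.
#' @param maxit Inner-loop iteration cap.
#'
#' @return An object of class `nipals_pls` with components `x_mean`,
#'   `y_mean`, `x_scale`, `weights` (W), `loadings` (P), `q`, `scores` (T),
#'   `coefficients` (a channels-by-ncomp matrix whose k-th column is the
#'   regression vector using the first k factors), `fitted_path`, `ncomp`,
#'   `y`.
#' @seealso [predict.nipals_pls()], [select_factors()]
#' @export
nipals_pls <- function(X, y, ncomp = 16, scale = FALSE, tol = 1e-10,
                       maxit = 500) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  p <- ncol(X)
  if (length(y) != n) stop("rows of X and y are not aligned")
  if (stats::var(y) < .Machine$double.eps) {
    stop("degenerate response: y has zero variance")
  }
  cap <- min(ncomp, n - 1, p)
  if (cap < ncomp) {
    warning("ncomp reduced from ", ncomp, " to ", cap,
            " (limited by n - 1 and channel count)", call. = FALSE)
  }
  x_mean <- colMeans(X)
  Xc <- X - rep(x_mean, each = n)
  x_scale <- NULL
  if (scale) {
    x_scale <- apply(X, 2, stats::sd)
    x_scale[x_scale == 0] <- 1
    Xc <- Xc / rep(x_scale, each = n)
  }
  y_mean <- mean(y)
  yc <- y - y_mean
  sse0 <- sum(yc^2)

  W <- P <- matrix(0, p, cap)
  Tm <- matrix(0, n, cap)
  qv <- numeric(cap)
  A <- 0L
  for (a in seq_len(cap)) {
    w <- drop(crossprod(Xc, yc))
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12 || sum(yc^2) < 1e-12 * max(sse0, 1)) break
    w <- w / wn
    for (it in seq_len(maxit)) {
      tv <- drop(Xc %*% w)
      tt <- sum(tv^2)
      if (tt < .Machine$double.eps) break
      qa <- sum(yc * tv) / tt
      w_new <- drop(crossprod(Xc, yc * qa))
      w_new <- w_new / sqrt(sum(w_new^2))
      if (sum((w_new - w)^2) < tol^2) break
      w <- w_new
    }
    tv <- drop(Xc %*% w)
    tt <- sum(tv^2)
    if (tt < 1e-12 * max(sum(Xc^2), 1)) break
    pa <- drop(crossprod(Xc, tv)) / tt
    qa <- sum(yc * tv) / tt
    Xc <- Xc - tcrossprod(tv, pa)
    yc <- yc - qa * tv
    A <- a
    W[, a] <- w
    P[, a] <- pa
    Tm[, a] <- tv
    qv[a] <- qa
  }
  if (A == 0L) stop("no informative factor could be extracted")
  if (A < cap && cap == ncomp) {
    warning("ncomp truncated to rank ", A, call. = FALSE)
  }
  W <- W[, seq_len(A), drop = FALSE]
  P <- P[, seq_len(A), drop = FALSE]
  Tm <- Tm[, seq_len(A), drop = FALSE]
  qv <- qv[seq_len(A)]

  # Coefficient paths: b_k = W_k (P_k' W_k)^{-1} q_k, assembled cumulatively.
  Rw <- W %*% solve(crossprod(P, W))
  B <- Rw %*% (outer(seq_len(A), seq_len(A), `<=`) * qv)
  if (scale) B <- B / x_scale
  Xc0 <- X - rep(x_mean, each = n)
  fitted_path <- y_mean + Xc0 %*% B

  structure(list(x_mean = x_mean, y_mean = y_mean, x_scale = x_scale,
                 weights = W, loadings = P, q = qv, scores = Tm,
                 coefficients = B, fitted_path = fitted_path,
                 ncomp = A, y = y),
            class = "nipals_pls")
}

#' @export
print.nipals_pls <- function(x, ...) {
  cat("NIPALS PLS1 model:", x$ncomp, "factors,",
      length(x$x_mean), "channels,", length(x$y), "training samples\n")
  invisible(x)
}

#' @export
summary.nipals_pls <- function(object, ...) {
  res <- object$y - object$fitted_path
  sst <- sum((object$y - mean(object$y))^2)
  tab <- data.frame(factors = seq_len(object$ncomp),
                    r2 = 1 - colSums(res^2) / sst,
                    rmse = sqrt(colMeans(res^2)))
  cat("NIPALS PLS1 fit (training):\n")
  print(tab, row.names = FALSE, digits = 4)
  invisible(tab)
}

#' Regression coefficients of a PLS model
#'
#' @param object A [nipals_pls()] model.
#' @param ncomp Number of factors to use (default: all extracted).
#' @param intercept Include the intercept as the first element.
#' @param ... Unused.
#' @return Named numeric vector of per-channel coefficients.
#' @export
coef.nipals_pls <- function(object, ncomp = object$ncomp,
                            intercept = FALSE, ...) {
  b <- object$coefficients[, ncomp]
  if (intercept) {
    c("(Intercept)" = object$y_mean - sum(object$x_mean * b), b)
  } else {
    b
  }
}

#' Predict from a PLS model
#'
#' Computes `y_mean + (X_new - x_mean) %*% b`. New spectra must already be
#' preprocessed with the same treatment as the training spectra.
#'
#' @param object A [nipals_pls()] model.
#' @param newdata Matrix (or vector) of preprocessed spectra.
#' @param ncomp Number of factors to use.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.nipals_pls <- function(object, newdata, ncomp = object$ncomp, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$x_mean)) {
    stop("channel mismatch: model expects ", length(object$x_mean),
         " channels, got ", ncol(newdata))
  }
  b <- object$coefficients[, ncomp]
  drop(object$y_mean +
         (newdata - rep(object$x_mean, each = nrow(newdata))) %*% b)
}

#' @export
fitted.nipals_pls <- function(object, ncomp = object$ncomp, ...) {
  drop(object$fitted_path[, ncomp])
}

#' @export
residuals.nipals_pls <- function(object, ncomp = object$ncomp, ...) {
  object$y - drop(object$fitted_path[, ncomp])
}

# Cross-validated prediction paths: returns pooled out-of-fold predictions
# for factor counts 1..cap, plus the per-count SECV. Folds with fewer
# extractable factors than cap contribute their deepest available column.
cv_pls_path <- function(X, y, cap = 16, cv = cv_spec()) {
  X <- as.matrix(X)
  n <- nrow(X)
  folds <- make_folds(n, cv)
  for (attempt in 1:2) {
    tr_var <- vapply(sort(unique(folds)), function(f) {
      stats::var(y[folds != f])
    }, numeric(1))
    if (all(tr_var > .Machine$double.eps)) break
    if (attempt == 2) stop("a training fold has zero response variance")
    folds <- make_folds(n, cv_spec(cv$scheme, cv$k, cv$seed + 1L, TRUE))
  }
  cap <- min(cap, n - max(tabulate(folds)) - 1, ncol(X))
  pred <- matrix(NA_real_, n, cap)
  for (f in sort(unique(folds))) {
    te <- folds == f
    fit <- suppressWarnings(
      nipals_pls(X[!te, , drop = FALSE], y[!te], ncomp = cap))
    pk <- vapply(seq_len(fit$ncomp), function(k) {
      predict(fit, X[te, , drop = FALSE], ncomp = k)
    }, numeric(sum(te)))
    pk <- matrix(pk, nrow = sum(te))
    if (fit$ncomp < cap) {
      pk <- cbind(pk, matrix(pk[, fit$ncomp],
                             sum(te), cap - fit$ncomp))
    }
    pred[te, ] <- pk
  }
  secv <- sqrt(colMeans((pred - y)^2))
  list(pred = pred, secv = secv, folds = folds, cap = cap)
}

make_folds <- function(n, cv) {
  if (cv$scheme == "leave_one_out") return(seq_len(n))
  k <- cv$k
  if (k < 2 || k > n) stop("cross-validation needs 2 <= k <= n")
  base <- rep_len(seq_len(k), n)
  if (cv$shuffle) with_seed(cv$seed, sample(base)) else base
}

#' Select the PLS factor count by cross-validation
#'
#' Returns the factor count (up to `cap`, the conventional 16-factor limit)
#' minimizing the cross-validated standard error; ties break toward fewer
#' factors.
#'
#' @param X Preprocessed predictor matrix.
#' @param y Response vector.
#' @param cap Maximum number of factors considered.
#' @param cv A [cv_spec()].
#' @return Integer factor count.
#' @export
select_factors <- function(X, y, cap = 16, cv = cv_spec()) {
  path <- cv_pls_path(X, y, cap = cap, cv = cv)
  which.min(path$secv)
}
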