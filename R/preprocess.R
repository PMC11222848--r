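# Spectral pretreatments: log(1/R), SNV, detrend, gap-segment derivatives,
# and their composition into the NIRS "math treatment" codes.

#' Reflectance to absorbance
#'
#' Element-wise log(1/R). Base 10 is the dominant NIRS convention for the
#' "log 1/R" transform; the natural log is selectable and differs only by a
#' constant factor that downstream regression absorbs.
#'
#' @param reflectance Numeric vector or matrix with values strictly in (0, 1].
#' @param base `"log10"` (default) or `"natural"`.
#' @return Same shape as the input, absorbance units.
#' @export
absorbance_transform <- function(reflectance, base = c("log10", "natural")) {
  base <- match.arg(base)
  bad <- reflectance <= 0 | reflectance > 1
  if (any(bad, na.rm = TRUE) || anyNA(reflectance)) {
    idx <- which(bad | is.na(reflectance))[1]
    if (is.matrix(reflectance)) {
      ai <- arrayInd(idx, dim(reflectance))
      stop("reflectance outside (0, 1] at row ", ai[1], ", column ", ai[2])
    }
    stop("reflectance outside (0, 1] at position ", idx)
  }
  if (base == "log10") -log10(reflectance) else -log(reflectance)
}

#' Standard normal variate (SNV)
#'
#' Centers and scales each spectrum to zero mean and unit sample standard
#' deviation (denominator n - 1), removing per-sample multiplicative scatter
#' and additive offsets.
#'
#' @param spectrum Numeric vector (a single spectrum) or matrix (spectra in
#'   rows, each transformed independently).
#' @return Transformed spectrum or matrix.
#' @export
snv <- function(spectrum) {
  if (is.matrix(spectrum)) return(snv_rows(spectrum))
  if (length(spectrum) < 2) stop("SNV needs at least two channels")
  s <- stats::sd(spectrum)
  if (!is.finite(s) || s == 0) {
    stop("degenerate (constant) spectrum: SNV undefined")
  }
  (spectrum - mean(spectrum)) / s
}

snv_rows <- function(X) {
  m <- rowMeans(X)
  Xc <- X - m
  s <- sqrt(rowSums(Xc^2) / (ncol(X) - 1))
  if (any(s == 0)) {
    stop("degenerate (constant) spectrum in row(s): ",
         paste(which(s == 0), collapse = ", "))
  }
  Xc / s
}

#' Detrend correction
#'
#' Removes a low-order polynomial baseline: returns the residual of a
#' least-squares fit of absorbance on wavelength. The residual is orthogonal
#' to the polynomial basis, and the operator is an idempotent projection.
#'
#' @param spectrum Numeric vector, or matrix with spectra in rows.
#' @param wavelengths Numeric grid matching the spectrum length.
#' @param poly_order Polynomial order of the baseline, default 2 (quadratic),
#'   the usual SNV-detrend convention.
#' @return Detrended spectrum (same shape as input).
#' @export
detrend <- function(spectrum, wavelengths, poly_order = 2) {
  if (poly_order < 0) stop("poly_order must be >= 0")
  p <- if (is.matrix(spectrum)) ncol(spectrum) else length(spectrum)
  if (length(wavelengths) != p) {
    stop("wavelengths length does not match the spectrum")
  }
  if (p <= poly_order + 1) {
    stop("spectrum too short for a degree-", poly_order, " baseline")
  }
  Q <- poly_basis(wavelengths, poly_order)
  if (is.matrix(spectrum)) {
    spectrum - (spectrum %*% Q) %*% t(Q)
  } else {
    drop(spectrum - Q %*% crossprod(Q, spectrum))
  }
}

# Orthonormal polynomial basis (degree 0..order) on a wavelength grid,
# computed on a [-1, 1] rescaling for conditioning.
poly_basis <- function(wavelengths, order) {
  x <- 2 * (wavelengths - min(wavelengths)) /
    (max(wavelengths) - min(wavelengths)) - 1
  V <- outer(x, 0:order, `^`)
  qr.Q(qr(V))
}

#' Gap-segment derivative
#'
#' The derivative treatment of scanning-NIRS software: a boxcar running mean
#' of width `smoothing` followed by `d` applications of the gap difference
#' operator, which subtracts the value `floor(gap/2)` channels to the left
#' from the value `ceiling(gap/2)` channels to the right. Margins consumed by
#' the windows are dropped, so the output is shorter than the input by
#' `smoothing - 1 + d * gap` channels; the attribute `"wavelengths"` carries
#' the centre wavelengths of the surviving channels when a grid is supplied.
#'
#' @param spectrum Numeric vector, or matrix with spectra in rows.
#' @param d Derivative order, an integer in 0..4; 0 means smoothing only.
#' @param gap Gap width in channels (>= 1).
#' @param smoothing Boxcar width in channels (>= 1; 1 disables smoothing).
#' @param wavelengths Optional grid for bookkeeping.
#' @return Derivative spectrum (vector or matrix), with a `"wavelengths"`
#'   attribute when a grid was given.
#' @export
gap_derivative <- function(spectrum, d, gap, smoothing = 1,
                           wavelengths = NULL) {
  if (d < 0 || d != round(d)) stop("derivative order d must be >= 0")
  if (gap < 1 || smoothing < 1) stop("gap and smoothing must be >= 1")
  X <- if (is.matrix(spectrum)) spectrum else matrix(spectrum, nrow = 1)
  n <- ncol(X)
  need <- smoothing + d * gap + 1
  if (n < need) {
    stop("spectrum of length ", n, " too short for treatment (d=", d,
         ", gap=", gap, ", smoothing=", smoothing, "); at least ", need,
         " channels required")
  }
  wl <- wavelengths
  if (!is.null(wl) && length(wl) != n) {
    stop("wavelengths length does not match the spectrum")
  }
  if (smoothing > 1) {
    cs <- cbind(0, t(apply(X, 1, cumsum)))
    X <- (cs[, (smoothing + 1):(n + 1), drop = FALSE] -
            cs[, 1:(n - smoothing + 1), drop = FALSE]) / smoothing
    if (!is.null(wl)) {
      cw <- c(0, cumsum(wl))
      wl <- (cw[(smoothing + 1):(n + 1)] - cw[1:(n - smoothing + 1)]) /
        smoothing
    }
    n <- ncol(X)
  }
  if (d > 0) {
    for (i in seq_len(d)) {
      X <- X[, (gap + 1):n, drop = FALSE] - X[, 1:(n - gap), drop = FALSE]
      if (!is.null(wl)) wl <- (wl[(gap + 1):n] + wl[1:(n - gap)]) / 2
      n <- ncol(X)
    }
  }
  out <- if (is.matrix(spectrum)) X else drop(X)
  if (!is.null(wl)) attr(out, "wavelengths") <- wl
  out
}

#' Define a math treatment
#'
#' The three-number preprocessing code of NIRS calibration software, read as
#' (derivative order, gap, smoothing), combined with the scatter-correction
#' switch. The full pipeline applied by [apply_treatment()] is: absorbance
#' (assumed already applied) -> SNV -> detrend -> gap-segment derivative.
#'
#' @param derivative Integer derivative order in 0..4.
#' @param gap Gap width in channels.
#' @param smoothing Boxcar smoothing width in channels.
#' @param scatter Scatter correction: `"snv_detrend"` (default), `"snv"` or
#'   `"none"`.
#' @param smoothing2 Second smoothing slot accepted for compatibility with
#'   four-number codes; default 1 (off).
#' @param poly_order Detrend polynomial order (used when `scatter`
#'   is `"snv_detrend"`).
#' @return An object of class `math_treatment`.
#' @export
math_treatment <- function(derivative = 1, gap = 4, smoothing = 4,
                           scatter = c("snv_detrend", "snv", "none"),
                           smoothing2 = 1, poly_order = 2) {
  scatter <- match.arg(scatter)
  if (!derivative %in% 0:4) stop("derivative order must be in 0..4")
  if (gap < 1 || smoothing < 1 || smoothing2 < 1) {
    stop("gap and smoothing must be >= 1")
  }
  structure(list(derivative = as.integer(derivative), gap = as.integer(gap),
                 smoothing = as.integer(smoothing),
                 smoothing2 = as.integer(smoothing2),
                 scatter = scatter, poly_order = as.integer(poly_order)),
            class = "math_treatment")
}

#' Parse a treatment code string
#'
#' Accepts the conventional notation, e.g. `"3,16,16"` for derivative order
#' 3, gap 16, smoothing 16; an optional fourth number is the second
#' smoothing slot.
#'
#' @param code Character scalar like `"1,4,4"`.
#' @param ... Passed to [math_treatment()] (e.g. `scatter`).
#' @return A [math_treatment()].
#' @export
parse_treatment <- function(code, ...) {
  parts <- suppressWarnings(as.integer(strsplit(trimws(code), ",")[[1]]))
  if (anyNA(parts) || !length(parts) %in% 3:4) {
    stop("treatment code must be 'd,gap,smoothing[,smoothing2]': ", code)
  }
  if (length(parts) == 3) parts <- c(parts, 1L)
  math_treatment(parts[1], parts[2], parts[3], smoothing2 = parts[4], ...)
}

#' @export
format.math_treatment <- function(x, ...) {
  code <- paste(x$derivative, x$gap, x$smoothing, sep = ",")
  if (x$smoothing2 > 1) code <- paste(code, x$smoothing2, sep = ",")
  code
}

#' @export
print.math_treatment <- function(x, ...) {
  cat("Math treatment", format(x), "with scatter correction:", x$scatter, "\n")
  invisible(x)
}

#' The default treatment grid
#'
#' The twelve derivative treatments searched by default: derivative orders
#' 1--4 crossed with (gap, smoothing) in {(4,4), (8,8), (16,16)}, all with
#' SNV + detrend scatter correction.
#'
#' @param scatter Scatter correction applied to every treatment.
#' @return List of 12 [math_treatment()] objects.
#' @export
default_treatments <- function(scatter = "snv_detrend") {
  grid <- expand.grid(gs = c(4L, 8L, 16L), d = 1:4)
  lapply(seq_len(nrow(grid)), function(i) {
    math_treatment(grid$d[i], grid$gs[i], grid$gs[i], scatter = scatter)
  })
}

#' Apply a math treatment to a spectrum set
#'
#' Transforms every spectrum identically through the pipeline
#' SNV -> detrend -> gap-segment derivative, as configured by the treatment.
#' Wavelength metadata is updated for the margins consumed by the windows.
#'
#' @param spectra A [spectrum_set()] of absorbance values.
#' @param treatment A [math_treatment()].
#' @return A [spectrum_set()] of transformed spectra.
#' @export
apply_treatment <- function(spectra, treatment) {
  stopifnot(inherits(spectra, "spectrum_set"),
            inherits(treatment, "math_treatment"))
  X <- spectra$absorbance
  wl <- spectra$wavelengths
  if (treatment$scatter %in% c("snv", "snv_detrend")) X <- snv_rows(X)
  if (treatment$scatter == "snv_detrend") {
    X <- detrend(X, wl, treatment$poly_order)
  }
  if (treatment$derivative > 0 || treatment$smoothing > 1) {
    X <- gap_derivative(X, treatment$derivative, treatment$gap,
                        treatment$smoothing, wavelengths = wl)
    wl <- attr(X, "wavelengths")
    attr(X, "wavelengths") <- NULL
  }
  if (treatment$smoothing2 > 1) {
    X <- gap_derivative(X, 0, 1, treatment$smoothing2, wavelengths = wl)
    wl <- attr(X, "wavelengths")
    attr(X, "wavelengths") <- NULL
  }
  out <- suppressWarnings(
    spectrum_set(X, wl, spectra$sample_ids, spectra$prep_state, spectra$meta))
  out$meta$treatment <- format(treatment)
  out
}
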