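# End-to-end calibration workflow: cross-validation statistics, outlier
# screening rounds, treatment grid search and acceptance rules.

#' Cross-validation specification
#'
#' @param scheme `"k_fold"` (default) or `"leave_one_out"`.
#' @param k Number of folds for k-fold, default 10.
#' @param seed Integer seed controlling fold assignment.
#' @param shuffle Shuffle samples into folds (default) or assign cyclically.
#' @return An object of class `cv_spec`.
#' @export
cv_spec <- function(scheme = c("k_fold", "leave_one_out"), k = 10,
                    seed = 1, shuffle = TRUE) {
  scheme <- match.arg(scheme)
  structure(list(scheme = scheme, k = as.integer(k),
                 seed = as.integer(seed), shuffle = isTRUE(shuffle)),
            class = "cv_spec")
}

#' Coefficient of determination
#'
#' `1 - SSE/SST` with the total sum of squares taken about the mean of the
#' observed values. Can be negative when predictions are worse than the
#' mean; a warning is emitted but the value is not clamped.
#'
#' @param y_obs Observed values (variance > 0).
#' @param y_pred Predicted values, aligned.
#' @return Numeric scalar.
#' @export
r_squared <- function(y_obs, y_pred) {
  if (length(y_obs) != length(y_pred)) stop("y_obs and y_pred not aligned")
  sst <- sum((y_obs - mean(y_obs))^2)
  if (sst < .Machine$double.eps) stop("y_obs has zero variance")
  r2 <- 1 - sum((y_pred - y_obs)^2) / sst
  if (r2 < 0) warning("negative R-squared: predictions worse than the mean",
                      call. = FALSE)
  r2
}

#' Ratio of performance to deviation (RPD)
#'
#' The standard deviation of the laboratory (observed) data divided by the
#' standard error of cross-validation (or prediction). An RPD above 2 is the
#' conventional threshold for a usable calibration.
#'
#' @param sd_reference Standard deviation of the reference values (> 0).
#' @param secv Standard error of cross-validation (> 0), same units.
#' @param units Optional length-2 character vector declaring the units of
#'   the two arguments; a mismatch raises an error.
#' @return Numeric scalar.
#' @export
rpd <- function(sd_reference, secv, units = NULL) {
  if (!is.null(units)) {
    units <- rep_len(units, 2)
    if (units[1] != units[2]) {
      stop("unit mismatch: sd_reference in ", units[1], ", secv in ",
           units[2])
    }
  }
  if (any(!is.finite(sd_reference) | sd_reference <= 0)) {
    stop("sd_reference must be > 0")
  }
  if (any(!is.finite(secv) | secv <= 0)) stop("secv must be > 0")
  sd_reference / secv
}

#' Acceptance rule for a calibration
#'
#' A model is accepted when the cross-validation R-squared exceeds 0.80 and
#' the RPD exceeds 2 (both strict). The SECV/SEC ratio is also examined:
#' SECV far above SEC signals overfitting, and a message is emitted when the
#' ratio exceeds `ratio_warn`.
#'
#' @param result A `nirs_calibration` object (or any list with elements
#'   `r2_cv`, `rpd`, `secv`, `sec`).
#' @param r2_min,rpd_min Acceptance thresholds (strict inequalities).
#' @param ratio_warn SECV/SEC "closeness" warning threshold, default 1.3.
#' @return Logical scalar.
#' @export
acceptance_check <- function(result, r2_min = 0.80, rpd_min = 2,
                             ratio_warn = 1.3) {
  ok <- isTRUE(result$r2_cv > r2_min) && isTRUE(result$rpd > rpd_min)
  if (!is.null(result$secv) && !is.null(result$sec) && result$sec > 0) {
    ratio <- result$secv / result$sec
    if (is.finite(ratio) && ratio > ratio_warn) {
      message("SECV/SEC ratio ", fmt_num(ratio), " exceeds ", ratio_warn,
              ": cross-validation error is not close to calibration error")
    }
  }
  ok
}

# Extract the percent-scale response for one analyte, dropping samples with
# a missing laboratory value. Returns list(spectra, y, ids).
analyte_subset <- function(dataset, analyte) {
  stopifnot(inherits(dataset, "aligned_dataset"))
  if (!analyte %in% dataset$reference$analytes) {
    stop("analyte ", analyte, " not present in the reference table")
  }
  ref_pct <- convert_units(dataset$reference, "percent")
  y <- ref_pct$values[, analyte]
  keep <- which(!is.na(y))
  if (length(keep) < 4) stop("too few non-missing values for ", analyte)
  list(spectra = suppressWarnings(dataset$spectra[keep]),
       y = as.numeric(y[keep]),
       ids = dataset$spectra$sample_ids[keep])
}

#' Cross-validated calibration for one analyte and treatment
#'
#' The core workflow step: preprocesses the spectra with the given math
#' treatment, screens spectral outliers (GH > `gh_cutoff`, up to
#' `max_rounds` rounds), fits an initial PLS calibration with
#' cross-validated factor selection, screens laboratory outliers
#' (t > `t_cutoff` standard errors), refits, and reports calibration and
#' cross-validation statistics. All statistics are computed and reported in
#' percent (g/kg divided by 10).
#'
#' SECV is the root-mean-square pooled out-of-fold residual (denominator n);
#' SEC uses denominator n - k - 1 where k is the number of PLS factors. RPD
#' is the standard deviation of the selected samples' reference values over
#' SECV.
#'
#' @param dataset An `aligned_dataset` from [align()] or [simulate_hay()].
#' @param analyte One of [hay_analytes].
#' @param treatment A [math_treatment()].
#' @param cv A [cv_spec()].
#' @param cap Maximum number of PLS factors, default 16.
#' @param screen Run outlier screening (default TRUE).
#' @param gh_cutoff,t_cutoff Screening cutoffs (3.0 and 2.5 by default).
#' @param max_rounds Spectral screening rounds, default 2.
#' @param rpd_sd `"selected"` (default) uses the post-screening sample SD in
#'   the RPD; `"full"` uses all samples with a laboratory value.
#' @return An object of class `nirs_calibration`.
#' @export
cross_validate <- function(dataset, analyte, treatment, cv = cv_spec(),
                           cap = 16, screen = TRUE, gh_cutoff = 3.0,
                           t_cutoff = 2.5, max_rounds = 2,
                           rpd_sd = c("selected", "full")) {
  rpd_sd <- match.arg(rpd_sd)
  sub <- analyte_subset(dataset, analyte)
  proc <- apply_treatment(sub$spectra, treatment)
  X <- proc$absorbance
  y <- sub$y
  ids <- sub$ids
  sd_full <- stats::sd(y)

  removed_spectral <- character(0)
  removed_lab <- character(0)
  if (screen && is.finite(gh_cutoff)) {
    rep_s <- screen_spectral(X, k = min(10, cap), cutoff = gh_cutoff,
                             y = y, max_rounds = max_rounds)
    drop_i <- which(!is.na(rep_s$round_removed))
    if (length(drop_i)) {
      removed_spectral <- ids[drop_i]
      X <- X[-drop_i, , drop = FALSE]
      y <- y[-drop_i]
      ids <- ids[-drop_i]
    }
  }
  if (screen && is.finite(t_cutoff)) {
    # Initial calibration to obtain SEC for the t-screen.
    path0 <- cv_pls_path(X, y, cap = cap, cv = cv)
    k0 <- which.min(path0$secv)
    fit0 <- suppressWarnings(nipals_pls(X, y, ncomp = k0))
    res0 <- y - fitted(fit0, ncomp = fit0$ncomp)
    sec0 <- sqrt(sum(res0^2) / max(length(y) - fit0$ncomp - 1, 1))
    rep_l <- screen_lab(y, fitted(fit0, ncomp = fit0$ncomp), sec0,
                        cutoff = t_cutoff, sample_ids = ids)
    drop_i <- which(rep_l$lab_flag)
    if (length(drop_i) && length(drop_i) < length(y) - 4) {
      removed_lab <- ids[drop_i]
      X <- X[-drop_i, , drop = FALSE]
      y <- y[-drop_i]
      ids <- ids[-drop_i]
    }
  }

  n <- length(y)
  path <- cv_pls_path(X, y, cap = cap, cv = cv)
  k_opt <- which.min(path$secv)
  secv <- path$secv[k_opt]
  y_cv <- path$pred[, k_opt]
  r2_cv <- suppressWarnings(r_squared(y, y_cv))

  fit <- suppressWarnings(nipals_pls(X, y, ncomp = k_opt))
  k_fit <- fit$ncomp
  y_fit <- fitted(fit, ncomp = k_fit)
  sec <- sqrt(sum((y - y_fit)^2) / max(n - k_fit - 1, 1))
  r2_cal <- suppressWarnings(r_squared(y, y_fit))
  sd_sel <- stats::sd(y)
  rpd_val <- rpd(if (rpd_sd == "selected") sd_sel else sd_full, secv)

  out <- structure(
    list(analyte = analyte, treatment = treatment,
         n_selected = n, n_factors = k_fit,
         r2_cal = r2_cal, sec = sec, r2_cv = r2_cv, secv = secv,
         rpd = rpd_val, sd_selected = sd_sel, sd_full = sd_full,
         accepted = NA, units = "percent",
         model = fit, wavelengths = proc$wavelengths,
         treatment_applied_grid = sub$spectra$wavelengths,
         y_obs = stats::setNames(y, ids), y_cv = stats::setNames(y_cv, ids),
         cv = cv,
         provenance = list(
           removed_spectral = removed_spectral,
           removed_lab = removed_lab,
           gh_cutoff = if (screen) gh_cutoff else Inf,
           t_cutoff = if (screen) t_cutoff else Inf,
           cap = cap, rpd_sd = rpd_sd,
           n_input = length(sub$y))),
    class = "nirs_calibration")
  out$accepted <- suppressMessages(acceptance_check(out))
  out
}

#' Grid search over math treatments
#'
#' Runs [cross_validate()] for every treatment in the list (default: the 12
#' standard derivative treatments) and returns the result with the lowest
#' SECV; ties break toward higher cross-validation R-squared, then toward
#' lower derivative order. The full per-treatment table is kept in
#' `$provenance$grid`.
#'
#' @inheritParams cross_validate
#' @param treatments List of [math_treatment()] objects.
#' @param ... Passed to [cross_validate()].
#' @return The best `nirs_calibration`, with the per-treatment comparison
#'   table attached.
#' @export
grid_search <- function(dataset, analyte, treatments = default_treatments(),
                        cv = cv_spec(), ...) {
  if (!length(treatments)) stop("empty treatment list")
  results <- lapply(treatments, function(t) {
    cross_validate(dataset, analyte, t, cv = cv, ...)
  })
  tab <- do.call(rbind, lapply(results, function(r) {
    data.frame(treatment = format(r$treatment),
               n_selected = r$n_selected, n_factors = r$n_factors,
               r2_cal = r$r2_cal, sec = r$sec,
               r2_cv = r$r2_cv, secv = r$secv, rpd = r$rpd,
               accepted = r$accepted, stringsAsFactors = FALSE)
  }))
  d_ord <- vapply(results, function(r) r$treatment$derivative, numeric(1))
  ord <- order(tab$secv, -tab$r2_cv, d_ord)
  best <- results[[ord[1]]]
  best$provenance$grid <- tab
  best
}

#' Calibrate an NIRS model for one analyte
#'
#' The main fitting entry point. With `treatment = NULL` (default) the 12
#' standard math treatments are grid-searched and the one with the lowest
#' cross-validated standard error wins; a single [math_treatment()] (or
#' code string such as `"1,4,4"`) skips the search.
#'
#' @inheritParams cross_validate
#' @param treatment A [math_treatment()], a code string, a list of
#'   treatments to search, or `NULL` for the default grid.
#' @param ... Passed to [cross_validate()].
#' @return A `nirs_calibration` object; see [cross_validate()].
#' @examples
#' ds <- simulate_hay(hay_sim_config(n_samples = 60, seed = 42))
#' fit <- nirs_calibrate(ds, "CP", treatment = "1,4,4")
#' fit
#' @export
nirs_calibrate <- function(dataset, analyte, treatment = NULL,
                           cv = cv_spec(), ...) {
  if (is.null(treatment)) {
    grid_search(dataset, analyte, cv = cv, ...)
  } else if (is.list(treatment) && !inherits(treatment, "math_treatment")) {
    grid_search(dataset, analyte, treatments = treatment, cv = cv, ...)
  } else {
    if (is.character(treatment)) treatment <- parse_treatment(treatment)
    cross_validate(dataset, analyte, treatment, cv = cv, ...)
  }
}

#' @export
print.nirs_calibration <- function(x, digits = 2, ...) {
  cat("NIRS calibration for", x$analyte, "(", x$units, ")\n")
  cat("  treatment   :", format(x$treatment), "| scatter:",
      x$treatment$scatter, "\n")
  cat("  selected n  :", x$n_selected, "of", x$provenance$n_input,
      "(", length(x$provenance$removed_spectral), "spectral,",
      length(x$provenance$removed_lab), "lab outliers removed )\n")
  cat("  PLS factors :", x$n_factors, "\n")
  cat("  calibration : R2 =", fmt_num(x$r2_cal, digits),
      " SEC =", fmt_num(x$sec, digits), "\n")
  cat("  cross-valid.: R2 =", fmt_num(x$r2_cv, digits),
      " SECV =", fmt_num(x$secv, digits), "\n")
  cat("  RPD         :", fmt_num(x$rpd, digits),
      if (x$accepted) " -> accepted (R2cv > 0.80, RPD > 2)"
      else " -> not accepted", "\n")
  invisible(x)
}

#' @export
summary.nirs_calibration <- function(object, ...) {
  print(object, ...)
  if (!is.null(object$provenance$grid)) {
    cat("\nTreatment grid (sorted by SECV):\n")
    g <- object$provenance$grid
    print(g[order(g$secv), ], row.names = FALSE, digits = 3)
  }
  invisible(object)
}

#' @export
coef.nirs_calibration <- function(object, ...) {
  coef(object$model, intercept = TRUE, ...)
}

#' @export
residuals.nirs_calibration <- function(object,
                                       type = c("cv", "calibration"), ...) {
  type <- match.arg(type)
  if (type == "cv") object$y_obs - object$y_cv
  else residuals(object$model)
}

#' Predict nutritive values for new spectra
#'
#' Applies the calibration's stored math treatment to new absorbance spectra
#' and evaluates the PLS regression vector. New spectra must be on the same
#' wavelength grid as the training spectra.
#'
#' @param object A `nirs_calibration`.
#' @param newdata A [spectrum_set()] of raw absorbance spectra, or a matrix
#'   already preprocessed with the model's treatment.
#' @param ... Unused.
#' @return Named numeric vector of predictions in percent.
#' @export
predict.nirs_calibration <- function(object, newdata, ...) {
  if (inherits(newdata, "aligned_dataset")) newdata <- newdata$spectra
  if (inherits(newdata, "spectrum_set")) {
    if (!grids_equal(newdata$wavelengths, object$treatment_applied_grid)) {
      stop("new spectra are not on the calibration's wavelength grid")
    }
    proc <- apply_treatment(newdata, object$treatment)
    stats::setNames(predict(object$model, proc$absorbance),
                    newdata$sample_ids)
  } else {
    predict(object$model, newdata)
  }
}

#' Observed versus cross-validated predictions
#'
#' @param x A `nirs_calibration`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.nirs_calibration <- function(x, ...) {
  graphics::plot(x$y_obs, x$y_cv,
                 xlab = paste0("Laboratory ", x$analyte, " (%)"),
                 ylab = paste0("Cross-validated NIRS ", x$analyte, " (%)"),
                 main = sprintf("%s: R2cv = %s, RPD = %s", x$analyte,
                                fmt_num(x$r2_cv), fmt_num(x$rpd)), ...)
  graphics::abline(0, 1, col = "grey50", lty = 2)
  invisible(x)
}

#' Tabulate calibration results
#'
#' Collects one or more `nirs_calibration` objects into the conventional
#' report table (treatment, selected n, PLS terms, calibration R2/SE,
#' cross-validation R2/SE, RPD).
#'
#' @param ... `nirs_calibration` objects, or a single list of them.
#' @param digits Rounding for display columns, default 2 (use `NA` to keep
#'   full precision).
#' @return A data.frame with one row per calibration.
#' @export
calibration_table <- function(..., digits = 2) {
  results <- list(...)
  if (length(results) == 1 && is.list(results[[1]]) &&
      !inherits(results[[1]], "nirs_calibration")) {
    results <- results[[1]]
  }
  tab <- do.call(rbind, lapply(results, function(r) {
    data.frame(analyte = r$analyte, treatment = format(r$treatment),
               n_selected = r$n_selected, n_factors = r$n_factors,
               r2_cal = r$r2_cal, sec = r$sec,
               r2_cv = r$r2_cv, secv = r$secv, rpd = r$rpd,
               accepted = r$accepted, stringsAsFactors = FALSE)
  }))
  if (!is.na(digits)) {
    num <- c("r2_cal", "sec", "r2_cv", "secv", "rpd")
    tab[num] <- lapply(tab[num], round, digits = digits)
  }
  tab
}

#' Write a calibration report
#'
#' Plain-text report with the statistics table and provenance (seeds,
#' cutoffs, removed samples). Every line except the timestamped header is
#' deterministic for a given calibration, so reports are reproducible
#' byte-for-byte modulo that one line.
#'
#' @param result A `nirs_calibration`.
#' @param path Output file path.
#' @param timestamp Include a timestamp header line (default TRUE).
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path, timestamp = TRUE) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (timestamp) {
    writeLines(paste("# generated:", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
               con)
  }
  writeLines(c(
    paste("analyte:", result$analyte),
    paste("units:", result$units),
    paste("treatment:", format(result$treatment)),
    paste("scatter:", result$treatment$scatter),
    paste("cv:", result$cv$scheme, "k =", result$cv$k,
          "seed =", result$cv$seed),
    paste("cutoffs: GH >", result$provenance$gh_cutoff,
          "; t >", result$provenance$t_cutoff),
    paste("n_input:", result$provenance$n_input),
    paste("n_selected:", result$n_selected),
    paste("removed_spectral:",
          paste(result$provenance$removed_spectral, collapse = ",")),
    paste("removed_lab:",
          paste(result$provenance$removed_lab, collapse = ",")),
    paste("n_factors:", result$n_factors),
    paste("r2_cal:", fmt_num(result$r2_cal, 6)),
    paste("sec:", fmt_num(result$sec, 6)),
    paste("r2_cv:", fmt_num(result$r2_cv, 6)),
    paste("secv:", fmt_num(result$secv, 6)),
    paste("rpd:", fmt_num(result$rpd, 6)),
    paste("accepted:", result$accepted)), con)
  invisible(path)
}

#' Save a calibration model as JSON
#'
#' Serializes everything needed to predict new samples standalone: the math
#' treatment, expected wavelength grid, centering, regression vector and
#' summary statistics.
#'
#' @param result A `nirs_calibration`.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_model <- function(result, path) {
  obj <- list(
    format = "haycal-pls-model",
    analyte = result$analyte,
    units = result$units,
    treatment = unclass(result$treatment),
    input_wavelengths = result$treatment_applied_grid,
    x_mean = unname(result$model$x_mean),
    y_mean = result$model$y_mean,
    coefficients = unname(result$model$coefficients[, result$n_factors]),
    n_factors = result$n_factors,
    stats = list(n_selected = result$n_selected, r2_cal = result$r2_cal,
                 sec = result$sec, r2_cv = result$r2_cv, secv = result$secv,
                 rpd = result$rpd, accepted = result$accepted))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a calibration model saved by [write_model()]
#'
#' @param path A `.json` file written by [write_model()].
#' @return An object of class `nirs_model` with a `predict` method taking a
#'   [spectrum_set()] of raw absorbance spectra.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "haycal-pls-model")) {
    stop(path, " is not a haycal model file")
  }
  obj$treatment <- do.call(math_treatment, as.list(
    obj$treatment[c("derivative", "gap", "smoothing", "scatter",
                    "smoothing2", "poly_order")]))
  structure(obj, class = "nirs_model")
}

#' @export
predict.nirs_model <- function(object, newdata, ...) {
  if (inherits(newdata, "spectrum_set")) {
    if (!grids_equal(newdata$wavelengths, object$input_wavelengths)) {
      stop("new spectra are not on the model's wavelength grid")
    }
    X <- apply_treatment(newdata, object$treatment)$absorbance
  } else {
    X <- as.matrix(newdata)
  }
  if (ncol(X) != length(object$x_mean)) {
    stop("channel mismatch: model expects ", length(object$x_mean),
         " channels, got ", ncol(X))
  }
  drop(object$y_mean +
         (X - rep(object$x_mean, each = nrow(X))) %*% object$coefficients)
}

#' @export
print.nirs_model <- function(x, ...) {
  cat("Serialized NIRS model for", x$analyte, "- treatment",
      paste(x$treatment$derivative, x$treatment$gap, x$treatment$smoothing,
            sep = ","),
      "with", x$n_factors, "factors\n")
  invisible(x)
}
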