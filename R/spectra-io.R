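# Containers and CSV readers for NIR spectra and reference chemistry.

#' Analytes handled by the package
#'
#' Dry matter (DM), crude protein (CP), neutral detergent fiber (NDF), acid
#' detergent fiber (ADF) and in vitro dry matter digestibility (IVDMD) --
#' the five forage nutritive-value analytes modelled.
#'
#' @export
hay_analytes <- c("DM", "CP", "NDF", "ADF", "IVDMD")

#' Default instrument wavelength grid
#'
#' The scanning monochromator grid used throughout: 680--2500 nm at 2 nm
#' intervals, i.e. exactly 911 channels.
#'
#' @return Numeric vector of wavelengths in nanometres.
#' @export
default_grid <- function() seq(680, 2500, by = 2)

#' Construct a spectrum set
#'
#' A `spectrum_set` holds a sample-by-wavelength matrix of absorbance
#' (log 1/R) values together with the wavelength grid, per-sample
#' preparation-state labels and free-form provenance metadata.
#'
#' @param absorbance Numeric matrix, samples in rows, wavelengths in columns.
#' @param wavelengths Strictly increasing numeric grid in nanometres; defaults
#'   to the column count of `absorbance` mapped onto [default_grid()] when the
#'   counts match.
#' @param sample_ids Unique sample identifiers; defaults to the row names of
#'   `absorbance`.
#' @param prep_state Per-sample label, `"ground"` or `"unground"` (recycled if
#'   length one); `NA` when unknown.
#' @param meta Named list of provenance (instrument, scan date, ...).
#'
#' @return An object of class `spectrum_set`.
#' @export
spectrum_set <- function(absorbance, wavelengths = NULL, sample_ids = NULL,
                         prep_state = NA_character_, meta = list()) {
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  n <- nrow(absorbance)
  if (is.null(sample_ids)) sample_ids <- rownames(absorbance)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%03d", seq_len(n))
  sample_ids <- as.character(sample_ids)
  if (is.null(wavelengths)) {
    wl_guess <- default_grid()
    if (ncol(absorbance) == length(wl_guess)) {
      wavelengths <- wl_guess
    } else {
      stop("`wavelengths` must be supplied when the matrix is not on the ",
           length(wl_guess), "-channel default grid")
    }
  }
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != ncol(absorbance)) {
    stop("length of `wavelengths` (", length(wavelengths),
         ") does not match the number of spectral columns (",
         ncol(absorbance), ")")
  }
  if (any(diff(wavelengths) <= 0)) {
    stop("wavelength grid must be strictly increasing")
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample IDs: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (length(sample_ids) != n) {
    stop("number of sample IDs does not match the number of spectra")
  }
  if (!all(is.finite(absorbance))) {
    bad <- which(!is.finite(absorbance), arr.ind = TRUE)[1, ]
    stop("non-finite absorbance at sample ", sample_ids[bad[1]],
         ", wavelength ", wavelengths[bad[2]], " nm")
  }
  prep_state <- rep_len(as.character(prep_state), n)
  ok <- is.na(prep_state) | prep_state %in% c("ground", "unground")
  if (!all(ok)) {
    stop("prep_state must be 'ground', 'unground' or NA")
  }
  if (!grids_equal(wavelengths, default_grid())) {
    warning("wavelength grid differs from the default 680-2500 nm / 2 nm ",
            "instrument grid (", length(wavelengths), " channels)",
            call. = FALSE)
  }
  dimnames(absorbance) <- list(sample_ids, NULL)
  structure(
    list(absorbance = absorbance, wavelengths = wavelengths,
         sample_ids = sample_ids, prep_state = prep_state, meta = meta),
    class = "spectrum_set"
  )
}

grids_equal <- function(a, b) {
  length(a) == length(b) && all(abs(a - b) < 1e-9)
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat("Spectrum set:", length(x$sample_ids), "samples x",
      length(x$wavelengths), "channels\n")
  cat("  wavelengths:", min(x$wavelengths), "-", max(x$wavelengths), "nm\n")
  ps <- table(factor(x$prep_state, levels = c("ground", "unground")),
              useNA = "ifany")
  cat("  prep state :", paste(names(ps), ps, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.spectrum_set <- function(x) dim(x$absorbance)

#' @export
`[.spectrum_set` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$sample_ids)
  spectrum_set(x$absorbance[i, , drop = FALSE], x$wavelengths,
               x$sample_ids[i], x$prep_state[i], x$meta) |>
    suppressWarnings()
}

#' Plot spectra
#'
#' Overlays all spectra in the set, optionally coloured by preparation state.
#'
#' @param x A [spectrum_set()].
#' @param col Line colours; defaults to colouring by prep state.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.spectrum_set <- function(x, col = NULL, ...) {
  if (is.null(col)) {
    col <- ifelse(is.na(x$prep_state), "grey40",
                  ifelse(x$prep_state == "ground", "steelblue", "darkgreen"))
  }
  graphics::matplot(x$wavelengths, t(x$absorbance), type = "l", lty = 1,
                    col = col, xlab = "Wavelength (nm)",
                    ylab = "log(1/R)", ...)
  invisible(x)
}

#' Construct a reference-chemistry table
#'
#' Laboratory values per sample and analyte, with declared units. Missing
#' cells are allowed and excluded analyte-wise downstream.
#'
#' @param values Numeric matrix, samples in rows, analytes in columns; column
#'   names must be a subset of [hay_analytes].
#' @param sample_ids Unique identifiers; default row names of `values`.
#' @param units Named character vector per analyte, each `"g/kg"` or
#'   `"percent"`; a single unnamed value is recycled.
#'
#' @return An object of class `reference_table`.
#' @export
reference_table <- function(values, sample_ids = NULL, units = "g/kg") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  analytes <- colnames(values)
  if (is.null(analytes) || !all(analytes %in% hay_analytes)) {
    stop("column names of `values` must be analytes among: ",
         paste(hay_analytes, collapse = ", "))
  }
  if (is.null(sample_ids)) sample_ids <- rownames(values)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%03d", seq_len(nrow(values)))
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample IDs: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (length(units) == 1 && is.null(names(units))) {
    units <- stats::setNames(rep(units, length(analytes)), analytes)
  }
  if (!all(analytes %in% names(units))) {
    stop("`units` must name every analyte present")
  }
  units <- units[analytes]
  if (!all(units %in% c("g/kg", "percent"))) {
    stop("units must be 'g/kg' or 'percent'")
  }
  if (any(values < 0, na.rm = TRUE)) {
    stop("reference values must be non-negative")
  }
  cap <- ifelse(units == "g/kg", 1000, 100)
  for (a in intersect(c("DM", "IVDMD"), analytes)) {
    if (any(values[, a] > cap[a], na.rm = TRUE)) {
      stop(a, " exceeds ", cap[a], " ", units[a])
    }
  }
  dimnames(values) <- list(sample_ids, analytes)
  structure(list(values = values, sample_ids = sample_ids,
                 analytes = analytes, units = units),
            class = "reference_table")
}

#' @export
print.reference_table <- function(x, ...) {
  cat("Reference table:", length(x$sample_ids), "samples,",
      length(x$analytes), "analytes\n")
  st <- rbind(mean = colMeans(x$values, na.rm = TRUE),
              sd = apply(x$values, 2, stats::sd, na.rm = TRUE),
              n = colSums(!is.na(x$values)))
  print(round(st, 2))
  cat("  units:", paste(x$analytes, x$units, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Convert reference units
#'
#' Conversion between g/kg and percent is a factor of exactly 10, so the
#' round trip is the identity.
#'
#' @param reference A [reference_table()].
#' @param to Target unit, `"percent"` or `"g/kg"`, applied to all analytes.
#' @return A [reference_table()] in the target units.
#' @export
convert_units <- function(reference, to = c("percent", "g/kg")) {
  to <- match.arg(to)
  vals <- reference$values
  for (a in reference$analytes) {
    from <- reference$units[[a]]
    if (from == to) next
    vals[, a] <- if (to == "percent") vals[, a] / 10 else vals[, a] * 10
  }
  reference_table(vals, reference$sample_ids,
                  stats::setNames(rep(to, length(reference$analytes)),
                                  reference$analytes))
}

#' Read a wide-format spectra CSV
#'
#' Expects a comma-separated UTF-8 file whose first column holds sample IDs
#' and whose remaining headers parse as wavelengths in nanometres (an "nm"
#' suffix is stripped). Reflectance input is converted to absorbance on read.
#'
#' @param path CSV file path.
#' @param value_kind Whether the file stores `"absorbance"` (log 1/R, the
#'   default) or raw `"reflectance"` in (0, 1], converted via
#'   [absorbance_transform()].
#' @param log_base Base used when converting reflectance; see
#'   [absorbance_transform()].
#' @param prep_state Optional per-sample preparation label.
#' @return A [spectrum_set()].
#' @export
read_spectra <- function(path, value_kind = c("absorbance", "reflectance"),
                         log_base = c("log10", "natural"),
                         prep_state = NA_character_) {
  value_kind <- match.arg(value_kind)
  log_base <- match.arg(log_base)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("spectra CSV needs an ID column plus wavelengths")
  ids <- as.character(df[[1]])
  wl_raw <- trimws(sub("nm$", "", trimws(names(df)[-1])))
  wl <- suppressWarnings(as.numeric(wl_raw))
  if (anyNA(wl)) {
    stop("non-wavelength column header(s): ",
         paste(names(df)[-1][is.na(wl)], collapse = ", "))
  }
  if (any(diff(wl) <= 0)) {
    stop("wavelength headers are not strictly increasing")
  }
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(is.na(suppressWarnings(matrix(as.numeric(mat), nrow(mat)))) &
                   !is.na(mat), arr.ind = TRUE)
    if (nrow(bad)) {
      stop("non-numeric cell at row ", ids[bad[1, 1]], ", column ",
           names(df)[-1][bad[1, 2]])
    }
    storage.mode(mat) <- "double"
  }
  if (value_kind == "reflectance") {
    mat <- absorbance_transform(mat, base = log_base)
  }
  spectrum_set(mat, wavelengths = wl, sample_ids = ids,
               prep_state = prep_state)
}

#' Write a spectrum set to wide CSV
#'
#' Values are written with enough digits that a read-back reproduces the
#' matrix to better than 1e-9 relative.
#'
#' @param spectra A [spectrum_set()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path) {
  df <- data.frame(sample_id = spectra$sample_ids,
                   format(spectra$absorbance, digits = 15, trim = TRUE,
                          scientific = FALSE) |> as.data.frame(),
                   check.names = FALSE)
  names(df) <- c("sample_id", format(spectra$wavelengths, trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a reference-chemistry CSV
#'
#' Expects an ID column (named `sample_id`, `id`, or the first column) plus
#' analyte columns. Units may be declared per column in the header as e.g.
#' `CP (g/kg)` or `CP (percent)`; otherwise the `units` argument applies.
#' Unknown columns are ignored with a warning; analyte columns that are
#' entirely empty are dropped with a warning.
#'
#' @param path CSV file path.
#' @param units Default unit for columns without a header declaration.
#' @return A [reference_table()].
#' @export
read_reference <- function(path, units = "g/kg") {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  nms <- names(df)
  idc <- which(tolower(nms) %in% c("sample_id", "id", "sample"))
  idc <- if (length(idc)) idc[1] else 1L
  ids <- as.character(df[[idc]])
  cols <- setdiff(seq_along(df), idc)
  parse_head <- function(h) {
    m <- regmatches(h, regexec("^\\s*(\\S+)\\s*(?:\\(([^)]+)\\))?\\s*$", h))[[1]]
    c(analyte = toupper(m[2]), unit = m[3])
  }
  heads <- vapply(nms[cols], parse_head, character(2))
  known <- heads["analyte", ] %in% hay_analytes
  if (any(!known)) {
    warning("ignoring unrecognized column(s): ",
            paste(nms[cols][!known], collapse = ", "), call. = FALSE)
  }
  cols <- cols[known]
  heads <- heads[, known, drop = FALSE]
  if (!length(cols)) stop("no recognized analyte column in ", path)
  vals <- as.matrix(df[, cols, drop = FALSE])
  storage.mode(vals) <- "double"
  colnames(vals) <- unname(heads["analyte", ])
  empty <- colSums(!is.na(vals)) == 0
  if (any(empty)) {
    warning("dropping empty analyte column(s): ",
            paste(colnames(vals)[empty], collapse = ", "), call. = FALSE)
    vals <- vals[, !empty, drop = FALSE]
    heads <- heads[, !empty, drop = FALSE]
  }
  if (!ncol(vals)) stop("no non-empty analyte column in ", path)
  u <- unname(ifelse(heads["unit", ] == "" | is.na(heads["unit", ]),
                     units, heads["unit", ]))
  reference_table(vals, sample_ids = ids,
                  units = stats::setNames(u, colnames(vals)))
}

#' Write a reference table to CSV
#'
#' @param reference A [reference_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(reference, path) {
  df <- data.frame(sample_id = reference$sample_ids,
                   as.data.frame(reference$values), check.names = FALSE)
  names(df) <- c("sample_id",
                 paste0(reference$analytes, " (", reference$units, ")"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Align spectra with reference chemistry by sample ID
#'
#' Restricts both components to the ID intersection, co-ordered in the
#' spectra's order.
#'
#' @param spectra A [spectrum_set()].
#' @param reference A [reference_table()].
#' @return An object of class `aligned_dataset` with elements `spectra` and
#'   `reference`.
#' @export
align <- function(spectra, reference) {
  stopifnot(inherits(spectra, "spectrum_set"),
            inherits(reference, "reference_table"))
  keep <- spectra$sample_ids[spectra$sample_ids %in% reference$sample_ids]
  if (!length(keep)) {
    stop("no sample IDs in common between spectra and reference")
  }
  sp <- suppressWarnings(spectra[keep])
  ref <- reference_table(
    reference$values[match(keep, reference$sample_ids), , drop = FALSE],
    keep, reference$units)
  message(length(keep), " of ", length(spectra$sample_ids),
          " spectra matched to reference chemistry")
  structure(list(spectra = sp, reference = ref), class = "aligned_dataset")
}

#' @export
print.aligned_dataset <- function(x, ...) {
  cat("Aligned NIRS dataset\n")
  print(x$spectra)
  print(x$reference)
  invisible(x)
}
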