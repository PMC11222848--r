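# Small fixtures built in code.

# A spectrum set of smooth random spectra on a short grid.
toy_spectra <- function(n = 5, p = 101, seed = 1, ids = NULL) {
  set.seed(seed)
  wl <- seq(1000, 1000 + 2 * (p - 1), by = 2)
  X <- t(replicate(n, {
    0.3 + 0.1 * sin(wl / 150) + cumsum(rnorm(p, 0, 0.002))
  }))
  spectrum_set(X, wl, sample_ids = ids %||% sprintf("T%02d", seq_len(n))) |>
    suppressWarnings()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Tiny aligned dataset with a known linear spectrum-chemistry link:
# absorbance = baseline + (CP/1000) * band + noise.
toy_dataset <- function(n = 40, p = 201, seed = 1, noise = 0,
                        analyte = "CP") {
  set.seed(seed)
  wl <- seq(1200, 1200 + 2 * (p - 1), by = 2)
  conc <- runif(n, 100, 220)
  band <- exp(-0.5 * ((wl - median(wl)) / 40)^2)
  X <- outer(rep(1, n), 0.2 + 0.05 * (wl - min(wl)) / diff(range(wl))) +
    outer(conc / 1000, band) +
    matrix(rnorm(n * p, 0, noise), n, p)
  ids <- sprintf("D%03d", seq_len(n))
  sp <- suppressWarnings(spectrum_set(X, wl, ids))
  ref <- reference_table(matrix(conc, ncol = 1,
                                dimnames = list(ids, analyte)),
                         ids, units = "g/kg")
  structure(list(spectra = sp, reference = ref),
            class = "aligned_dataset")
}
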