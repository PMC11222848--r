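# Synthetic hay NIR dataset generator: Beer-Lambert-style Gaussian band
# mixing of nutritive-value analytes plus prep-state-dependent scatter.

#' Reference population statistics for hay
#'
#' Descriptive statistics (minimum, maximum, mean, SD; g/kg, DM as-is and
#' the others on a dry-matter basis) of the alfalfa (n = 227) and timothy
#' (n = 360) hay populations used as generator defaults.
#'
#' @param species `"alfalfa"` or `"timothy"`.
#' @return List with named numeric vectors `mean`, `sd`, `min`, `max` over
#'   [hay_analytes], plus the population size `n`.
#' @export
hay_population <- function(species = c("alfalfa", "timothy")) {
  species <- match.arg(species)
  a <- hay_analytes
  if (species == "alfalfa") {
    list(mean = stats::setNames(c(918, 155, 502, 349, 692), a),
         sd   = stats::setNames(c(12.4, 26.3, 37.1, 35.8, 42.1), a),
         min  = stats::setNames(c(828, 85, 351, 230, 526), a),
         max  = stats::setNames(c(955, 212, 616, 492, 784), a),
         n = 227L)
  } else {
    list(mean = stats::setNames(c(922, 53.8, 674, 383, 673), a),
         sd   = stats::setNames(c(14.6, 16.6, 17.6, 21.5, 17.6), a),
         min  = stats::setNames(c(870, 22, 620, 237, 455), a),
         max  = stats::setNames(c(950, 115, 725, 434, 703), a),
         n = 360L)
  }
}

#' Default absorption band library
#'
#' Gaussian bands assigned to each analyte: water/moisture bands near 1450
#' and 1940 nm (driving the dry-matter signal through its moisture
#' complement), protein N-H bands near 1510, 2054 and 2180 nm,
#' carbohydrate/cellulose bands near 1200, 1730 and 2270 nm (NDF) and
#' 1220, 1680 and 2310 nm (ADF), and digestibility-associated bands near
#' 1585, 1665 and 2100 nm. Centers cover the commonly reported hay
#' absorption regions (~1200, 1400-1500, 1900-2000 nm); widths 30-80 nm.
#' Loadings are absorbance per unit mass fraction of the driving analyte.
#'
#' @return A data.frame with columns `analyte`, `center` (nm), `width` (nm),
#'   `loading`.
#' @export
default_band_library <- function() {
  data.frame(
    analyte = c("DM", "DM",
                "CP", "CP", "CP",
                "NDF", "NDF", "NDF",
                "ADF", "ADF", "ADF",
                "IVDMD", "IVDMD", "IVDMD"),
    center = c(1450, 1940,
               1510, 2054, 2180,
               1200, 1730, 2270,
               1220, 1680, 2310,
               1585, 1665, 2100),
    width = c(45, 55,
              35, 40, 40,
              60, 50, 45,
              55, 45, 40,
              50, 40, 45),
    loading = c(1.2, 1.8,
                0.5, 0.9, 0.7,
                0.25, 0.20, 0.35,
                0.20, 0.25, 0.30,
                0.15, 0.12, 0.18),
    stringsAsFactors = FALSE)
}

#' Default scatter-distortion magnitudes per preparation state
#'
#' Per-sample distortion of a clean absorbance spectrum x(l):
#' `x * (1 + a + g(l)) + b + c * t(l)`, where `t(l)` is the wavelength
#' rescaled to \[-0.5, 0.5\], a, b, c are zero-mean Gaussian draws, and
#' g(l) is a smooth zero-mean random gain field (broad Gaussian bumps with
#' per-sample random coefficients). `mult` is the SD of the flat
#' multiplicative scatter a, `mult_tilt` the per-channel SD of the
#' wavelength-dependent gain g -- the signature of particle-size scattering
#' that survives SNV and detrend -- `add` the SD of the baseline offset b
#' and `tilt` the SD of the baseline slope c. Unground (coarse, <10 cm)
#' material scatters more than 1-mm ground material on every component.
#'
#' The `presentation` component models aliquot-representativeness error:
#' the spectrum responds to the composition of the scanned aliquot, which
#' for coarse intact stems differs from the milled aliquot analysed in the
#' laboratory. It is the SD of that composition difference expressed as a
#' fraction of each analyte's population SD, and it acts inside the band
#' mixing (a structured spectral distortion), leaving the laboratory value
#' untouched. Grinding to 1 mm homogenizes the sample, which is why the
#' ground default is near zero.
#'
#' @return Named list with elements `ground` and `unground`.
#' @export
default_scatter <- function() {
  list(ground = c(mult = 0.02, add = 0.01, tilt = 0.01, mult_tilt = 0.01,
                  presentation = 0.05),
       unground = c(mult = 0.08, add = 0.05, tilt = 0.05, mult_tilt = 0.15,
                    presentation = 0.55))
}

#' Configure the synthetic hay generator
#'
#' @param species `"alfalfa"` or `"timothy"`; sets the default analyte
#'   means, SDs and truncation ranges from [hay_population()].
#' @param n_samples Number of samples (>= 10), default 200.
#' @param prep_state `"ground"` or `"unground"`.
#' @param analytes Analytes to generate (default all five).
#' @param analyte_means,analyte_sds,analyte_min,analyte_max Named numeric
#'   overrides in g/kg; draws are truncated to \[min, max\].
#' @param band_library Band table as in [default_band_library()].
#' @param scatter Distortion magnitudes as in [default_scatter()].
#' @param noise_sd I.i.d. channel noise SD in absorbance, default 0.001.
#' @param wavelengths Wavelength grid, default [default_grid()].
#' @param seed Integer seed.
#' @return An object of class `hay_sim_config`.
#' @export
hay_sim_config <- function(species = c("alfalfa", "timothy"),
                           n_samples = 200,
                           prep_state = c("ground", "unground"),
                           analytes = hay_analytes,
                           analyte_means = NULL, analyte_sds = NULL,
                           analyte_min = NULL, analyte_max = NULL,
                           band_library = default_band_library(),
                           scatter = default_scatter(),
                           noise_sd = 0.001,
                           wavelengths = default_grid(),
                           seed = 1) {
  species <- match.arg(species)
  prep_state <- match.arg(prep_state)
  if (n_samples < 10) stop("n_samples must be >= 10")
  stopifnot(all(analytes %in% hay_analytes))
  pop <- hay_population(species)
  take <- function(ovr, def) {
    out <- def[analytes]
    if (!is.null(ovr)) out[names(ovr)] <- ovr
    out
  }
  cfg <- structure(list(
    species = species, n_samples = as.integer(n_samples),
    prep_state = prep_state, analytes = analytes,
    analyte_means = take(analyte_means, pop$mean),
    analyte_sds = take(analyte_sds, pop$sd),
    analyte_min = take(analyte_min, pop$min),
    analyte_max = take(analyte_max, pop$max),
    band_library = band_library[band_library$analyte %in% analytes, ,
                                drop = FALSE],
    scatter = scatter, noise_sd = noise_sd,
    wavelengths = as.numeric(wavelengths), seed = as.integer(seed)),
    class = "hay_sim_config")
  if (any(cfg$analyte_sds < 0) || noise_sd < 0) stop("SDs must be >= 0")
  for (comp in names(scatter$ground)) {
    if (scatter$unground[comp] < scatter$ground[comp]) {
      stop("unground scatter must be >= ground scatter (component ",
           comp, ")")
    }
  }
  if (!nrow(cfg$band_library)) stop("band library is empty")
  cfg
}

#' @export
print.hay_sim_config <- function(x, ...) {
  cat("Synthetic hay generator:", x$species, "|", x$n_samples, "samples |",
      x$prep_state, "| seed", x$seed, "\n")
  cat("  analytes:", paste(x$analytes, collapse = ", "), "\n")
  cat("  noise_sd:", x$noise_sd, "| scatter (", x$prep_state, "):",
      paste(names(x$scatter[[x$prep_state]]),
            x$scatter[[x$prep_state]], sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# One truncated-normal draw per cell by rejection.
rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lo | out[bad] > hi]
  }
  out
}

# Chemistry + clean spectra + distortion innovations, all from one seeded
# stream so that paired prep states can share everything but the scatter
# magnitudes.
sim_core <- function(config) {
  n <- config$n_samples
  wl <- config$wavelengths
  p <- length(wl)
  chem <- with_seed(config$seed, {
    vals <- sapply(config$analytes, function(a) {
      m <- config$analyte_means[[a]]
      s <- config$analyte_sds[[a]]
      lo <- config$analyte_min[[a]]
      hi <- config$analyte_max[[a]]
      if (a == "CP") {
        # crude protein is generated as total nitrogen x 6.25
        6.25 * rtruncnorm(n, m / 6.25, s / 6.25, lo / 6.25, hi / 6.25)
      } else {
        rtruncnorm(n, m, s, lo, hi)
      }
    })
    innov <- list(a = stats::rnorm(n),
                  a2 = matrix(stats::rnorm(n * 4L), n, 4L),
                  b = stats::rnorm(n), c = stats::rnorm(n),
                  jitter = matrix(stats::rnorm(n * length(config$analytes)),
                                  n, length(config$analytes)),
                  noise = matrix(stats::rnorm(n * p), n, p))
    list(values = matrix(vals, nrow = n,
                         dimnames = list(NULL, config$analytes)),
         innov = innov)
  })
  # analyte "drivers": mass fractions; DM drives through its moisture
  # complement so wetter (low-DM) samples show stronger water bands
  drivers <- chem$values / 1000
  if ("DM" %in% config$analytes) {
    drivers[, "DM"] <- (1000 - chem$values[, "DM"]) / 1000
  }
  resp <- t(vapply(config$analytes, function(a) {
    bl <- config$band_library[config$band_library$analyte == a, ,
                              drop = FALSE]
    r <- numeric(p)
    for (j in seq_len(nrow(bl))) {
      r <- r + bl$loading[j] * exp(-0.5 * ((wl - bl$center[j]) /
                                             bl$width[j])^2)
    }
    r
  }, numeric(p)))
  tilt <- (wl - mean(range(wl))) / diff(range(wl))  # in [-0.5, 0.5]
  baseline <- 0.35 + 0.15 * (tilt + 0.5)
  clean <- rep(baseline, each = n) + drivers %*% resp
  list(chem = chem$values, clean = clean, innov = chem$innov, tilt = tilt,
       gain_basis = gain_basis(wl), resp = resp,
       driver_sd = config$analyte_sds[config$analytes] / 1000)
}

# Smooth basis for the wavelength-dependent scattering gain: broad Gaussian
# bumps spanning the range, each standardized to unit SD across channels,
# so a coefficient SD of s gives a per-channel gain SD close to s.
gain_basis <- function(wl) {
  centers <- min(wl) + diff(range(wl)) * c(0.15, 0.4, 0.65, 0.9)
  width <- diff(range(wl)) / 6
  B <- t(vapply(centers, function(cc) exp(-0.5 * ((wl - cc) / width)^2),
                numeric(length(wl))))
  B <- B - rowMeans(B)
  B / sqrt(rowMeans(B^2)) / sqrt(nrow(B))
}

distort <- function(core, config, prep_state) {
  s <- config$scatter[[prep_state]]
  n <- config$n_samples
  iv <- core$innov
  gain <- 1 + s[["mult"]] * iv$a +
    s[["mult_tilt"]] * (iv$a2 %*% core$gain_basis)
  # aliquot-representativeness error: the scanned portion's composition
  # differs from the lab aliquot's by a state-dependent jitter
  pres <- if ("presentation" %in% names(s)) s[["presentation"]] else 0
  scanned <- core$clean +
    (iv$jitter * rep(pres * core$driver_sd, each = nrow(iv$jitter))) %*%
    core$resp
  scanned * gain +
    s[["add"]] * iv$b + outer(s[["tilt"]] * iv$c, core$tilt) +
    config$noise_sd * iv$noise
}

#' Generate a synthetic hay dataset
#'
#' Draws reference chemistry from truncated normals (crude protein
#' internally as nitrogen times 6.25), builds clean absorbance spectra as a
#' linear Gaussian-band mixture of the analyte mass fractions on top of a
#' smooth baseline, applies per-sample scatter distortion for the configured
#' preparation state, and adds i.i.d. channel noise.
#'
#' @param config A [hay_sim_config()].
#' @return An `aligned_dataset` (spectra plus reference chemistry in g/kg).
#' @examples
#' ds <- simulate_hay(hay_sim_config(n_samples = 30, seed = 7))
#' ds
#' @export
simulate_hay <- function(config) {
  stopifnot(inherits(config, "hay_sim_config"))
  core <- sim_core(config)
  build_dataset(core, config, config$prep_state)
}

build_dataset <- function(core, config, prep_state) {
  X <- distort(core, config, prep_state)
  # IDs identify the physical sample, not the scan, so paired ground and
  # unground portions of the same sample share an ID
  ids <- sprintf("%s_%04d", substr(config$species, 1, 3),
                 seq_len(config$n_samples))
  sp <- suppressWarnings(spectrum_set(
    X, config$wavelengths, ids, prep_state,
    meta = list(generator = "haycal::simulate_hay", species = config$species,
                seed = config$seed)))
  ref <- reference_table(core$chem, ids, units = "g/kg")
  structure(list(spectra = sp, reference = ref), class = "aligned_dataset")
}

#' Generate paired ground/unground datasets
#'
#' Emulates splitting each hay sample into two portions scanned once ground
#' and once unground: reference chemistry, clean spectra, and all random
#' innovations are shared between the two outputs; only the scatter
#' magnitudes differ by preparation state, isolating the sample-preparation
#' contrast.
#'
#' @param config A [hay_sim_config()]; its `prep_state` is ignored.
#' @return Named list with `aligned_dataset` elements `ground` and
#'   `unground`.
#' @export
paired_prep_states <- function(config) {
  stopifnot(inherits(config, "hay_sim_config"))
  core <- sim_core(config)
  list(ground = build_dataset(core, config, "ground"),
       unground = build_dataset(core, config, "unground"))
}
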