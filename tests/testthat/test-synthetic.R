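test_that("generated chemistry recovers the configured moments", {
  cfg <- hay_sim_config(species = "alfalfa", n_samples = 227, seed = 42)
  ds <- simulate_hay(cfg)
  pop <- hay_population("alfalfa")
  vals <- ds$reference$values
  for (a in hay_analytes) {
    se <- pop$sd[a] / sqrt(227)
    expect_lt(abs(mean(vals[, a]) - pop$mean[a]), 3 * se)
    # truncation keeps draws inside the population range
    expect_gte(min(vals[, a]), pop$min[a])
    expect_lte(max(vals[, a]), pop$max[a])
    # SD within Monte-Carlo error (~3 * sd/sqrt(2n) for a normal SD)
    expect_lt(abs(sd(vals[, a]) - pop$sd[a]),
              3 * pop$sd[a] / sqrt(2 * 227) + 0.1 * pop$sd[a])
  }
})

test_that("the generator is deterministic in its seed", {
  cfg <- hay_sim_config(n_samples = 30, seed = 99)
  d1 <- simulate_hay(cfg)
  d2 <- simulate_hay(cfg)
  expect_identical(d1$spectra$absorbance, d2$spectra$absorbance)
  expect_identical(d1$reference$values, d2$reference$values)
  d3 <- simulate_hay(hay_sim_config(n_samples = 30, seed = 100))
  expect_false(identical(d1$spectra$absorbance, d3$spectra$absorbance))
})

test_that("clean spectra are exactly affine in the concentrations", {
  cfg <- hay_sim_config(n_samples = 12, seed = 5)
  core <- haycal:::sim_core(cfg)
  # an affine regression of every channel on the five concentrations must
  # reproduce the clean spectra exactly (zero residual)
  D <- cbind(1, core$chem / 1000)
  fit <- stats::lm.fit(D, core$clean)
  expect_lt(max(abs(fit$residuals)), 1e-9)
  # the recovered per-unit-fraction effect of CP is exactly its band
  # response (DM enters through its moisture complement, hence negated)
  expect_equal(unname(fit$coefficients["CP", ]), core$resp["CP", ],
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(unname(fit$coefficients["DM", ]), -core$resp["DM", ],
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("a noise-free single-analyte problem calibrates with <= 2 factors", {
  sc <- list(ground = c(mult = 0, add = 0, tilt = 0, mult_tilt = 0,
                        presentation = 0),
             unground = c(mult = 0, add = 0, tilt = 0, mult_tilt = 0,
                          presentation = 0))
  bl <- data.frame(analyte = c("CP", "CP"), center = c(1700, 2100),
                   width = c(50, 60), loading = c(0.8, 0.6))
  cfg <- hay_sim_config(n_samples = 60, analytes = "CP", band_library = bl,
                        scatter = sc, noise_sd = 0, seed = 31)
  ds <- simulate_hay(cfg)
  res <- cross_validate(ds, "CP", math_treatment(0, 1, 1, scatter = "none"),
                        cv = cv_spec(seed = 1), cap = 2, screen = FALSE)
  expect_gt(res$r2_cv, 0.999)
  expect_lte(res$n_factors, 2)
})

test_that("paired prep states share chemistry and differ only in distortion", {
  cfg <- hay_sim_config(n_samples = 40, seed = 17)
  pair <- paired_prep_states(cfg)
  expect_identical(pair$ground$reference$values,
                   pair$unground$reference$values)
  # unground spectra scatter more around the population mean spectrum
  dev <- function(ds) {
    mu <- colMeans(ds$spectra$absorbance)
    mean(apply(ds$spectra$absorbance - rep(mu, each = 40), 1, sd))
  }
  expect_gt(dev(pair$unground), dev(pair$ground))
  # equalized distortions collapse the two arms onto the same dataset
  sc_eq <- default_scatter()
  sc_eq$unground <- sc_eq$ground
  pair_eq <- paired_prep_states(hay_sim_config(n_samples = 20, seed = 3,
                                               scatter = sc_eq))
  expect_equal(pair_eq$ground$spectra$absorbance,
               pair_eq$unground$spectra$absorbance, ignore_attr = TRUE)
})

test_that("config validation rejects inconsistent setups", {
  expect_error(hay_sim_config(n_samples = 5), "n_samples")
  sc <- default_scatter()
  sc$unground[["mult"]] <- 0.001
  expect_error(hay_sim_config(scatter = sc), "unground scatter")
  expect_error(hay_sim_config(band_library = data.frame(
    analyte = "XX", center = 1500, width = 40, loading = 1)), "empty")
})

test_that("ground calibrations beat unground ones on the same samples", {
  # the sample-preparation contrast, one seed; the multi-seed version is an
  # acceptance-level check
  pair <- paired_prep_states(hay_sim_config(n_samples = 120, seed = 23))
  for (a in c("CP", "NDF")) {
    fg <- suppressWarnings(nirs_calibrate(pair$ground, a,
                                          treatment = "1,4,4",
                                          cv = cv_spec(seed = 1)))
    fu <- suppressWarnings(nirs_calibrate(pair$unground, a,
                                          treatment = "1,4,4",
                                          cv = cv_spec(seed = 1)))
    expect_gt(fg$r2_cv, fu$r2_cv)
  }
})
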