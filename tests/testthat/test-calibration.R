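test_that("R-squared matches closed forms", {
  y <- c(0, 1, 2)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 3)), 0)
  expect_warning(r2 <- r_squared(y, c(0, 1, 4)), "negative")
  expect_equal(r2, -1)
  expect_error(r_squared(rep(1, 3), y), "zero variance")
})

test_that("RPD is the reference SD over SECV, with unit guarding", {
  expect_equal(rpd(1.5, 1.5), 1)
  expect_equal(round(rpd(1.24, 0.34), 2), 3.65)
  expect_error(rpd(1.24, 0.34, units = c("percent", "g/kg")),
               "unit mismatch")
  expect_error(rpd(0, 1), "sd_reference")
  expect_error(rpd(1, 0), "secv")
})

test_that("acceptance rule is strict on both thresholds", {
  mk <- function(r2, rp) list(r2_cv = r2, rpd = rp, secv = 1, sec = 1)
  expect_true(acceptance_check(mk(0.95, 4.88)))
  expect_false(acceptance_check(mk(0.80, 3)))   # boundary r2
  expect_false(acceptance_check(mk(0.9, 2)))    # boundary rpd
  expect_false(acceptance_check(mk(0.9, 1.9)))
  expect_message(acceptance_check(list(r2_cv = 0.9, rpd = 3, secv = 2,
                                       sec = 1)), "SECV/SEC")
})

test_that("a noise-free linear response cross-validates essentially perfectly", {
  # derivative only, no SNV: the spectra stay exactly linear in the response
  ds <- toy_dataset(n = 100, noise = 0)
  res <- cross_validate(ds, "CP", math_treatment(1, 4, 4, scatter = "none"),
                        cv = cv_spec(seed = 2), screen = FALSE)
  expect_gt(res$r2_cv, 0.999)
  expect_gt(res$rpd, 20)
})

test_that("permuted responses carry no cross-validated signal", {
  ds <- toy_dataset(n = 60, noise = 1e-4)
  r2s <- vapply(1:20, function(s) {
    set.seed(s)
    ds_perm <- structure(list(spectra = ds$spectra,
                              reference = reference_table(
                                matrix(sample(ds$reference$values), ncol = 1,
                                       dimnames = dimnames(ds$reference$values)),
                                ds$reference$sample_ids, "g/kg")),
                         class = "aligned_dataset")
    suppressWarnings(
      cross_validate(ds_perm, "CP", math_treatment(1, 4, 4),
                     cv = cv_spec(seed = s), screen = FALSE)$r2_cv)
  }, numeric(1))
  expect_lt(mean(r2s), 0.1)
})

test_that("identical seed and data give identical results and reports", {
  ds <- toy_dataset(n = 50, noise = 0.002)
  r1 <- cross_validate(ds, "CP", math_treatment(1, 4, 4),
                       cv = cv_spec(seed = 7))
  r2 <- cross_validate(ds, "CP", math_treatment(1, 4, 4),
                       cv = cv_spec(seed = 7))
  expect_identical(r1[c("r2_cal", "sec", "r2_cv", "secv", "rpd",
                        "n_selected", "n_factors")],
                   r2[c("r2_cal", "sec", "r2_cv", "secv", "rpd",
                        "n_selected", "n_factors")])
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_report(r1, f1, timestamp = FALSE)
  write_report(r2, f2, timestamp = FALSE)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("the RPD identity links secv, rpd and the selected-set SD", {
  ds <- toy_dataset(n = 80, noise = 0.003)
  res <- cross_validate(ds, "CP", math_treatment(1, 4, 4),
                        cv = cv_spec(seed = 4))
  expect_equal(res$rpd * res$secv, res$sd_selected,
               tolerance = 0.005 * res$sd_selected)
})

test_that("grid search returns a member of the list with best SECV", {
  ds <- toy_dataset(n = 60, noise = 0.002)
  one <- grid_search(ds, "CP", treatments = list(math_treatment(2, 8, 8)),
                     cv = cv_spec(seed = 1))
  expect_equal(format(one$treatment), "2,8,8")
  tl <- list(math_treatment(1, 4, 4), math_treatment(2, 8, 8),
             math_treatment(3, 16, 16))
  best <- grid_search(ds, "CP", treatments = tl, cv = cv_spec(seed = 1))
  g <- best$provenance$grid
  expect_equal(nrow(g), 3)
  expect_true(format(best$treatment) %in% vapply(tl, format, character(1)))
  expect_equal(best$secv, min(g$secv))
  expect_error(grid_search(ds, "CP", treatments = list()), "empty")
})

test_that("slope-driven responses favour a first-derivative treatment", {
  # response encoded in the local slope of a band edge: d=1 should beat d=4
  set.seed(12)
  n <- 60; wl <- seq(1200, 1700, by = 2); p <- length(wl)
  conc <- runif(n, 50, 150)
  # band whose width (hence edge slope) tracks the response
  X <- t(vapply(seq_len(n), function(i) {
    0.3 + (conc[i] / 1000) * (wl - 1200) / 500 +
      0.2 * exp(-0.5 * ((wl - 1450) / 40)^2) +
      rnorm(p, 0, 5e-4)
  }, numeric(p)))
  ids <- sprintf("E%03d", 1:n)
  ds <- structure(list(
    spectra = suppressWarnings(spectrum_set(X, wl, ids)),
    reference = reference_table(matrix(conc, ncol = 1,
                                       dimnames = list(ids, "CP")),
                                ids, "g/kg")),
    class = "aligned_dataset")
  tl <- list(math_treatment(1, 4, 4), math_treatment(4, 16, 16))
  best <- grid_search(ds, "CP", treatments = tl, cv = cv_spec(seed = 5),
                      screen = FALSE)
  expect_equal(best$treatment$derivative, 1)
})

test_that("predict applies the stored treatment to new spectra", {
  ds <- toy_dataset(n = 60, noise = 0.001)
  res <- cross_validate(ds, "CP", math_treatment(1, 4, 4),
                        cv = cv_spec(seed = 3), screen = FALSE)
  preds <- predict(res, ds$spectra)
  y <- ds$reference$values[, "CP"] / 10
  expect_gt(r_squared(y, preds), 0.999)
  expect_equal(unname(coef(res)["(Intercept)"]),
               res$model$y_mean - sum(res$model$x_mean * coef(res)[-1]))
})

test_that("models survive a JSON serialization round trip", {
  ds <- toy_dataset(n = 50, noise = 0.002)
  res <- cross_validate(ds, "CP", math_treatment(1, 4, 4),
                        cv = cv_spec(seed = 9), screen = FALSE)
  f <- withr::local_tempfile(fileext = ".json")
  write_model(res, f)
  m <- read_model(f)
  expect_equal(unname(predict(m, ds$spectra)),
               unname(predict(res, ds$spectra)), tolerance = 1e-10)
  expect_equal(m$stats$secv, res$secv)
})
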