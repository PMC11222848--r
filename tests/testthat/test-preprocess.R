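test_that("absorbance transform matches closed forms and guards domain", {
  expect_equal(absorbance_transform(1, "log10"), 0)
  expect_equal(absorbance_transform(1, "natural"), 0)
  expect_equal(absorbance_transform(0.1, "log10"), 1)
  expect_equal(absorbance_transform(exp(-1), "natural"), 1)
  expect_error(absorbance_transform(c(0.5, 0)), "position 2")
  expect_error(absorbance_transform(matrix(c(0.5, 1.2), 1)), "row 1")
})

test_that("SNV centers and scales each spectrum", {
  expect_equal(snv(c(1, 2, 3)), c(-1, 0, 1))
  x <- rnorm(50)
  z <- snv(x)
  expect_equal(snv(z), z, tolerance = 1e-12)      # idempotent on normalized
  expect_equal(snv(3.7 * x + 42), snv(x), tolerance = 1e-12)  # affine inv.
  expect_error(snv(rep(1, 10)), "degenerate")
  # matrix form: every row zero-mean, unit sample SD
  X <- matrix(rnorm(200), 8)
  Z <- snv(X)
  expect_lt(max(abs(rowMeans(Z))), 1e-10)
  expect_lt(max(abs(apply(Z, 1, sd) - 1)), 1e-10)
})

test_that("detrend is an exact projection orthogonal to the poly basis", {
  wl <- seq(1000, 1400, by = 2)
  quad <- 3 + 0.01 * wl - 2e-6 * wl^2
  expect_lt(max(abs(detrend(quad, wl, 2))), 1e-8)
  x <- sin(wl / 30) + 0.005 * wl
  d1 <- detrend(x, wl, 2)
  expect_equal(detrend(d1, wl, 2), d1, tolerance = 1e-10)  # idempotent
  # residual orthogonal to 1, wl, wl^2 (relative inner products)
  for (k in 0:2) {
    b <- ((wl - min(wl)) / diff(range(wl)))^k
    expect_lt(abs(sum(d1 * b)) / (sqrt(sum(d1^2)) * sqrt(sum(b^2))), 1e-8)
  }
  expect_error(detrend(x, wl, -1), "poly_order")
})

test_that("detrend recovers a band on a sloped baseline (normal-equations oracle)", {
  wl <- seq(1000, 2200, by = 2)
  band <- 0.5 * exp(-0.5 * ((wl - 1600) / 15)^2)
  x <- 0.1 + 0.002 * (wl - 1000) + band
  got <- detrend(x, wl, 2)
  # independent oracle: explicit least squares via the normal equations
  # (on a standardized abscissa so the 3x3 solve is well conditioned)
  z <- (wl - mean(wl)) / sd(wl)
  V <- cbind(1, z, z^2)
  beta <- solve(t(V) %*% V, t(V) %*% x)
  oracle <- x - drop(V %*% beta)
  expect_equal(got, oracle, tolerance = 1e-6)
  # away from the band the residual baseline is small vs the band height
  off_band <- abs(wl - 1600) > 100
  expect_lt(max(abs(got[off_band])), 0.1 * max(band))
})

naive_gap_derivative <- function(x, d, gap, smoothing) {
  # nested-loop reference implementation
  if (smoothing > 1) {
    x <- vapply(seq_len(length(x) - smoothing + 1),
                function(j) mean(x[j:(j + smoothing - 1)]), numeric(1))
  }
  for (r in seq_len(d)) {
    n <- length(x)
    out <- numeric(n - gap)
    for (i in seq_len(n - gap)) out[i] <- x[i + gap] - x[i]
    x <- out
  }
  x
}

test_that("gap derivative matches closed forms and the nested-loop oracle", {
  expect_true(all(gap_derivative(rep(5, 60), d = 1, gap = 4) == 0))
  expect_true(all(gap_derivative(rep(5, 60), d = 3, gap = 8) == 0))
  ramp <- 0.25 * seq_len(80)
  expect_equal(gap_derivative(ramp, d = 1, gap = 4, smoothing = 1),
               rep(4 * 0.25, 76))
  i <- seq_len(120)
  cubic <- 2 + i - 0.5 * i^2 + 0.01 * i^3
  expect_lt(max(abs(gap_derivative(cubic, d = 4, gap = 6))), 1e-9)
  set.seed(3)
  x <- rnorm(100)
  for (par in list(c(1, 4, 4), c(2, 8, 8), c(3, 16, 16), c(4, 4, 1))) {
    expect_equal(gap_derivative(x, par[1], par[2], par[3]),
                 naive_gap_derivative(x, par[1], par[2], par[3]),
                 tolerance = 1e-12)
  }
  expect_error(gap_derivative(rnorm(10), d = 4, gap = 16), "too short")
})

test_that("gap derivative is linear and annihilates low-degree polynomials", {
  set.seed(4)
  x <- rnorm(90); y <- rnorm(90)
  a <- 2.5; b <- -1.3
  for (d in 1:4) {
    lhs <- gap_derivative(a * x + b * y, d, 8, 4)
    rhs <- a * gap_derivative(x, d, 8, 4) + b * gap_derivative(y, d, 8, 4)
    expect_equal(lhs, rhs, tolerance = 1e-9)
    i <- seq_len(90)
    pol <- rowSums(outer(i / 10, 0:(d - 1), `^`))  # degree d-1
    expect_lt(max(abs(gap_derivative(pol, d, 8, 1))), 1e-9)
  }
})

test_that("treatment codes parse and the default grid has 12 entries", {
  t1 <- parse_treatment("3,16,16")
  expect_equal(c(t1$derivative, t1$gap, t1$smoothing), c(3, 16, 16))
  expect_equal(t1$scatter, "snv_detrend")
  expect_equal(format(math_treatment(1, 4, 4)), "1,4,4")
  tl <- default_treatments()
  expect_length(tl, 12)
  codes <- vapply(tl, format, character(1))
  expect_setequal(codes, c(outer(1:4, c("4,4", "8,8", "16,16"),
                                 function(d, gs) paste(d, gs, sep = ","))))
  expect_error(parse_treatment("1,4"), "code")
  expect_error(math_treatment(5, 4, 4), "0..4")
})

test_that("apply_treatment composes the operators in the declared order", {
  ss <- toy_spectra(n = 4, p = 151, seed = 9)
  # identity treatment: no derivative, no scatter correction
  tid <- math_treatment(0, 1, 1, scatter = "none")
  expect_equal(apply_treatment(ss, tid)$absorbance, ss$absorbance)
  # SNV scale invariance: scalar multiples map to the same row
  X <- ss$absorbance
  X2 <- rbind(X[1, ], 3 * X[1, ] + 0.2)
  ss2 <- suppressWarnings(spectrum_set(X2, ss$wavelengths, c("u", "v")))
  out <- apply_treatment(ss2, math_treatment(1, 4, 4, scatter = "snv"))
  expect_equal(out$absorbance[1, ], out$absorbance[2, ], tolerance = 1e-10)
  # composition oracle: 1,4,4 equals manual SNV -> detrend -> derivative
  tr <- math_treatment(1, 4, 4, scatter = "snv_detrend")
  got <- apply_treatment(ss, tr)
  manual <- t(apply(X, 1, function(row) {
    gap_derivative(detrend(snv(row), ss$wavelengths, 2), 1, 4, 4)
  }))
  expect_equal(got$absorbance, manual, ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_length(got$wavelengths, ncol(manual))
  # margin bookkeeping: smoothing 4 + one gap-4 difference eats 7 channels
  expect_equal(ncol(manual), 151 - 3 - 4)
})

test_that("treatments act sample-wise: permuting rows permutes outputs", {
  ss <- toy_spectra(n = 6, p = 131, seed = 2)
  perm <- c(4, 1, 6, 2, 5, 3)
  ssp <- suppressWarnings(spectrum_set(ss$absorbance[perm, ],
                                       ss$wavelengths,
                                       ss$sample_ids[perm]))
  tr <- math_treatment(2, 8, 8)
  a <- apply_treatment(ss, tr)$absorbance
  b <- apply_treatment(ssp, tr)$absorbance
  expect_equal(b, a[perm, ], ignore_attr = TRUE)
})
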