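gauss_band <- function(grid, center, amp, width = 6) {
  amp * exp(-(grid - center)^2 / (2 * width^2))
}

test_that("difference_spectrum subtracts pointwise on matched grids", {
  g <- ftir_grid()
  base <- ftir_spectrum(g, rep(0.3, length(g)))
  expect_equal(difference_spectrum(base, base)$absorbance,
               rep(0, length(g)))
  band <- gauss_band(g, 1662, 0.5)
  on <- ftir_spectrum(g, base$absorbance + band)
  expect_equal(difference_spectrum(on, base)$absorbance, band)
  set.seed(31)
  a <- ftir_spectrum(g, stats::rnorm(length(g)))
  b <- ftir_spectrum(g, stats::rnorm(length(g)))
  expect_equal(difference_spectrum(a, b)$absorbance,
               a$absorbance - b$absorbance)
  short <- ftir_spectrum(ftir_grid(1800, 1200), rep(0, 301))
  expect_error(difference_spectrum(a, short), "grids do not match")
})

test_that("average_cycles takes the pointwise mean and tracks n_cycles", {
  g <- ftir_grid()
  zero <- ftir_spectrum(g, rep(0, length(g)))
  mk <- function(v) difference_spectrum(ftir_spectrum(g, v), zero)
  one <- mk(gauss_band(g, 1554, -0.4))
  expect_equal(average_cycles(list(one))$absorbance, one$absorbance)
  v <- stats::rnorm(length(g))
  expect_equal(average_cycles(list(mk(v), mk(-v)))$absorbance,
               rep(0, length(g)))
  # k copies of one spectrum average to that spectrum
  expect_equal(average_cycles(rep(list(one), 6))$absorbance, one$absorbance)

  # 6 noisy replicates: noise sd shrinks ~ 1/sqrt(6)
  set.seed(8)
  signal <- gauss_band(g, 1648, -1)
  reps <- lapply(1:6, function(i) mk(signal + stats::rnorm(length(g), 0, 0.1)))
  avg <- average_cycles(reps)
  expect_equal(avg$n_cycles, 6L)
  resid_sd <- stats::sd(avg$absorbance - signal)
  expect_lt(resid_sd, 0.1 / sqrt(6) * 1.3)
  expect_gt(resid_sd, 0.1 / sqrt(6) / 1.3)
  expect_error(average_cycles(list()), "at least one")
})

test_that("subtract_baseline removes drift fitted on anchor regions", {
  g <- ftir_grid()
  zero <- ftir_spectrum(g, rep(0, length(g)))
  ramp <- 0.05 + 3e-4 * (g - 1400)
  d <- difference_spectrum(ftir_spectrum(g, ramp), zero)
  flat <- subtract_baseline(d, "linear")
  expect_equal(flat$absorbance, rep(0, length(g)), tolerance = 1e-10)

  # bands + quadratic drift: bands recovered within 1% amplitude
  set.seed(12)
  bands <- gauss_band(g, 1662, 1) + gauss_band(g, 1648, -1.2)
  drift <- 0.02 + 1e-4 * (g - 1400) + 2e-7 * (g - 1400)^2
  d2 <- difference_spectrum(ftir_spectrum(g, bands + drift), zero)
  rec <- subtract_baseline(d2, "polynomial", degree = 2)
  expect_lt(max(abs(rec$absorbance - bands)), 0.01 * 1.2)
  # closed form including the overlap of the two Gaussians 14 cm-1 apart
  cross <- exp(-14^2 / (2 * 6^2))
  want <- (1 - 1.2 * cross) - (-1.2 + 1 * cross)
  expect_equal(band_intensity(rec, c(1662, 1648)), want, tolerance = 1e-6)

  expect_identical(subtract_baseline(d2, "none"), d2)
  expect_error(subtract_baseline(d2, "polynomial", degree = 50,
                                 anchor_regions = list(c(1004, 1000))),
               "anchor point count")
  expect_error(subtract_baseline(d2, "linear",
                                 anchor_regions = list(c(1900, 1850))),
               "outside the grid")
})

test_that("double_difference isolates the selective response and is linear", {
  g <- ftir_grid()
  zero <- ftir_spectrum(g, rep(0, length(g)))
  mk <- function(v) difference_spectrum(ftir_spectrum(g, v), zero)
  common <- gauss_band(g, 1554, -0.5) + gauss_band(g, 1394, 0.3)
  selective <- gauss_band(g, 1662, 1) + gauss_band(g, 1648, -1.2)

  # identical Na and K responses -> flat line (the mutant phenotype)
  dd_flat <- double_difference(mk(common), mk(common))
  expect_equal(dd_flat$absorbance, rep(0, length(g)))

  dd <- double_difference(mk(common + selective), mk(common))
  expect_equal(dd$absorbance, selective)

  # linearity: adding any shared spectrum c to both arms changes nothing
  set.seed(4)
  a <- stats::rnorm(length(g)); b <- stats::rnorm(length(g))
  cc <- stats::rnorm(length(g))
  expect_equal(double_difference(mk(a + cc), mk(b + cc))$absorbance,
               double_difference(mk(a), mk(b))$absorbance)
})

test_that("band_intensity is peak minus trough at nearest gridpoints", {
  g <- ftir_grid()
  zero <- ftir_spectrum(g, rep(0, length(g)))
  v <- numeric(length(g))
  v[g == 1662] <- 0.5
  v[g == 1648] <- -0.5
  d <- difference_spectrum(ftir_spectrum(g, v), zero)
  expect_equal(band_intensity(d, c(1662, 1648)), 1.0)
  expect_equal(band_intensity(difference_spectrum(zero, zero),
                              c(1115, 1061)), 0)
  # closed-form two-Gaussian model; 1115/1061 are off the even 2 cm-1 grid
  # so the evaluation points are the nearest gridpoints
  w <- 6
  v2 <- gauss_band(g, 1115, 0.5, w) + gauss_band(g, 1061, -0.4, w)
  d2 <- difference_spectrum(ftir_spectrum(g, v2), zero)
  snap <- function(p) g[which.min(abs(g - p))]
  closed_form <- function(p) {
    gauss_band(snap(p), 1115, 0.5, w) + gauss_band(snap(p), 1061, -0.4, w)
  }
  want <- closed_form(1115) - closed_form(1061)
  expect_equal(band_intensity(d2, c(1115, 1061)), want)
  # an off-grid wavenumber snaps to the same nearest gridpoint
  expect_equal(band_intensity(d2, c(snap(1115) + 0.9, 1061)), want)
  expect_error(band_intensity(d2, c(900, 1061)), "outside the grid")
})

test_that("fit_hill recovers parameters on noiseless designs", {
  conc <- c(0.5, 2, 10, 20, 50, 100)
  fit <- fit_hill(conc, hill_model(conc, 1, 1, 1))
  expect_equal(fit$amplitude, 1, tolerance = 1e-6)
  expect_equal(fit$kd, 1, tolerance = 1e-6)
  expect_equal(fit$n_hill, 1, tolerance = 1e-6)

  # measured binding parameters for the two band pairs
  for (p in list(c(0.8, 3.5, 0.9), c(0.5, 6.5, 0.7))) {
    f <- fit_hill(conc, hill_model(conc, p[1], p[2], p[3]))
    expect_equal(f$kd, p[2], tolerance = 1e-4)
    expect_equal(f$n_hill, p[3], tolerance = 1e-4)
    expect_lt(f$residual_rms, 1e-6)
  }
  expect_error(fit_hill(c(1, 2), c(0.1, 0.2)), "3 distinct")
})

test_that("fit_hill recovery holds across the Kd/n design space and under
           noise", {
  conc <- c(0.5, 2, 10, 20, 50, 100)
  for (kd in c(0.5, 5, 50)) {
    for (n in c(0.5, 1, 2)) {
      f <- fit_hill(conc, hill_model(conc, 1, kd, n))
      expect_equal(f$kd, kd, tolerance = 1e-4)
      expect_equal(f$n_hill, n, tolerance = 1e-4)
    }
  }
  # Monte-Carlo: median Kd within 15% of the generator at 5% noise
  set.seed(77)
  kds <- replicate(200, {
    y <- hill_model(conc, 1, 3.5, 0.9) + stats::rnorm(6, 0, 0.05)
    fit_hill(conc, y)$kd
  })
  expect_lt(abs(stats::median(kds) - 3.5) / 3.5, 0.15)
})

test_that("nu_separations crosses candidates and rejects negatives", {
  got <- nu_separations(c(1545, 1525), c(1425, 1406))
  expect_setequal(got$delta, c(120, 100, 139, 119))
  expect_equal(range(got$delta), c(100, 139))
  expect_equal(nu_separations(1500, 1500)$delta, 0)
  expect_equal(nu_separations(1554, 1417)$delta, 137)
  # negative pairs are dropped, not returned
  mixed <- nu_separations(c(1400, 1545), 1425)
  expect_equal(nrow(mixed), 1)
  expect_error(nu_separations(numeric(0), 1425), "non-empty")
})

test_that("classify_coordination separates the two published ranges", {
  expect_equal(classify_coordination(139)$call, "bidentate_or_pseudobridged")
  expect_equal(classify_coordination(100)$call, "bidentate_or_pseudobridged")
  expect_equal(classify_coordination(160)$call, "less_bidentate")
  expect_equal(classify_coordination(164)$call, "less_bidentate")
  expect_equal(classify_coordination(145)$call, "indeterminate")
  expect_error(classify_coordination(-1), ">= 0")
  # thresholds are configurable
  expect_equal(classify_coordination(145, bidentate_max = 146)$call,
               "bidentate_or_pseudobridged")
})
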