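test_that("a pure tone produces a spectral peak at its frequency", {
  n <- 256
  t <- (0:(n - 1)) / 40e6
  blk <- list(data = matrix(rep(sin(2 * pi * 5e6 * t), 4), 4, n,
                            byrow = TRUE),
              center_depth_cm = 1)
  s <- block_power_spectrum(blk)
  expect_equal(s$frequencies[which.max(s$power_db)], 5, tolerance = 0.05)
})

test_that("white-noise periodograms average to the flat theoretical PSD", {
  set.seed(21)
  sigma <- 2
  blk <- list(data = matrix(rnorm(200 * 512, 0, sigma), 200, 512),
              center_depth_cm = 1)
  s <- block_power_spectrum(blk)
  sel <- s$frequencies >= 2 & s$frequencies <= 15
  lin <- 10^(s$power_db[sel] / 10)
  # two-sided PSD of white noise is sigma^2 / fs
  expect_equal(mean(lin), sigma^2 / 40e6, tolerance = 0.05)
  trend <- stats::lm(lin ~ s$frequencies[sel])
  expect_lt(abs(coef(trend)[2]) * 13, 0.1 * mean(lin))
})

test_that("normalization subtracts the reference in dB", {
  f <- seq(0, 20, by = 0.1)
  a <- as_qus_spectrum(f, rnorm(length(f)), 1.5)
  expect_equal(normalize_spectrum(a, a)$power_db, rep(0, length(f)))
  b <- as_qus_spectrum(f, a$power_db + 6, 1.5)
  expect_equal(normalize_spectrum(b, a)$power_db, rep(6, length(f)))
  g <- as_qus_spectrum(f + 0.05, a$power_db, 1.5)
  expect_error(normalize_spectrum(a, g), "grids differ")
})

test_that("point attenuation compensation adds the exact round-trip tilt", {
  f <- seq(3, 8, by = 0.05)
  flat <- as_qus_spectrum(f, rep(-10, length(f)), 1)
  same <- attenuation_correct(flat, attenuation_model(0, 0, 0, 1))
  expect_equal(same$power_db, flat$power_db)
  tilted <- attenuation_correct(flat, attenuation_model(0, 0, 1, 1))
  fit0 <- fit_spectral_line(flat)
  fit1 <- fit_spectral_line(tilted)
  expect_equal(fit1$ss - fit0$ss, 2, tolerance = 1e-12)
  expect_error(attenuation_correct(flat, attenuation_model(1, 0, 1, 3)),
               "inconsistent")
  expect_error(attenuation_model(-1, 0, 0, 0), ">= 0")
})

test_that("spectral line fits are exact on exact lines", {
  f <- seq(3, 8, by = 0.1)
  flat <- fit_spectral_line(as_qus_spectrum(f, rep(-10, length(f)), 1))
  expect_equal(flat$ss, 0, tolerance = 1e-12)
  expect_equal(flat$si, -10, tolerance = 1e-12)
  expect_equal(flat$mbf, -10, tolerance = 1e-12)
  line <- fit_spectral_line(as_qus_spectrum(f, 2 * f - 5, 1))
  expect_equal(line$ss, 2, tolerance = 1e-12)
  expect_equal(line$si, -5, tolerance = 1e-12)
  expect_equal(line$mbf, 6, tolerance = 1e-12)
  expect_error(fit_spectral_line(as_qus_spectrum(f, f, 1), band = c(9, 10)),
               "fewer than 2")
})

test_that("fits equal the closed-form normal equations and MBF identity holds", {
  set.seed(31)
  f <- seq(3, 8, by = 0.078125)
  for (i in 1:25) {
    y <- rnorm(1) + rnorm(1) * f + rnorm(length(f), 0, 0.8)
    fit <- fit_spectral_line(as_qus_spectrum(f, y, 1))
    # normal-equations oracle
    sxx <- sum((f - mean(f))^2)
    slope <- sum((f - mean(f)) * (y - mean(y))) / sxx
    intercept <- mean(y) - slope * mean(f)
    expect_equal(fit$ss, slope, tolerance = 1e-9)
    expect_equal(fit$si, intercept, tolerance = 1e-9)
    expect_equal(fit$mbf, fit$si + fit$ss * 5.5, tolerance = 1e-12)
  }
})

test_that("ACE is exact on noiseless spectra built from the attenuation law", {
  f <- seq(3, 8, by = 0.1)
  depths <- seq(1, 2.2, by = 0.2)
  make_specs <- function(alpha_s, alpha_r = 0.15) {
    lapply(depths, function(z) {
      as_qus_spectrum(f, -2 * f * (alpha_s - alpha_r) * z, z)
    })
  }
  ref <- lapply(depths, function(z) as_qus_spectrum(f, rep(0, length(f)), z))
  expect_equal(estimate_ace(make_specs(1.0), ref), 1.0, tolerance = 1e-9)
  expect_equal(estimate_ace(make_specs(0.5), ref), 0.5, tolerance = 1e-9)
  expect_equal(estimate_ace(make_specs(0.15), ref), 0.15, tolerance = 1e-9)
  # sample identical to reference at every depth -> ACE = alpha_ref
  flat <- lapply(depths, function(z) as_qus_spectrum(f, rep(3, length(f)), z))
  flat_ref <- lapply(depths, function(z) as_qus_spectrum(f, rep(3, length(f)), z))
  expect_equal(estimate_ace(flat, flat_ref), 0.15, tolerance = 1e-9)
  expect_error(estimate_ace(make_specs(1)[1:2], ref[1:2]), "too shallow")
})

test_that("spectral slope decreases with scatterer radius (analytic ratio)", {
  f <- seq(3, 8, by = 0.1)
  ref <- analytic_bsc(reference_medium(), f)
  ss <- sapply(c(15, 25, 40), function(a) {
    m <- medium_spec(scatterer_radius_um = a, number_density = 100)
    norm_db <- 10 * log10(analytic_bsc(m, f)$bsc / ref$bsc)
    fit_spectral_line(as_qus_spectrum(f, norm_db, 1))$ss
  })
  expect_true(all(diff(ss) < 0))
})
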