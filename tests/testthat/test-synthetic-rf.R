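test_that("scatterer fields are reproducible and Poisson in expectation", {
  med <- medium_spec(number_density = 5, attenuation = 0)
  vol <- list(depth_m = c(0, 10e-3), width_m = 10e-3)
  f1 <- sample_field(med, vol, seed = 4)
  f2 <- sample_field(med, vol, seed = 4)
  expect_identical(f1, f2)
  # 5 / mm^3 over a 10 x 10 mm plane with the 2 mm slice: 1000 expected
  expect_equal(f1$n_diffuse, 1000, tolerance = 0.15)
  expect_true(all(f1$z >= 0 & f1$z <= 10e-3))
})

test_that("a regular 1 mm spacing lays down the expected lattice layers", {
  med <- medium_spec(number_density = 5, regular_spacing_mm = 1,
                     regular_fraction = 2)
  vol <- list(depth_m = c(0, 10e-3), width_m = 10e-3)
  f <- sample_field(med, vol, seed = 9)
  n_layers <- length(seq(0.5e-3, 10e-3, by = 1e-3))
  n_cols <- length(seq(0.125e-3, 10e-3, by = 0.25e-3))
  expect_equal(f$n_lattice, n_layers * n_cols)
  # lattice depths concentrate near multiples of the spacing
  zl <- f$z[(f$n_diffuse + 1):length(f$z)]
  jitter <- abs(zl - round((zl - 0.5e-3) / 1e-3) * 1e-3 - 0.5e-3)
  expect_lt(stats::median(jitter), 0.1e-3)
})

test_that("same medium and seed render an identical frame", {
  acq <- tiny_acq(n_lines = 8, n_samples = 400)
  f1 <- synthesize_reference(acq, seed = 6)
  f2 <- synthesize_reference(acq, seed = 6)
  expect_identical(f1$samples, f2$samples)
})

test_that("without attenuation the echo level is flat with depth", {
  acq <- tiny_acq(n_lines = 24, n_samples = 1200)
  med <- medium_spec(attenuation = 0, number_density = 100)
  frame <- simulate_sample_frame(med, acq, seed = 12)
  p1 <- mean(frame$samples[, 200:500]^2)
  p2 <- mean(frame$samples[, 700:1000]^2)
  expect_lt(abs(10 * log10(p1 / p2)), 1)
})

test_that("simulated depth decay follows the closed-form attenuation law", {
  acq <- acq_params(n_lines = 40, n_samples = 1300, depth_origin = 2e-3)
  med <- medium_spec(attenuation = 1, number_density = 100)
  frame <- simulate_sample_frame(med, acq, seed = 13)
  roi <- roi_from_rect(frame, c(2, 39), c(8, 23))
  blocks <- partition_roi(frame, roi)
  specs <- lapply(blocks, block_power_spectrum)
  depths <- sapply(specs, `[[`, "center_depth_cm")
  shallow <- which(abs(depths - 1.0) < 0.1)
  deep <- which(abs(depths - 2.0) < 0.1)
  band_power <- function(s) {
    sel <- s$frequencies >= 3 & s$frequencies <= 8
    mean(10^(s$power_db[sel] / 10))
  }
  got_db <- 10 * log10(mean(sapply(specs[shallow], band_power)) /
                         mean(sapply(specs[deep], band_power)))
  # closed-form oracle: band-integrated pulse power under the round-trip
  # law 2 alpha f z dB at each depth
  f <- seq(3, 8, by = 0.01)
  g2 <- pulse_amplitude(pulse_spec(), f * 1e6)^2
  expected_db <- 10 * log10(
    sum(g2 * 10^(-2 * 1 * f * 1.0 / 10)) /
      sum(g2 * 10^(-2 * 1 * f * 2.0 / 10)))
  expect_equal(got_db, expected_db, tolerance = 0.15 * expected_db)
})

test_that("a frame with no scatterers is pure noise at the set floor", {
  empty <- structure(list(z = numeric(0), x = numeric(0),
                          amp = numeric(0), n_diffuse = 0L, n_lattice = 0L,
                          seed = 1,
                          volume = list(depth_m = c(0, 1e-2),
                                        width_m = 1e-2)),
                     class = "scatterer_field")
  acq <- tiny_acq(n_lines = 4, n_samples = 256)
  frame <- synthesize_rf(empty, pulse_spec(), acq,
                         medium_spec(attenuation = 0), snr_db = 40)
  expect_gt(sqrt(mean(frame$samples^2)), 0)
  expect_lt(sqrt(mean(frame$samples^2)), 0.1)
})

test_that("a pulse band beyond Nyquist is rejected", {
  acq <- tiny_acq(n_lines = 4, n_samples = 128)
  fld <- sample_field(medium_spec(number_density = 100, attenuation = 0),
                      acq_volume(acq, 1540), seed = 1)
  expect_error(
    synthesize_rf(fld, pulse_spec(15e6, 1.5), acq,
                  medium_spec(number_density = 100, attenuation = 0)),
    "Nyquist")
})

test_that("reference phantom speckle approaches Rayleigh statistics", {
  acq <- acq_params(n_lines = 40, n_samples = 1100, depth_origin = 2e-3)
  frame <- synthesize_reference(acq, seed = 15)
  env <- rf_envelope(frame)[, 100:1000]
  snr <- mean(env) / stats::sd(env)
  # fully developed speckle has envelope mean/SD = 1.91; finite
  # scatterer-per-cell counts sit slightly below the limit
  expect_equal(snr, 1.91, tolerance = 0.08)
})

test_that("planar reflector echoes arrive at the round-trip delay", {
  acq <- acq_params(n_lines = 4, n_samples = 3600, depth_origin = 0)
  for (d in c(1, 3, 6)) {
    frame <- synthesize_planar_reflector(acq, d)
    peak <- which.max(abs(frame$samples[1, ]))
    expect_equal(peak - 1, 2 * d * 1e-2 / 1540 * 40e6, tolerance = 2e-3)
  }
  expect_error(synthesize_planar_reflector(acq, 0.5), "1-6")
  expect_error(synthesize_planar_reflector(acq, 7), "1-6")
  bank <- planar_reflector_bank(acq)
  expect_named(bank, as.character(1:6))
})

test_that("the gated reflector spectrum reproduces the pulse spectrum", {
  acq <- acq_params(n_lines = 4, n_samples = 3600, depth_origin = 0)
  spec <- reflector_spectrum_bank(planar_reflector_bank(acq, 2),
                                  seq(3, 8, by = 0.05))[[1]]
  want_db <- 20 * log10(pulse_amplitude(pulse_spec(),
                                        spec$frequencies * 1e6))
  resid <- (spec$power_db - want_db) - mean(spec$power_db - want_db)
  expect_lt(max(abs(resid)), 1.5)
})

test_that("the analytic BSC obeys Rayleigh, linearity and log-linearity", {
  f <- seq(3, 8, by = 0.1)
  tiny <- medium_spec(scatterer_radius_um = 1e-3, number_density = 10)
  b <- analytic_bsc(tiny, f)
  expect_equal(b$bsc / f^4, rep(b$bsc[1] / f[1]^4, length(f)))
  m1 <- medium_spec(scatterer_radius_um = 25, number_density = 10)
  m2 <- medium_spec(scatterer_radius_um = 25, number_density = 20)
  expect_equal(analytic_bsc(m2, f)$bsc, 2 * analytic_bsc(m1, f)$bsc)
  y <- log(analytic_bsc(m1, f)$bsc / f^4)
  fit <- stats::lm(y ~ I(f^2))
  kf <- 2 * pi * 1e6 / 1540
  expect_equal(unname(coef(fit)[2]), -0.827 * kf^2 * (25e-6)^2,
               tolerance = 1e-10)
  expect_lt(max(abs(residuals(fit))), 1e-12)
})
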