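test_that("Burg recursion matches the reference implementation", {
  set.seed(51)
  for (i in 1:100) {
    n <- sample(80:400, 1)
    p <- sample(2:20, 1)
    x <- as.numeric(stats::arima.sim(list(ar = 0.6), n)) + rnorm(n, 0, 0.3)
    mine <- burg_ar(x, p)
    ref <- stats::ar.burg(x, aic = FALSE, order.max = p, demean = FALSE)
    expect_lt(max(abs(mine$ar - ref$ar)), 1e-10)
    expect_equal(mine$noise_variance, ref$var.pred, tolerance = 1e-10)
    expect_true(all(abs(mine$reflection) < 1))
  }
})

test_that("an AR(2) spectrum matches its closed form within 1 dB", {
  set.seed(52)
  phi <- c(0.6, -0.5)
  x <- as.numeric(stats::arima.sim(list(ar = phi), 4096))
  m <- burg_ar(x, 2)
  f <- seq(1, 18, by = 0.1)
  got <- ar_power_spectrum(m, f, 40e6)$power_db
  omega <- 2 * pi * f * 1e6 / 40e6
  denom <- Mod(1 - phi[1] * exp(-1i * omega) - phi[2] * exp(-2i * omega))^2
  want <- 10 * log10(1 / denom)
  resid <- (got - want) - mean(got - want)
  expect_lt(max(abs(resid)), 1)
})

test_that("two tones appear as AR spectral peaks; white noise stays flat", {
  t <- (0:511) / 40e6
  x <- sin(2 * pi * 4e6 * t) + sin(2 * pi * 7e6 * t) + rnorm(512, 0, 0.05)
  f <- seq(2, 9, by = 0.01)
  db <- ar_power_spectrum(burg_ar(x, 50), f, 40e6)$power_db
  pk <- which(diff(sign(diff(db))) == -2) + 1
  top2 <- sort(f[pk[order(db[pk], decreasing = TRUE)][1:2]])
  expect_equal(top2, c(4, 7), tolerance = 0.05)
  set.seed(53)
  w <- rnorm(2048)
  dbw <- ar_power_spectrum(burg_ar(w, 10), seq(2, 18, by = 0.1), 40e6)$power_db
  expect_lt(diff(range(dbw)), 6)
  expect_error(burg_ar(rnorm(40), 20), "too short")
})

test_that("planar normalization picks the nearest depth, shallow on ties", {
  f <- seq(3, 8, by = 0.1)
  bank <- stats::setNames(lapply(1:6, function(d) {
    as_qus_spectrum(f, rep(d, length(f)), d)
  }), as.character(1:6))
  spec <- as_qus_spectrum(f, rep(0, length(f)), 2.4)
  expect_equal(planar_normalize(spec, 2.4, bank)$power_db,
               rep(-2, length(f)))
  expect_equal(planar_normalize(spec, 2.5, bank)$power_db,
               rep(-2, length(f)))   # tie 2 vs 3 cm -> shallow
  expect_equal(planar_normalize(bank[["4"]], 4, bank)$power_db,
               rep(0, length(f)))
  expect_error(planar_normalize(spec, 2, list()), "empty")
})

test_that("an exactly periodic spectrum maps to SAS = c / (2 df)", {
  f <- seq(3, 8, by = 0.01)
  spec <- as_qus_spectrum(f, 10 * log10(2 + cos(2 * pi * f / 0.77)), 2)
  expect_equal(estimate_sas(spec, sound_speed = 1540), 1.0,
               tolerance = 0.02)
  # halving the spacing doubles the spectral period and vice versa
  half <- as_qus_spectrum(f, 10 * log10(2 + cos(2 * pi * f / 1.54)), 2)
  dbl <- as_qus_spectrum(f, 10 * log10(2 + cos(2 * pi * f / 0.385)), 2)
  expect_equal(estimate_sas(half, sound_speed = 1540), 0.5,
               tolerance = 0.02)
  expect_equal(estimate_sas(dbl, sound_speed = 1540), 2.0,
               tolerance = 0.05)
  # no periodicity -> no peak -> missing, not zero
  smooth <- as_qus_spectrum(f, -0.5 * f, 2)
  expect_true(is.na(estimate_sas(smooth, sound_speed = 1540)))
})

test_that("block SAS is invariant to overall RF gain", {
  acq <- tiny_acq(n_lines = 16, n_samples = 900)
  med <- medium_spec(attenuation = 0.3, number_density = 100,
                     regular_spacing_mm = 1, regular_fraction = 6)
  frame <- simulate_sample_frame(med, acq, seed = 55)
  racq <- acq_params(n_lines = 4, n_samples = 3600, depth_origin = 0)
  refl <- reflector_spectrum_bank(planar_reflector_bank(racq),
                                  seq(3, 8, by = 0.02))
  roi <- roi_from_rect(frame, c(3, 14), c(6, 12))
  blocks <- partition_roi(frame, roi)
  b <- blocks[[25]]
  s1 <- block_sas(b, refl)
  b2 <- b; b2$data <- b2$data * 37
  s2 <- block_sas(b2, refl)
  expect_equal(s1, s2, tolerance = 1e-9)
})
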