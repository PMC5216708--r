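#' Scattering medium specification
#'
#' Ground-truth description of a simulated scattering medium: frequency-
#' dependent attenuation, sound speed, effective scatterer radius, number
#' density and relative echogenicity, with an optional regularly spaced
#' (coherent) scatterer component for spacing-among-scatterers studies.
#'
#' @param attenuation one-way amplitude attenuation in dB/cm-MHz.
#' @param sound_speed m/s.
#' @param scatterer_radius_um effective scatterer radius in micrometers.
#' @param number_density scatterers per mm^3 (realized in a 1 mm-thick
#'   simulated slice, so also per mm^2 of the imaged plane).
#' @param echogenicity_variance relative impedance-contrast variance; the
#'   diffuse scatterer amplitudes are N(0, sqrt(echogenicity_variance)).
#' @param regular_spacing_mm axial spacing of the coherent component in mm,
#'   or `NULL` for a purely diffuse medium.
#' @param regular_fraction amplitude of the coherent component relative to
#'   the diffuse amplitude scale.
#' @return An object of class `medium_spec`.
#' @export
medium_spec <- function(attenuation = 0.5, sound_speed = 1540,
                        scatterer_radius_um = 25, number_density = 100,
                        echogenicity_variance = 1,
                        regular_spacing_mm = NULL, regular_fraction = 0) {
  if (attenuation < 0) stop("attenuation must be >= 0")
  if (number_density <= 0) stop("number_density must be > 0")
  structure(
    list(attenuation = attenuation, sound_speed = sound_speed,
         scatterer_radius_um = scatterer_radius_um,
         number_density = number_density,
         echogenicity_variance = echogenicity_variance,
         regular_spacing_mm = regular_spacing_mm,
         regular_fraction = regular_fraction),
    class = "medium_spec")
}

#' Reference phantom medium
#'
#' The tissue-mimicking reference: attenuation 0.15 dB/cm-MHz, sound speed
#' 1515 m/s, glass microspheres of 18 um diameter (9 um effective radius)
#' in agar. Its known attenuation and backscatter make it the normalization
#' standard for the reference phantom method.
#'
#' @param number_density scatterers per mm^3 for the simulated realization.
#'   The default follows the phantom recipe: 2.2 g/L of 18 um glass spheres
#'   (2.5 g/cm^3) is about 2.9e8 spheres per liter, i.e. ~290 per mm^3.
#' @return a `medium_spec`.
#' @export
reference_medium <- function(number_density = 290) {
  medium_spec(attenuation = 0.15, sound_speed = 1515,
              scatterer_radius_um = 9, number_density = number_density,
              echogenicity_variance = 1)
}

#' Transmit pulse specification
#'
#' Gaussian-modulated pulse defined by its center frequency and -6 dB
#' fractional bandwidth. The default (6 MHz, fractional bandwidth 1.0)
#' gives a -6 dB band of 3-9 MHz, covering the 3-8 MHz analysis band.
#'
#' @param center_frequency Hz.
#' @param fractional_bandwidth -6 dB bandwidth as a fraction of
#'   `center_frequency`.
#' @return An object of class `pulse_spec`.
#' @export
pulse_spec <- function(center_frequency = 6e6, fractional_bandwidth = 1.0) {
  structure(list(center_frequency = center_frequency,
                 fractional_bandwidth = fractional_bandwidth),
            class = "pulse_spec")
}

# amplitude spectrum of the pulse at frequencies f (Hz); Gaussian power
# spectrum with -6 dB full width = fractional_bandwidth * f0
pulse_amplitude <- function(pulse, f) {
  f0 <- pulse$center_frequency
  half_bw <- pulse$fractional_bandwidth * f0 / 2
  sigma_p <- half_bw / sqrt(2 * log(10^0.6))   # power-spectrum SD
  exp(-(abs(f) - f0)^2 / (4 * sigma_p^2))
}

#' Acquisition parameters for the simulator
#'
#' @param n_lines number of scan lines.
#' @param n_samples axial samples per line.
#' @param sampling_rate Hz.
#' @param line_pitch m.
#' @param depth_origin m, depth of the first sample.
#' @return a plain list used by the `synthesize_*` functions.
#' @export
acq_params <- function(n_lines = 48, n_samples = 1300,
                       sampling_rate = 40e6, line_pitch = 0.3e-3,
                       depth_origin = 2e-3) {
  list(n_lines = n_lines, n_samples = n_samples,
       sampling_rate = sampling_rate, line_pitch = line_pitch,
       depth_origin = depth_origin)
}

#' Imaged region implied by an acquisition geometry
#'
#' @param acq acquisition parameters from [acq_params()].
#' @param sound_speed m/s (depth mapping depends on it).
#' @return list with `depth_m` (min, max) and `width_m`, the volume a
#'   scatterer field must populate to fill the acquired frame.
#' @export
acq_volume <- function(acq, sound_speed) {
  z1 <- acq$depth_origin +
    (acq$n_samples - 1) * sound_speed / (2 * acq$sampling_rate)
  list(depth_m = c(acq$depth_origin, z1),
       width_m = acq$n_lines * acq$line_pitch)
}

#' Realize a scatterer field from a medium specification
#'
#' Diffuse scatterers are placed uniformly in the imaged plane with count
#' Poisson(density x area); amplitudes are zero-mean Gaussian. If the
#' medium has a regular axial spacing, coherent scatterer layers are
#' superposed: axial planes at the given spacing (position jitter SD = 5%
#' of the spacing), laterally sampled every 0.25 mm, at constant positive
#' amplitude `regular_fraction * sqrt(echogenicity_variance)`.
#'
#' @param medium a `medium_spec`.
#' @param volume list with `depth_m` (min, max) and `width_m`, e.g. from an
#'   acquisition geometry.
#' @param seed integer; the field is reproducible from (medium, volume, seed).
#' @param slice_mm elevational slice thickness collapsed into the imaged
#'   plane (default 2 mm, a typical linear-array elevational beam width);
#'   the realized areal density is `number_density * slice_mm` per mm^2.
#' @return An object of class `scatterer_field`: data frame of axial `z` and
#'   lateral `x` positions (m) and per-scatterer `amp`.
#' @export
sample_field <- function(medium, volume, seed = 1, slice_mm = 2) {
  stopifnot(inherits(medium, "medium_spec"))
  depth_mm <- 1e3 * diff(volume$depth_m)
  width_mm <- 1e3 * volume$width_m
  area_mm2 <- depth_mm * width_mm * slice_mm
  if (medium$number_density * area_mm2 < 1) {
    stop("volume too small: expected scatterer count below 1")
  }
  set.seed(seed)
  n <- stats::rpois(1, medium$number_density * area_mm2)
  gamma_sd <- sqrt(medium$echogenicity_variance)
  z <- stats::runif(n, volume$depth_m[1], volume$depth_m[2])
  x <- stats::runif(n, 0, volume$width_m)
  amp <- stats::rnorm(n, 0, gamma_sd)
  n_lattice <- 0L
  if (!is.null(medium$regular_spacing_mm)) {
    d <- medium$regular_spacing_mm * 1e-3
    z_layers <- seq(volume$depth_m[1] + d / 2, volume$depth_m[2], by = d)
    x_cols <- seq(0.125e-3, volume$width_m, by = 0.25e-3)
    grid <- expand.grid(zl = z_layers, xc = x_cols)
    zj <- grid$zl + stats::rnorm(nrow(grid), 0, 0.05 * d)
    n_lattice <- nrow(grid)
    z <- c(z, zj)
    x <- c(x, grid$xc)
    amp <- c(amp, rep(medium$regular_fraction * gamma_sd, n_lattice))
  }
  structure(list(z = z, x = x, amp = amp,
                 n_diffuse = n, n_lattice = n_lattice,
                 seed = seed, volume = volume),
            class = "scatterer_field")
}

# depth-dependent attenuation applied by short-time Fourier segments:
# Hann windows (hop = half window) are COLA, so with a per-segment
# frequency-domain gain 10^(-2 alpha f z_seg / 20) the overlap-add
# reconstructs the line with the round-trip attenuation of each depth.
apply_attenuation <- function(line, alpha, fs, sound_speed, depth_origin,
                              seg_mm = 2) {
  if (alpha <= 0) return(line)
  n <- length(line)
  L <- 2 * max(16L, round(seg_mm * 1e-3 * 2 * fs / sound_speed / 2))
  hop <- L / 2
  win <- 0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / L)  # periodic Hann, COLA
  Lf <- 2 * L
  f_mhz <- abs(((0:(Lf - 1) + Lf / 2) %% Lf) - Lf / 2) * fs / Lf / 1e6
  pad <- L
  xp <- c(numeric(pad), line, numeric(pad + L))
  out <- numeric(length(xp))
  starts <- seq(1, length(xp) - L + 1, by = hop)
  for (s0 in starts) {
    idx <- s0:(s0 + L - 1)
    seg <- xp[idx] * win
    if (all(seg == 0)) next
    ctr_sample <- s0 + L / 2 - pad           # center in original indexing
    z_cm <- 1e2 * (depth_origin +
                     (ctr_sample - 1) * sound_speed / (2 * fs))
    z_cm <- max(z_cm, 0)
    H <- 10^(-2 * alpha * f_mhz * z_cm / 20)
    seg_f <- stats::fft(c(seg, numeric(Lf - L))) * H
    out[s0:(s0 + Lf - 1)] <- out[s0:(s0 + Lf - 1)] +
      Re(stats::fft(seg_f, inverse = TRUE)) / Lf
  }
  out[(pad + 1):(pad + n)]
}

#' Synthesize an RF frame from a scatterer field
#'
#' Each scan line collects the scatterers nearest to it laterally (binned
#' by line pitch). Echoes are placed at round-trip delay 2z/c with linear
#' fractional-sample interpolation, attenuated segment-wise by the exact
#' round-trip law `10^(-2 alpha f z / 20)` (alpha in dB/cm-MHz, z in cm, f
#' in MHz), then filtered by the pulse amplitude spectrum times the square
#' root of the Gaussian form factor `exp(-0.827 k^2 a^2)` so the simulated
#' backscatter follows the Gaussian form-factor model. White electronic
#' noise is added at `snr_db` below the echo RMS.
#'
#' @param field a `scatterer_field`.
#' @param pulse a `pulse_spec`.
#' @param acq acquisition parameters from [acq_params()].
#' @param medium the `medium_spec` the field was drawn from.
#' @param snr_db electronic signal-to-noise ratio in dB.
#' @param noise_seed integer seed for the noise realization.
#' @return an `rf_frame`.
#' @export
synthesize_rf <- function(field, pulse, acq, medium, snr_db = 40,
                          noise_seed = 1) {
  fs <- acq$sampling_rate
  c0 <- medium$sound_speed
  if (pulse$center_frequency * (1 + pulse$fractional_bandwidth) > fs / 2) {
    stop("pulse band exceeds Nyquist frequency")
  }
  n <- acq$n_samples
  nl <- acq$n_lines
  line_bin <- pmin(pmax(round(field$x / acq$line_pitch) + 1L, 1L), nl)

  nfft <- 2^ceiling(log2(2 * n))
  f_hz <- abs(((0:(nfft - 1) + nfft / 2) %% nfft) - nfft / 2) * fs / nfft
  a_m <- medium$scatterer_radius_um * 1e-6
  k <- 2 * pi * f_hz / c0
  G <- pulse_amplitude(pulse, f_hz) * sqrt(exp(-0.827 * k^2 * a_m^2))

  samples <- matrix(0, nl, n)
  for (l in seq_len(nl)) {
    sel <- line_bin == l
    if (!any(sel)) next
    u <- (field$z[sel] - acq$depth_origin) * 2 * fs / c0  # 0-based sample
    amp <- field$amp[sel]
    keep <- u >= 0 & u <= n - 2
    if (!any(keep)) next
    u <- u[keep]; amp <- amp[keep]
    i0 <- floor(u)
    frac <- u - i0
    idx_all <- c(i0 + 1L, i0 + 2L)
    w_all <- c(amp * (1 - frac), amp * frac)
    acc <- rowsum(w_all, idx_all)
    imp <- numeric(n)
    imp[as.integer(rownames(acc))] <- acc[, 1]
    imp <- apply_attenuation(imp, medium$attenuation, fs, c0,
                             acq$depth_origin)
    spec <- stats::fft(c(imp, numeric(nfft - n))) * G
    samples[l, ] <- Re(stats::fft(spec, inverse = TRUE) / nfft)[1:n]
  }
  sig_rms <- sqrt(mean(samples^2))
  if (sig_rms == 0) sig_rms <- 1
  set.seed(noise_seed)
  samples <- samples + matrix(stats::rnorm(nl * n, 0,
                                           sig_rms * 10^(-snr_db / 20)),
                              nl, n)
  rf_frame(samples, sampling_rate = fs,
           center_frequency = pulse$center_frequency,
           line_pitch = acq$line_pitch, sound_speed = c0,
           depth_origin = acq$depth_origin)
}

#' Simulate the reference phantom frame
#'
#' Fixed-parameter wrapper around [synthesize_rf()] with the reference
#' medium (0.15 dB/cm-MHz, 1515 m/s, 9 um effective radius).
#'
#' @param acq acquisition parameters.
#' @param seed integer seed (field and noise).
#' @param pulse a `pulse_spec`.
#' @return an `rf_frame`.
#' @export
synthesize_reference <- function(acq, seed = 1, pulse = pulse_spec()) {
  medium <- reference_medium()
  field <- sample_field(medium, acq_volume(acq, medium$sound_speed),
                        seed = seed)
  synthesize_rf(field, pulse, acq, medium, noise_seed = seed + 1L)
}

#' Simulate a planar-reflector frame
#'
#' A single specular echo (pulse replica) at the given depth on every scan
#' line, as acquired from a Plexiglas-water interface; negligible
#' backscatter elsewhere. Used to normalize AR spectra for spacing
#' estimation; a bank at depths 1-6 cm covers the imaging range.
#'
#' @param acq acquisition parameters.
#' @param depth_cm reflector depth in cm, within 1-6.
#' @param pulse a `pulse_spec`.
#' @param sound_speed m/s of the water path (default 1540 to match the
#'   sample depth mapping).
#' @return an `rf_frame`.
#' @export
synthesize_planar_reflector <- function(acq, depth_cm, pulse = pulse_spec(),
                                        sound_speed = 1540) {
  if (depth_cm < 1 || depth_cm > 6) {
    stop("reflector depth must lie within 1-6 cm")
  }
  fs <- acq$sampling_rate
  n <- acq$n_samples
  u <- (depth_cm * 1e-2 - acq$depth_origin) * 2 * fs / sound_speed
  if (u < 0 || u > n - 2) stop("reflector depth outside the acquired window")
  imp <- numeric(n)
  i0 <- floor(u); frac <- u - i0
  imp[i0 + 1L] <- 1 - frac
  imp[i0 + 2L] <- frac
  nfft <- 2^ceiling(log2(2 * n))
  f_hz <- abs(((0:(nfft - 1) + nfft / 2) %% nfft) - nfft / 2) * fs / nfft
  spec <- stats::fft(c(imp, numeric(nfft - n))) * pulse_amplitude(pulse, f_hz)
  line <- Re(stats::fft(spec, inverse = TRUE) / nfft)[1:n]
  samples <- matrix(rep(line, each = acq$n_lines), acq$n_lines, n)
  rf_frame(samples, sampling_rate = fs,
           center_frequency = pulse$center_frequency,
           line_pitch = acq$line_pitch, sound_speed = sound_speed,
           depth_origin = acq$depth_origin)
}

#' Bank of planar-reflector frames at 1-6 cm
#' @param acq acquisition parameters (its depth window must reach the
#'   requested depths).
#' @param depths_cm reflector depths, default 1:6.
#' @inheritParams synthesize_planar_reflector
#' @return named list of `rf_frame`s, names `"1"`, `"2"`, ...
#' @export
planar_reflector_bank <- function(acq, depths_cm = 1:6,
                                  pulse = pulse_spec(), sound_speed = 1540) {
  stats::setNames(
    lapply(depths_cm, function(d)
      synthesize_planar_reflector(acq, d, pulse, sound_speed)),
    as.character(depths_cm))
}

# fixed scale constant of the analytic backscatter model; only relative
# levels matter after reference-phantom normalization
.bsc_constant <- 1e-6

#' Analytic backscatter coefficient of a medium
#'
#' Gaussian form-factor backscatter model
#' `BSC(f) = C n gamma^2 f^4 exp(-0.827 k^2 a^2)`, `k = 2 pi f / c`, with
#' `a` the effective scatterer radius, `n` the number density, `gamma^2`
#' the echogenicity variance and `C` a fixed scale constant. In the
#' Rayleigh limit (a -> 0) this reduces to `f^4` scattering.
#'
#' @param medium a `medium_spec`.
#' @param freqs_mhz frequency grid in MHz.
#' @return An object of class `bsc_curve` with fields `frequencies` (MHz),
#'   `bsc` (linear, 1/(cm sr)) and `provenance = "analytic"`.
#' @export
analytic_bsc <- function(medium, freqs_mhz) {
  a_m <- medium$scatterer_radius_um * 1e-6
  k <- 2 * pi * freqs_mhz * 1e6 / medium$sound_speed
  bsc <- .bsc_constant * medium$number_density *
    medium$echogenicity_variance * freqs_mhz^4 * exp(-0.827 * k^2 * a_m^2)
  structure(list(frequencies = freqs_mhz, bsc = bsc,
                 provenance = "analytic"),
            class = "bsc_curve")
}

#' Envelope of an RF frame
#'
#' Magnitude of the per-line analytic signal (FFT-based Hilbert transform).
#' Used for speckle statistics; fully developed speckle has envelope
#' mean/SD near the Rayleigh value 1.91.
#'
#' @param frame an `rf_frame`.
#' @return matrix of envelope values, same shape as `frame$samples`.
#' @export
rf_envelope <- function(frame) {
  env <- frame$samples
  n <- ncol(env)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  for (l in seq_len(nrow(env))) {
    env[l, ] <- Mod(stats::fft(stats::fft(frame$samples[l, ]) * h,
                               inverse = TRUE) / n)
  }
  env
}
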