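#' Burg autoregressive model of a gated RF segment
#'
#' Burg's recursion estimates AR coefficients by minimizing the summed
#' forward and backward prediction error at each order; the reflection
#' coefficients are bounded in (-1, 1), so the model is always stable.
#' Used here because AR spectra of short gates show more conspicuous
#' periodicity peaks than FFT periodograms and are free of gate-ringing
#' artifacts; the working order for breast RF blocks is 50.
#'
#' @param x numeric vector, the gated RF segment.
#' @param order AR model order p; must satisfy `2 * order < length(x)`.
#' @return An object of class `ar_model`: `ar` (the coefficients phi of
#'   `x_t = sum phi_i x_(t-i) + e_t`), `reflection` (k_1..k_p),
#'   `noise_variance`, `order`.
#' @export
burg_ar <- function(x, order = 50) {
  n <- length(x)
  if (2 * order >= n) stop("segment too short: need length > 2 * order")
  f <- x
  b <- x
  a <- 1                      # error-filter polynomial A(z)
  refl <- numeric(order)
  e <- sum(x^2) / n
  for (m in seq_len(order)) {
    f <- f[-1]
    b <- b[-length(b)]
    denom <- sum(f^2) + sum(b^2)
    k <- if (denom > 0) -2 * sum(f * b) / denom else 0
    refl[m] <- k
    f_new <- f + k * b
    b_new <- b + k * f
    f <- f_new
    b <- b_new
    a <- c(a, 0) + k * rev(c(a, 0))
    e <- e * (1 - k^2)
  }
  structure(list(ar = -a[-1], reflection = refl,
                 noise_variance = e, order = order),
            class = "ar_model")
}

#' Power spectrum of an AR model
#'
#' `S(f) = sigma^2 / |1 - sum phi_j exp(-i 2 pi f j / fs)|^2`, evaluated on
#' an arbitrary frequency grid (the AR spectrum is a continuous function of
#' frequency, so the grid can be made as dense as the peak search needs).
#'
#' @param model an `ar_model`.
#' @param freqs_mhz evaluation grid in MHz.
#' @param sampling_rate Hz.
#' @param center_depth_cm optional depth context carried into the result.
#' @return a `qus_spectrum` (power in dB).
#' @export
ar_power_spectrum <- function(model, freqs_mhz, sampling_rate = 40e6,
                              center_depth_cm = NA) {
  omega <- 2 * pi * freqs_mhz * 1e6 / sampling_rate
  j <- seq_len(model$order)
  E <- exp(-1i * outer(omega, j))        # grid x order
  denom <- Mod(1 - as.vector(E %*% model$ar))^2
  as_qus_spectrum(freqs_mhz,
                  10 * log10(model$noise_variance / pmax(denom, 1e-300)),
                  center_depth_cm)
}

#' Planar-reflector normalization of a block spectrum
#'
#' Subtracts (in dB) the planar-reflector spectrum whose acquisition depth
#' is nearest to the block depth, from a pre-recorded bank at 1-6 cm; a
#' tie between two depths is broken toward the shallower one. This removes
#' the system transfer function before the spectral-autocorrelation
#' spacing analysis.
#'
#' @param spec a `qus_spectrum` (e.g. an AR spectrum of a block).
#' @param block_depth_cm depth of the block center, cm.
#' @param reflector_bank named list of reflector spectra; names are depths
#'   in cm (as produced by [reflector_spectrum_bank()]).
#' @return the normalized `qus_spectrum` (dBr).
#' @export
planar_normalize <- function(spec, block_depth_cm, reflector_bank) {
  if (length(reflector_bank) == 0) stop("empty planar-reflector bank")
  depths <- as.numeric(names(reflector_bank))
  dist <- abs(depths - block_depth_cm)
  # stable ordering: among equal distances pick the shallower depth
  pick <- order(dist, depths)[1]
  ref <- reflector_bank[[pick]]
  normalize_spectrum(spec, ref)
}

#' Reflector spectra on a chosen frequency grid
#'
#' Gates the specular echo of each planar-reflector frame, computes its
#' averaged periodogram and interpolates it (in dB) onto the analysis
#' grid, yielding the normalization bank used by [planar_normalize()].
#'
#' @param bank named list of reflector `rf_frame`s from
#'   [planar_reflector_bank()].
#' @param freqs_mhz target frequency grid in MHz.
#' @param gate_mm gate length centered on the echo, mm.
#' @return named list of `qus_spectrum`s keyed by depth in cm.
#' @export
reflector_spectrum_bank <- function(bank, freqs_mhz, gate_mm = 4) {
  lapply(bank, function(frame) {
    env <- abs(frame$samples[1, ])
    peak <- which.max(env)
    half <- max(8L, round(gate_mm / rf_mm_per_sample(frame) / 2))
    idx <- max(1, peak - half):min(ncol(frame$samples), peak + half)
    blk <- list(data = frame$samples[, idx, drop = FALSE],
                center_depth_cm = 1e2 * rf_depth_axis(frame)[peak])
    ps <- block_power_spectrum(blk, frame$sampling_rate)
    db <- stats::approx(ps$frequencies, ps$power_db, xout = freqs_mhz,
                        rule = 2)$y
    as_qus_spectrum(freqs_mhz, db, blk$center_depth_cm)
  })
}

#' Spacing among scatterers from a normalized power spectrum
#'
#' Coherent, quasi-regularly spaced scatterers at axial spacing d imprint
#' a periodicity of `c / (2 d)` on the backscatter power spectrum. The
#' estimator mean-subtracts the linear-power spectrum, computes its
#' autocorrelation over frequency lag, locates the dominant peak within
#' the search window (default 0.2-2.5 MHz, excluding the trivial lag-0
#' self-peak by two grid cells), refines it by parabolic interpolation,
#' and converts the peak lag to spacing: `SAS = c / (2 df)` in mm.
#'
#' @param norm_spec normalized `qus_spectrum` covering the analysis band.
#' @param sound_speed m/s.
#' @param search search window for the peak lag, MHz.
#' @param band band over which the autocorrelation is formed, MHz.
#' @return SAS in mm, or `NA_real_` when no local maximum lies in the
#'   window (reported missing, never zero).
#' @export
estimate_sas <- function(norm_spec, sound_speed = 1540,
                         search = c(0.2, 2.5), band = c(3, 8)) {
  sac <- spectral_autocorrelation(norm_spec, band)
  sas_from_sac(sac, sound_speed, search)
}

# autocorrelation of the mean-subtracted linear-power spectrum;
# normalized to 1 at lag 0, symmetric by construction
spectral_autocorrelation <- function(norm_spec, band = c(3, 8)) {
  sel <- norm_spec$frequencies >= band[1] & norm_spec$frequencies <= band[2]
  if (sum(sel) < 8) stop("normalized spectrum must cover the analysis band")
  p <- 10^(norm_spec$power_db[sel] / 10)
  p <- p - mean(p)
  nlag <- length(p) - 1
  ac <- vapply(0:nlag, function(l) {
    sum(p[1:(length(p) - l)] * p[(1 + l):length(p)])
  }, numeric(1))
  df <- diff(norm_spec$frequencies[sel][1:2])
  list(lags_mhz = (0:nlag) * df,
       ac = if (ac[1] > 0) ac / ac[1] else ac,
       df_mhz = df)
}

# first dominant autocorrelation peak -> spacing in mm. Harmonics of the
# spectral comb produce secondary peaks at multiples of the fundamental
# lag, so the first local maximum reaching at least half the height of the
# tallest in-window peak is taken as the fundamental.
sas_from_sac <- function(sac, sound_speed, search = c(0.2, 2.5),
                         dominance = 0.5) {
  lags <- sac$lags_mhz
  ac <- sac$ac
  lo <- max(search[1], 2 * sac$df_mhz)
  cand <- which(lags >= lo & lags <= search[2])
  cand <- cand[cand > 1 & cand < length(ac)]
  is_peak <- cand[ac[cand] > ac[cand - 1] & ac[cand] >= ac[cand + 1]]
  is_peak <- is_peak[ac[is_peak] > 0]
  if (length(is_peak) == 0) return(NA_real_)
  i <- is_peak[ac[is_peak] >= dominance * max(ac[is_peak])][1]
  # parabolic refinement around the peak
  denom <- ac[i - 1] - 2 * ac[i] + ac[i + 1]
  delta <- if (denom < 0) 0.5 * (ac[i - 1] - ac[i + 1]) / denom else 0
  df_star <- lags[i] + delta * sac$df_mhz
  sound_speed / (2 * df_star * 1e6) * 1e3
}

#' SAS of one analysis block
#'
#' Full SAS chain for an `rf_block`: Burg AR model of each scan line's
#' full axial gate, AR power spectrum on a dense grid over the band,
#' planar-reflector normalization at the nearest bank depth, per-line
#' spectral autocorrelation averaged across lines, then peak search.
#'
#' @param block an `rf_block`.
#' @param reflector_bank reflector spectra from [reflector_spectrum_bank()]
#'   (must be on the grid implied by `band` and `grid_step_mhz`).
#' @param sampling_rate Hz.
#' @param sound_speed m/s.
#' @param order AR order (default 50).
#' @param band analysis band, MHz.
#' @param search peak search window, MHz.
#' @param grid_step_mhz AR spectrum evaluation step.
#' @return SAS in mm or `NA_real_`.
#' @export
block_sas <- function(block, reflector_bank, sampling_rate = 40e6,
                      sound_speed = 1540, order = 50, band = c(3, 8),
                      search = c(0.2, 2.5), grid_step_mhz = 0.02) {
  freqs <- seq(band[1], band[2], by = grid_step_mhz)
  acc <- NULL
  nl <- 0
  for (l in seq_len(nrow(block$data))) {
    x <- block$data[l, ]
    if (2 * order >= length(x)) next
    m <- burg_ar(x, order)
    sp <- ar_power_spectrum(m, freqs, sampling_rate, block$center_depth_cm)
    ns <- planar_normalize(sp, block$center_depth_cm, reflector_bank)
    sac <- spectral_autocorrelation(ns, band)
    if (is.null(acc)) acc <- sac$ac * 0
    acc <- acc + sac$ac
    nl <- nl + 1
    df <- sac$df_mhz
    lags <- sac$lags_mhz
  }
  if (nl == 0) return(NA_real_)
  sas_from_sac(list(lags_mhz = lags, ac = acc / nl, df_mhz = df),
               sound_speed, search)
}
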