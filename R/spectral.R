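#' Power spectrum of an analysis block
#'
#' Per-line Hann-windowed periodograms, zero-padded to the next power of
#' two at least four times the block length (frequency resolution finer
#' than 0.1 MHz at 40 MHz sampling), averaged across the block's scan
#' lines and expressed in dB (10 log10 of mean periodogram).
#'
#' @param block an `rf_block` from [partition_roi()], or any list with a
#'   `data` matrix (lines x samples) and `center_depth_cm`.
#' @param sampling_rate Hz.
#' @param window window name; only `"hann"` is implemented.
#' @return An object of class `qus_spectrum`: `frequencies` (MHz, one-sided
#'   grid), `power_db`, `center_depth_cm`, and `center_line` if present.
#' @export
block_power_spectrum <- function(block, sampling_rate = 40e6,
                                 window = "hann") {
  x <- block$data
  if (is.null(dim(x)) || nrow(x) < 2) stop("block needs at least 2 scan lines")
  n <- ncol(x)
  win <- switch(window,
                hann = 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1)),
                stop("unknown window: ", window))
  nfft <- 2^ceiling(log2(4 * n))
  xw <- sweep(x, 2, win, `*`)
  # periodogram normalization: |X|^2 / (fs * sum(win^2)) per line
  p <- matrix(0, nrow(x), nfft)
  for (l in seq_len(nrow(x))) {
    p[l, ] <- Mod(stats::fft(c(xw[l, ], numeric(nfft - n))))^2
  }
  pmean <- colMeans(p) / (sampling_rate * sum(win^2))
  half <- 1:(nfft / 2 + 1)
  structure(
    list(frequencies = (half - 1) * sampling_rate / nfft / 1e6,
         power_db = 10 * log10(pmax(pmean[half], .Machine$double.xmin)),
         center_depth_cm = block$center_depth_cm,
         center_line = block$center_line),
    class = "qus_spectrum")
}

# make a qus_spectrum from raw pieces (used by simulators and tests)
as_qus_spectrum <- function(frequencies, power_db, center_depth_cm = NA,
                            center_line = NA) {
  structure(list(frequencies = frequencies, power_db = power_db,
                 center_depth_cm = center_depth_cm,
                 center_line = center_line),
            class = "qus_spectrum")
}

#' Average spectra in the linear power domain
#'
#' @param specs list of `qus_spectrum` objects on a common grid.
#' @return a `qus_spectrum` whose linear power is the mean of the inputs
#'   (depth context averaged).
#' @export
average_spectra <- function(specs) {
  stopifnot(length(specs) > 0)
  f <- specs[[1]]$frequencies
  lin <- sapply(specs, function(s) {
    if (!isTRUE(all.equal(s$frequencies, f))) {
      stop("spectra are on different frequency grids")
    }
    10^(s$power_db / 10)
  })
  as_qus_spectrum(f, 10 * log10(rowMeans(as.matrix(lin))),
                  mean(sapply(specs, `[[`, "center_depth_cm")))
}

#' Normalize a sample spectrum by a reference spectrum
#'
#' Reference-phantom normalization: subtraction in the dB domain cancels
#' the system transfer function (transmit pulse, receive electronics,
#' diffraction) common to sample and reference, leaving relative tissue
#' backscatter in dBr.
#'
#' @param sample,reference `qus_spectrum` objects on the same frequency
#'   grid; the reference should come from the same depth (within half a
#'   block).
#' @return a `qus_spectrum` in dBr, carrying the sample's depth context.
#' @export
normalize_spectrum <- function(sample, reference) {
  if (!isTRUE(all.equal(sample$frequencies, reference$frequencies))) {
    stop("sample and reference frequency grids differ")
  }
  as_qus_spectrum(sample$frequencies,
                  sample$power_db - reference$power_db,
                  sample$center_depth_cm, sample$center_line)
}

#' Depth-binned reference spectra from a phantom frame
#'
#' Partitions the full reference frame with the same block geometry as the
#' sample ROI and averages spectra laterally within each depth row, giving
#' one reference spectrum per depth. Sample blocks are normalized by the
#' reference spectrum nearest in depth.
#'
#' @param ref_frame reference-phantom `rf_frame`, or a list of frames
#'   (independent planes of the same phantom) whose spectra are pooled —
#'   the phantom is static, so averaging planes suppresses its speckle
#'   noise in the normalization.
#' @param block_size_mm,overlap_fraction block geometry (match the sample).
#' @return list with `depths_cm` and `spectra` (one averaged
#'   `qus_spectrum` per depth).
#' @export
build_reference_bank <- function(ref_frame, block_size_mm = 2,
                                 overlap_fraction = 0.8) {
  frames <- if (inherits(ref_frame, "rf_frame")) list(ref_frame) else
    ref_frame
  specs <- list()
  for (fr in frames) {
    full <- roi_from_mask(fr, matrix(TRUE, nrow(fr$samples),
                                     ncol(fr$samples)))
    blocks <- partition_roi(fr, full, block_size_mm, overlap_fraction)
    specs <- c(specs, lapply(blocks, block_power_spectrum,
                             sampling_rate = fr$sampling_rate))
  }
  depths <- round(sapply(specs, `[[`, "center_depth_cm"), 6)
  ud <- sort(unique(depths))
  list(depths_cm = ud,
       spectra = lapply(ud, function(d) average_spectra(specs[depths == d])))
}

# reference spectrum nearest in depth to a sample block
nearest_reference <- function(bank, depth_cm) {
  bank$spectra[[which.min(abs(bank$depths_cm - depth_cm))]]
}

#' Total-attenuation model for point compensation
#'
#' Two-layer attenuation path from the transducer face to the center of an
#' analysis block: intervening tissue (`alpha0`, path `x0_cm`, 1 dB/cm-MHz
#' assumed for breast from ultrasound tomography) and the tumor's own
#' attenuation (`alpha1` = ACE, path `x1_cm` from ROI top to block center).
#' One-way amplitude attenuation is `A(f) = (alpha0 x0 + alpha1 x1) f` dB.
#'
#' @param alpha0,alpha1 dB/cm-MHz, both >= 0.
#' @param x0_cm,x1_cm path lengths in cm, both >= 0.
#' @return An object of class `attenuation_model`.
#' @export
attenuation_model <- function(alpha0 = 1, x0_cm = 0, alpha1 = 0, x1_cm = 0) {
  if (alpha0 < 0 || alpha1 < 0) stop("attenuation coefficients must be >= 0")
  if (x0_cm < 0 || x1_cm < 0) stop("path lengths must be >= 0")
  structure(list(alpha0 = alpha0, x0_cm = x0_cm,
                 alpha1 = alpha1, x1_cm = x1_cm),
            class = "attenuation_model")
}

#' Point attenuation compensation of a block spectrum
#'
#' Adds the round-trip attenuation `2 A(f)` dB back onto the power
#' spectrum, with `A(f)` the one-way amplitude loss of the two-layer model
#' (amplitude dB and power dB coincide numerically, so the round-trip
#' correction on the power spectrum is twice the one-way `A(f)`).
#'
#' @param spec a `qus_spectrum`.
#' @param model an `attenuation_model`; its total path `x0 + x1` must match
#'   the block's center depth to within `depth_tol_cm` when the spectrum
#'   carries one.
#' @param depth_tol_cm tolerance on the path/depth consistency check.
#' @return the corrected `qus_spectrum`.
#' @export
attenuation_correct <- function(spec, model, depth_tol_cm = 0.25) {
  stopifnot(inherits(model, "attenuation_model"))
  total_path <- model$x0_cm + model$x1_cm
  if (is.finite(spec$center_depth_cm) && !is.na(spec$center_depth_cm) &&
      abs(total_path - spec$center_depth_cm) > depth_tol_cm) {
    stop(sprintf(
      "attenuation path x0 + x1 = %.2f cm inconsistent with block depth %.2f cm",
      total_path, spec$center_depth_cm))
  }
  A <- (model$alpha0 * model$x0_cm + model$alpha1 * model$x1_cm) *
    spec$frequencies
  as_qus_spectrum(spec$frequencies, spec$power_db + 2 * A,
                  spec$center_depth_cm, spec$center_line)
}

#' Attenuation coefficient estimate by the reference phantom method
#'
#' Spectral-difference estimation of the tumor attenuation: sample block
#' spectra are normalized by depth-matched reference-phantom spectra,
#' averaged across laterally adjacent blocks, and the rate of change of
#' the normalized spectral magnitude with depth is fitted by least squares
#' at every frequency in the band. Because the normalized round-trip loss
#' changes by `-2 f (ACE - alpha_ref)` dB per cm of depth, the estimate is
#' `ACE = alpha_ref - mean_f s(f) / (2 f)` with `s(f)` the fitted slope in
#' dB/cm: a sample more attenuating than the reference gives ACE above
#' `alpha_ref`.
#'
#' @param sample_specs list of `qus_spectrum` for the ROI blocks (with
#'   depth and lateral context).
#' @param ref_bank reference bank from [build_reference_bank()], or a list
#'   of reference spectra matching `sample_specs` one-to-one.
#' @param band analysis band in MHz (default 3-8).
#' @param alpha_ref known reference attenuation, dB/cm-MHz.
#' @return ACE in dB/cm-MHz.
#' @export
estimate_ace <- function(sample_specs, ref_bank, band = c(3, 8),
                         alpha_ref = 0.15) {
  norm <- lapply(sample_specs, function(s) {
    ref <- if (!is.null(ref_bank$depths_cm)) {
      nearest_reference(ref_bank, s$center_depth_cm)
    } else {
      ref_bank[[which.min(abs(sapply(ref_bank, `[[`, "center_depth_cm") -
                                s$center_depth_cm))]]
    }
    normalize_spectrum(s, ref)
  })
  depths <- round(sapply(norm, `[[`, "center_depth_cm"), 6)
  ud <- sort(unique(depths))
  if (length(ud) < 3) stop("ROI too shallow for ACE (need >= 3 block depths)")
  by_depth <- lapply(ud, function(d) average_spectra(norm[depths == d]))

  f <- by_depth[[1]]$frequencies
  in_band <- f >= band[1] & f <= band[2]
  fb <- f[in_band]
  mag <- sapply(by_depth, function(s) s$power_db[in_band])  # freq x depth
  X <- cbind(1, ud)
  slopes <- stats::lm.fit(X, t(mag))$coefficients[2, ]      # dB per cm
  alpha_ref - mean(slopes / (2 * fb))
}

#' Linear fit of a normalized, attenuation-corrected spectrum
#'
#' Ordinary least squares of dBr power on frequency over the analysis
#' band. SI is the intercept extrapolated to 0 MHz, SS the slope, and MBF
#' the fit magnitude at the band center (5.5 MHz for 3-8 MHz), so
#' `MBF = SI + SS * f_center` identically.
#'
#' @param spec a `qus_spectrum` in dBr.
#' @param band fit band in MHz.
#' @return An object of class `spectral_fit` with `mbf`, `ss`, `si`,
#'   `f_center`, `band`, `r2`.
#' @export
fit_spectral_line <- function(spec, band = c(3, 8)) {
  sel <- spec$frequencies >= band[1] & spec$frequencies <= band[2]
  if (sum(sel) < 2) stop("fewer than 2 spectral points in the fit band")
  f <- spec$frequencies[sel]
  y <- spec$power_db[sel]
  fit <- stats::lm.fit(cbind(1, f), y)
  si <- fit$coefficients[[1]]
  ss <- fit$coefficients[[2]]
  f_center <- mean(band)
  ssr <- sum(fit$residuals^2)
  sst <- sum((y - mean(y))^2)
  structure(list(mbf = si + ss * f_center, ss = ss, si = si,
                 f_center = f_center, band = band,
                 r2 = if (sst > 0) 1 - ssr / sst else NA_real_),
            class = "spectral_fit")
}
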