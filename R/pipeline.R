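# restrict a spectrum to an analysis band
spectrum_band <- function(spec, band) {
  sel <- spec$frequencies >= band[1] & spec$frequencies <= band[2]
  as_qus_spectrum(spec$frequencies[sel], spec$power_db[sel],
                  spec$center_depth_cm, spec$center_line)
}

#' Extract the seven QUS features from one RF frame
#'
#' Runs the full single-frame analysis: block partitioning of the ROI,
#' per-block power spectra, ACE by the reference phantom method, point
#' attenuation compensation of sample and reference spectra, reference
#' normalization, linear spectral fits (MBF/SS/SI maps), backscatter-
#' coefficient estimation with a Gaussian form-factor fit (ASD, AAC) on
#' the ROI-averaged spectrum, and Burg-AR spacing-among-scatterers (SAS)
#' per block. Block maps are summarized to tumor-level values by the mean
#' (median for SAS, whose per-block estimates can be missing when no
#' autocorrelation peak lies in the search window).
#'
#' @param frame sample `rf_frame`.
#' @param roi `rf_roi` on the frame.
#' @param ref_bank reference-phantom spectrum bank from
#'   [build_reference_bank()] (geometry must match `block_size_mm`,
#'   `overlap_fraction`).
#' @param reflector_spectra planar-reflector spectra from
#'   [reflector_spectrum_bank()] on the SAS analysis grid, or `NULL` to
#'   skip SAS.
#' @param band analysis band, MHz.
#' @param alpha0,x0_cm intervening-tissue attenuation (dB/cm-MHz) and path
#'   (cm) above the ROI; the remaining path to each block center uses the
#'   estimated ACE.
#' @param alpha_ref reference-phantom attenuation, dB/cm-MHz.
#' @param ref_medium `medium_spec` of the reference phantom (for its
#'   analytic BSC).
#' @param block_size_mm,overlap_fraction block geometry.
#' @param ar_order Burg AR order for SAS.
#' @param sas_search SAS peak search window, MHz.
#' @param sas_stride compute SAS on every `sas_stride`-th block (maps get
#'   `NA` elsewhere; the tumor summary uses the computed subset).
#' @return list with `features` (named vector MBF, SS, SI, SAS, ACE, ASD,
#'   AAC), `maps` (per-block data.frame), `n_blocks`.
#' @export
extract_qus_features <- function(frame, roi, ref_bank,
                                 reflector_spectra = NULL,
                                 band = c(3, 8), alpha0 = 1, x0_cm = 0,
                                 alpha_ref = 0.15,
                                 ref_medium = reference_medium(),
                                 block_size_mm = 2, overlap_fraction = 0.8,
                                 ar_order = 50, sas_search = c(0.2, 2.5),
                                 sas_stride = 1) {
  blocks <- partition_roi(frame, roi, block_size_mm, overlap_fraction)
  if (length(blocks) == 0) stop("ROI produced no analysis blocks")
  specs <- lapply(blocks, block_power_spectrum,
                  sampling_rate = frame$sampling_rate)

  ace <- tryCatch(estimate_ace(specs, ref_bank, band, alpha_ref),
                  error = function(e) NA_real_)
  alpha1 <- if (is.na(ace)) alpha_ref else max(ace, 0)

  n <- length(blocks)
  mbf <- ss <- si <- sas <- rep(NA_real_, n)
  norm_corr <- vector("list", n)
  for (i in seq_len(n)) {
    s <- specs[[i]]
    d <- s$center_depth_cm
    ref <- nearest_reference(ref_bank, d)
    x1 <- max(d - x0_cm, 0)
    s_corr <- attenuation_correct(s, attenuation_model(alpha0, min(x0_cm, d),
                                                       alpha1, x1))
    r_corr <- attenuation_correct(ref, attenuation_model(0, 0, alpha_ref,
                                                         ref$center_depth_cm))
    nc <- normalize_spectrum(s_corr, r_corr)
    norm_corr[[i]] <- nc
    fit <- fit_spectral_line(nc, band)
    mbf[i] <- fit$mbf; ss[i] <- fit$ss; si[i] <- fit$si
  }

  # tumor-level BSC from the ROI-averaged normalized spectrum
  avg_norm <- spectrum_band(average_spectra(norm_corr), band)
  ref_bsc <- analytic_bsc(ref_medium, avg_norm$frequencies)
  ff <- tryCatch(
    fit_gaussian_form_factor(estimate_bsc(avg_norm, ref_bsc), band,
                             sound_speed = frame$sound_speed),
    error = function(e) list(asd_um = NA_real_, aac_db = NA_real_))

  if (!is.null(reflector_spectra)) {
    for (i in seq(1, n, by = sas_stride)) {
      sas[i] <- block_sas(blocks[[i]], reflector_spectra,
                          sampling_rate = frame$sampling_rate,
                          sound_speed = frame$sound_speed,
                          order = ar_order, band = band,
                          search = sas_search)
    }
  }
  sas_values <- if (is.null(reflector_spectra)) NA_real_ else
    sas[seq(1, n, by = sas_stride)]

  maps <- data.frame(
    center_depth_cm = sapply(blocks, `[[`, "center_depth_cm"),
    center_line = sapply(blocks, `[[`, "center_line"),
    MBF = mbf, SS = ss, SI = si, SAS = sas)

  list(features = c(MBF = summarize_roi(mbf),
                    SS = summarize_roi(ss),
                    SI = summarize_roi(si),
                    SAS = summarize_roi(sas_values, stat = "median"),
                    ACE = ace,
                    ASD = ff$asd_um,
                    AAC = ff$aac_db),
       maps = maps, n_blocks = n)
}
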