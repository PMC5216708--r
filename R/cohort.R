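#' Synthetic study cohort specification
#'
#' Defines a full simulated study: per-patient longitudinal scattering
#' media whose drift encodes the treatment response, a clinical table in
#' the cohort schema, and recurrence-free-survival data. Default group
#' sizes follow the study cohort (42 responders, 16 non-responders) and
#' the default effect directions follow the observed treatment-time
#' trends: backscatter-intensity parameters (MBF, SI, AAC) and attenuation
#' rise in responders and stay flat in non-responders. Effect magnitudes
#' are a simulation choice (the per-week responder echogenicity gains
#' below give roughly 80% week-4 separability, so pipeline regressions are
#' detectable without making the task trivial).
#'
#' @param n_responders,n_non_responders group sizes.
#' @param weeks scan weeks (0 = pre-treatment).
#' @param echo_gain_db mean responder echogenicity gain (dB) per week,
#'   named by week.
#' @param echo_gain_sd_db between-patient SD of the responder gain.
#' @param echo_null_sd_db SD of the (zero-mean) non-responder change.
#' @param attn_shift mean responder attenuation increase (dB/cm-MHz) per
#'   week, named by week.
#' @param attn_sd between-patient SD of the attenuation change.
#' @param hazard_ratio responder/non-responder recurrence hazard ratio.
#' @param seed master seed; everything derived is deterministic in it.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_responders = 42, n_non_responders = 16,
                        weeks = c(0, 1, 4, 8),
                        echo_gain_db = c("0" = 0, "1" = 2.5, "4" = 6,
                                         "8" = 7),
                        echo_gain_sd_db = 2.5,
                        echo_null_sd_db = 2,
                        attn_shift = c("0" = 0, "1" = 0.2, "4" = 0.3,
                                       "8" = 0.3),
                        attn_sd = 0.1,
                        hazard_ratio = 0.3, seed = 1) {
  if (n_responders <= 0 || n_non_responders <= 0) {
    stop("group sizes must be positive")
  }
  if (hazard_ratio <= 0) stop("hazard_ratio must be > 0")
  structure(list(n_responders = n_responders,
                 n_non_responders = n_non_responders,
                 weeks = weeks,
                 echo_gain_db = echo_gain_db,
                 echo_gain_sd_db = echo_gain_sd_db,
                 echo_null_sd_db = echo_null_sd_db,
                 attn_shift = attn_shift, attn_sd = attn_sd,
                 hazard_ratio = hazard_ratio, seed = seed),
            class = "cohort_spec")
}

#' Generate a synthetic study cohort
#'
#' Draws per-patient baseline tissue properties, drifts them over the scan
#' weeks according to the patient's (ground-truth) response, and emits the
#' clinical table, the per-patient-week media, and survival data. RF
#' frames are rendered on demand by [render_cohort_frame()] /
#' [extract_cohort_features()]. Fully seed-deterministic.
#'
#' @param spec a `cohort_spec`.
#' @return list of class `qus_cohort`: `patients` (clinical table with
#'   ground-truth `label`), `media` (media\[\[patient\]\]\[\[week\]\]),
#'   `survival` (from [simulate_survival()]), and `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_responders + spec$n_non_responders
  label <- rep(c("responder", "non-responder"),
               c(spec$n_responders, spec$n_non_responders))
  set.seed(spec$seed)
  age <- round(pmin(pmax(stats::rnorm(n, 49, 10), 29), 67))
  base_alpha <- stats::runif(n, 0.4, 0.8)
  base_echo <- exp(stats::rnorm(n, 0, 0.5))
  base_radius <- pmax(stats::rnorm(n, 25, 3), 10)
  init_diam <- round(stats::runif(n, 2, 10), 1)

  is_resp <- label == "responder"
  bts <- numeric(n)
  bts[is_resp] <- pmin(stats::rnorm(sum(is_resp), 68, 35), 100)
  bts[!is_resp] <- pmin(stats::rnorm(sum(!is_resp), -16, 40), 25)
  # a few responders respond by cellularity rather than shrinkage
  cellularity <- rep("none", n)
  cellularity[is_resp & bts <= 30] <- "low"
  residual <- round(init_diam * pmax(1 - bts / 100, 0), 1)
  residual_str <- ifelse(is_resp & bts >= 99.5, "No residual",
                         as.character(residual))

  media <- vector("list", n)
  wk_key <- as.character(spec$weeks)
  for (p in seq_len(n)) {
    media[[p]] <- stats::setNames(vector("list", length(spec$weeks)), wk_key)
    for (w in wk_key) {
      if (is_resp[p]) {
        gain_db <- spec$echo_gain_db[[w]] +
          (if (w == "0") 0 else stats::rnorm(1, 0, spec$echo_gain_sd_db))
        dalpha <- spec$attn_shift[[w]] +
          (if (w == "0") 0 else stats::rnorm(1, 0, spec$attn_sd))
      } else {
        gain_db <- if (w == "0") 0 else
          stats::rnorm(1, 0, spec$echo_null_sd_db)
        dalpha <- if (w == "0") 0 else stats::rnorm(1, 0, spec$attn_sd)
      }
      media[[p]][[w]] <- medium_spec(
        attenuation = max(base_alpha[p] + dalpha, 0.05),
        sound_speed = 1540,
        scatterer_radius_um = base_radius[p],
        number_density = 100,
        echogenicity_variance = base_echo[p] * 10^(gain_db / 10))
    }
  }

  patients <- data.frame(
    patient_id = seq_len(n),
    age_years = age,
    initial_dimensions_cm = as.character(init_diam),
    residual_dimensions_cm = residual_str,
    bts_printed_pct = round(bts),
    cellularity = cellularity,
    response_recorded = label,
    pathology_override = FALSE,
    label = label,
    stringsAsFactors = FALSE)

  surv <- simulate_survival(spec$n_responders, spec$n_non_responders,
                            hazard_ratio = spec$hazard_ratio,
                            seed = spec$seed + 101L)
  structure(list(patients = patients, media = media, survival = surv,
                 spec = spec),
            class = "qus_cohort")
}

#' Default acquisition geometry for cohort frames
#' @return an [acq_params()] list: 44 lines at 0.3 mm pitch, 900 samples
#'   at 40 MHz from 2 mm depth (about 19 mm imaging depth).
#' @export
cohort_acq <- function() {
  acq_params(n_lines = 44, n_samples = 900, sampling_rate = 40e6,
             line_pitch = 0.3e-3, depth_origin = 2e-3)
}

#' Render the RF frame of one patient-week
#'
#' @param cohort a `qus_cohort`.
#' @param patient patient id.
#' @param week scan week (must be in the cohort's weeks).
#' @param acq acquisition geometry.
#' @return an `rf_frame`.
#' @export
render_cohort_frame <- function(cohort, patient, week, acq = cohort_acq()) {
  medium <- cohort$media[[patient]][[as.character(week)]]
  if (is.null(medium)) stop("no medium for patient ", patient,
                            " at week ", week)
  seed <- cohort$spec$seed * 10000L + patient * 10L + match(
    as.character(week), as.character(cohort$spec$weeks))
  field <- sample_field(medium, acq_volume(acq, medium$sound_speed),
                        seed = seed)
  synthesize_rf(field, pulse_spec(), acq, medium, noise_seed = seed + 1L)
}

#' Extract QUS feature vectors for a whole cohort
#'
#' Renders every patient-week frame, runs [extract_qus_features()] on a
#' centered rectangular tumor ROI, and returns the long table of feature
#' vectors ready for [build_feature_table()]. One simulated reference-
#' phantom frame and one planar-reflector bank are shared by all frames.
#'
#' @param cohort a `qus_cohort`.
#' @param acq acquisition geometry.
#' @param roi_mm ROI edge length, mm (centered rectangle).
#' @param roi_top_mm depth of the ROI top, mm.
#' @param sas_stride compute SAS on every `sas_stride`-th block.
#' @param weeks subset of weeks to extract (default: all in the spec).
#' @param verbose print progress.
#' @return data.frame with `patient_id`, `week`, `label` and the seven QUS
#'   parameters.
#' @export
extract_cohort_features <- function(cohort, acq = cohort_acq(), roi_mm = 8,
                                    roi_top_mm = 5, sas_stride = 2,
                                    weeks = cohort$spec$weeks,
                                    verbose = FALSE) {
  ref_frame <- synthesize_reference(acq, seed = cohort$spec$seed + 77L)
  ref_bank <- build_reference_bank(ref_frame)
  band <- c(3, 8)
  refl_frames <- planar_reflector_bank(
    acq_params(n_lines = 4, n_samples = acq$n_samples * 4,
               sampling_rate = acq$sampling_rate,
               line_pitch = acq$line_pitch, depth_origin = 0),
    depths_cm = 1:6)
  refl_spectra <- reflector_spectrum_bank(refl_frames,
                                          seq(band[1], band[2], by = 0.02))
  n_lat_lines <- round(roi_mm / (1e3 * acq$line_pitch))
  l0 <- max(1, floor((acq$n_lines - n_lat_lines) / 2))
  rows <- list()
  for (p in cohort$patients$patient_id) {
    for (w in weeks) {
      frame <- render_cohort_frame(cohort, p, w, acq)
      roi <- roi_from_rect(frame, c(l0, l0 + n_lat_lines - 1),
                           c(roi_top_mm, roi_top_mm + roi_mm))
      res <- extract_qus_features(frame, roi, ref_bank, refl_spectra,
                                  band = band, alpha0 = 0, x0_cm = 0,
                                  sas_stride = sas_stride)
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = p, week = w,
        label = cohort$patients$label[cohort$patients$patient_id == p],
        t(res$features))
      if (verbose) {
        message(sprintf("patient %d week %s: %s", p, w,
                        paste(sprintf("%s=%.2f", names(res$features),
                                      res$features), collapse = " ")))
      }
    }
  }
  do.call(rbind, rows)
}
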