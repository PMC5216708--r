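#' Parameter-recovery experiments on simulated phantoms
#'
#' Each experiment simulates media with known ground truth, runs the full
#' estimation chain (reference-phantom normalization, ACE, attenuation
#' correction, spectral and form-factor fits, Burg-AR spacing analysis)
#' and returns the per-seed estimates, so estimator accuracy can be read
#' off as recovery of the planted values. A fresh reference-phantom
#' realization is drawn per seed so reference speckle error averages out
#' across the ensemble.
#'
#' @param n_seeds ensemble size.
#' @param seed_base offset added to the per-iteration seeds.
#' @param alpha_true planted tumor attenuation, dB/cm-MHz.
#' @param radius_um planted effective scatterer radius, um.
#' @param acq acquisition geometry.
#' @return `run_attenuation_recovery`: data.frame with one row per seed
#'   (`ace`, `asd_um`, `aac_db`, `ss`); the planted values are carried in
#'   the attributes `alpha_true` and `radius_um`.
#' @export
run_attenuation_recovery <- function(n_seeds = 20, seed_base = 0,
                                     alpha_true = 1.0, radius_um = 25,
                                     acq = acq_params(n_lines = 40,
                                                      n_samples = 1200)) {
  rows <- lapply(seq_len(n_seeds), function(i) {
    s <- seed_base + 1000L * i
    med <- medium_spec(attenuation = alpha_true,
                       scatterer_radius_um = radius_um,
                       number_density = 100)
    ref <- synthesize_reference(acq, seed = s + 1L)
    bank <- build_reference_bank(ref)
    field <- sample_field(med, acq_volume(acq, med$sound_speed), seed = s)
    frame <- synthesize_rf(field, pulse_spec(), acq, med,
                           noise_seed = s + 2L)
    roi <- roi_from_rect(frame, c(2, acq$n_lines - 1), c(6, 18))
    feats <- suppressWarnings(
      extract_qus_features(frame, roi, bank, NULL, alpha0 = 0,
                           x0_cm = 0)$features)
    data.frame(seed = s, ace = feats[["ACE"]], asd_um = feats[["ASD"]],
               aac_db = feats[["AAC"]], ss = feats[["SS"]])
  })
  out <- do.call(rbind, rows)
  attr(out, "alpha_true") <- alpha_true
  attr(out, "radius_um") <- radius_um
  out
}

#' @rdname run_attenuation_recovery
#' @param radii_um ladder of planted effective radii.
#' @param n_planes image planes simulated per tumor; normalized spectra
#'   are pooled across planes before the form-factor fit, as multiple
#'   acquisition planes of one tumor would be.
#' @return `run_scatterer_size_recovery`: data.frame with one row per
#'   (radius, seed): `radius_um`, `seed`, `asd_um`, `ss`.
#' @export
run_scatterer_size_recovery <- function(radii_um = c(15, 25, 40),
                                        n_seeds = 20, seed_base = 0,
                                        n_planes = 3,
                                        acq = acq_params(n_lines = 40,
                                                         n_samples = 1200)) {
  band <- c(3, 8)
  rows <- list()
  for (i in seq_len(n_seeds)) {
    s <- seed_base + 1000L * i
    refs <- lapply(1:4, function(j) synthesize_reference(acq, seed = s + j))
    bank <- build_reference_bank(refs)
    for (a in radii_um) {
      med <- medium_spec(attenuation = 0.7, scatterer_radius_um = a,
                         number_density = 100)
      norm_all <- list()
      ss_planes <- numeric(0)
      for (pl in seq_len(n_planes)) {
        field <- sample_field(med, acq_volume(acq, med$sound_speed),
                              seed = s + 10L * match(a, radii_um) + pl)
        frame <- synthesize_rf(field, pulse_spec(), acq, med,
                               noise_seed = s + 100L * pl)
        roi <- roi_from_rect(frame, c(2, acq$n_lines - 1), c(6, 18))
        blocks <- partition_roi(frame, roi)
        specs <- lapply(blocks, block_power_spectrum,
                        sampling_rate = frame$sampling_rate)
        a1 <- max(estimate_ace(specs, bank, band), 0)
        norm <- lapply(specs, function(sp) {
          d <- sp$center_depth_cm
          sc <- attenuation_correct(sp, attenuation_model(0, 0, a1, d))
          rc <- attenuation_correct(nearest_reference(bank, d),
                                    attenuation_model(0, 0, 0.15, d))
          normalize_spectrum(sc, rc)
        })
        ss_planes <- c(ss_planes,
                       fit_spectral_line(average_spectra(norm), band)$ss)
        norm_all <- c(norm_all, norm)
      }
      avg <- spectrum_band(average_spectra(norm_all), band)
      ref_bsc <- analytic_bsc(reference_medium(), avg$frequencies)
      ff <- suppressWarnings(
        fit_gaussian_form_factor(estimate_bsc(avg, ref_bsc), band,
                                 sound_speed = med$sound_speed))
      rows[[length(rows) + 1L]] <- data.frame(
        radius_um = a, seed = s, asd_um = ff$asd_um,
        a2_um2 = ff$a2_um2, ss = mean(ss_planes))
    }
  }
  do.call(rbind, rows)
}

#' @rdname run_attenuation_recovery
#' @param spacing_mm planted lattice spacing, mm.
#' @param sas_stride evaluate SAS on every `sas_stride`-th ROI block.
#' @return `run_sas_recovery`: data.frame with one row per seed:
#'   `seed`, `sas_mm` (the median block SAS of that frame).
#' @export
run_sas_recovery <- function(n_seeds = 20, seed_base = 0, spacing_mm = 1.0,
                             sas_stride = 8,
                             acq = acq_params(n_lines = 48,
                                              n_samples = 1300)) {
  racq <- acq_params(n_lines = 4, n_samples = 3600, depth_origin = 0)
  refl <- reflector_spectrum_bank(planar_reflector_bank(racq),
                                  seq(3, 8, by = 0.02))
  rows <- lapply(seq_len(n_seeds), function(i) {
    s <- seed_base + 1000L * i
    med <- medium_spec(attenuation = 0.3, scatterer_radius_um = 25,
                       number_density = 100, echogenicity_variance = 1,
                       regular_spacing_mm = spacing_mm,
                       regular_fraction = 6)
    field <- sample_field(med, acq_volume(acq, med$sound_speed), seed = s)
    frame <- synthesize_rf(field, pulse_spec(), acq, med,
                           noise_seed = s + 2L)
    roi <- roi_from_rect(frame, c(6, acq$n_lines - 5), c(6, 16))
    blocks <- partition_roi(frame, roi)
    sas <- vapply(blocks[seq(1, length(blocks), by = sas_stride)],
                  block_sas, numeric(1), reflector_bank = refl,
                  sampling_rate = frame$sampling_rate,
                  sound_speed = frame$sound_speed)
    data.frame(seed = s, sas_mm = stats::median(sas, na.rm = TRUE))
  })
  do.call(rbind, rows)
}

#' Pooled ensemble scatterer diameter
#'
#' Ensemble ASD from per-fit signed `a2_um2` values: averaging in the a^2
#' domain (where the log-linear fit is unbiased) before the square root
#' avoids the downward bias that averaging per-fit diameters incurs when
#' individual fits are noisy or clamped at zero.
#'
#' @param a2_um2 per-fit signed squared effective radii, um^2.
#' @return pooled ASD in um (0 if the pooled a^2 is non-positive).
#' @export
pooled_asd_um <- function(a2_um2) {
  m <- mean(a2_um2, na.rm = TRUE)
  if (!is.finite(m) || m <= 0) return(0)
  2 * sqrt(m)
}

#' End-to-end synthetic-cohort classification experiment
#'
#' Generates a reduced synthetic cohort (default 10 responders + 10
#' non-responders scanned at weeks 0 and 4), renders and analyzes every
#' patient-week RF frame, builds the week-4 baseline-normalized feature
#' table, and evaluates the balanced, repeat-averaged KNN classifier.
#' The pooled per-repeat predictions give a binomial test of accuracy
#' against chance.
#'
#' @param n_per_group patients per response group.
#' @param weeks scan weeks (must include 0 and the classification week).
#' @param week classification week.
#' @param seed master seed.
#' @param n_repeats balanced resampling repeats.
#' @return list with `features` (the long feature table), `table` (the
#'   week feature table), `perf` (a `performance_summary`), `n_correct`,
#'   `n_total`, and `binom_p` (one-sided, against 50% accuracy).
#' @export
run_cohort_experiment <- function(n_per_group = 10, weeks = c(0, 4),
                                  week = 4, seed = 1, n_repeats = 10) {
  spec <- cohort_spec(n_responders = n_per_group,
                      n_non_responders = n_per_group,
                      weeks = weeks, seed = seed)
  cohort <- generate_cohort(spec)
  feats <- extract_cohort_features(cohort)
  tab <- build_feature_table(feats, week = week)
  labels <- cohort$patients$label[match(tab$patient_id,
                                        cohort$patients$patient_id)]
  x <- tab[, setdiff(names(tab), "patient_id")]
  perf <- balance_and_evaluate(x, labels, n_repeats = n_repeats,
                               seed = seed)
  n_per_rep <- 2 * min(table(labels))
  n_correct <- round(sum(perf$per_repeat$accuracy / 100 * n_per_rep))
  n_total <- n_repeats * n_per_rep
  list(features = feats, table = tab, labels = labels, perf = perf,
       n_correct = n_correct, n_total = n_total,
       binom_p = stats::binom.test(n_correct, n_total, 0.5,
                                   alternative = "greater")$p.value)
}
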