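#' Summarize a parametric map into one tumor-level value
#'
#' Block-level estimates are aggregated to a single per-patient-week value
#' by the arithmetic mean over non-missing blocks (median available). The
#' summary is reported missing when more than half the blocks are missing.
#'
#' @param values numeric vector of block estimates (may contain `NA`).
#' @param stat `"mean"` or `"median"`.
#' @return scalar, or `NA_real_` if more than 50% of blocks are missing.
#' @export
summarize_roi <- function(values, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  if (length(values) == 0) return(NA_real_)
  if (mean(is.na(values)) > 0.5) return(NA_real_)
  if (stat == "mean") mean(values, na.rm = TRUE)
  else stats::median(values, na.rm = TRUE)
}

#' Parse tumor dimensions from a clinical-table string
#'
#' Dimension strings list one or more foci, each as up to three diameters:
#' foci are separated by `";"` and diameters by `"x"` (e.g.
#' `"2.3 x 2.5 x 2.5; 1.0 x 1.0 x 0.7"`). `"No residual"` (or an empty
#' string) parses to no diameters.
#'
#' @param s character scalar.
#' @return numeric vector of diameters in cm (length 0 for no residual).
#' @export
parse_dimensions <- function(s) {
  if (is.na(s) || !nzchar(trimws(s))) return(numeric(0))
  if (grepl("no residual|whole breast", s, ignore.case = TRUE)) {
    # "whole breast" carries no measurable diameters either; its BTS is
    # taken from the printed value
    return(numeric(0))
  }
  parts <- unlist(strsplit(s, "[;x]", perl = TRUE))
  v <- suppressWarnings(as.numeric(trimws(parts)))
  v[!is.na(v)]
}

#' Bulk tumor shrinkage
#'
#' Relative reduction in the sum of tumor-focus diameters from
#' pre-treatment to pre-operation:
#' `BTS = 100 (1 - sum(residual) / sum(initial))`. A tumor with no
#' residual disease scores 100%; growth gives negative values.
#'
#' @param initial numeric vector of initial diameters (cm) over all foci.
#' @param residual numeric vector of residual diameters (cm); length 0
#'   means no residual tumor.
#' @return BTS in percent.
#' @export
compute_bts <- function(initial, residual) {
  if (length(residual) == 0) return(100)
  if (length(initial) == 0 || sum(initial) <= 0) return(NA_real_)
  100 * (1 - sum(residual) / sum(initial))
}

#' Clinical response label
#'
#' A patient is a responder when the summed tumor-focus diameters shrink
#' by more than 30% (the partial-response threshold of diameter-based
#' response criteria) or when residual tumor cellularity is pathologically
#' low; otherwise a non-responder. Where the recorded pathological
#' response conflicts with this rule, pathology wins (`override_label`).
#'
#' @param bts_pct bulk tumor shrinkage in percent (may be `NA`).
#' @param cellularity `"low"`, `"high"` or `"none"` (no cellularity note).
#' @param override_label optional pathology-determined label that takes
#'   precedence when not `NA`.
#' @return `"responder"`, `"non-responder"`, or `NA_character_` when both
#'   BTS and cellularity are unavailable.
#' @export
label_response <- function(bts_pct, cellularity = "none",
                           override_label = NA_character_) {
  n <- max(length(bts_pct), length(cellularity), length(override_label))
  bts_pct <- rep_len(bts_pct, n)
  cellularity <- rep_len(cellularity, n)
  override_label <- rep_len(override_label, n)
  out <- character(n)
  for (i in seq_len(n)) {
    if (!is.na(override_label[i])) {
      out[i] <- override_label[i]
    } else if (is.na(bts_pct[i]) && cellularity[i] == "none") {
      out[i] <- NA_character_
    } else if ((!is.na(bts_pct[i]) && bts_pct[i] > 30) ||
               cellularity[i] == "low") {
      out[i] <- "responder"
    } else {
      out[i] <- "non-responder"
    }
  }
  out
}

#' Read a clinical cohort table
#'
#' Loads a per-patient clinical CSV (id, age, initial and residual tumor
#' dimensions, printed BTS, cellularity note, recorded response, pathology
#' override flag), recomputes BTS from the dimension strings where
#' possible, applies the response-labelling rule, and reports any
#' disagreement between the rule and the recorded response for patients
#' without a pathology override (disagreements are listed in the
#' `rule_mismatch` column, never silently overridden: the printed BTS and
#' recorded response stay authoritative).
#'
#' @param path CSV path; defaults to the packaged 58-patient cohort table.
#' @return data.frame with one row per patient including `bts_computed_pct`,
#'   `label` (the applied response label) and `rule_mismatch`.
#' @export
read_clinical_table <- function(path = system.file("extdata",
                                                   "clinical_cohort.csv",
                                                   package = "quspred")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "age_years", "initial_dimensions_cm",
            "residual_dimensions_cm", "bts_printed_pct", "cellularity",
            "response_recorded", "pathology_override")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("clinical table missing column(s): ", paste(missing, collapse = ", "))
  }
  tab$bts_computed_pct <- mapply(function(ini, res) {
    compute_bts(parse_dimensions(ini), parse_dimensions(res))
  }, tab$initial_dimensions_cm, tab$residual_dimensions_cm)
  # the printed BTS is authoritative for labelling (a few cells are not
  # exactly reproducible from the printed dimensions)
  bts <- ifelse(is.na(tab$bts_printed_pct), tab$bts_computed_pct,
                tab$bts_printed_pct)
  rule <- label_response(bts, tab$cellularity)
  tab$label <- ifelse(tab$pathology_override, tab$response_recorded, rule)
  tab$rule_mismatch <- !tab$pathology_override &
    !is.na(rule) & rule != tab$response_recorded
  if (any(tab$rule_mismatch)) {
    message("response rule disagrees with recorded response for patient(s): ",
            paste(tab$patient_id[tab$rule_mismatch], collapse = ", "))
  }
  tab
}

#' Cohort summary statistics
#'
#' @param tab clinical table from [read_clinical_table()].
#' @return list with patient count, responder/non-responder counts,
#'   response rate (%), mean age, and per-group mean printed BTS.
#' @export
summarize_cohort <- function(tab) {
  resp <- tab$label == "responder"
  list(n_patients = nrow(tab),
       n_responders = sum(resp, na.rm = TRUE),
       n_non_responders = sum(!resp, na.rm = TRUE),
       response_rate_pct = 100 * mean(resp, na.rm = TRUE),
       mean_age_years = mean(tab$age_years, na.rm = TRUE),
       mean_bts_responders_pct =
         mean(tab$bts_printed_pct[resp], na.rm = TRUE),
       mean_bts_non_responders_pct =
         mean(tab$bts_printed_pct[!resp], na.rm = TRUE))
}

.qus_features <- c("MBF", "SS", "SI", "SAS", "ACE", "ASD", "AAC")

#' Baseline-normalized feature table for one week
#'
#' Builds the classification table for a chosen week: one row per patient,
#' columns the change of each QUS parameter from its pre-treatment value
#' (`dMBF = MBF(week) - MBF(0)`, ...), optionally concatenated with the
#' week-0 absolute values (`MBF_wk0`, ...). Baseline normalization removes
#' between-patient differences in breast echogenicity. Patients lacking a
#' week-0 vector (or the requested week) are excluded with a message.
#'
#' @param vectors data.frame of per-patient-week feature vectors with
#'   columns `patient_id`, `week`, and the QUS parameters
#'   `MBF, SS, SI, SAS, ACE, ASD, AAC`.
#' @param week the treatment week to build the table for.
#' @param include_baseline also include the week-0 absolute features.
#' @return data.frame with `patient_id` and the feature columns.
#' @export
build_feature_table <- function(vectors, week, include_baseline = FALSE) {
  stopifnot(all(c("patient_id", "week", .qus_features) %in% names(vectors)))
  wk0 <- vectors[vectors$week == 0, , drop = FALSE]
  wkw <- vectors[vectors$week == week, , drop = FALSE]
  ids <- intersect(wkw$patient_id, wk0$patient_id)
  dropped <- setdiff(unique(c(wkw$patient_id, wk0$patient_id)), ids)
  if (length(dropped)) {
    message("excluded (missing week-0 or week-", week, " vector): ",
            paste(dropped, collapse = ", "))
  }
  wk0 <- wk0[match(ids, wk0$patient_id), , drop = FALSE]
  wkw <- wkw[match(ids, wkw$patient_id), , drop = FALSE]
  out <- data.frame(patient_id = ids)
  for (p in .qus_features) {
    out[[paste0("d", p)]] <- wkw[[p]] - wk0[[p]]
    if (include_baseline) out[[paste0(p, "_wk0")]] <- wk0[[p]]
  }
  out
}
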