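#' Raw RF frame container
#'
#' A beamformed radiofrequency (RF) frame is the raw pre-envelope echo data
#' from one image plane: a matrix of scan lines by axial samples plus the
#' acquisition metadata needed to map sample indices to physical depth.
#'
#' @param samples numeric matrix, scan lines in rows and axial samples in
#'   columns (arbitrary amplitude units).
#' @param sampling_rate axial sampling rate in Hz (40 MHz for the target
#'   scanner configuration).
#' @param center_frequency transducer center frequency in Hz.
#' @param line_pitch lateral spacing between adjacent scan lines in m.
#' @param sound_speed assumed speed of sound in m/s (1540 for soft tissue,
#'   1515 for the reference phantom).
#' @param depth_origin depth of the first axial sample from the transducer
#'   face, in m.
#' @return An object of class `rf_frame`.
#' @export
rf_frame <- function(samples, sampling_rate, center_frequency, line_pitch,
                     sound_speed, depth_origin = 0) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples) || !all(is.finite(samples))) {
    stop("'samples' must be a finite numeric matrix")
  }
  for (nm in c("sampling_rate", "center_frequency", "line_pitch",
               "sound_speed", "depth_origin")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("metadata field '", nm, "' must be a finite scalar")
    }
  }
  if (sampling_rate <= 0 || center_frequency <= 0 || line_pitch <= 0 ||
      sound_speed <= 0 || depth_origin < 0) {
    stop("acquisition metadata out of range")
  }
  structure(
    list(samples = samples,
         sampling_rate = sampling_rate,
         center_frequency = center_frequency,
         line_pitch = line_pitch,
         sound_speed = sound_speed,
         depth_origin = depth_origin),
    class = "rf_frame")
}

#' @export
print.rf_frame <- function(x, ...) {
  d <- dim(x$samples)
  cat(sprintf("<rf_frame> %d lines x %d samples, fs = %.1f MHz, f0 = %.1f MHz\n",
              d[1], d[2], x$sampling_rate / 1e6, x$center_frequency / 1e6))
  cat(sprintf("  depth %.1f-%.1f mm, pitch %.2f mm, c = %.0f m/s\n",
              1e3 * x$depth_origin, 1e3 * max(rf_depth_axis(x)),
              1e3 * x$line_pitch, x$sound_speed))
  invisible(x)
}

#' Physical depth of each axial sample
#'
#' Depth of axial sample i (1-based) is
#' `depth_origin + (i - 1) * sound_speed / (2 * sampling_rate)`: the echo at
#' sample i has made the round trip to that depth and back.
#'
#' @param frame an `rf_frame`.
#' @return numeric vector of depths in m, one per axial sample.
#' @export
rf_depth_axis <- function(frame) {
  n <- ncol(frame$samples)
  frame$depth_origin + (seq_len(n) - 1) * frame$sound_speed /
    (2 * frame$sampling_rate)
}

#' Axial sample length in mm
#' @param frame an `rf_frame`.
#' @return mm of depth spanned by one axial sample.
#' @export
rf_mm_per_sample <- function(frame) {
  1e3 * frame$sound_speed / (2 * frame$sampling_rate)
}

.rf_meta_keys <- c("sampling_rate_hz", "center_frequency_hz", "line_pitch_m",
                   "sound_speed_mps", "depth_origin_m", "n_lines", "n_samples")

#' Write / read the RF container
#'
#' The on-disk container is a raw little-endian float64 payload (line-major:
#' all samples of line 1, then line 2, ...) accompanied by a JSON sidecar
#' `<path>.json` holding the acquisition metadata and array shape. The pair
#' round-trips an `rf_frame` bitwise.
#'
#' @param frame an `rf_frame`.
#' @param path payload file path; the sidecar is written to `<path>.json`.
#' @return `write_rf_container` returns `path` invisibly;
#'   `read_rf_container` returns an `rf_frame`.
#' @export
write_rf_container <- function(frame, path) {
  stopifnot(inherits(frame, "rf_frame"))
  meta <- list(
    sampling_rate_hz = frame$sampling_rate,
    center_frequency_hz = frame$center_frequency,
    line_pitch_m = frame$line_pitch,
    sound_speed_mps = frame$sound_speed,
    depth_origin_m = frame$depth_origin,
    n_lines = nrow(frame$samples),
    n_samples = ncol(frame$samples))
  con <- file(path, "wb")
  on.exit(close(con))
  # t() so the payload is line-major regardless of R's column-major storage
  writeBin(as.vector(t(frame$samples)), con, size = 8, endian = "little")
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rf_container
#' @export
read_rf_container <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop("missing metadata sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  meta <- lapply(meta, as.numeric)   # JSON may round-trip doubles as ints
  missing <- setdiff(.rf_meta_keys, names(meta))
  if (length(missing)) {
    stop("RF container metadata missing required key(s): ",
         paste(missing, collapse = ", "))
  }
  n <- meta$n_lines * meta$n_samples
  con <- file(path, "rb")
  on.exit(close(con))
  raw <- readBin(con, "double", n = n, size = 8, endian = "little")
  if (length(raw) != n) stop("RF payload truncated: expected ", n, " samples")
  samples <- matrix(raw, nrow = meta$n_lines, ncol = meta$n_samples,
                    byrow = TRUE)
  rf_frame(samples,
           sampling_rate = meta$sampling_rate_hz,
           center_frequency = meta$center_frequency_hz,
           line_pitch = meta$line_pitch_m,
           sound_speed = meta$sound_speed_mps,
           depth_origin = meta$depth_origin_m)
}
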