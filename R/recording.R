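#' BCG recording object
#'
#' A single-subject ballistocardiogram: a real-valued amplitude series in
#' arbitrary units together with its sampling rate, class label and subject id.
#' Recordings are the unit of input to the preprocessing pipeline.
#'
#' @param samples Numeric vector of amplitudes (length >= 1, all finite).
#' @param fs Sampling rate in Hz (default 100, the rate of typical
#'   piezoelectric mattress acquisition systems).
#' @param label Class label, one of `"HPT"` (hypertensive) or `"NRT"`
#'   (normotensive).
#' @param subject_id Character scalar identifying the subject.
#' @param bit_depth Optional ADC bit depth (16 when emulating a 16-bit
#'   acquisition chain); `NA` when the series is not quantized.
#'
#' @return An object of class `bcg_recording`: a list with elements
#'   `samples`, `fs`, `label`, `subject_id`, `bit_depth`.
#' @export
#' @examples
#' rec <- bcg_recording(sin(seq(0, 2 * pi, length.out = 200)), fs = 100,
#'                      label = "NRT", subject_id = "S001")
#' rec
bcg_recording <- function(samples, fs = 100, label = c("HPT", "NRT"),
                          subject_id = "S000", bit_depth = NA_integer_) {
  label <- match.arg(label)
  samples <- as.numeric(samples)
  if (length(samples) < 1L) {
    abort("`samples` must contain at least one value.")
  }
  if (!all(is.finite(samples))) {
    abort("`samples` must be finite throughout.")
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    abort("`fs` must be a single positive number (Hz).")
  }
  structure(
    list(samples = samples, fs = fs, label = label,
         subject_id = as.character(subject_id),
         bit_depth = as.integer(bit_depth)),
    class = "bcg_recording"
  )
}

#' @export
print.bcg_recording <- function(x, ...) {
  dur <- length(x$samples) / x$fs
  cat(sprintf("<bcg_recording> subject %s [%s], %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$label, length(x$samples), x$fs, dur))
  invisible(x)
}

#' @export
length.bcg_recording <- function(x) length(x$samples)

#' Read a BCG recording from a plain-text amplitude file
#'
#' The expected dialect is one sample per line (UTF-8, `.` decimal separator),
#' with an optional single non-numeric header line which is skipped. This is a
#' deliberately simple interchange format; exports from other acquisition
#' systems should be converted to it first.
#'
#' @param path Path to the file.
#' @param fs Sampling rate in Hz of the stored series.
#' @param label Class label (`"HPT"` or `"NRT"`).
#' @param subject_id Subject identifier.
#' @return A [bcg_recording()].
#' @export
read_recording <- function(path, fs = 100, label = c("HPT", "NRT"),
                           subject_id = "S000") {
  label <- match.arg(label)
  if (!file.exists(path)) {
    abort(sprintf("Recording file not found: %s", path))
  }
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    abort(sprintf("Recording file is empty: %s", path))
  }
  offset <- 0L
  vals <- suppressWarnings(as.numeric(lines))
  if (is.na(vals[1L]) && length(lines) > 1L) {
    # header line
    offset <- 1L
    lines <- lines[-1L]
    vals <- suppressWarnings(as.numeric(lines))
  }
  bad <- which(is.na(vals))
  if (length(bad) > 0L) {
    abort(sprintf("Non-numeric value at line %d of %s: '%s'",
                  bad[1L] + offset, path, lines[bad[1L]]))
  }
  bcg_recording(vals, fs = fs, label = label, subject_id = subject_id)
}

#' Write a BCG recording to a plain-text amplitude file
#'
#' One sample per line with full double precision, so that
#' [read_recording()] round-trips the series to within 1e-9.
#'
#' @param rec A [bcg_recording()].
#' @param path Output file path.
#' @param header Logical; write an `"amplitude"` header line (default `FALSE`).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, header = FALSE) {
  stopifnot(inherits(rec, "bcg_recording"))
  if (length(rec$samples) == 0L) {
    abort("Refusing to write an empty recording.")
  }
  lines <- sprintf("%.12g", rec$samples)
  if (header) lines <- c("amplitude", lines)
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read or write a cohort manifest
#'
#' The manifest is the inter-stage contract of the pipeline: a CSV with columns
#' `subject_id`, `label`, `path`, `duration_s`, one row per recording.
#'
#' @param path CSV file path.
#' @return `read_manifest()` returns a tibble; `write_manifest()` returns
#'   `path` invisibly.
#' @export
read_manifest <- function(path) {
  m <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_manifest(m)
  m
}

#' @rdname read_manifest
#' @param manifest A manifest tibble.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  readr::write_csv(manifest, path, progress = FALSE)
  invisible(path)
}

validate_manifest <- function(m) {
  need <- c("subject_id", "label", "path", "duration_s")
  missing_cols <- setdiff(need, names(m))
  if (length(missing_cols) > 0L) {
    abort(sprintf("Manifest is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(m$subject_id)) {
    abort("Manifest subject_ids must be unique.")
  }
  if (!all(m$label %in% c("HPT", "NRT"))) {
    abort("Manifest labels must be 'HPT' or 'NRT'.")
  }
  invisible(m)
}
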