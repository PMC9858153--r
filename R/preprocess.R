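#' Median absolute deviation (raw, no consistency constant)
#'
#' The robust scale estimate used by the normalization stage:
#' `median(|x - median(x)|)`. Unlike the usual Gaussian-consistent estimator,
#' no 1.4826 constant is applied, so that a normalized signal has MAD exactly
#' 1 rather than SD approximately 1.
#'
#' @param x Numeric vector (length >= 1).
#' @return The raw MAD, a single number.
#' @export
#' @examples
#' bcg_mad(c(1, 2, 3, 4, 5))  # 1
bcg_mad <- function(x) {
  if (length(x) < 1L) abort("`x` must contain at least one value.")
  stats::mad(x, constant = 1)
}

#' Robust z-score normalization by median and MAD
#'
#' Centers a signal on its median and scales by its raw median absolute
#' deviation, so the output has median 0 and MAD 1. This removes the
#' subject-dependent amplitude scale (body weight strongly affects BCG
#' amplitudes) without being distorted by heavy-tailed amplitude
#' distributions the way mean/SD scaling is.
#'
#' @param x Numeric vector (length >= 2) with non-zero MAD.
#' @return An object of class `bcg_normalized`: list with `samples` (the
#'   normalized series), `center` (the original median) and `scale` (the
#'   original MAD).
#' @export
#' @examples
#' z <- mad_zscore(c(1, 2, 3, 4, 5))
#' z$samples  # -2 -1 0 1 2
mad_zscore <- function(x) {
  if (length(x) < 2L) abort("Need at least 2 samples to normalize.")
  ctr <- median(x)
  scl <- bcg_mad(x)
  if (scl <= 0) {
    abort("Signal is degenerate (MAD = 0); cannot normalize a (near-)constant series.")
  }
  structure(list(samples = (x - ctr) / scl, center = ctr, scale = scl),
            class = "bcg_normalized")
}

#' The canonical BCG bandpass filter coefficients
#'
#' Returns the fixed fourth-order IIR transfer function used by the canonical
#' pipeline, reported as a Chebyshev type II bandpass at 1-50 Hz for 100 Hz
#' sampling:
#' numerator (0.028, 0.053, 0.071, 0.053, 0.028) and denominator
#' (1, -2.026, 2.148, -1.159, 0.279). These constants are the reproducible
#' contract of the filtering stage and are used verbatim; note that their DC
#' gain is 0.963 (near unity) and the claimed upper band edge coincides with
#' Nyquist, so they do not correspond to any textbook 1-50 Hz bandpass design
#' at this rate (see the package vignette). [design_cheby2_bandpass()] exists
#' for user-configured alternatives.
#'
#' @return An object of class `bcg_filter`: list with `b`, `a` and design
#'   metadata (`order`, `f_low`, `f_high`, `fs`).
#' @export
canonical_filter <- function() {
  new_bcg_filter(
    b = c(0.028, 0.053, 0.071, 0.053, 0.028),
    a = c(1, -2.026, 2.148, -1.159, 0.279),
    order = 4L, f_low = 1, f_high = 50, fs = 100,
    design = "fixed canonical coefficients"
  )
}

new_bcg_filter <- function(b, a, order, f_low, f_high, fs, design) {
  if (length(b) != length(a)) abort("`b` and `a` must have equal length.")
  if (abs(a[1] - 1) > 1e-12) abort("Denominator must be normalized (a[1] = 1).")
  structure(list(b = as.numeric(b), a = as.numeric(a), order = as.integer(order),
                 f_low = f_low, f_high = f_high, fs = fs, design = design),
            class = "bcg_filter")
}

#' @export
print.bcg_filter <- function(x, ...) {
  cat(sprintf("<bcg_filter> order %d, band %g-%g Hz @ fs %g Hz (%s)\n",
              x$order, x$f_low, x$f_high, x$fs, x$design))
  cat("  b:", paste(signif(x$b, 4), collapse = " "), "\n")
  cat("  a:", paste(signif(x$a, 4), collapse = " "), "\n")
  invisible(x)
}

#' Poles of an IIR filter and a stability check
#'
#' @param coeffs A `bcg_filter`.
#' @return `filter_poles()`: complex vector of denominator roots.
#'   `is_stable()`: `TRUE` when all poles lie strictly inside the unit circle.
#' @export
filter_poles <- function(coeffs) {
  a <- coeffs$a
  # roots of a[1] z^(n) + a[2] z^(n-1) + ... ; polyroot wants ascending order
  polyroot(rev(a))
}

#' @rdname filter_poles
#' @export
is_stable <- function(coeffs) {
  all(Mod(filter_poles(coeffs)) < 1)
}

#' Design a Chebyshev type II bandpass filter
#'
#' A configurable alternative to [canonical_filter()], delegating to
#' [signal::cheby2()]. `order` is the overall filter order (must be even for
#' a bandpass; the underlying low-pass prototype has order `order/2`).
#'
#' @param order Overall filter order (even, >= 2).
#' @param f_low,f_high Band edges in Hz; `0 < f_low < f_high < fs/2`. A
#'   discrete-time bandpass with its upper edge at the Nyquist frequency is
#'   not realizable, so edges at or above `fs/2` are rejected.
#' @param fs Sampling rate in Hz.
#' @param stop_atten_db Stopband attenuation in dB (default 20).
#' @return A `bcg_filter`.
#' @export
design_cheby2_bandpass <- function(order = 4L, f_low = 1, f_high = 49,
                                   fs = 100, stop_atten_db = 20) {
  if (order < 2 || order %% 2 != 0) {
    abort("`order` must be an even integer >= 2 for a bandpass design.")
  }
  if (!(f_low > 0 && f_high > f_low)) {
    abort("Band edges must satisfy 0 < f_low < f_high.")
  }
  if (f_high >= fs / 2) {
    abort(sprintf(
      "Upper band edge (%g Hz) must be strictly below Nyquist (%g Hz).",
      f_high, fs / 2))
  }
  des <- signal::cheby2(order / 2, Rp = stop_atten_db,
                        W = c(f_low, f_high) / (fs / 2), type = "pass")
  new_bcg_filter(b = des$b, a = des$a, order = order,
                 f_low = f_low, f_high = f_high, fs = fs,
                 design = sprintf("Chebyshev II, %g dB stopband", stop_atten_db))
}

#' Apply an IIR filter to a signal
#'
#' Single-pass causal filtering with zero initial conditions (direct-form
#' difference equation), the default of the canonical pipeline. Set
#' `zero_phase = TRUE` for forward-backward filtering when phase distortion
#' matters more than causality.
#'
#' @param x Numeric vector.
#' @param coeffs A `bcg_filter` (default [canonical_filter()]).
#' @param zero_phase Logical; use [signal::filtfilt()] instead of a single
#'   forward pass.
#' @return Filtered numeric vector, same length as `x`.
#' @export
apply_iir_filter <- function(x, coeffs = canonical_filter(), zero_phase = FALSE) {
  stopifnot(inherits(coeffs, "bcg_filter"))
  if (length(x) < 1L) abort("`x` must contain at least one sample.")
  if (!is_stable(coeffs)) {
    abort("Filter is unstable (poles on or outside the unit circle); refusing to apply it.")
  }
  if (zero_phase) {
    as.numeric(signal::filtfilt(coeffs$b, coeffs$a, x))
  } else {
    as.numeric(signal::filter(coeffs$b, coeffs$a, x))
  }
}

#' Filter coefficient serialization
#'
#' Writes/reads a `bcg_filter` as a small JSON record (`b`, `a`, metadata) so
#' coefficient sets can be exchanged and pinned.
#'
#' @param coeffs A `bcg_filter`.
#' @param path JSON file path.
#' @return `write_filter()`: `path`, invisibly. `read_filter()`: a `bcg_filter`.
#' @export
write_filter <- function(coeffs, path) {
  stopifnot(inherits(coeffs, "bcg_filter"))
  jsonlite::write_json(unclass(coeffs), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_filter
#' @export
read_filter <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_bcg_filter(x$b, x$a, x$order, x$f_low, x$f_high, x$fs, x$design)
}

#' Split a signal into non-overlapping fixed-length segments
#'
#' Cuts the series into consecutive windows of `window_s` seconds
#' (`window_s * fs` samples, default 30 s), discarding any trailing
#' remainder shorter than one window. Segment indices are 0-based and
#' increase in time order.
#'
#' @param x Numeric vector, or a [bcg_recording()] (in which case `fs`,
#'   `label` and `subject_id` are taken from it).
#' @param fs Sampling rate in Hz.
#' @param window_s Window length in seconds; `fs * window_s` must be a whole
#'   number of samples.
#' @param subject_id,label Provenance carried onto each segment.
#' @return A tibble with columns `subject_id`, `label`, `segment_index` and a
#'   list-column `samples` (each element a numeric vector of exactly
#'   `window_s * fs` samples). Zero rows when the input is shorter than one
#'   window.
#' @export
#' @examples
#' seg <- segment_signal(rnorm(6500), fs = 100, window_s = 30)
#' nrow(seg)  # 2; the trailing 500 samples are dropped
segment_signal <- function(x, fs = 100, window_s = 30,
                           subject_id = "S000", label = "NRT") {
  if (inherits(x, "bcg_recording")) {
    fs <- x$fs; subject_id <- x$subject_id; label <- x$label
    x <- x$samples
  }
  w <- fs * window_s
  if (abs(w - round(w)) > 1e-9) {
    abort("`fs * window_s` must be an integer number of samples.")
  }
  w <- as.integer(round(w))
  n_seg <- length(x) %/% w
  if (n_seg == 0L) {
    return(tibble(subject_id = character(), label = character(),
                  segment_index = integer(), samples = list()))
  }
  segs <- lapply(seq_len(n_seg) - 1L, function(i) x[(i * w + 1L):((i + 1L) * w)])
  tibble(subject_id = subject_id, label = label,
         segment_index = seq_len(n_seg) - 1L, samples = segs)
}

#' Preprocess one recording: normalize, filter, segment
#'
#' The canonical preprocessing chain, in the fixed order normalize ->
#' bandpass filter -> segment. Normalization is computed over the whole
#' (already trimmed) recording, not per segment.
#'
#' @param rec A [bcg_recording()].
#' @param coeffs A `bcg_filter` (default [canonical_filter()]).
#' @param window_s Segmentation window in seconds.
#' @param trim_s Optional duration in seconds to which the recording is
#'   truncated before normalization; `NULL` keeps the full length. An error
#'   is raised if the recording is shorter than `trim_s`.
#' @param zero_phase Passed to [apply_iir_filter()].
#' @return A segment tibble as returned by [segment_signal()].
#' @export
preprocess_recording <- function(rec, coeffs = canonical_filter(),
                                 window_s = 30, trim_s = NULL,
                                 zero_phase = FALSE) {
  stopifnot(inherits(rec, "bcg_recording"))
  x <- rec$samples
  if (!is.null(trim_s)) {
    n_want <- round(trim_s * rec$fs)
    if (length(x) < n_want) {
      abort(sprintf("Recording %s is %.1f s long, shorter than the %.1f s trim.",
                    rec$subject_id, length(x) / rec$fs, trim_s))
    }
    x <- x[seq_len(n_want)]
  }
  x <- mad_zscore(x)$samples
  x <- apply_iir_filter(x, coeffs, zero_phase = zero_phase)
  segment_signal(x, fs = rec$fs, window_s = window_s,
                 subject_id = rec$subject_id, label = rec$label)
}
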