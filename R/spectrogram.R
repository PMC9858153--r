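#' Spectrogram configuration
#'
#' Parameters of the time-frequency imaging stage. Defaults follow the tuned
#' settings of the pipeline: a 128-sample Hann window with 15/16 overlap
#' (hop of 8 samples), a 128-point FFT, power expressed in dB, a relative
#' amplitude threshold that blanks low-energy points, and rendering first at
#' 420 x 560 and then down to the 224 x 224 x 3 classifier input.
#'
#' `threshold_db` is the one consequential free parameter of the imaging
#' stage: every point more than `|threshold_db|` dB below the per-segment
#' maximum is clamped to that floor before color mapping. The default of
#' -40 dB keeps the beat harmonics and suppresses the noise floor; it is
#' deliberately configurable because rendered images (and anything trained
#' on them) are sensitive to it.
#'
#' @param window_type `"hanning"` (symmetric Hann, default) or
#'   `"hanning_periodic"`.
#' @param window_len Analysis window length in samples.
#' @param overlap Overlap between consecutive windows in samples
#'   (default 120 = 15/16 of 128).
#' @param nfft FFT length (>= `window_len`).
#' @param scale `"db_power"` (default) or `"linear"` magnitude-squared.
#' @param threshold_db Relative floor in dB (< 0) applied below the
#'   per-segment maximum; `-Inf` disables thresholding.
#' @param db_floor Absolute dB floor substituted for zero power.
#' @param colormap Name of a `grDevices::hcl.colors()` palette
#'   (default `"viridis"`, perceptually ordered).
#' @param render_size Initial rendered image size (height, width).
#' @param final_size Final image size fed to the classifier (height, width).
#' @return A list of class `spectrogram_config`.
#' @export
spectrogram_config <- function(window_type = c("hanning", "hanning_periodic"),
                               window_len = 128L, overlap = 120L, nfft = 128L,
                               scale = c("db_power", "linear"),
                               threshold_db = -40,
                               db_floor = -120,
                               colormap = "viridis",
                               render_size = c(420L, 560L),
                               final_size = c(224L, 224L)) {
  window_type <- match.arg(window_type)
  scale <- match.arg(scale)
  window_len <- as.integer(window_len); overlap <- as.integer(overlap)
  nfft <- as.integer(nfft)
  if (window_len < 2L) abort("`window_len` must be >= 2.")
  if (overlap < 0L || overlap >= window_len) {
    abort("`overlap` must satisfy 0 <= overlap < window_len.")
  }
  if (nfft < window_len) abort("`nfft` must be >= window_len.")
  if (any(render_size < 1L) || any(final_size < 1L)) {
    abort("Image sizes must be positive.")
  }
  if (!is.infinite(threshold_db) && threshold_db >= 0) {
    abort("`threshold_db` must be negative (a floor below the maximum).")
  }
  structure(list(window_type = window_type, window_len = window_len,
                 overlap = overlap, nfft = nfft, scale = scale,
                 threshold_db = threshold_db, db_floor = db_floor,
                 colormap = colormap,
                 render_size = as.integer(render_size),
                 final_size = as.integer(final_size)),
            class = "spectrogram_config")
}

#' Hann window weights
#'
#' Symmetric Hann taper `0.5 * (1 - cos(2*pi*k/(n-1)))`, k = 0..n-1 (zero at
#' both endpoints), or the periodic variant (period `n`) used by some FFT
#' tooling.
#'
#' @param n Window length (>= 2).
#' @param periodic Logical; use the periodic variant.
#' @return Numeric vector of length `n`.
#' @export
#' @examples
#' hann_window(5)  # 0 0.5 1 0.5 0
hann_window <- function(n, periodic = FALSE) {
  if (!is.numeric(n) || length(n) != 1L || n < 2) {
    abort("`n` must be a single integer >= 2.")
  }
  n <- as.integer(n)
  if (periodic) {
    0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))
  } else {
    as.numeric(signal::hanning(n))
  }
}

#' Short-time Fourier magnitude of a segment
#'
#' Slides the analysis window in hops of `window_len - overlap` samples,
#' windows each frame, and takes the one-sided magnitude-squared DFT
#' (`nfft/2 + 1` frequency rows including DC and Nyquist). With
#' `scale = "db_power"` the result is `10*log10(power)` with `db_floor`
#' substituted for zeros.
#'
#' @param x Numeric vector (a preprocessed segment), length >= `window_len`.
#' @param cfg A [spectrogram_config()].
#' @param fs Sampling rate in Hz (for the frequency/time axes).
#' @return An object of class `bcg_tf`: list with `values`
#'   (frequency rows x time columns), `freq_hz`, `time_s`, `fs`, `scale`.
#' @export
stft_magnitude <- function(x, cfg = spectrogram_config(), fs = 100) {
  if (inherits(x, "bcg_recording")) x <- x$samples
  x <- as.numeric(x)
  W <- cfg$window_len
  if (length(x) < W) {
    abort(sprintf("Segment (%d samples) is shorter than the window (%d).",
                  length(x), W))
  }
  hop <- W - cfg$overlap
  n_frames <- (length(x) - W) %/% hop + 1L
  win <- hann_window(W, periodic = cfg$window_type == "hanning_periodic")
  # frame matrix: W x n_frames
  idx <- outer(seq_len(W), (seq_len(n_frames) - 1L) * hop, "+")
  frames <- matrix(x[idx], nrow = W) * win
  if (cfg$nfft > W) {
    frames <- rbind(frames, matrix(0, cfg$nfft - W, n_frames))
  }
  spec <- stats::mvfft(frames)
  n_bins <- cfg$nfft %/% 2L + 1L
  power <- Mod(spec[seq_len(n_bins), , drop = FALSE])^2
  vals <- if (cfg$scale == "db_power") {
    10 * log10(pmax(power, 10^(cfg$db_floor / 10)))
  } else {
    power
  }
  structure(list(values = vals,
                 freq_hz = (seq_len(n_bins) - 1L) * fs / cfg$nfft,
                 time_s = ((seq_len(n_frames) - 1L) * hop + W / 2) / fs,
                 fs = fs, scale = cfg$scale),
            class = "bcg_tf")
}

#' @export
print.bcg_tf <- function(x, ...) {
  cat(sprintf("<bcg_tf> %d freq bins x %d frames (%s), 0-%g Hz\n",
              nrow(x$values), ncol(x$values), x$scale, max(x$freq_hz)))
  invisible(x)
}

#' Clamp low-amplitude points of a dB spectrogram
#'
#' Every value more than `|threshold_db|` dB below the matrix maximum is
#' raised to that floor, eliminating low-amplitude points before rendering.
#' Idempotent; `threshold_db = -Inf` is the identity.
#'
#' @param tf A `bcg_tf` in dB scale (or a plain numeric matrix of dB values).
#' @param threshold_db Negative number of dB below the maximum.
#' @return Same type as the input, thresholded.
#' @export
threshold_spectrogram <- function(tf, threshold_db = -40) {
  if (!is.infinite(threshold_db) && threshold_db >= 0) {
    abort("`threshold_db` must be negative.")
  }
  vals <- if (inherits(tf, "bcg_tf")) tf$values else tf
  if (inherits(tf, "bcg_tf") && tf$scale != "db_power") {
    abort("Thresholding is defined on dB-scaled spectrograms.")
  }
  if (!is.infinite(threshold_db)) {
    floor_val <- max(vals) + threshold_db
    vals[vals < floor_val] <- floor_val
  }
  if (inherits(tf, "bcg_tf")) {
    tf$values <- vals
    tf
  } else {
    vals
  }
}

# ---- separable linear resampling ----------------------------------------

# Anti-aliased triangle-kernel (bilinear) resampling weights, n_out x n_in.
# When downscaling, the kernel support widens by the scale factor so source
# pixels are averaged rather than skipped. Rows sum to 1, so constants are
# preserved exactly.
resample_weights <- function(n_in, n_out) {
  scale <- n_in / n_out
  s <- max(1, scale)
  Wm <- matrix(0, n_out, n_in)
  centers <- (seq_len(n_out) - 0.5) * scale - 0.5  # 0-based source coords
  half <- s + 1
  for (i in seq_len(n_out)) {
    j0 <- max(0L, floor(centers[i] - half))
    j1 <- min(n_in - 1L, ceiling(centers[i] + half))
    j <- j0:j1
    w <- pmax(0, 1 - abs(j - centers[i]) / s)
    if (sum(w) == 0) {
      j <- max(0L, min(n_in - 1L, round(centers[i])))
      w <- 1
    }
    Wm[i, j + 1L] <- w / sum(w)
  }
  Wm
}

# cache for composed resize operators keyed by dimensions
.resize_cache <- new.env(parent = emptyenv())

resize_operators <- function(n_freq, n_time, render_size, final_size) {
  key <- paste(n_freq, n_time, render_size[1], render_size[2],
               final_size[1], final_size[2], sep = "_")
  hit <- get0(key, envir = .resize_cache)
  if (!is.null(hit)) return(hit)
  A1 <- resample_weights(n_freq, render_size[1])
  B1 <- resample_weights(n_time, render_size[2])
  A2 <- resample_weights(render_size[1], final_size[1])
  B2 <- resample_weights(render_size[2], final_size[2])
  ops <- list(A1 = A1, B1 = B1, A2 = A2, B2 = B2,
              A = A2 %*% A1, B = B2 %*% B1)
  assign(key, ops, envir = .resize_cache)
  ops
}

colormap_lut <- function(name, n = 256L) {
  cols <- grDevices::hcl.colors(n, palette = name)
  t(grDevices::col2rgb(cols)) / 255
}

#' Render a spectrogram matrix as an RGB heat-map image
#'
#' Min-max normalizes the (thresholded) matrix, maps it through a
#' perceptually ordered colormap, places low frequencies at the bottom, and
#' resamples with an anti-aliased bilinear kernel first to `render_size`
#' (420 x 560 by default) and then to `final_size` (224 x 224). The two
#' resampling stages are linear, so they are applied as one fused operator;
#' the result is identical to resizing twice. Axes, ticks and margins are
#' never drawn: the image is the data.
#'
#' A constant matrix (zero dynamic range) renders as a uniform image.
#' Because of the min-max normalization, images are invariant to additive
#' dB offsets.
#'
#' @param tf A `bcg_tf` or numeric matrix (frequency rows x time columns;
#'   row 1 = DC).
#' @param cfg A [spectrogram_config()].
#' @return An object of class `bcg_spec_image`: list with `rgb`
#'   (`final_size[1] x final_size[2] x 3` array in [0, 1]) and `config_hash`.
#' @export
render_heatmap <- function(tf, cfg = spectrogram_config()) {
  vals <- if (inherits(tf, "bcg_tf")) tf$values else as.matrix(tf)
  if (!all(is.finite(vals))) abort("Spectrogram matrix must be finite.")
  rng <- range(vals)
  norm <- if (rng[2] > rng[1]) (vals - rng[1]) / (rng[2] - rng[1]) else
    matrix(0, nrow(vals), ncol(vals))
  lut <- colormap_lut(cfg$colormap)
  idx <- matrix(as.integer(round(norm * (nrow(lut) - 1L))) + 1L,
                nrow(norm), ncol(norm))
  # flip so low frequencies end up at the bottom of the image
  idx <- idx[rev(seq_len(nrow(idx))), , drop = FALSE]
  ops <- resize_operators(nrow(idx), ncol(idx), cfg$render_size, cfg$final_size)
  out <- array(0, c(cfg$final_size[1], cfg$final_size[2], 3L))
  for (ch in 1:3) {
    channel <- matrix(lut[idx, ch], nrow(idx), ncol(idx))
    out[, , ch] <- ops$A %*% channel %*% t(ops$B)
  }
  out[out < 0] <- 0
  out[out > 1] <- 1
  structure(list(rgb = out,
                 config_hash = rlang::hash(unclass(cfg))),
            class = "bcg_spec_image")
}

#' @export
print.bcg_spec_image <- function(x, ...) {
  d <- dim(x$rgb)
  cat(sprintf("<bcg_spec_image> %d x %d x %d, values in [%.3f, %.3f]\n",
              d[1], d[2], d[3], min(x$rgb), max(x$rgb)))
  invisible(x)
}

#' Segment to heat-map image
#'
#' The composed imaging stage: STFT magnitude (dB) -> amplitude threshold ->
#' heat-map rendering. Deterministic: identical segments and configuration
#' give identical images.
#'
#' @param x Numeric vector (one preprocessed segment).
#' @param cfg A [spectrogram_config()].
#' @param fs Sampling rate in Hz.
#' @return A `bcg_spec_image`.
#' @export
spectrogram_image <- function(x, cfg = spectrogram_config(), fs = 100) {
  tf <- stft_magnitude(x, cfg, fs = fs)
  if (cfg$scale == "db_power") {
    tf <- threshold_spectrogram(tf, cfg$threshold_db)
  }
  render_heatmap(tf, cfg)
}

#' Build a spectrogram image set from a segment table
#'
#' Applies [spectrogram_image()] to every row of a segment tibble (as
#' produced by [segment_signal()] / [preprocess_recording()]). With
#' `out_dir` set, each image is written as an 8-bit RGB PNG named
#' `<subject>_<index>.png` and the returned manifest points at the files;
#' otherwise the images are kept in memory as a list-column.
#'
#' @param segments Segment tibble with columns `subject_id`, `label`,
#'   `segment_index`, `samples`.
#' @param cfg A [spectrogram_config()].
#' @param fs Sampling rate in Hz.
#' @param out_dir Optional directory for PNG output.
#' @return A tibble with `image_path` (or list-column `image`), `subject_id`,
#'   `segment_index`, `label`.
#' @export
build_image_set <- function(segments, cfg = spectrogram_config(), fs = 100,
                            out_dir = NULL) {
  stopifnot(all(c("subject_id", "label", "segment_index", "samples") %in%
                  names(segments)))
  n <- nrow(segments)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    paths <- character(n)
    for (i in seq_len(n)) {
      img <- spectrogram_image(segments$samples[[i]], cfg, fs = fs)
      paths[i] <- file.path(out_dir, sprintf("%s_%04d.png",
                                             segments$subject_id[i],
                                             segments$segment_index[i]))
      png::writePNG(img$rgb, paths[i])
    }
    tibble(image_path = paths, subject_id = segments$subject_id,
           segment_index = segments$segment_index, label = segments$label)
  } else {
    imgs <- lapply(seq_len(n), function(i) {
      spectrogram_image(segments$samples[[i]], cfg, fs = fs)$rgb
    })
    tibble(image = imgs, subject_id = segments$subject_id,
           segment_index = segments$segment_index, label = segments$label)
  }
}

#' Stack an image manifest into a 4-d array
#'
#' Reads PNG files (manifest with `image_path`) or stacks in-memory images
#' (manifest with list-column `image`) into an `h x w x 3 x n` array
#' suitable for [train_convmixer()] and [cross_validate()].
#'
#' @param manifest An image manifest tibble from [build_image_set()].
#' @return Numeric 4-d array.
#' @export
image_array <- function(manifest) {
  n <- nrow(manifest)
  if (n == 0L) abort("Empty image manifest.")
  get_img <- if ("image" %in% names(manifest)) {
    function(i) manifest$image[[i]]
  } else {
    function(i) png::readPNG(manifest$image_path[i])
  }
  first <- get_img(1L)
  d <- dim(first)
  out <- array(0, c(d[1], d[2], d[3], n))
  out[, , , 1L] <- first
  if (n > 1L) for (i in 2:n) out[, , , i] <- get_img(i)
  out
}
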