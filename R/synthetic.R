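#' Parameters of the synthetic BCG cohort generator
#'
#' Controls every ingredient of the simulated ballistocardiogram: the class
#' heart-rate distributions (hypertensive subjects beat slightly faster on
#' average than normotensive ones, with heavily overlapping distributions),
#' beat-to-beat interval jitter, a per-subject log-normal amplitude scale
#' emulating body-weight differences, sub-passband baseline wander, broadband
#' sensor noise and an optional mains interference tone. Each heartbeat is a
#' Gaussian-modulated sinusoid standing in for the BCG IJK complex: its energy
#' sits near `beat_center_hz` inside the 1-50 Hz analysis band without
#' claiming physiological morphology.
#'
#' In `"easy"` separation mode the two classes are given disjoint beat wavelet
#' center frequencies (10 Hz for HPT, 4 Hz for NRT) and non-overlapping
#' heart-rate distributions, so their spectrogram signatures are separable by
#' construction; this mode exists for end-to-end checks of the imaging and
#' classification stages, not as a model of real data. In `"realistic"` mode
#' the heart-rate distributions default to published cohort statistics
#' (77.1 +/- 9.2 BPM hypertensive vs 73.6 +/- 8.3 BPM normotensive) and the
#' classes overlap substantially.
#'
#' @param hr_mean_hpt,hr_sd_hpt Heart-rate distribution (BPM) for hypertensive
#'   subjects.
#' @param hr_mean_nrt,hr_sd_nrt Heart-rate distribution (BPM) for normotensive
#'   subjects.
#' @param hrv_jitter Fractional SD of the beat-to-beat interval (0.03 = 3%).
#' @param amp_meanlog,amp_sdlog Log-normal parameters of the per-subject
#'   amplitude scale.
#' @param wander_freq Baseline-wander frequency in Hz; must sit below the
#'   1 Hz passband edge of the bandpass filter.
#' @param wander_amp Baseline-wander amplitude (same arbitrary units as the
#'   unit-amplitude beat wavelet).
#' @param noise_sd SD of additive white sensor noise.
#' @param mains_freq,mains_amp Optional mains interference tone (Hz and
#'   amplitude); `mains_freq = NA` disables it.
#' @param beat_center_hz Center frequency of the Gaussian-modulated beat
#'   wavelet in Hz.
#' @param beat_width_s Full width at half maximum of the wavelet's Gaussian
#'   envelope, in seconds.
#' @param resp_freq,resp_depth Optional respiration-like amplitude modulation
#'   of the beat train (Hz, fractional depth); depth 0 disables it.
#' @param quantize_bits Optional ADC bit depth; `NA` (default) leaves the
#'   series unquantized, 16 emulates a 16-bit converter.
#' @param separation_mode `"realistic"` (default) or `"easy"` (see Details).
#'
#' @return A list of class `synthetic_params`.
#' @export
synthetic_params <- function(hr_mean_hpt = 77.1, hr_sd_hpt = 9.2,
                             hr_mean_nrt = 73.6, hr_sd_nrt = 8.3,
                             hrv_jitter = 0.03,
                             amp_meanlog = 0, amp_sdlog = 0.5,
                             wander_freq = 0.2, wander_amp = 0.5,
                             noise_sd = 0.3,
                             mains_freq = NA_real_, mains_amp = 0,
                             beat_center_hz = 5, beat_width_s = 0.15,
                             resp_freq = 0.25, resp_depth = 0,
                             quantize_bits = NA_integer_,
                             separation_mode = c("realistic", "easy")) {
  separation_mode <- match.arg(separation_mode)
  p <- list(hr_mean_hpt = hr_mean_hpt, hr_sd_hpt = hr_sd_hpt,
            hr_mean_nrt = hr_mean_nrt, hr_sd_nrt = hr_sd_nrt,
            hrv_jitter = hrv_jitter,
            amp_meanlog = amp_meanlog, amp_sdlog = amp_sdlog,
            wander_freq = wander_freq, wander_amp = wander_amp,
            noise_sd = noise_sd,
            mains_freq = mains_freq, mains_amp = mains_amp,
            beat_center_hz = beat_center_hz, beat_width_s = beat_width_s,
            resp_freq = resp_freq, resp_depth = resp_depth,
            quantize_bits = as.integer(quantize_bits),
            separation_mode = separation_mode)
  if (separation_mode == "easy") {
    # separable by construction: disjoint beat wavelet centers (set per label
    # in beat_center_for()), disjoint HR ranges, and wander/noise kept small
    # enough that the beat wavelet is the dominant spectral signature
    p$hr_mean_hpt <- 85; p$hr_sd_hpt <- 1.5
    p$hr_mean_nrt <- 65; p$hr_sd_nrt <- 1.5
    p$wander_amp <- 0.1
    p$noise_sd <- 0.1
  }
  rates <- c(p$hr_mean_hpt, p$hr_sd_hpt, p$hr_mean_nrt, p$hr_sd_nrt,
             p$hrv_jitter, p$noise_sd)
  if (any(!is.finite(rates)) || any(rates[1:4] <= 0) || p$hrv_jitter < 0 ||
      p$noise_sd < 0) {
    abort("Heart-rate parameters must be positive; jitter and noise SD non-negative.")
  }
  if (!is.finite(p$wander_freq) || p$wander_freq <= 0 || p$wander_freq >= 1) {
    abort("`wander_freq` must lie in (0, 1) Hz, below the passband edge.")
  }
  if (p$beat_center_hz <= 0 || p$beat_width_s <= 0) {
    abort("Beat wavelet parameters must be positive.")
  }
  structure(p, class = "synthetic_params")
}

# wavelet center frequency for a label, honoring easy-mode class separation
beat_center_for <- function(params, label) {
  if (params$separation_mode == "easy") {
    return(if (label == "HPT") 10 else 4)
  }
  params$beat_center_hz
}

#' Generate one synthetic BCG recording
#'
#' Simulates a subject of the given class: a heart rate is drawn from the
#' class distribution, a quasi-periodic train of Gaussian-modulated sinusoid
#' wavelets with beat-interval jitter is laid down, scaled by a subject-level
#' log-normal amplitude factor, and baseline wander, white noise and an
#' optional mains tone are added. The construction is fully deterministic for
#' a fixed seed.
#'
#' @param label `"HPT"` or `"NRT"`.
#' @param duration_s Recording duration in seconds (>= 30).
#' @param fs Sampling rate in Hz; must satisfy the Nyquist condition for the
#'   beat wavelet (`fs >= 2 * beat_center_hz`).
#' @param params A [synthetic_params()] object.
#' @param seed Integer seed; the same seed reproduces the recording bit for bit.
#' @param subject_id Subject identifier stored on the recording.
#' @param keep_components Logical; if `TRUE`, attach the noise-free beat train
#'   and the other additive components for inspection and testing.
#'
#' @return A [bcg_recording()] with `round(duration_s * fs)` samples. The
#'   drawn heart rate (BPM), beat times and amplitude scale are attached as
#'   the `meta` attribute.
#' @export
#' @examples
#' rec <- generate_subject("NRT", duration_s = 60, seed = 1)
#' length(rec$samples)  # 6000
generate_subject <- function(label = c("HPT", "NRT"), duration_s, fs = 100,
                             params = synthetic_params(), seed = 1L,
                             subject_id = NULL,
                             keep_components = FALSE) {
  label <- match.arg(label)
  stopifnot(inherits(params, "synthetic_params"))
  if (!is.numeric(duration_s) || length(duration_s) != 1L ||
      !is.finite(duration_s) || duration_s < 30) {
    abort("`duration_s` must be a single number >= 30 seconds.")
  }
  f_beat <- beat_center_for(params, label)
  if (!is.numeric(fs) || fs <= 0 || fs < 2 * f_beat) {
    abort(sprintf(
      "`fs` must be positive and at least twice the beat center frequency (%g Hz).",
      f_beat))
  }
  if (is.null(subject_id)) subject_id <- sprintf("%s_s%d", label, seed)

  n <- round(duration_s * fs)
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))

  if (label == "HPT") {
    hr <- rnorm(1, params$hr_mean_hpt, params$hr_sd_hpt)
  } else {
    hr <- rnorm(1, params$hr_mean_nrt, params$hr_sd_nrt)
  }
  hr <- min(max(hr, 40), 150)
  amp_scale <- rlnorm(1, params$amp_meanlog, params$amp_sdlog)

  # beat times: jittered intervals around 60/hr seconds
  base_ivl <- 60 / hr
  n_beats_max <- ceiling(duration_s / base_ivl * 1.5) + 8L
  ivls <- base_ivl * pmax(0.5, 1 + rnorm(n_beats_max, 0, params$hrv_jitter))
  beat_times <- cumsum(ivls)
  beat_times <- beat_times[beat_times < duration_s]

  sigma <- params$beat_width_s / (2 * sqrt(2 * log(2)))  # FWHM -> sd
  t <- (seq_len(n) - 1) / fs
  beats <- numeric(n)
  half_support <- ceiling(4 * sigma * fs)
  for (tb in beat_times) {
    ic <- round(tb * fs) + 1
    idx <- max(1L, ic - half_support):min(n, ic + half_support)
    dt <- t[idx] - tb
    beats[idx] <- beats[idx] +
      sin(2 * pi * f_beat * dt) * exp(-dt^2 / (2 * sigma^2))
  }
  if (params$resp_depth > 0) {
    beats <- beats * (1 + params$resp_depth * sin(2 * pi * params$resp_freq * t))
  }

  wander <- params$wander_amp * sin(2 * pi * params$wander_freq * t + runif(1, 0, 2 * pi))
  noise <- rnorm(n, 0, params$noise_sd)
  x <- amp_scale * beats + wander + noise
  if (!is.na(params$mains_freq) && params$mains_amp > 0) {
    x <- x + params$mains_amp * sin(2 * pi * params$mains_freq * t + runif(1, 0, 2 * pi))
  }
  bit_depth <- NA_integer_
  if (!is.na(params$quantize_bits)) {
    bit_depth <- params$quantize_bits
    full <- max(abs(x))
    if (full > 0) {
      levels <- 2^(bit_depth - 1) - 1
      x <- round(x / full * levels) / levels * full
    }
  }

  rec <- bcg_recording(x, fs = fs, label = label, subject_id = subject_id,
                       bit_depth = bit_depth)
  rec$meta <- list(hr_bpm = hr, beat_times = beat_times,
                   amplitude_scale = amp_scale, beat_center_hz = f_beat)
  if (keep_components) {
    rec$components <- list(beats = amp_scale * beats, wander = wander,
                           noise = noise)
  }
  rec
}

#' Generate a synthetic BCG cohort
#'
#' Generates `n_hpt` hypertensive and `n_nrt` normotensive recordings with
#' unique subject ids and per-subject seeds derived deterministically from the
#' master seed, plus a cohort manifest. When `out_dir` is given, recordings
#' are written as single-column text files and the manifest as
#' `manifest.csv` alongside them.
#'
#' @param n_hpt,n_nrt Number of subjects per class (>= 1 each).
#' @param duration_s Duration per recording in seconds.
#' @param params A [synthetic_params()] object.
#' @param seed Master seed; the whole cohort is reproducible from it.
#' @param fs Sampling rate in Hz.
#' @param out_dir Optional output directory; `NULL` keeps the cohort in memory.
#'
#' @return A list with `manifest` (tibble: subject_id, label, path,
#'   duration_s) and `recordings` (named list of [bcg_recording()]).
#' @export
generate_cohort <- function(n_hpt, n_nrt, duration_s, params = synthetic_params(),
                            seed = 1L, fs = 100, out_dir = NULL) {
  if (!is.numeric(n_hpt) || !is.numeric(n_nrt) || n_hpt < 1 || n_nrt < 1) {
    abort("`n_hpt` and `n_nrt` must both be >= 1.")
  }
  n_hpt <- as.integer(n_hpt); n_nrt <- as.integer(n_nrt)
  labels <- c(rep("HPT", n_hpt), rep("NRT", n_nrt))
  ids <- c(sprintf("HPT%03d", seq_len(n_hpt)), sprintf("NRT%03d", seq_len(n_nrt)))
  n_total <- n_hpt + n_nrt
  sub_seeds <- (as.numeric(seed) + 7919 * seq_len(n_total)) %% 2147483647

  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  recs <- vector("list", n_total)
  paths <- rep(NA_character_, n_total)
  for (i in seq_len(n_total)) {
    recs[[i]] <- generate_subject(labels[i], duration_s = duration_s, fs = fs,
                                  params = params, seed = sub_seeds[i],
                                  subject_id = ids[i])
    if (!is.null(out_dir)) {
      paths[i] <- file.path(out_dir, paste0(ids[i], ".txt"))
      write_recording(recs[[i]], paths[i])
    }
  }
  names(recs) <- ids
  manifest <- tibble(subject_id = ids, label = labels, path = paths,
                     duration_s = duration_s)
  if (!is.null(out_dir)) {
    write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  }
  list(manifest = manifest, recordings = recs)
}
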