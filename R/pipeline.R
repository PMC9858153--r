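#' Full pipeline configuration
#'
#' One nested, schema-checked configuration object covering every stage:
#' synthetic cohort parameters, the filter choice, segmentation window,
#' spectrogram settings, model and training hyperparameters, evaluation
#' protocol and the equal-count experiment's trim rule. Every default equals
#' the pipeline's canonical value (30 s window; Hann 128 / overlap 120 /
#' NFFT 128; 420 x 560 then 224 x 224 images; patch 5 / hidden 32 / depth 7;
#' sgdm, batch 64, 7 epochs, lr 0.001; k = 10; trim 50 min). Unknown keys
#' are rejected.
#'
#' @param synthetic A [synthetic_params()].
#' @param filter `"canonical"` (the fixed printed coefficients) or a
#'   `bcg_filter` from [design_cheby2_bandpass()].
#' @param zero_phase Logical; forward-backward filtering.
#' @param window_s Segmentation window in seconds.
#' @param spectrogram A [spectrogram_config()].
#' @param model A [convmixer_config()].
#' @param training A [train_config()].
#' @param k Cross-validation folds.
#' @param grouping `"image_level"` (the default protocol: random split over
#'   images) or `"subject_level"` (no subject spans folds; see
#'   [kfold_split()] for why this matters).
#' @param trim_minutes Minutes each recording is truncated to in the
#'   equal-count experiment.
#' @param seed Master seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_params(),
                            filter = "canonical",
                            zero_phase = FALSE,
                            window_s = 30,
                            spectrogram = spectrogram_config(),
                            model = convmixer_config(),
                            training = train_config(),
                            k = 10L,
                            grouping = c("image_level", "subject_level"),
                            trim_minutes = 50,
                            seed = 1L) {
  grouping <- match.arg(grouping)
  if (!(identical(filter, "canonical") || inherits(filter, "bcg_filter"))) {
    abort("`filter` must be \"canonical\" or a bcg_filter object.")
  }
  stopifnot(inherits(synthetic, "synthetic_params"),
            inherits(spectrogram, "spectrogram_config"),
            inherits(model, "convmixer_config"),
            inherits(training, "train_config"))
  if (window_s <= 0 || trim_minutes <= 0 || k < 2) {
    abort("window_s and trim_minutes must be positive; k >= 2.")
  }
  structure(list(synthetic = synthetic, filter = filter,
                 zero_phase = zero_phase, window_s = window_s,
                 spectrogram = spectrogram, model = model,
                 training = training, k = as.integer(k),
                 grouping = grouping, trim_minutes = trim_minutes,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Hash of a pipeline configuration
#'
#' Stable fingerprint stamped into run records so artifacts can be traced
#' to the exact configuration that produced them.
#'
#' @param cfg A `pipeline_config`.
#' @return Character hash.
#' @export
config_hash <- function(cfg) {
  rlang::hash(rapply(unclass(cfg), unclass, how = "replace"))
}

resolve_filter <- function(cfg) {
  if (identical(cfg$filter, "canonical")) canonical_filter() else cfg$filter
}

#' Run the equal-count experiment end to end
#'
#' The first-experiment protocol: every recording is trimmed to
#' `trim_minutes` (recordings shorter than that are rejected by name),
#' preprocessed (normalize, bandpass filter, 30-s segmentation), imaged as
#' spectrogram heat maps, and optionally evaluated with k-fold
#' cross-validation of the ConvMixer. With 61 + 67 subjects at 50 minutes
#' each this yields exactly 100 segments per subject and 12,800 images
#' (6,100 hypertensive, 6,700 normotensive).
#'
#' @param cohort A list with `manifest` and `recordings` (as from
#'   [generate_cohort()]), or a manifest tibble whose `path` column points
#'   at recording files.
#' @param cfg A [pipeline_config()].
#' @param out_dir Directory for PNG images and CSV/JSON artifacts.
#' @param run_cv Logical; run the cross-validation stage (training k models
#'   can dominate the runtime, so accounting-only runs may disable it).
#' @param verbose Print per-stage progress.
#' @return A run record: list with `config_hash`, `counts` (per-stage item
#'   counts), `image_manifest`, `cv` (a `bcg_cv` or `NULL`), `timings`
#'   (seconds per stage) and `out_dir`.
#' @export
run_experiment1 <- function(cohort, cfg = pipeline_config(), out_dir,
                            run_cv = TRUE, verbose = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (is.data.frame(cohort)) cohort <- list(manifest = cohort, recordings = NULL)
  manifest <- validate_manifest(cohort$manifest)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  coeffs <- resolve_filter(cfg)
  trim_s <- cfg$trim_minutes * 60
  fs_used <- NULL
  timings <- c()

  get_rec <- function(i) {
    if (!is.null(cohort$recordings)) {
      cohort$recordings[[manifest$subject_id[i]]]
    } else {
      read_recording(manifest$path[i], label = manifest$label[i],
                     subject_id = manifest$subject_id[i])
    }
  }

  t0 <- Sys.time()
  img_dir <- file.path(out_dir, "images")
  if (!dir.exists(img_dir)) dir.create(img_dir)
  image_manifests <- vector("list", nrow(manifest))
  n_segments <- 0L
  for (i in seq_len(nrow(manifest))) {
    rec <- get_rec(i)
    fs_used <- rec$fs
    segs <- preprocess_recording(rec, coeffs, window_s = cfg$window_s,
                                 trim_s = trim_s, zero_phase = cfg$zero_phase)
    n_segments <- n_segments + nrow(segs)
    image_manifests[[i]] <- build_image_set(segs, cfg$spectrogram,
                                            fs = rec$fs, out_dir = img_dir)
    if (verbose && i %% 16 == 0) {
      message(sprintf("  imaged %d/%d subjects", i, nrow(manifest)))
    }
  }
  image_manifest <- dplyr::bind_rows(image_manifests)
  readr::write_csv(image_manifest, file.path(out_dir, "image_manifest.csv"),
                   progress = FALSE)
  timings["images"] <- as.numeric(difftime(Sys.time(), t0, units = "secs"))

  counts <- list(
    n_subjects = nrow(manifest),
    n_segments = n_segments,
    n_images = nrow(image_manifest),
    n_images_hpt = sum(image_manifest$label == "HPT"),
    n_images_nrt = sum(image_manifest$label == "NRT")
  )
  if (counts$n_segments != counts$n_images) {
    abort("Stage count mismatch: segments in != images out.")
  }

  cv <- NULL
  if (run_cv) {
    t0 <- Sys.time()
    groups <- if (cfg$grouping == "subject_level") image_manifest$subject_id
              else NULL
    tc <- cfg$training
    tc$seed <- cfg$seed
    cv <- cross_validate(image_manifest, model_cfg = cfg$model, tc = tc,
                         k = cfg$k, groups = groups, seed = cfg$seed,
                         verbose = verbose)
    timings["cv"] <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    readr::write_csv(cv$fold_metrics, file.path(out_dir, "fold_metrics.csv"),
                     progress = FALSE)
    readr::write_csv(tidy(cv$cumulative),
                     file.path(out_dir, "cumulative_confusion.csv"),
                     progress = FALSE)
    jsonlite::write_json(as.list(cv$mean_metrics),
                         file.path(out_dir, "mean_metrics.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  record <- list(config_hash = config_hash(cfg),
                 package_version = as.character(utils::packageVersion("bcgmixer")),
                 timestamp = format(Sys.time(), tz = "UTC"),
                 fs = fs_used,
                 counts = counts,
                 timings = timings,
                 image_manifest = image_manifest,
                 cv = cv,
                 out_dir = out_dir)
  jsonlite::write_json(
    list(config_hash = record$config_hash,
         package_version = record$package_version,
         timestamp = record$timestamp, counts = counts,
         timings = as.list(timings)),
    file.path(out_dir, "run_record.json"), auto_unbox = TRUE, digits = NA)
  class(record) <- "bcg_run_record"
  record
}

#' @export
print.bcg_run_record <- function(x, ...) {
  cat(sprintf("<bcg_run_record> %d subjects -> %d segments -> %d images (%d HPT / %d NRT)\n",
              x$counts$n_subjects, x$counts$n_segments, x$counts$n_images,
              x$counts$n_images_hpt, x$counts$n_images_nrt))
  cat(sprintf("  config %s, artifacts in %s\n", substr(x$config_hash, 1, 10),
              x$out_dir))
  if (!is.null(x$cv)) print(x$cv)
  invisible(x)
}
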