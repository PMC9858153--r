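#' Random k-fold assignment
#'
#' Partitions `n_items` into `k` folds whose sizes differ by at most one.
#' With `groups` given (e.g. subject ids), whole groups are assigned to
#' folds instead, so no group is ever split across folds; this is the
#' leakage-free alternative to the default image-level split, in which
#' segments of one subject can land on both sides of a train/test boundary.
#'
#' @param n_items Number of items (>= k).
#' @param k Number of folds (>= 2).
#' @param seed Integer seed; assignment is deterministic per seed.
#' @param groups Optional vector of length `n_items` of group ids for
#'   subject-level splitting.
#' @return An object of class `fold_plan`: list with `k`, `assignment`
#'   (integer vector in 1..k, one per item), `grouping`, `seed`.
#' @export
kfold_split <- function(n_items, k = 10L, seed = 1L, groups = NULL) {
  n_items <- as.integer(n_items); k <- as.integer(k)
  if (k < 2L) abort("`k` must be >= 2.")
  if (n_items < k) abort("`k` cannot exceed the number of items.")
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))

  if (is.null(groups)) {
    # sizes differ by <= 1; remainder spread one per fold
    sizes <- rep(n_items %/% k, k) + (seq_len(k) <= n_items %% k)
    assignment <- integer(n_items)
    assignment[sample.int(n_items)] <- rep(seq_len(k), times = sizes)
    grouping <- "image_level"
  } else {
    if (length(groups) != n_items) {
      abort("`groups` must have one entry per item.")
    }
    gids <- unique(groups)
    if (length(gids) < k) abort("Fewer groups than folds.")
    g_fold <- integer(length(gids))
    g_fold[sample.int(length(gids))] <- rep(seq_len(k),
                                            length.out = length(gids))
    assignment <- g_fold[match(groups, gids)]
    grouping <- "subject_level"
  }
  structure(list(k = k, assignment = assignment, grouping = grouping,
                 seed = as.integer(seed)),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> k = %d, %s, sizes: %s\n", x$k, x$grouping,
              paste(tabulate(x$assignment, x$k), collapse = " ")))
  invisible(x)
}

#' Confusion counts with the hypertensive class positive
#'
#' @param y_true,y_pred Label vectors of equal length with values `"HPT"` /
#'   `"NRT"`.
#' @param positive The positive class (default `"HPT"`).
#' @return An object of class `confusion_counts`: list with `tp`, `fp`,
#'   `fn`, `tn`, `positive`.
#' @export
confusion_counts <- function(y_true, y_pred, positive = "HPT") {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred) || length(y_true) < 1L) {
    abort("`y_true` and `y_pred` must be equal-length, non-empty vectors.")
  }
  ok <- c("HPT", "NRT")
  bad <- setdiff(unique(c(y_true, y_pred)), ok)
  if (length(bad) > 0L) {
    abort(sprintf("Unknown label value(s): %s", paste(bad, collapse = ", ")))
  }
  pos_t <- y_true == positive
  pos_p <- y_pred == positive
  structure(list(tp = sum(pos_t & pos_p), fp = sum(!pos_t & pos_p),
                 fn = sum(pos_t & !pos_p), tn = sum(!pos_t & !pos_p),
                 positive = positive),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> (+ = %s) tp %d  fp %d  fn %d  tn %d\n",
              x$positive, x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' @export
`+.confusion_counts` <- function(e1, e2) {
  stopifnot(identical(e1$positive, e2$positive))
  structure(list(tp = e1$tp + e2$tp, fp = e1$fp + e2$fp,
                 fn = e1$fn + e2$fn, tn = e1$tn + e2$tn,
                 positive = e1$positive),
            class = "confusion_counts")
}

safe_ratio <- function(num, den) {
  if (den == 0) list(value = 0, degenerate = TRUE)
  else list(value = num / den, degenerate = FALSE)
}

#' Classification metrics from confusion counts
#'
#' Accuracy, per-class precision/recall/F1 and their macro averages, all in
#' percent. Ratios with zero denominators (e.g. precision when a class is
#' never predicted) are reported as 0, flagged in the `degenerate` column,
#' and accompanied by a warning.
#'
#' @param conf A `confusion_counts`.
#' @return A tibble with rows `HPT`, `NRT`, `macro` and columns `class`,
#'   `accuracy`, `precision`, `recall`, `f1`, `degenerate` (percent scale).
#' @export
metrics_report <- function(conf) {
  stopifnot(inherits(conf, "confusion_counts"))
  n <- conf$tp + conf$fp + conf$fn + conf$tn
  if (n == 0) abort("Empty confusion counts.")
  acc <- (conf$tp + conf$tn) / n

  one_class <- function(tp, fp, fn) {
    p <- safe_ratio(tp, tp + fp)
    r <- safe_ratio(tp, tp + fn)
    f <- safe_ratio(2 * p$value * r$value, p$value + r$value)
    list(precision = p$value, recall = r$value, f1 = f$value,
         degenerate = p$degenerate || r$degenerate || f$degenerate)
  }
  pos <- one_class(conf$tp, conf$fp, conf$fn)
  neg <- one_class(conf$tn, conf$fn, conf$fp)  # swap roles for the other class
  if (pos$degenerate || neg$degenerate) {
    warn("Some metrics had zero denominators and were reported as 0.")
  }
  classes <- if (conf$positive == "HPT") c("HPT", "NRT") else c("NRT", "HPT")
  tibble(
    class = c(classes, "macro"),
    accuracy = 100 * acc,
    precision = 100 * c(pos$precision, neg$precision,
                        (pos$precision + neg$precision) / 2),
    recall = 100 * c(pos$recall, neg$recall, (pos$recall + neg$recall) / 2),
    f1 = 100 * c(pos$f1, neg$f1, (pos$f1 + neg$f1) / 2),
    degenerate = c(pos$degenerate, neg$degenerate,
                   pos$degenerate || neg$degenerate)
  )
}

#' k-fold cross-validation of the ConvMixer on a spectrogram image set
#'
#' For each fold, trains a freshly initialized model on the other k-1 folds
#' and scores the held-out fold. Reports per-fold metrics, their arithmetic
#' mean (the "average k-fold" convention of standard reporting), and the
#' cumulative confusion counts summed over test folds (each image is tested
#' exactly once).
#'
#' @param images `h x w x c x n` array, or an image manifest tibble from
#'   [build_image_set()] (PNG paths are then read per fold).
#' @param labels Class labels, length n (taken from the manifest when one
#'   is supplied).
#' @param model_cfg A [convmixer_config()].
#' @param tc A [train_config()]; its seed, combined with the fold number,
#'   seeds each fold's initialization and shuffling.
#' @param k Number of folds (ignored when `fold_plan` is given).
#' @param fold_plan Optional [kfold_split()] result, for persisted/auditable
#'   assignments.
#' @param groups Optional subject ids for subject-level splitting.
#' @param seed Seed for the fold assignment when `fold_plan` is `NULL`.
#' @param verbose Print per-fold progress.
#' @return An object of class `bcg_cv`: list with `fold_metrics` (tibble),
#'   `mean_metrics` (tibble), `cumulative` (`confusion_counts`),
#'   `fold_plan`, `histories` (list of training histories).
#' @export
cross_validate <- function(images, labels = NULL,
                           model_cfg = convmixer_config(),
                           tc = train_config(), k = 10L, fold_plan = NULL,
                           groups = NULL, seed = 1L, verbose = FALSE) {
  manifest <- NULL
  if (is.data.frame(images)) {
    manifest <- images
    labels <- manifest$label
    if (is.null(groups) && "subject_id" %in% names(manifest)) {
      # groups only used if explicitly requested via grouping arg upstream
    }
    n <- nrow(manifest)
  } else {
    n <- dim(images)[4]
  }
  if (is.null(labels) || length(labels) != n) {
    abort("`labels` must be provided with one entry per image.")
  }
  if (is.null(fold_plan)) {
    fold_plan <- kfold_split(n, k = k, seed = seed, groups = groups)
  }
  k <- fold_plan$k
  if (length(fold_plan$assignment) != n) {
    abort("Fold plan does not match the number of images.")
  }

  fetch <- function(idx) {
    if (is.null(manifest)) {
      images[, , , idx, drop = FALSE]
    } else {
      image_array(manifest[idx, , drop = FALSE])
    }
  }

  fold_metrics <- list(); histories <- list(); cumulative <- NULL
  for (fold in seq_len(k)) {
    te <- which(fold_plan$assignment == fold)
    tr <- which(fold_plan$assignment != fold)
    if (length(unique(labels[tr])) < 2L) {
      abort(sprintf("Fold %d has a single-class training split.", fold))
    }
    tc_fold <- tc
    tc_fold$seed <- tc$seed + fold
    model <- build_convmixer(model_cfg, seed = tc_fold$seed)
    model <- train_convmixer(model, fetch(tr), labels[tr], tc_fold)
    pred <- predict(model, fetch(te), type = "class")
    conf <- confusion_counts(labels[te], pred)
    cumulative <- if (is.null(cumulative)) conf else cumulative + conf
    m <- metrics_report(conf)
    fold_metrics[[fold]] <- dplyr::mutate(m, fold = fold, .before = 1)
    histories[[fold]] <- model$history
    if (verbose) {
      message(sprintf("fold %d/%d: accuracy %.2f%%", fold, k,
                      m$accuracy[m$class == "macro"]))
    }
  }
  fold_metrics <- dplyr::bind_rows(fold_metrics)
  mean_metrics <- fold_metrics %>%
    group_by(.data$class) %>%
    summarise(accuracy = mean(.data$accuracy),
              precision = mean(.data$precision),
              recall = mean(.data$recall),
              f1 = mean(.data$f1), .groups = "drop")
  structure(list(fold_metrics = fold_metrics, mean_metrics = mean_metrics,
                 cumulative = cumulative, fold_plan = fold_plan,
                 histories = histories),
            class = "bcg_cv")
}

#' @export
print.bcg_cv <- function(x, ...) {
  mm <- x$mean_metrics[x$mean_metrics$class == "macro", ]
  cat(sprintf(
    "<bcg_cv> %d-fold (%s): mean accuracy %.2f%%, macro precision %.2f%%, recall %.2f%%, F1 %.2f%%\n",
    x$fold_plan$k, x$fold_plan$grouping, mm$accuracy, mm$precision,
    mm$recall, mm$f1))
  print(x$cumulative)
  invisible(x)
}
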