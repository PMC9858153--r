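#' Tidy confusion counts
#'
#' @param x A `confusion_counts`.
#' @param ... Unused.
#' @return A one-row tibble with `tp`, `fp`, `fn`, `tn`, `n`, `positive`.
#' @method tidy confusion_counts
#' @export
tidy.confusion_counts <- function(x, ...) {
  tibble(tp = x$tp, fp = x$fp, fn = x$fn, tn = x$tn,
         n = x$tp + x$fp + x$fn + x$tn, positive = x$positive)
}

#' Tidy cross-validation results
#'
#' `tidy()` returns the per-fold metric table; `glance()` returns a one-row
#' summary of the fold-averaged macro metrics (the headline numbers).
#'
#' @param x A `bcg_cv` object from [cross_validate()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy bcg_cv
#' @export
tidy.bcg_cv <- function(x, ...) {
  x$fold_metrics
}

#' @rdname tidy.bcg_cv
#' @method glance bcg_cv
#' @export
glance.bcg_cv <- function(x, ...) {
  mm <- x$mean_metrics[x$mean_metrics$class == "macro", ]
  tibble(k = x$fold_plan$k, grouping = x$fold_plan$grouping,
         mean_accuracy = mm$accuracy, macro_precision = mm$precision,
         macro_recall = mm$recall, macro_f1 = mm$f1,
         n = x$cumulative$tp + x$cumulative$fp + x$cumulative$fn +
           x$cumulative$tn)
}

#' Model summary
#'
#' @param x A `convmixer_model`.
#' @param ... Unused.
#' @return A one-row tibble: parameter count, architecture fields, trained
#'   flag.
#' @method glance convmixer_model
#' @export
glance.convmixer_model <- function(x, ...) {
  g <- patch_grid(x$cfg)
  tibble(n_parameters = count_parameters(x), patch = x$cfg$patch,
         hidden_dim = x$cfg$hidden_dim, depth = x$cfg$depth,
         kernel = x$cfg$kernel, grid_h = g[1], grid_w = g[2],
         n_classes = x$cfg$n_classes, trained = x$trained)
}

#' Plot a spectrogram matrix
#'
#' Heat map of a `bcg_tf` with time on the x axis and frequency on the y
#' axis (low frequencies at the bottom), colored with the same perceptually
#' ordered palette the imaging stage uses.
#'
#' @param object A `bcg_tf` from [stft_magnitude()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bcg_tf
#' @export
autoplot.bcg_tf <- function(object, ...) {
  df <- expand.grid(time_s = object$time_s, freq_hz = object$freq_hz)
  df$value <- as.vector(t(object$values))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$freq_hz,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(
      name = if (object$scale == "db_power") "power (dB)" else "power") +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)") +
    ggplot2::theme_minimal()
}

#' Plot a training history
#'
#' Loss per iteration with train/validation accuracy overlaid where logged.
#'
#' @param object A `convmixer_history` tibble (the `history` element of a
#'   trained model).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot convmixer_history
#' @export
autoplot.convmixer_history <- function(object, ...) {
  df <- as_tibble(object)
  long <- dplyr::bind_rows(
    tibble(iteration = df$iteration, value = df$loss, series = "loss"),
    tibble(iteration = df$iteration, value = df$train_acc,
           series = "train accuracy"),
    tibble(iteration = df$iteration, value = df$val_acc,
           series = "validation accuracy"))
  long <- long[!is.na(long$value), ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iteration, y = .data$value,
                                     color = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~ series, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "iteration", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Plot per-fold cross-validation accuracy
#'
#' @param object A `bcg_cv`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bcg_cv
#' @export
autoplot.bcg_cv <- function(object, ...) {
  df <- object$fold_metrics[object$fold_metrics$class == "macro", ]
  mm <- mean(df$accuracy)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$fold), y = .data$accuracy)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = mm, linetype = "dashed") +
    ggplot2::labs(x = "fold", y = "accuracy (%)",
                  subtitle = sprintf("mean %.2f%%", mm)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
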