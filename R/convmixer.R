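#' ConvMixer architecture configuration
#'
#' Hyperparameters of the patch-based all-convolutional classifier. The
#' defaults are the configuration used throughout the pipeline: 224 x 224 x 3
#' input, 5 x 5 patch embedding with 32 hidden channels, 7 mixer blocks and a
#' 5 x 5 same-padded depthwise kernel, giving 16,674 trainable parameters.
#'
#' Each mixer block applies a residual-wrapped spatial mixing stage
#' (depthwise convolution -> GELU -> batch norm, with the block input added
#' back) followed by channel mixing (pointwise 1 x 1 convolution -> GELU ->
#' batch norm). `residual = "pre_act"` selects the variant in which the
#' block input is added to the depthwise output *before* the activation,
#' for users who prefer that reading of the architecture; the default
#' `"post_norm"` is the reference ConvMixer ordering.
#'
#' @param input_size Integer vector (height, width, channels).
#' @param patch Patch size p; the embedding is a valid (no-padding)
#'   convolution with kernel p x p and stride p.
#' @param hidden_dim Embedding width h (channels through all blocks).
#' @param depth Number of mixer blocks.
#' @param kernel Depthwise kernel size (odd; same padding).
#' @param n_classes Number of output classes.
#' @param residual `"post_norm"` (default) or `"pre_act"` (see Details).
#' @param bn_eps Batch-normalization variance epsilon.
#' @return A list of class `convmixer_config`.
#' @export
convmixer_config <- function(input_size = c(224L, 224L, 3L), patch = 5L,
                             hidden_dim = 32L, depth = 7L, kernel = 5L,
                             n_classes = 2L,
                             residual = c("post_norm", "pre_act"),
                             bn_eps = 1e-5) {
  residual <- match.arg(residual)
  patch <- as.integer(patch); hidden_dim <- as.integer(hidden_dim)
  depth <- as.integer(depth); kernel <- as.integer(kernel)
  n_classes <- as.integer(n_classes)
  if (patch < 1L || hidden_dim < 1L || depth < 1L || n_classes < 1L) {
    abort("patch, hidden_dim, depth and n_classes must all be >= 1.")
  }
  if (kernel %% 2L == 0L) {
    abort("`kernel` must be odd (same-padded depthwise convolution).")
  }
  input_size <- as.integer(input_size)
  if (length(input_size) != 3L || any(input_size < 1L)) {
    abort("`input_size` must be (height, width, channels).")
  }
  if (input_size[1] < patch || input_size[2] < patch) {
    abort("Input must be at least one patch in each spatial dimension.")
  }
  structure(list(input_size = input_size, patch = patch,
                 hidden_dim = hidden_dim, depth = depth, kernel = kernel,
                 n_classes = n_classes, residual = residual, bn_eps = bn_eps),
            class = "convmixer_config")
}

#' Training configuration for the ConvMixer
#'
#' Stochastic gradient descent with momentum ("sgdm"), the optimizer the
#' architecture is trained with throughout: minibatch 64, 7 epochs, initial
#' learning rate 0.001, momentum 0.9, cross-entropy loss. A fraction of the
#' training split is held out as a validation stream for curve logging, and
#' inputs are zero-centered per channel using training-split means.
#'
#' @param batch_size Minibatch size.
#' @param epochs Maximum number of epochs.
#' @param lr Initial (and only; no schedule) learning rate.
#' @param momentum SGD momentum coefficient.
#' @param validation_fraction Fraction of the training data held out for
#'   validation-curve logging (0 disables it).
#' @param seed Integer seed governing initialization, shuffling and the
#'   validation split.
#' @param bn_momentum Exponential decay of the running batch-norm statistics.
#' @param finalize_bn Logical; after training, recompute inference
#'   batch-norm statistics in one pass over the training data.
#' @return A list of class `train_config`.
#' @export
train_config <- function(batch_size = 64L, epochs = 7L, lr = 0.001,
                         momentum = 0.9, validation_fraction = 0.1,
                         seed = 1L, bn_momentum = 0.9, finalize_bn = TRUE) {
  if (batch_size < 1 || epochs < 1 || lr <= 0 || momentum < 0 ||
      momentum >= 1 || validation_fraction < 0 || validation_fraction >= 1) {
    abort("Invalid training configuration.")
  }
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr = lr, momentum = momentum,
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed), bn_momentum = bn_momentum,
                 finalize_bn = isTRUE(finalize_bn)),
            class = "train_config")
}

cfg_to_cpp <- function(cfg) {
  list(in_h = cfg$input_size[1], in_w = cfg$input_size[2],
       in_c = cfg$input_size[3], patch = cfg$patch, hdim = cfg$hidden_dim,
       depth = cfg$depth, k = cfg$kernel, n_classes = cfg$n_classes,
       pre_act = cfg$residual == "pre_act", bn_eps = cfg$bn_eps)
}

#' Spatial grid size after patch embedding
#'
#' @param cfg A [convmixer_config()].
#' @return Integer vector (grid height, grid width); 44 x 44 at the defaults.
#' @export
patch_grid <- function(cfg) {
  c((cfg$input_size[1] - cfg$patch) %/% cfg$patch + 1L,
    (cfg$input_size[2] - cfg$patch) %/% cfg$patch + 1L)
}

#' Build (initialize) a ConvMixer model
#'
#' Allocates the full layer stack — patch embedding convolution, GELU, batch
#' norm, `depth` mixer blocks (residual depthwise stage + pointwise stage),
#' global average pooling and a softmax head — with He-normal weight
#' initialization, zero biases, unit batch-norm gains.
#'
#' @param cfg A [convmixer_config()].
#' @param classes Character vector of class names, in output-unit order
#'   (default `c("HPT", "NRT")`).
#' @param seed Integer seed for the weight initialization.
#' @return An object of class `convmixer_model`: list with `cfg`, `params`,
#'   running batch-norm statistics, `classes`, `channel_means` and a
#'   `trained` flag.
#' @export
build_convmixer <- function(cfg = convmixer_config(),
                            classes = c("HPT", "NRT"), seed = 1L) {
  stopifnot(inherits(cfg, "convmixer_config"))
  if (length(classes) != cfg$n_classes) {
    abort("`classes` must have length `n_classes`.")
  }
  h <- cfg$hidden_dim; d <- cfg$depth; k <- cfg$kernel
  pp_c <- cfg$patch^2 * cfg$input_size[3]
  n_bn <- 2L * d + 1L

  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))

  he <- function(nr, nc, fan_in) matrix(rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
  params <- list(
    We = he(h, pp_c, pp_c),
    be = numeric(h),
    bn_gamma = matrix(1, h, n_bn),
    bn_beta = matrix(0, h, n_bn),
    dwW = array(rnorm(h * k^2 * d, 0, sqrt(2 / k^2)), c(h, k^2, d)),
    dwb = matrix(0, h, d),
    pwW = array(rnorm(h * h * d, 0, sqrt(2 / h)), c(h, h, d)),
    pwb = matrix(0, h, d),
    fcW = he(cfg$n_classes, h, h),
    fcb = numeric(cfg$n_classes)
  )
  structure(list(cfg = cfg, params = params,
                 bn_mean = matrix(0, h, n_bn),
                 bn_var = matrix(1, h, n_bn),
                 classes = as.character(classes),
                 channel_means = numeric(cfg$input_size[3]),
                 trained = FALSE,
                 history = NULL),
            class = "convmixer_model")
}

#' @export
print.convmixer_model <- function(x, ...) {
  g <- patch_grid(x$cfg)
  cat(sprintf(
    "<convmixer_model> %dx%dx%d -> patch %d -> %dx%dx%d, depth %d, %s params%s\n",
    x$cfg$input_size[1], x$cfg$input_size[2], x$cfg$input_size[3],
    x$cfg$patch, g[1], g[2], x$cfg$hidden_dim, x$cfg$depth,
    format(count_parameters(x), big.mark = ","),
    if (x$trained) " (trained)" else " (untrained)"))
  invisible(x)
}

#' Number of trainable parameters
#'
#' Sum of all weight, bias and batch-norm gain/shift entries.
#'
#' @param model A `convmixer_model` (or a `convmixer_config`, which is built
#'   first).
#' @return Integer count; 16,674 at the default configuration.
#' @export
count_parameters <- function(model) {
  if (inherits(model, "convmixer_config")) {
    model <- build_convmixer(model, classes = paste0("C", seq_len(model$n_classes)))
  }
  sum(vapply(model$params, length, integer(1)))
}

as_label_index <- function(labels, classes) {
  idx <- match(as.character(labels), classes)
  if (anyNA(idx)) {
    abort(sprintf("Unknown label value(s): %s",
                  paste(unique(labels[is.na(idx)]), collapse = ", ")))
  }
  idx - 1L  # 0-based for the C++ side
}

center_channels <- function(images, means) {
  for (ch in seq_along(means)) {
    images[, , ch, ] <- images[, , ch, ] - means[ch]
  }
  images
}

#' Class probabilities for a batch of images
#'
#' Runs the model forward in inference mode (running batch-norm statistics,
#' streaming one image at a time). Rows are in batch order and sum to 1.
#'
#' @param object A `convmixer_model`.
#' @param images `h x w x c x n` (or single `h x w x c`) array with values
#'   in [0, 1]; the model's stored per-channel training means are subtracted.
#' @param type `"prob"` for a probability matrix, `"class"` for predicted
#'   labels.
#' @param ... Unused.
#' @return Matrix `n x n_classes` (columns named by class) or a character
#'   vector of predicted labels.
#' @export
predict.convmixer_model <- function(object, images, type = c("prob", "class"),
                                    ...) {
  type <- match.arg(type)
  if (length(dim(images)) == 3L) dim(images) <- c(dim(images), 1L)
  images <- center_channels(images, object$channel_means)
  res <- cm_run(images, integer(0), object$params, cfg_to_cpp(object$cfg),
                object$bn_mean, object$bn_var, FALSE, FALSE)
  probs <- res$probs
  colnames(probs) <- object$classes
  if (type == "prob") probs else object$classes[max.col(probs, ties.method = "first")]
}

# one fused forward/backward pass; internal
cm_gradient <- function(model, images, y_idx, want_grad = TRUE) {
  cm_run(images, as.integer(y_idx), model$params, cfg_to_cpp(model$cfg),
         model$bn_mean, model$bn_var, TRUE, want_grad)
}

#' Train a ConvMixer with SGD + momentum
#'
#' Runs `epochs` passes over shuffled minibatches of the training split,
#' updating all parameters with classical momentum
#' (`v <- momentum * v - lr * grad; w <- w + v`) against the cross-entropy
#' loss. A validation stream (fraction `validation_fraction` of the input,
#' never trained on) is scored at every epoch end. Per-channel means of the
#' training split are subtracted from all inputs and stored on the model for
#' use at prediction time. Fully reproducible for a fixed
#' `train_config()$seed`.
#'
#' @param model An untrained (or warm) `convmixer_model`.
#' @param images `h x w x c x n` array in [0, 1].
#' @param labels Vector of class labels (matching `model$classes`).
#' @param tc A [train_config()].
#' @param verbose Logical; print per-epoch progress.
#' @return The trained model, with a `history` tibble (iteration, epoch,
#'   loss, train_acc, val_acc) attached.
#' @export
train_convmixer <- function(model, images, labels, tc = train_config(),
                            verbose = FALSE) {
  stopifnot(inherits(model, "convmixer_model"), inherits(tc, "train_config"))
  n <- dim(images)[4]
  if (length(labels) != n) abort("`labels` must match the number of images.")
  y <- as_label_index(labels, model$classes)
  if (length(unique(y)) < 2L) {
    abort("Training set contains a single class; need at least two.")
  }
  if (tc$batch_size > n) abort("`batch_size` exceeds the number of images.")

  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(tc$seed)

  # validation split
  n_val <- floor(tc$validation_fraction * n)
  val_idx <- if (n_val > 0) sample.int(n, n_val) else integer(0)
  tr_idx <- setdiff(seq_len(n), val_idx)
  if (length(unique(y[tr_idx])) < 2L) {
    abort("Training split lost a class in the validation holdout; lower `validation_fraction`.")
  }

  # per-channel zero-centering with training-split means
  ch_means <- vapply(seq_len(dim(images)[3]),
                     function(ch) mean(images[, , ch, tr_idx]), numeric(1))
  images <- center_channels(images, ch_means)
  model$channel_means <- ch_means

  vel <- lapply(model$params, function(p) p * 0)
  hist_rows <- list()
  iter <- 0L
  n_tr <- length(tr_idx)

  for (epoch in seq_len(tc$epochs)) {
    ord <- tr_idx[sample.int(n_tr)]
    starts <- seq(1L, n_tr, by = tc$batch_size)
    for (s in starts) {
      idx <- ord[s:min(s + tc$batch_size - 1L, n_tr)]
      if (length(idx) < 2L) next  # a 1-image batch has degenerate BN
      res <- cm_gradient(model, images[, , , idx, drop = FALSE], y[idx])
      iter <- iter + 1L
      # sgdm update
      for (nm in names(model$params)) {
        vel[[nm]] <- tc$momentum * vel[[nm]] - tc$lr * res$grads[[nm]]
        model$params[[nm]] <- model$params[[nm]] + vel[[nm]]
      }
      # running BN statistics (exponential moving average)
      model$bn_mean <- tc$bn_momentum * model$bn_mean +
        (1 - tc$bn_momentum) * res$bn_mean
      model$bn_var <- tc$bn_momentum * model$bn_var +
        (1 - tc$bn_momentum) * res$bn_var
      batch_acc <- mean(max.col(res$probs, ties.method = "first") - 1L == y[idx])
      hist_rows[[iter]] <- tibble(iteration = iter, epoch = epoch,
                                  loss = res$loss, train_acc = batch_acc,
                                  val_acc = NA_real_)
    }
    if (length(val_idx) > 0) {
      vp <- cm_run(images[, , , val_idx, drop = FALSE], integer(0),
                   model$params, cfg_to_cpp(model$cfg), model$bn_mean,
                   model$bn_var, FALSE, FALSE)$probs
      va <- mean(max.col(vp, ties.method = "first") - 1L == y[val_idx])
      hist_rows[[iter]]$val_acc <- va
      if (verbose) {
        message(sprintf("epoch %d/%d  loss %.4f  train %.3f  val %.3f",
                        epoch, tc$epochs, hist_rows[[iter]]$loss,
                        hist_rows[[iter]]$train_acc, va))
      }
    } else if (verbose) {
      message(sprintf("epoch %d/%d  loss %.4f", epoch, tc$epochs,
                      hist_rows[[iter]]$loss))
    }
  }

  if (tc$finalize_bn) {
    stats <- bn_dataset_stats(model, images, tr_idx, tc$batch_size)
    model$bn_mean <- stats$mean
    model$bn_var <- stats$var
  }
  model$trained <- TRUE
  model$history <- dplyr::bind_rows(hist_rows)
  class(model$history) <- c("convmixer_history", class(model$history))
  cm_release_workspace()
  model
}

# exact inference BN statistics from a pass over the (already centered)
# training images, combining per-batch moments by the law of total variance
bn_dataset_stats <- function(model, images, idx, batch_size) {
  starts <- seq(1L, length(idx), by = batch_size)
  mus <- list(); vars <- list(); wts <- numeric(0)
  for (s in starts) {
    bi <- idx[s:min(s + batch_size - 1L, length(idx))]
    if (length(bi) < 2L) next
    res <- cm_run(images[, , , bi, drop = FALSE], integer(0), model$params,
                  cfg_to_cpp(model$cfg), model$bn_mean, model$bn_var,
                  TRUE, FALSE)
    mus[[length(mus) + 1L]] <- res$bn_mean
    vars[[length(vars) + 1L]] <- res$bn_var
    wts <- c(wts, length(bi))
  }
  w <- wts / sum(wts)
  mu_bar <- Reduce(`+`, Map(`*`, mus, w))
  second <- Reduce(`+`, Map(function(v, m, wi) wi * (v + m^2), vars, mus, w))
  list(mean = mu_bar, var = pmax(second - mu_bar^2, 0))
}

#' Save / load a ConvMixer checkpoint
#'
#' Checkpoints are RDS files holding the whole model object (configuration,
#' weights, batch-norm statistics, class names, channel means, history).
#'
#' @param model A `convmixer_model`.
#' @param path Checkpoint file path.
#' @return `write_convmixer()`: `path` invisibly; `read_convmixer()`: the model.
#' @export
write_convmixer <- function(model, path) {
  stopifnot(inherits(model, "convmixer_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_convmixer
#' @export
read_convmixer <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "convmixer_model"))
  m
}

#' Training-mode loss of a batch (for diagnostics and gradient checking)
#'
#' Computes the mean cross-entropy of a labeled batch under batch-statistics
#' normalization, without updating anything.
#'
#' @param model A `convmixer_model`.
#' @param images `h x w x c x n` array (already centered as desired).
#' @param labels Class labels.
#' @return A single number.
#' @export
convmixer_loss <- function(model, images, labels) {
  y <- as_label_index(labels, model$classes)
  cm_run(images, as.integer(y), model$params, cfg_to_cpp(model$cfg),
         model$bn_mean, model$bn_var, TRUE, FALSE)$loss
}

#' Analytic gradients of the training loss (for gradient checking)
#'
#' @inheritParams convmixer_loss
#' @return Named list of gradient arrays matching `model$params`.
#' @export
convmixer_gradients <- function(model, images, labels) {
  y <- as_label_index(labels, model$classes)
  cm_gradient(model, images, y)$grads
}
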