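# Shared fixtures, built lazily and cached for the session: generating and
# imaging an easy-mode cohort is the expensive part of several tests.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# 4 easy-mode subjects (2 + 2), 2 min each: 16 segments after preprocessing
small_easy_segments <- function() {
  fixture("small_easy_segments", function() {
    p <- synthetic_params(separation_mode = "easy")
    coh <- generate_cohort(2, 2, duration_s = 120, params = p, seed = 101)
    dplyr::bind_rows(lapply(coh$recordings, preprocess_recording))
  })
}

# training configuration for desk-scale separability checks: the default
# learning rate is calibrated to full-size image sets (hundreds of SGD
# iterations); at a few dozen iterations the rate is scaled up accordingly
desk_train_config <- function(seed = 1L, ...) {
  train_config(lr = 0.05, seed = seed, ...)
}

# tiny random-but-separable image set for fast classifier plumbing tests:
# class A bright top half, class B bright bottom half, plus noise
tiny_image_set <- function(n_per_class = 6, size = 20L, seed = 5) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  n <- 2L * n_per_class
  X <- array(runif(size * size * n, 0, 0.3), c(size, size, 1L, n))
  labels <- rep(c("HPT", "NRT"), each = n_per_class)
  for (i in seq_len(n)) {
    rows <- if (labels[i] == "HPT") 1:(size / 2) else (size / 2 + 1):size
    X[rows, , 1, i] <- X[rows, , 1, i] + 0.6
  }
  list(images = X, labels = labels)
}

# pure-R reference forward pass for a depth-1 ConvMixer on single-channel
# input, used as an independent oracle against the compiled engine
r_reference_forward <- function(model, images, residual = model$cfg$residual,
                                skip_spatial = FALSE) {
  cfg <- model$cfg
  p <- cfg$patch; h <- cfg$hidden_dim; k <- cfg$kernel
  stopifnot(cfg$depth == 1L, cfg$input_size[3] == 1L)
  g <- patch_grid(cfg); gh <- g[1]; gw <- g[2]
  n <- dim(images)[4]
  gelu <- function(z) 0.5 * z * (1 + tanh(sqrt(2 / pi) * (z + 0.044715 * z^3)))
  bn <- function(A, gamma, beta, eps = cfg$bn_eps) {
    # A: list of h x npos matrices; batch statistics per channel (row)
    all <- do.call(cbind, A)
    mu <- rowMeans(all)
    v <- rowMeans((all - mu)^2)
    lapply(A, function(a) (a - mu) / sqrt(v + eps) * gamma + beta)
  }
  # patch embedding
  Z <- lapply(seq_len(n), function(i) {
    img <- images[, , 1, i]
    cols <- matrix(0, p * p, gh * gw)
    for (gx in seq_len(gw)) for (gy in seq_len(gh)) {
      patch <- img[((gy - 1) * p + 1):(gy * p), ((gx - 1) * p + 1):(gx * p)]
      cols[, (gx - 1) * gh + gy] <- as.vector(patch)
    }
    model$params$We %*% cols + model$params$be
  })
  A <- bn(lapply(Z, gelu), model$params$bn_gamma[, 1], model$params$bn_beta[, 1])
  # depthwise conv (same padding) per channel
  dw <- function(a) {
    out <- matrix(0, h, gh * gw)
    r <- (k - 1) / 2
    for (ch in seq_len(h)) {
      G <- matrix(a[ch, ], gh, gw)
      Gp <- matrix(0, gh + 2 * r, gw + 2 * r)
      Gp[(r + 1):(r + gh), (r + 1):(r + gw)] <- G
      O <- matrix(0, gh, gw)
      kern <- matrix(model$params$dwW[ch, , 1], k, k)
      for (dx in 0:(k - 1)) for (dy in 0:(k - 1)) {
        O <- O + kern[dy + 1, dx + 1] * Gp[(1 + dy):(gh + dy), (1 + dx):(gw + dx)]
      }
      out[ch, ] <- as.vector(O) + model$params$dwb[ch, 1]
    }
    out
  }
  if (skip_spatial) {
    # spatial-mixing stage removed outright: the pointwise stage sees the
    # block input unchanged
    R <- A
  } else {
    U <- lapply(A, dw)
    if (residual == "pre_act") {
      U <- Map(`+`, U, A)
      V <- bn(lapply(U, gelu), model$params$bn_gamma[, 2], model$params$bn_beta[, 2])
      R <- V
    } else {
      V <- bn(lapply(U, gelu), model$params$bn_gamma[, 2], model$params$bn_beta[, 2])
      R <- Map(`+`, A, V)
    }
  }
  W <- lapply(R, function(r) model$params$pwW[, , 1] %*% r + model$params$pwb[, 1])
  X2 <- bn(lapply(W, gelu), model$params$bn_gamma[, 3], model$params$bn_beta[, 3])
  FF <- vapply(X2, rowMeans, numeric(h))  # h x n
  logits <- model$params$fcW %*% FF + model$params$fcb
  probs <- apply(logits, 2, function(l) { e <- exp(l - max(l)); e / sum(e) })
  t(probs)
}
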