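test_that("Hann window values and symmetry", {
  expect_equal(hann_window(3), c(0, 1, 0))
  expect_equal(hann_window(5), c(0, 0.5, 1, 0.5, 0))
  w <- hann_window(128)
  expect_equal(w, rev(w))
  wp <- hann_window(8, periodic = TRUE)
  expect_equal(wp, 0.5 * (1 - cos(2 * pi * (0:7) / 8)))
  expect_error(hann_window(1), ">= 2")
})

test_that("STFT dimensions follow the frame-count formula", {
  tf <- stft_magnitude(rnorm(3000))
  expect_equal(dim(tf$values), c(65, 360))
  expect_equal(tf$freq_hz[1], 0)
  expect_equal(tf$freq_hz[65], 50)

  # property: n_frames = floor((L - W)/H) + 1 against a naive slider
  set.seed(17)
  for (i in 1:10) {
    W <- sample(c(8, 16, 32), 1)
    ov <- sample(0:(W - 1), 1)
    L <- sample(W:500, 1)
    cfg <- spectrogram_config(window_len = W, overlap = ov, nfft = W)
    tf <- stft_magnitude(rnorm(L), cfg)
    naive <- 0; pos <- 1
    while (pos + W - 1 <= L) { naive <- naive + 1; pos <- pos + (W - ov) }
    expect_equal(ncol(tf$values), naive)
  }
  expect_error(stft_magnitude(rnorm(100)), "shorter")
})

test_that("pure tones localize in their own frequency bin", {
  cfg <- spectrogram_config(scale = "linear")
  fs <- 100; nfft <- 128
  t <- (0:2999) / fs
  for (k in c(2, 5, 16, 32, 48, 62)) {
    tone <- sin(2 * pi * (k * fs / nfft) * t)
    tf <- stft_magnitude(tone, cfg, fs = fs)
    argmax <- apply(tf$values, 2, which.max)
    expect_true(all(argmax == k + 1L), info = sprintf("bin %d", k))
  }
})

test_that("windowed frame energy is conserved across the spectrum", {
  # Parseval: sum_k |X_k|^2 = nfft * sum_n |x_w[n]|^2; reconstruct the
  # two-sided sum from the one-sided matrix (double interior bins)
  cfg <- spectrogram_config(scale = "linear", overlap = 0L)
  set.seed(23)
  x <- rnorm(512)
  tf <- stft_magnitude(x, cfg)
  win <- hann_window(128)
  for (fr in seq_len(ncol(tf$values))) {
    frame <- x[((fr - 1) * 128 + 1):(fr * 128)] * win
    one <- tf$values[, fr]
    two_sided <- 2 * sum(one) - one[1] - one[65]
    expect_equal(two_sided, 128 * sum(frame^2), tolerance = 1e-8)
  }
})

test_that("zero input yields the dB floor everywhere", {
  tf <- stft_magnitude(rep(0, 3000))
  expect_true(all(tf$values == -120))
  tl <- stft_magnitude(rep(0, 3000), spectrogram_config(scale = "linear"))
  expect_true(all(tl$values == 0))
})

test_that("thresholding clamps below max + threshold and is idempotent", {
  m <- matrix(c(0, -10, -50, -90), 2, 2, byrow = TRUE)
  out <- threshold_spectrogram(m, -40)
  expect_equal(out, matrix(c(0, -10, -40, -40), 2, 2, byrow = TRUE))

  # idempotent and monotone
  set.seed(3)
  for (i in 1:10) {
    m <- matrix(rnorm(60, -40, 30), 6, 10)
    t1 <- threshold_spectrogram(m, -25)
    expect_identical(threshold_spectrogram(t1, -25), t1)
    expect_true(all(t1 >= m))
    expect_true(all(t1[m >= max(m) - 25] == m[m >= max(m) - 25]))
  }

  # -Inf disables; non-negative thresholds are rejected
  expect_identical(threshold_spectrogram(m, -Inf), m)
  expect_error(threshold_spectrogram(m, 0), "negative")
  expect_error(spectrogram_config(threshold_db = 0), "negative")
})

test_that("heat-map rendering has the advertised shape and invariances", {
  set.seed(41)
  m <- matrix(rnorm(65 * 360, -50, 15), 65, 360)
  img <- render_heatmap(m)
  expect_equal(dim(img$rgb), c(224, 224, 3))
  expect_true(all(img$rgb >= 0 & img$rgb <= 1))

  # invariance to additive dB offsets
  img2 <- render_heatmap(m + 17.3)
  expect_equal(img2$rgb, img$rgb, tolerance = 1e-12)

  # constant matrix renders as a uniform image
  flat <- render_heatmap(matrix(-30, 65, 360))
  expect_equal(max(abs(sweep(flat$rgb, 3, flat$rgb[1, 1, ]))), 0)
})

test_that("the fused resize operator equals resizing twice", {
  ops <- bcgmixer:::resize_operators(65, 360, c(420L, 560L), c(224L, 224L))
  set.seed(2)
  ch <- matrix(runif(65 * 360), 65, 360)
  stepwise <- ops$A2 %*% (ops$A1 %*% ch %*% t(ops$B1)) %*% t(ops$B2)
  fused <- ops$A %*% ch %*% t(ops$B)
  expect_equal(fused, stepwise, tolerance = 1e-10)

  # resampling weights preserve constants (rows sum to one)
  W <- bcgmixer:::resample_weights(65, 420)
  expect_equal(rowSums(W), rep(1, 420))
  W2 <- bcgmixer:::resample_weights(560, 224)
  expect_equal(rowSums(W2), rep(1, 224))
})

test_that("segment-to-image pipeline is deterministic to the byte", {
  seg <- small_easy_segments()$samples[[1]]
  img1 <- spectrogram_image(seg)
  img2 <- spectrogram_image(seg)
  expect_identical(img1$rgb, img2$rgb)
  f1 <- withr::local_tempfile(fileext = ".png")
  f2 <- withr::local_tempfile(fileext = ".png")
  png::writePNG(img1$rgb, f1); png::writePNG(img2$rgb, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("image sets are written with manifests and re-stack faithfully", {
  segs <- small_easy_segments()[1:4, ]
  dir <- withr::local_tempdir()
  man <- build_image_set(segs, out_dir = dir)
  expect_equal(nrow(man), 4)
  expect_true(all(file.exists(man$image_path)))
  expect_identical(man$label, segs$label)

  X <- image_array(man)
  expect_equal(dim(X), c(224, 224, 3, 4))
  # PNG storage quantizes to 8 bits
  direct <- spectrogram_image(segs$samples[[1]])$rgb
  expect_equal(X[, , , 1], direct, tolerance = 1 / 255)

  # in-memory variant agrees with the files
  man2 <- build_image_set(segs[1, ])
  expect_equal(man2$image[[1]], direct)
})
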