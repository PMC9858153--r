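test_that("raw MAD matches hand-enumerated values", {
  expect_equal(bcg_mad(c(1, 2, 3, 4, 5)), 1)
  expect_equal(bcg_mad(c(7, 7, 7)), 0)
  # deviations from median 2 are {1,1,0,0,2,4,7}; their median is 1
  expect_equal(bcg_mad(c(1, 1, 2, 2, 4, 6, 9)), 1)
  expect_error(bcg_mad(numeric(0)), "at least one")
})

test_that("MAD z-score normalization centers and scales as promised", {
  z <- mad_zscore(c(1, 2, 3, 4, 5))
  expect_equal(z$samples, c(-2, -1, 0, 1, 2))
  expect_equal(z$center, 3)
  expect_equal(z$scale, 1)

  # property: median 0, MAD 1 for arbitrary non-degenerate input
  set.seed(31)
  for (i in 1:20) {
    n <- sample(10:2000, 1)
    x <- rnorm(n, mean = runif(1, -50, 50), sd = runif(1, 0.01, 100))
    out <- mad_zscore(x)$samples
    expect_equal(median(out), 0, tolerance = 1e-12)
    expect_equal(bcg_mad(out), 1, tolerance = 1e-12)
  }

  # idempotence on an already-normalized signal
  x <- rnorm(501)
  once <- mad_zscore(x)$samples
  twice <- mad_zscore(once)$samples
  expect_equal(twice, once, tolerance = 1e-12)

  expect_error(mad_zscore(rep(4, 10)), "degenerate")
  expect_error(mad_zscore(1), "at least 2")
})

test_that("canonical filter carries the fixed published constants and is stable", {
  f <- canonical_filter()
  expect_identical(f$b, c(0.028, 0.053, 0.071, 0.053, 0.028))
  expect_identical(f$a, c(1, -2.026, 2.148, -1.159, 0.279))
  expect_equal(f$order, 4L)
  expect_true(all(Mod(filter_poles(f)) < 1))
  expect_true(is_stable(f))
})

test_that("IIR filtering matches a direct difference-equation oracle", {
  f <- canonical_filter()
  set.seed(4)
  x <- rnorm(200)
  y <- apply_iir_filter(x, f)
  expect_length(y, length(x))

  # oracle: literal evaluation of y[n] = sum b x - sum a y
  oracle <- numeric(length(x))
  for (n in seq_along(x)) {
    acc <- 0
    for (k in 0:4) {
      if (n - k >= 1) acc <- acc + f$b[k + 1] * x[n - k]
    }
    for (k in 1:4) {
      if (n - k >= 1) acc <- acc - f$a[k + 1] * oracle[n - k]
    }
    oracle[n] <- acc
  }
  expect_equal(y, oracle, tolerance = 1e-12)

  # impulse response starts at b0; step settles at sum(b)/sum(a)
  imp <- apply_iir_filter(c(1, rep(0, 30)), f)
  expect_equal(imp[1], 0.028)
  stp <- apply_iir_filter(rep(1, 3000), f)
  expect_equal(stp[3000], sum(f$b) / sum(f$a), tolerance = 1e-9)

  expect_equal(apply_iir_filter(rep(0, 50), f), rep(0, 50))
})

test_that("filtering is linear and time-invariant", {
  f <- canonical_filter()
  set.seed(8)
  x <- rnorm(300)
  expect_equal(apply_iir_filter(3.7 * x, f), 3.7 * apply_iir_filter(x, f),
               tolerance = 1e-12)
  shifted <- c(rep(0, 40), x)
  y <- apply_iir_filter(c(x, rep(0, 40)), f)
  ys <- apply_iir_filter(shifted, f)
  expect_equal(ys[41:340], y[1:300], tolerance = 1e-12)
})

test_that("unstable coefficient sets are rejected before filtering", {
  bad <- bcgmixer:::new_bcg_filter(b = c(1, 0), a = c(1, -1.5), order = 1L,
                                   f_low = 1, f_high = 50, fs = 100, "test")
  expect_false(is_stable(bad))
  expect_error(apply_iir_filter(rnorm(10), bad), "unstable")
})

test_that("the configurable Chebyshev II designer meets band specifications", {
  f <- design_cheby2_bandpass(order = 4, f_low = 1, f_high = 45, fs = 100,
                              stop_atten_db = 20)
  expect_length(f$b, 5)
  expect_true(is_stable(f))
  H <- function(coef, freq, fs) {
    z <- exp(1i * 2 * pi * freq / fs)
    abs(sum(coef$b * z^-(0:4)) / sum(coef$a * z^-(0:4)))
  }
  # near-unit gain at the geometric band center, deep attenuation at DC
  expect_gt(H(f, sqrt(1 * 45), 100), 0.7)
  expect_lt(H(f, 0.01, 100), 10^(-20 / 20) * 1.5)
  expect_error(design_cheby2_bandpass(order = 4, f_low = 1, f_high = 60,
                                      fs = 100), "Nyquist")
  expect_error(design_cheby2_bandpass(order = 3), "even")
})

test_that("filter coefficients round-trip through JSON", {
  f <- canonical_filter()
  path <- withr::local_tempfile(fileext = ".json")
  write_filter(f, path)
  g <- read_filter(path)
  expect_equal(g$b, f$b)
  expect_equal(g$a, f$a)
  expect_equal(g$fs, f$fs)
})

test_that("segmentation uses non-overlapping floor division", {
  x <- rnorm(300000)
  segs <- segment_signal(x, fs = 100, window_s = 30)
  expect_equal(nrow(segs), 100)
  expect_true(all(lengths(segs$samples) == 3000))
  expect_equal(segs$segment_index, 0:99)

  expect_equal(nrow(segment_signal(rnorm(3000))), 1)
  expect_equal(nrow(segment_signal(rnorm(2999))), 0)
  segs2 <- segment_signal(rnorm(6500))
  expect_equal(nrow(segs2), 2)

  # conservation and disjointness for random sizes
  set.seed(13)
  for (i in 1:10) {
    n <- sample(50:5000, 1); w <- sample(2:8, 1)
    x <- rnorm(n)
    s <- segment_signal(x, fs = 10, window_s = w)
    wlen <- 10 * w
    expect_equal(nrow(s), n %/% wlen)
    if (nrow(s) > 0) {
      expect_identical(unlist(s$samples), x[seq_len(nrow(s) * wlen)])
    }
  }
  expect_error(segment_signal(rnorm(100), fs = 3, window_s = 0.5), "integer")
})

test_that("preprocessing runs normalize -> filter -> segment in order", {
  rec <- generate_subject("HPT", duration_s = 90, seed = 6)
  segs <- preprocess_recording(rec)
  expect_equal(nrow(segs), 3)
  # the composed output equals applying the stages by hand in that order
  byhand <- segment_signal(
    apply_iir_filter(mad_zscore(rec$samples)$samples),
    fs = rec$fs, window_s = 30, subject_id = rec$subject_id, label = rec$label)
  expect_identical(segs, byhand)

  # trimming rejects too-short recordings by name
  expect_error(preprocess_recording(rec, trim_s = 120), rec$subject_id)
  trimmed <- preprocess_recording(rec, trim_s = 60)
  expect_equal(nrow(trimmed), 2)
})
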