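test_that("image-level folds partition the items with near-equal sizes", {
  fp <- kfold_split(12800, k = 10, seed = 1)
  expect_equal(tabulate(fp$assignment, 10), rep(1280, 10))

  set.seed(27)
  for (i in 1:8) {
    n <- sample(20:500, 1); k <- sample(2:10, 1)
    if (n < k) next
    fp <- kfold_split(n, k, seed = i)
    sizes <- tabulate(fp$assignment, k)
    expect_equal(sum(sizes), n)                    # every item in one fold
    expect_lte(max(sizes) - min(sizes), 1)         # sizes differ by <= 1
  }
  # deterministic per seed
  expect_identical(kfold_split(100, 5, seed = 3)$assignment,
                   kfold_split(100, 5, seed = 3)$assignment)
  expect_error(kfold_split(5, 10), "exceed")
  expect_error(kfold_split(100, 1), ">= 2")
})

test_that("subject-level folds never split a subject", {
  subjects <- rep(sprintf("S%03d", 1:128), each = 100)
  fp <- kfold_split(length(subjects), k = 10, seed = 2, groups = subjects)
  expect_equal(fp$grouping, "subject_level")
  per_subject <- tapply(fp$assignment, subjects, function(a) length(unique(a)))
  expect_true(all(per_subject == 1))
  subj_fold <- tapply(fp$assignment, subjects, unique)
  sizes <- tabulate(subj_fold, 10)
  expect_true(all(sizes %in% c(12, 13)))
})

test_that("confusion counts treat the hypertensive class as positive", {
  y <- c(rep("HPT", 50), rep("NRT", 50))
  cc <- confusion_counts(y, y)
  expect_equal(unclass(cc)[c("tp", "fp", "fn", "tn")],
               list(tp = 50, fp = 0, fn = 0, tn = 50))

  y2 <- c(rep("HPT", 30), rep("NRT", 70))
  cc2 <- confusion_counts(y2, rep("HPT", 100))
  expect_equal(unclass(cc2)[c("tp", "fp", "fn", "tn")],
               list(tp = 30, fp = 70, fn = 0, tn = 0))

  # conservation over random predictions
  set.seed(5)
  for (i in 1:10) {
    n <- sample(5:200, 1)
    yt <- sample(c("HPT", "NRT"), n, replace = TRUE)
    yp <- sample(c("HPT", "NRT"), n, replace = TRUE)
    cc <- confusion_counts(yt, yp)
    expect_equal(cc$tp + cc$fp + cc$fn + cc$tn, n)
  }
  expect_error(confusion_counts(c("HPT", "XX"), c("HPT", "HPT")), "Unknown")
  expect_error(confusion_counts("HPT", c("HPT", "NRT")), "equal-length")
})

test_that("metric formulas match hand computation and an independent oracle", {
  cc <- structure(list(tp = 40, fp = 10, fn = 20, tn = 30, positive = "HPT"),
                  class = "confusion_counts")
  m <- metrics_report(cc)
  hpt <- m[m$class == "HPT", ]
  expect_equal(hpt$accuracy, 70)
  expect_equal(hpt$precision, 80)
  expect_equal(hpt$recall, 200 / 3, tolerance = 1e-9)
  expect_equal(hpt$f1, 800 / 11, tolerance = 1e-9)

  perfect <- metrics_report(confusion_counts(c("HPT", "NRT"), c("HPT", "NRT")))
  expect_true(all(perfect$accuracy == 100 & perfect$f1 == 100))

  # random tables against a test-side oracle; swapping class roles swaps
  # per-class rows and preserves accuracy and macro F1
  oracle <- function(tp, fp, fn) {
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    c(p, r, f) * 100
  }
  set.seed(77)
  for (i in 1:12) {
    v <- sample(0:40, 4, replace = TRUE)
    if (sum(v) == 0) v[1] <- 1
    cc <- structure(list(tp = v[1], fp = v[2], fn = v[3], tn = v[4],
                         positive = "HPT"), class = "confusion_counts")
    m <- suppressWarnings(metrics_report(cc))
    expect_equal(unlist(m[m$class == "HPT", c("precision", "recall", "f1")]),
                 setNames(oracle(v[1], v[2], v[3]),
                          c("precision", "recall", "f1")))
    expect_equal(unlist(m[m$class == "NRT", c("precision", "recall", "f1")]),
                 setNames(oracle(v[4], v[3], v[2]),
                          c("precision", "recall", "f1")))
    swapped <- structure(list(tp = v[4], fp = v[3], fn = v[2], tn = v[1],
                              positive = "HPT"), class = "confusion_counts")
    ms <- suppressWarnings(metrics_report(swapped))
    expect_equal(ms$accuracy[1], m$accuracy[1])
    expect_equal(ms$f1[ms$class == "macro"], m$f1[m$class == "macro"])
  }
})

test_that("zero denominators are flagged and reported as zero", {
  cc <- confusion_counts(c("HPT", "NRT"), c("NRT", "NRT"))  # never predicts HPT
  expect_warning(m <- metrics_report(cc), "zero denominators")
  expect_equal(m$precision[m$class == "HPT"], 0)
  expect_true(m$degenerate[m$class == "HPT"])
})

test_that("cross-validation trains k models and conserves test counts", {
  d <- tiny_image_set(n_per_class = 8)
  cfg <- convmixer_config(input_size = c(20, 20, 1), patch = 5, hidden_dim = 3,
                          depth = 1, kernel = 3)
  # barely-trained fold models may never predict one of the classes, which
  # legitimately raises the degenerate-metrics warning
  cv <- suppressWarnings(
    cross_validate(d$images, d$labels, model_cfg = cfg,
                   tc = desk_train_config(seed = 2, batch_size = 4,
                                          epochs = 2,
                                          validation_fraction = 0),
                   k = 4, seed = 2))
  expect_length(cv$histories, 4)
  expect_equal(nrow(cv$fold_metrics), 4 * 3)  # 3 metric rows per fold
  total <- cv$cumulative$tp + cv$cumulative$fp + cv$cumulative$fn +
    cv$cumulative$tn
  expect_equal(total, 16)  # every image tested exactly once

  # mean metrics are the arithmetic mean of per-fold values
  macro <- cv$fold_metrics[cv$fold_metrics$class == "macro", ]
  expect_equal(cv$mean_metrics$accuracy[cv$mean_metrics$class == "macro"],
               mean(macro$accuracy))

  g <- glance(cv)
  expect_equal(g$n, 16)
  td <- tidy(cv)
  expect_identical(td, cv$fold_metrics)
})

test_that("a fold whose training split is single-class is rejected by id", {
  d <- tiny_image_set(n_per_class = 3)
  cfg <- convmixer_config(input_size = c(20, 20, 1), patch = 5, hidden_dim = 2,
                          depth = 1, kernel = 3)
  # force all HPT items into folds 2..3 so fold training can lose a class
  fp <- structure(list(k = 2L, assignment = c(1L, 1L, 1L, 2L, 2L, 2L),
                       grouping = "image_level", seed = 1L),
                  class = "fold_plan")
  expect_error(
    cross_validate(d$images, d$labels, model_cfg = cfg,
                   tc = desk_train_config(batch_size = 2, epochs = 1,
                                          validation_fraction = 0),
                   fold_plan = fp),
    "single-class")
})
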