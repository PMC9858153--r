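test_that("patch embedding geometry and parameter count match closed forms", {
  cfg <- convmixer_config()
  expect_equal(patch_grid(cfg), c(44L, 44L))
  expect_equal(count_parameters(cfg), 16674)

  # closed-form oracle over random configurations
  set.seed(9)
  for (i in 1:5) {
    p <- sample(2:6, 1); h <- sample(3:12, 1); d <- sample(1:4, 1)
    k <- sample(c(3, 5), 1); cls <- sample(2:4, 1); ch <- sample(1:3, 1)
    cfg <- convmixer_config(input_size = c(40, 40, ch), patch = p,
                            hidden_dim = h, depth = d, kernel = k,
                            n_classes = cls)
    embed <- p^2 * ch * h + h + 2 * h
    block <- (k^2 * h + h + 2 * h) + (h * h + h + 2 * h)
    head <- h * cls + cls
    expect_equal(count_parameters(cfg), embed + d * block + head)
  }

  # doubling depth adds exactly depth * per-block parameters
  c1 <- count_parameters(convmixer_config(depth = 3))
  c2 <- count_parameters(convmixer_config(depth = 6))
  per_block <- (25 * 32 + 32 + 64) + (32 * 32 + 32 + 64)
  expect_equal(c2 - c1, 3 * per_block)

  expect_error(convmixer_config(kernel = 4), "odd")
})

test_that("forward pass produces valid, order-preserving probabilities", {
  cfg <- convmixer_config(input_size = c(30, 30, 1), hidden_dim = 8, depth = 2)
  m <- build_convmixer(cfg, seed = 2)
  set.seed(11)
  X <- array(runif(30 * 30 * 1 * 6), c(30, 30, 1, 6))
  p <- predict(m, X)
  expect_equal(dim(p), c(6, 2))
  expect_true(all(p >= 0))
  expect_equal(rowSums(p), rep(1, 6), tolerance = 1e-6)

  # identical inputs give identical rows; permutation permutes rows
  Xsame <- array(rep(X[, , , 1], 3), c(30, 30, 1, 3))
  ps <- predict(m, Xsame)
  expect_equal(ps[1, ], ps[2, ])
  expect_equal(ps[2, ], ps[3, ])
  perm <- c(4, 1, 6, 2, 5, 3)
  expect_equal(predict(m, X[, , , perm, drop = FALSE]), p[perm, ],
               tolerance = 1e-12)

  expect_error(predict(m, array(0, c(10, 10, 1, 2))), "dimensions")
})

test_that("compiled forward pass agrees with a pure-R reference", {
  for (res in c("post_norm", "pre_act")) {
    cfg <- convmixer_config(input_size = c(20, 20, 1), patch = 5,
                            hidden_dim = 4, depth = 1, kernel = 3,
                            residual = res)
    m <- build_convmixer(cfg, seed = 14)
    set.seed(15)
    X <- array(runif(20 * 20 * 1 * 4), c(20, 20, 1, 4))
    probs_cpp <- bcgmixer:::cm_run(X, integer(0), m$params, bcgmixer:::cfg_to_cpp(cfg),
                        m$bn_mean, m$bn_var, TRUE, FALSE)$probs
    probs_r <- r_reference_forward(m, X)
    expect_equal(probs_cpp, probs_r, tolerance = 1e-10)
  }
})

test_that("a zeroed depthwise stage reduces the residual block to identity mixing", {
  # with dw weights and biases zero, gelu(0) = 0 and batch norm of a
  # constant zero map outputs beta = 0, so R = x + 0 = x: the model must
  # equal one whose spatial-mixing stage is skipped entirely
  cfg <- convmixer_config(input_size = c(20, 20, 1), patch = 5, hidden_dim = 4,
                          depth = 1, kernel = 3)
  m <- build_convmixer(cfg, seed = 21)
  m$params$dwW[] <- 0
  m$params$dwb[] <- 0
  set.seed(22)
  X <- array(runif(20 * 20 * 4), c(20, 20, 1, 4))
  probs <- bcgmixer:::cm_run(X, integer(0), m$params, bcgmixer:::cfg_to_cpp(cfg),
                  m$bn_mean, m$bn_var, TRUE, FALSE)$probs
  # oracle in which the spatial-mixing stage is removed outright: the
  # residual path must make both computations identical
  skip_oracle <- r_reference_forward(m, X, skip_spatial = TRUE)
  expect_equal(probs, skip_oracle, tolerance = 1e-10)
})

test_that("analytic gradients match central finite differences", {
  for (res in c("post_norm", "pre_act")) {
    cfg <- convmixer_config(input_size = c(10, 10, 1), patch = 5,
                            hidden_dim = 2, depth = 1, kernel = 3,
                            residual = res)
    m <- build_convmixer(cfg, seed = 3)
    set.seed(42)
    X <- array(runif(10 * 10 * 1 * 3), c(10, 10, 1, 3))
    y <- c("HPT", "NRT", "HPT")
    g <- convmixer_gradients(m, X, y)
    eps <- 1e-6
    for (nm in names(m$params)) {
      p <- m$params[[nm]]
      for (i in sample(length(p), min(6, length(p)))) {
        mp <- m; mp$params[[nm]][i] <- p[i] + eps
        mm2 <- m; mm2$params[[nm]][i] <- p[i] - eps
        fd <- (convmixer_loss(mp, X, y) - convmixer_loss(mm2, X, y)) / (2 * eps)
        expect_equal(g[[nm]][i], fd, tolerance = 1e-4,
                     label = sprintf("%s[%d] (%s)", nm, i, res))
      }
    }
  }
})

test_that("training reduces loss on a separable set and is seed-reproducible", {
  d <- tiny_image_set()
  cfg <- convmixer_config(input_size = c(20, 20, 1), patch = 5, hidden_dim = 4,
                          depth = 2, kernel = 3)
  tc <- desk_train_config(seed = 6, batch_size = 4, epochs = 4,
                          validation_fraction = 0)
  m1 <- train_convmixer(build_convmixer(cfg, seed = 6), d$images, d$labels, tc)
  h <- m1$history
  expect_lt(tail(h$loss, 1), h$loss[1])
  expect_equal(nrow(h), 4 * 3)  # 12 train images, batch 4, 4 epochs

  m2 <- train_convmixer(build_convmixer(cfg, seed = 6), d$images, d$labels, tc)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)

  expect_error(train_convmixer(build_convmixer(cfg, seed = 1), d$images,
                               rep("HPT", length(d$labels)), tc),
               "single class")
})

test_that("checkpoints round-trip models exactly", {
  d <- tiny_image_set()
  cfg <- convmixer_config(input_size = c(20, 20, 1), patch = 5, hidden_dim = 3,
                          depth = 1, kernel = 3)
  m <- train_convmixer(build_convmixer(cfg, seed = 4), d$images, d$labels,
                       desk_train_config(seed = 4, batch_size = 4, epochs = 1,
                                         validation_fraction = 0))
  path <- withr::local_tempfile(fileext = ".rds")
  write_convmixer(m, path)
  back <- read_convmixer(path)
  expect_identical(back$params, m$params)
  expect_identical(predict(back, d$images), predict(m, d$images))
})
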