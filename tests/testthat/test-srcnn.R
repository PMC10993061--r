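test_that("default architecture has exactly 8129 trainable parameters", {
  expect_equal(count_parameters(srcnn_config()), 8129)
  # closed form agrees with actual weight shapes for arbitrary configs
  set.seed(7)
  for (i in 1:5) {
    ks <- sample(c(1L, 3L, 5L, 7L, 9L), 3, replace = TRUE)
    ch <- sample(1:8, 3, replace = TRUE)
    cfg <- srcnn_config(kernel_sizes = ks, channels = ch)
    m <- build_model(cfg, seed = i)
    n_actual <- sum(vapply(m$weights, length, 0))
    expect_equal(count_parameters(cfg), n_actual)
  }
  expect_error(srcnn_config(kernel_sizes = c(9, 2, 5)), "odd")
  expect_error(srcnn_config(channels = c(64, 0, 1)), "positive")
})

test_that("forward pass preserves spatial shape and zero last layer forces zero output", {
  cfg <- srcnn_config()
  m <- build_model(cfg, seed = 1)
  x <- matrix(runif(40 * 56), 40, 56)
  y <- brushsim:::srcnn_forward(m$weights, cfg, x)
  expect_identical(dim(y), c(40L, 56L, 1L))
  m$weights$W3[] <- 0
  m$weights$b3[] <- 0
  y0 <- brushsim:::srcnn_forward(m$weights, cfg, x)
  expect_true(all(y0 == 0))
})

test_that("compiled convolution matches the brute-force oracle", {
  set.seed(19)
  for (trial in list(list(k = 3, cin = 1, cout = 4, h = 9, w = 11),
                     list(k = 5, cin = 3, cout = 2, h = 12, w = 8),
                     list(k = 1, cin = 4, cout = 3, h = 7, w = 7))) {
    x <- array(runif(trial$h * trial$w * trial$cin),
               c(trial$h, trial$w, trial$cin))
    W <- matrix(rnorm(trial$k^2 * trial$cin * trial$cout),
                trial$k^2 * trial$cin, trial$cout)
    b <- rnorm(trial$cout)
    got <- brushsim:::cpp_conv2d(x, W, b, trial$k)
    want <- brute_conv2d(x, weights_to_array(W, trial$k, trial$cin, trial$cout),
                         b, trial$k)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("backpropagation matches finite differences", {
  cfg <- srcnn_config(kernel_sizes = c(3, 1, 3), channels = c(4, 3, 1))
  m <- build_model(cfg, seed = 2)
  set.seed(3)
  x <- matrix(runif(8 * 8), 8, 8)
  tgt <- matrix(runif(8 * 8), 8, 8)
  fwd <- brushsim:::srcnn_forward(m$weights, cfg, x, keep = TRUE)
  g <- brushsim:::srcnn_backward(m$weights, cfg, x, fwd, tgt)
  loss <- function(w) {
    mean((as.vector(brushsim:::srcnn_forward(w, cfg, x)) - as.vector(tgt))^2)
  }
  eps <- 1e-6
  for (nm in names(m$weights)) {
    idx <- sample(length(m$weights[[nm]]), min(6, length(m$weights[[nm]])))
    for (i in idx) {
      wp <- m$weights; wp[[nm]][i] <- wp[[nm]][i] + eps
      wm <- m$weights; wm[[nm]][i] <- wm[[nm]][i] - eps
      fd <- (loss(wp) - loss(wm)) / (2 * eps)
      expect_equal(g[[nm]][i], fd, tolerance = 1e-5)
    }
  }
})

test_that("patch extraction is aligned, complete and deterministic", {
  set.seed(23)
  pairs <- lapply(1:206, function(i) {
    x <- matrix(runif(16 * 16), 16, 16)
    list(lr = x / 2, hr = x)
  })
  tc <- train_config(patches_per_image = 10, patch_size_px = 8, seed = 4)
  patches <- extract_patches(pairs, tc)
  expect_identical(length(patches), 2060L)
  # identical crop coordinates for lr and hr of each pair
  p <- patches[[17]]
  src <- pairs[[(17 - 1) %/% 10 + 1]]
  expect_identical(p$lr, src$lr[p$row:(p$row + 7), p$col:(p$col + 7)])
  expect_identical(p$hr, src$hr[p$row:(p$row + 7), p$col:(p$col + 7)])
  expect_identical(p$hr, p$lr * 2)
  # determinism
  again <- extract_patches(pairs, tc)
  expect_identical(patches, again)
  # too-small image rejected
  expect_error(extract_patches(list(list(lr = matrix(0, 4, 4),
                                         hr = matrix(0, 4, 4))), tc),
               "smaller than the patch")
})

test_that("training fits a constant identity pair to near-zero loss", {
  cpair <- list(lr = matrix(0.5, 16, 16), hr = matrix(0.5, 16, 16))
  tc <- train_config(learning_rate = 1e-3, epochs = 50, batch_size = 1,
                     patches_per_image = 32, patch_size_px = 16, seed = 6)
  m <- train_srcnn(build_model(srcnn_config(), seed = 6),
                   list(cpair), list(cpair), tc)
  expect_lt(min(m$history$train_mse), 1e-6)
  expect_true(m$trained)
})

test_that("training overfits a single phantom pair", {
  hr <- tiny_phantom(seed = 77, h = 64, w = 64)
  lr <- degrade(hr, degradation_params(4, 8, 0))$lr_image
  pair <- list(list(lr = lr, hr = hr))
  tc <- train_config(learning_rate = 1e-3, epochs = 200, batch_size = 2,
                     patches_per_image = 2, patch_size_px = 64, seed = 8)
  m <- train_srcnn(build_model(srcnn_config(), seed = 8), pair, pair, tc)
  expect_lt(m$history$train_mse[200], m$history$train_mse[1] / 10)
})

test_that("checkpointing selects the epoch with minimum validation loss", {
  hist <- data.frame(epoch = 1:6,
                     train_mse = c(5, 4, 3, 2, 1, 0.5) / 10,
                     val_mse = c(0.5, 0.3, 0.6, 0.25, 0.4, 0.3))
  expect_identical(best_checkpoint(hist), 4L)
  expect_error(best_checkpoint(data.frame(epoch = 1)), "val_mse")
})

test_that("training on identity pairs improves monotonically over checkpoints", {
  hr1 <- tiny_phantom(seed = 91, h = 32, w = 32)
  hr2 <- tiny_phantom(seed = 92, h = 32, w = 32)
  pairs <- list(list(lr = hr1, hr = hr1))
  val <- list(list(lr = hr2, hr = hr2))
  tc <- train_config(learning_rate = 1e-2, epochs = 20, batch_size = 2,
                     patches_per_image = 4, patch_size_px = 32, seed = 9)
  m <- train_srcnn(build_model(srcnn_config(), seed = 9), pairs, val, tc)
  run_min <- cummin(m$history$val_mse)
  expect_true(all(diff(run_min) <= 0))
  expect_lt(tail(run_min, 1), m$history$val_mse[1])
  expect_identical(m$best_epoch, which.min(m$history$val_mse))
})

test_that("super_resolve clips, preserves shape and requires training", {
  m <- build_model(srcnn_config(), seed = 3)
  x <- matrix(runif(24 * 24), 24, 24)
  expect_error(super_resolve(m, x), "not been trained")
  m$trained <- TRUE
  # inflate the last-layer bias so raw outputs leave [0, 1]
  m$weights$b3 <- 5
  y <- super_resolve(m, x)
  expect_identical(dim(y), dim(x))
  expect_lte(max(y), 1)
  expect_gte(min(y), 0)
})

test_that("the network is translation covariant away from borders", {
  cfg <- srcnn_config()
  m <- build_model(cfg, seed = 10)
  set.seed(10)
  x <- matrix(runif(64 * 64), 64, 64)
  xs <- rbind(x[9:64, ], x[1:8, ])  # cyclic shift by 8 rows
  y <- brushsim:::srcnn_forward(m$weights, cfg, x)[, , 1]
  ys <- brushsim:::srcnn_forward(m$weights, cfg, xs)[, , 1]
  inner <- 17:40  # >= 16 px from every border in both frames
  expect_lt(max(abs(y[inner + 8, inner] - ys[inner, inner])), 1e-5)
})

test_that("models round-trip through JSON serialization", {
  cfg <- srcnn_config(kernel_sizes = c(3, 1, 3), channels = c(4, 2, 1))
  m <- build_model(cfg, seed = 5)
  m$trained <- TRUE
  m$best_epoch <- 3L
  m$history <- data.frame(epoch = 1:3, train_mse = c(3, 2, 1) / 10,
                          val_mse = c(4, 3, 2) / 10)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  expect_equal(m2$weights, m$weights, tolerance = 1e-12)
  x <- matrix(runif(16 * 16), 16, 16)
  expect_equal(super_resolve(m2, x), super_resolve(m, x), tolerance = 1e-12)
})
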