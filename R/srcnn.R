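# Three-layer super-resolution convolutional network (SRCNN) mapping a
# reconstituted LR image to an SR estimate of the HR image, trained with
# pixelwise MSE and Adam. Convolutions use "same" zero padding so the SR
# output is directly comparable with the HR target pixel by pixel.
#
# Weights of a k x k layer mapping cin -> cout channels are stored as a
# (k*k*cin) x cout matrix with row index ki + k*kj + k*k*c (0-based kernel row
# offset ki, column offset kj, input channel c), matching the compiled im2col.

#' SRCNN architecture configuration
#'
#' Three feedforward convolutional layers interspersed with leaky-ReLU
#' nonlinearities (none after the last layer). Defaults: kernel sizes 9x9,
#' 1x1, 5x5 with 64, 32, and 1 filters, a single grayscale input channel, and
#' leaky-ReLU negative slope 0.2.
#'
#' @param kernel_sizes integer vector of three odd kernel sizes.
#' @param channels integer vector of three filter counts; the last is the
#'   output channel count (1 for grayscale).
#' @param input_channels number of input channels (default 1).
#' @param leaky_slope negative slope of the leaky ReLU (default 0.2).
#' @return object of class `srcnn_config`.
#' @export
srcnn_config <- function(kernel_sizes = c(9L, 1L, 5L),
                         channels = c(64L, 32L, 1L),
                         input_channels = 1L, leaky_slope = 0.2) {
  stop_if_not(length(kernel_sizes) == 3L && all(kernel_sizes >= 1) &&
                all(kernel_sizes == round(kernel_sizes)) &&
                all(kernel_sizes %% 2 == 1),
              "kernel_sizes must be three positive odd integers")
  stop_if_not(length(channels) == 3L && all(channels >= 1) &&
                all(channels == round(channels)),
              "channels must be three positive integers")
  stop_if_not(is_count(input_channels), "input_channels must be positive")
  stop_if_not(is_number(leaky_slope) && leaky_slope >= 0 && leaky_slope < 1,
              "leaky_slope must be in [0, 1)")
  structure(list(kernel_sizes = as.integer(kernel_sizes),
                 channels = as.integer(channels),
                 input_channels = as.integer(input_channels),
                 leaky_slope = leaky_slope, padding = "same"),
            class = "srcnn_config")
}

#' Training configuration
#'
#' Optimization settings for [train_srcnn()]. Full-scale defaults follow the
#' reference protocol (Adam, learning rate 1e-4, 300 epochs, batch size 8, 10
#' random 512x512 patches per image, MSE loss, best-validation checkpointing);
#' desk-scale runs shrink `epochs`, `patch_size_px` and `patches_per_image`.
#'
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param epochs number of epochs (default 300).
#' @param batch_size patches per optimization step (default 8).
#' @param patches_per_image random crops taken from each training pair
#'   (default 10).
#' @param patch_size_px square patch side (default 512); must not exceed the
#'   image dimensions.
#' @param seed integer seed governing initialization, patch positions and
#'   shuffling.
#' @return object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, epochs = 300L, batch_size = 8L,
                         patches_per_image = 10L, patch_size_px = 512L,
                         seed = 1L) {
  stop_if_not(is_number(learning_rate) && learning_rate > 0,
              "learning_rate must be > 0")
  for (v in list(epochs, batch_size, patches_per_image, patch_size_px)) {
    stop_if_not(is_count(v), "all counts must be positive integers")
  }
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 patches_per_image = as.integer(patches_per_image),
                 patch_size_px = as.integer(patch_size_px),
                 loss = "mse", optimizer = "adam", seed = as.integer(seed),
                 checkpoint_rule = "best_validation_loss"),
            class = "train_config")
}

layer_channels <- function(cfg) {
  c(cfg$input_channels, cfg$channels)
}

#' Count trainable parameters
#'
#' Closed form `sum(k_i^2 * c_{i-1} * c_i + c_i)`; the default architecture
#' has 8129 parameters.
#'
#' @param cfg an [srcnn_config()].
#' @return integer parameter count.
#' @export
count_parameters <- function(cfg) {
  stop_if_not(inherits(cfg, "srcnn_config"), "cfg must be an srcnn_config")
  ch <- layer_channels(cfg)
  sum(cfg$kernel_sizes^2 * head(ch, -1) * tail(ch, -1) + tail(ch, -1))
}

#' Build an (untrained) SRCNN
#'
#' Convolution weights are He-normal initialized (`sd = sqrt(2 / fan_in)`),
#' biases zero; seeded.
#'
#' @param cfg an [srcnn_config()].
#' @param seed integer seed for the initialization.
#' @return object of class `srcnn_model` with fields `config`, `weights`
#'   (list `W1,b1,W2,b2,W3,b3`), `trained`, `history`, `best_epoch`.
#' @export
build_model <- function(cfg = srcnn_config(), seed = 1L) {
  stop_if_not(inherits(cfg, "srcnn_config"), "cfg must be an srcnn_config")
  ch <- layer_channels(cfg)
  weights <- withr::with_seed(seed, {
    w <- list()
    for (i in 1:3) {
      fan_in <- cfg$kernel_sizes[i]^2 * ch[i]
      w[[paste0("W", i)]] <- matrix(rnorm(fan_in * ch[i + 1], 0,
                                          sqrt(2 / fan_in)),
                                    fan_in, ch[i + 1])
      w[[paste0("b", i)]] <- numeric(ch[i + 1])
    }
    w
  })
  structure(list(config = cfg, weights = weights, trained = FALSE,
                 history = NULL, best_epoch = NA_integer_),
            class = "srcnn_model")
}

as_cube <- function(x) {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  x
}

lrelu <- function(x, slope) ifelse(x > 0, x, slope * x)
lrelu_grad <- function(x, slope) ifelse(x > 0, 1, slope)

srcnn_forward <- function(weights, cfg, x, keep = FALSE) {
  k <- cfg$kernel_sizes; sl <- cfg$leaky_slope
  a1 <- cpp_conv2d(as_cube(x), weights$W1, weights$b1, k[1])
  z1 <- lrelu(a1, sl)
  a2 <- cpp_conv2d(z1, weights$W2, weights$b2, k[2])
  z2 <- lrelu(a2, sl)
  a3 <- cpp_conv2d(z2, weights$W3, weights$b3, k[3])
  if (keep) list(a1 = a1, z1 = z1, a2 = a2, z2 = z2, y = a3) else a3
}

# Rearrange forward weights for the input-gradient pass: the transposed
# convolution of a (k*k*cin) x cout weight matrix is a (k*k*cout) x cin matrix
# holding the spatially flipped kernels.
flip_weights <- function(w, k, cin, cout) {
  wt <- matrix(0, k * k * cout, cin)
  kk <- k * k
  flip <- as.vector(matrix(kk:1, k, k))  # flips both kernel axes
  for (c in seq_len(cin)) {
    block <- w[((c - 1) * kk + 1):(c * kk), , drop = FALSE]  # kk x cout
    wt[, c] <- as.vector(block[flip, , drop = FALSE])
  }
  wt
}

srcnn_backward <- function(weights, cfg, x, fwd, target) {
  k <- cfg$kernel_sizes; sl <- cfg$leaky_slope
  ch <- layer_channels(cfg)
  n <- length(target)
  d3 <- fwd$y
  d3[] <- 2 * (as.vector(fwd$y) - as.vector(target)) / n
  gW3 <- cpp_conv2d_gradw(fwd$z2, d3, k[3])
  gb3 <- apply(d3, 3, sum)
  wt3 <- flip_weights(weights$W3, k[3], ch[3], ch[4])
  dz2 <- cpp_conv2d(d3, wt3, numeric(ch[3]), k[3])
  d2 <- dz2 * lrelu_grad(fwd$a2, sl)
  gW2 <- cpp_conv2d_gradw(fwd$z1, d2, k[2])
  gb2 <- apply(d2, 3, sum)
  wt2 <- flip_weights(weights$W2, k[2], ch[2], ch[3])
  dz1 <- cpp_conv2d(d2, wt2, numeric(ch[2]), k[2])
  d1 <- dz1 * lrelu_grad(fwd$a1, sl)
  gW1 <- cpp_conv2d_gradw(as_cube(x), d1, k[1])
  gb1 <- apply(d1, 3, sum)
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2, W3 = gW3, b3 = gb3)
}

#' Extract aligned random LR/HR patch pairs
#'
#' Per pair, `patches_per_image` square crops at identical, uniformly random
#' positions in the LR and HR image; deterministic under `tc$seed`.
#'
#' @param pairs list of `list(lr = , hr = )` matrices of equal size.
#' @param tc a [train_config()].
#' @return list of `list(lr, hr, row, col)` patches.
#' @export
extract_patches <- function(pairs, tc) {
  stop_if_not(inherits(tc, "train_config"), "tc must be a train_config")
  stop_if_not(length(pairs) > 0, "pairs must be nonempty")
  p <- tc$patch_size_px
  withr::with_seed(tc$seed, {
    out <- vector("list", length(pairs) * tc$patches_per_image)
    t <- 0L
    for (pr in pairs) {
      stop_if_not(all(dim(pr$lr) == dim(pr$hr)),
                  "lr and hr of a pair must have identical shapes")
      h <- nrow(pr$hr); w <- ncol(pr$hr)
      stop_if_not(p <= h && p <= w, "image smaller than the patch size")
      for (j in seq_len(tc$patches_per_image)) {
        r0 <- sample.int(h - p + 1L, 1L)
        c0 <- sample.int(w - p + 1L, 1L)
        t <- t + 1L
        out[[t]] <- list(lr = pr$lr[r0:(r0 + p - 1L), c0:(c0 + p - 1L)],
                         hr = pr$hr[r0:(r0 + p - 1L), c0:(c0 + p - 1L)],
                         row = r0, col = c0)
      }
    }
    out
  })
}

adam_init <- function(weights) {
  list(m = lapply(weights, function(w) w * 0),
       v = lapply(weights, function(w) w * 0), t = 0L)
}

adam_step <- function(weights, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(weights)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    weights[[nm]] <- weights[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(weights = weights, state = state)
}

patch_mse <- function(weights, cfg, patches) {
  mean(vapply(patches, function(p) {
    mean((as.vector(srcnn_forward(weights, cfg, p$lr)) - as.vector(p$hr))^2)
  }, 0))
}

#' Epoch index selected by best-validation checkpointing
#'
#' @param history data.frame with a `val_mse` column.
#' @return index of the first minimum of the validation loss.
#' @export
best_checkpoint <- function(history) {
  stop_if_not(is.data.frame(history) && "val_mse" %in% names(history) &&
                nrow(history) > 0, "history must have a val_mse column")
  which.min(history$val_mse)
}

#' Train an SRCNN on paired LR/HR images
#'
#' Minimizes pixelwise MSE with Adam over randomly cropped aligned patches;
#' validation loss is computed once per epoch over the full validation patch
#' set, and the returned weights are those of the epoch with the lowest
#' validation loss. Seeded runs are reproducible.
#'
#' @param model an `srcnn_model` from [build_model()].
#' @param train_pairs,val_pairs nonempty lists of `list(lr =, hr =)` pairs.
#' @param tc a [train_config()].
#' @param verbose print per-epoch losses.
#' @return the trained `srcnn_model`, with `history` (per-epoch train/val
#'   MSE) and `best_epoch` populated.
#' @export
train_srcnn <- function(model, train_pairs, val_pairs, tc = train_config(),
                        verbose = FALSE) {
  stop_if_not(inherits(model, "srcnn_model"), "model must be an srcnn_model")
  stop_if_not(length(train_pairs) > 0 && length(val_pairs) > 0,
              "train and validation sets must be nonempty")
  cfg <- model$config
  tr_patches <- extract_patches(train_pairs, tc)
  val_tc <- tc
  val_tc$seed <- tc$seed + 1L
  val_patches <- extract_patches(val_pairs, val_tc)
  weights <- model$weights
  state <- adam_init(weights)
  n_p <- length(tr_patches)
  history <- data.frame(epoch = integer(), train_mse = numeric(),
                        val_mse = numeric())
  best <- list(val = Inf, weights = weights, epoch = NA_integer_)
  order_seeds <- derive_seeds(tc$seed + 2L, tc$epochs)
  for (ep in seq_len(tc$epochs)) {
    ord <- withr::with_seed(order_seeds[ep], sample.int(n_p))
    ep_loss <- 0
    n_batches <- 0L
    for (b0 in seq(1L, n_p, by = tc$batch_size)) {
      idx <- ord[b0:min(b0 + tc$batch_size - 1L, n_p)]
      grads <- NULL
      loss <- 0
      for (i in idx) {
        p <- tr_patches[[i]]
        fwd <- srcnn_forward(weights, cfg, p$lr, keep = TRUE)
        loss <- loss + mean((as.vector(fwd$y) - as.vector(p$hr))^2)
        g <- srcnn_backward(weights, cfg, p$lr, fwd, p$hr)
        grads <- if (is.null(grads)) g else Map(`+`, grads, g)
      }
      grads <- lapply(grads, `/`, length(idx))
      loss <- loss / length(idx)
      if (!is.finite(loss)) {
        stop(sprintf("training diverged to non-finite loss at epoch %d", ep),
             call. = FALSE)
      }
      upd <- adam_step(weights, grads, state, tc$learning_rate)
      weights <- upd$weights
      state <- upd$state
      ep_loss <- ep_loss + loss
      n_batches <- n_batches + 1L
    }
    val_mse <- patch_mse(weights, cfg, val_patches)
    history <- rbind(history, data.frame(epoch = ep,
                                         train_mse = ep_loss / n_batches,
                                         val_mse = val_mse))
    if (val_mse < best$val) best <- list(val = val_mse, weights = weights,
                                         epoch = ep)
    if (verbose) {
      message(sprintf("epoch %3d  train %.6g  val %.6g", ep,
                      ep_loss / n_batches, val_mse))
    }
  }
  model$weights <- best$weights
  model$trained <- TRUE
  model$history <- history
  model$best_epoch <- best$epoch
  model
}

#' Super-resolve a full image
#'
#' Single forward pass over the whole image (no tiling); the output is clipped
#' to `[0, 1]` and has the input's shape.
#'
#' @param model a trained `srcnn_model`.
#' @param lr numeric matrix in `[0, 1]`.
#' @return super-resolved matrix in `[0, 1]`.
#' @export
super_resolve <- function(model, lr) {
  stop_if_not(inherits(model, "srcnn_model"), "model must be an srcnn_model")
  stop_if_not(isTRUE(model$trained), "model has not been trained")
  assert_gray(lr)
  y <- srcnn_forward(model$weights, model$config, lr)
  clamp01(matrix(y[, , 1], nrow(lr), ncol(lr)))
}

#' Save / load a trained model
#'
#' Weights and metadata are stored as a single JSON file (plain text), with
#' the architecture config, training history and best epoch alongside the
#' weight matrices.
#'
#' @param model an `srcnn_model`.
#' @param path output `.json` path.
#' @return `path` invisibly (`save_model`); an `srcnn_model` (`load_model`).
#' @export
save_model <- function(model, path) {
  stop_if_not(inherits(model, "srcnn_model"), "model must be an srcnn_model")
  obj <- list(config = unclass(model$config),
              weights = model$weights, trained = model$trained,
              history = model$history, best_epoch = model$best_epoch)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::fromJSON(readLines(path), simplifyMatrix = TRUE)
  cfg <- do.call(srcnn_config, obj$config[c("kernel_sizes", "channels",
                                            "input_channels", "leaky_slope")])
  weights <- lapply(obj$weights, function(w) if (is.matrix(w)) w else as.numeric(w))
  ch <- layer_channels(cfg)
  for (i in 1:3) {  # length-1 dims collapse in JSON; restore matrix shape
    nm <- paste0("W", i)
    if (!is.matrix(weights[[nm]])) {
      weights[[nm]] <- matrix(weights[[nm]], cfg$kernel_sizes[i]^2 * ch[i],
                              ch[i + 1])
    }
  }
  structure(list(config = cfg, weights = weights,
                 trained = isTRUE(obj$trained),
                 history = if (is.null(obj$history)) NULL else as.data.frame(obj$history),
                 best_epoch = obj$best_epoch),
            class = "srcnn_model")
}
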