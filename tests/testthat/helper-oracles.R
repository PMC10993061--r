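# Independent oracles, written against the documented contracts and kept
# deliberately naive (plain loops, no shared code with the implementation).

# Brute-force sparse-acquisition oracle: per-block loops over the FOV tiling,
# ROI centered in the clipped block extent, offset applied, ROI clipped to the
# image; block mean fills the block.
brute_degrade <- function(hr, m_px, s_px, off_dy, off_dx) {
  h <- nrow(hr); w <- ncol(hr)
  nby <- ceiling(h / s_px); nbx <- ceiling(w / s_px)
  lr <- matrix(NA_real_, h, w)
  means <- matrix(NA_real_, nby, nbx)
  mask <- matrix(FALSE, h, w)
  for (by in seq_len(nby)) {
    for (bx in seq_len(nbx)) {
      y0 <- (by - 1) * s_px + 1
      x0 <- (bx - 1) * s_px + 1
      y1 <- min(y0 + s_px - 1, h)
      x1 <- min(x0 + s_px - 1, w)
      ry <- y0 + floor(((y1 - y0 + 1) - m_px) / 2) + off_dy[by, bx]
      rx <- x0 + floor(((x1 - x0 + 1) - m_px) / 2) + off_dx[by, bx]
      rows <- intersect(ry:(ry + m_px - 1), 1:h)
      cols <- intersect(rx:(rx + m_px - 1), 1:w)
      if (length(rows) == 0 || length(cols) == 0) {
        mu <- mean(hr[y0:y1, x0:x1])
      } else {
        acc <- 0
        for (cc in cols) for (r in rows) {  # column-major, R's natural order
          acc <- acc + hr[r, cc]
          mask[r, cc] <- TRUE
        }
        mu <- acc / (length(rows) * length(cols))
      }
      means[by, bx] <- mu
      lr[y0:y1, x0:x1] <- mu
    }
  }
  list(lr = lr, means = means, mask = mask)
}

# Direct 2-D convolution (cross-correlation) with zero "same" padding, naive
# quadruple loop; x: H x W x Cin array, w_arr: k x k x Cin x Cout array.
brute_conv2d <- function(x, w_arr, bias, k) {
  if (length(dim(x)) == 2) dim(x) <- c(dim(x), 1)
  h <- dim(x)[1]; w <- dim(x)[2]; cin <- dim(x)[3]
  cout <- dim(w_arr)[4]
  pad <- (k - 1) / 2
  out <- array(0, c(h, w, cout))
  for (o in seq_len(cout)) {
    acc <- matrix(bias[o], h, w)
    for (c in seq_len(cin)) {
      for (ki in seq_len(k)) {
        for (kj in seq_len(k)) {
          shifted <- matrix(0, h, w)
          rs <- (1:h) + ki - 1 - pad
          cs <- (1:w) + kj - 1 - pad
          ok_r <- rs >= 1 & rs <= h
          ok_c <- cs >= 1 & cs <= w
          shifted[ok_r, ok_c] <- x[rs[ok_r], cs[ok_c], c]
          acc <- acc + w_arr[ki, kj, c, o] * shifted
        }
      }
    }
    out[, , o] <- acc
  }
  out
}

# Convert the package's (k*k*cin) x cout weight matrix into the k x k x cin x
# cout array the brute-force oracle expects (row index ki + k*kj + k*k*c,
# 0-based).
weights_to_array <- function(W, k, cin, cout) {
  arr <- array(0, c(k, k, cin, cout))
  for (o in seq_len(cout)) {
    for (c in seq_len(cin)) {
      for (kj in seq_len(k)) {
        for (ki in seq_len(k)) {
          arr[ki, kj, c, o] <- W[(ki - 1) + k * (kj - 1) + k * k * (c - 1) + 1, o]
        }
      }
    }
  }
  arr
}

# Hexagonal-lattice comb oracle: enumerate candidate core centers, assign each
# pixel to the nearest, per-core means by explicit accumulation.
brute_comb <- function(image, pitch_px, radius_px, atten) {
  h <- nrow(image); w <- ncol(image)
  dy <- pitch_px * sqrt(3) / 2
  centers <- list()
  for (j in 0:ceiling((h - 1) / dy + 1)) {
    off <- (j %% 2) * pitch_px / 2
    for (i in floor(-off / pitch_px - 1):ceiling((w - 1 - off) / pitch_px + 1)) {
      centers[[length(centers) + 1]] <- c(y = j * dy, x = i * pitch_px + off)
    }
  }
  cen <- do.call(rbind, centers)
  assign_id <- matrix(NA_integer_, h, w)
  for (r in 1:h) {
    for (cc in 1:w) {
      d2 <- (cen[, "y"] - (r - 1))^2 + (cen[, "x"] - (cc - 1))^2
      i_min <- which.min(d2)
      if (d2[i_min] <= radius_px^2) assign_id[r, cc] <- i_min
    }
  }
  out <- image * (1 - atten)
  for (id in unique(assign_id[!is.na(assign_id)])) {
    sel <- !is.na(assign_id) & assign_id == id
    out[sel] <- mean(image[sel])
  }
  out
}

# Pooled-variance two-sample t statistic from the textbook formula.
brute_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp <- sqrt(((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2))
  t <- (mean(a) - mean(b)) / (sp * sqrt(1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Deterministic small phantom for image-level tests.
tiny_phantom <- function(seed = 1L, h = 96L, w = 96L,
                         class_label = "non_neoplastic", ...) {
  generate_phantom(phantom_preset(class_label, height_px = h, width_px = w,
                                  seed = seed, ...))$image
}
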