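# Sparse "brush" acquisition model for an end-expandable fiber probe.
#
# The expanded bundle samples tissue discontinuously: each fiber strand (an
# m x m pixel ROI) sits near the center of the s x s pixel FOV tile it is
# responsible for, possibly displaced by a random deformation offset of at
# most d pixels per axis (strand flexibility). A fiber reports one number --
# the mean intensity over its ROI -- and the low-resolution image is
# reconstituted by filling each FOV tile with its fiber's value.

#' Degradation model parameters
#'
#' Fiber geometry in micrometres: fiber (ROI) diameter `m`, inter-fiber
#' distance (FOV tile side) `s`, and maximum deformation offset per axis `d`,
#' plus the physical pixel size used to convert to pixel units.
#'
#' @param m_um fiber diameter (ROI side), um; `0 < m_um <= s_um`.
#' @param s_um inter-fiber distance (FOV tile side), um.
#' @param d_um maximum deformation offset per axis, um; `>= 0` (default 0).
#' @param pixel_size_um physical pixel size, um (default 2).
#' @param seed integer seed for the per-tile random offsets.
#' @return object of class `degradation_params`.
#' @export
degradation_params <- function(m_um, s_um, d_um = 0, pixel_size_um = 2,
                               seed = 1L) {
  stop_if_not(is_number(m_um) && m_um > 0, "m_um must be > 0")
  stop_if_not(is_number(s_um) && s_um >= m_um, "need 0 < m_um <= s_um")
  stop_if_not(is_number(d_um) && d_um >= 0, "d_um must be >= 0")
  stop_if_not(is_number(pixel_size_um) && pixel_size_um > 0,
              "pixel_size_um must be > 0")
  p <- structure(list(m_um = m_um, s_um = s_um, d_um = d_um,
                      pixel_size_um = pixel_size_um, seed = as.integer(seed)),
                 class = "degradation_params")
  to_pixel_params(p)  # validates the pixel-unit geometry
  p
}

#' Convert degradation parameters to pixel units
#'
#' Half-up rounding of each length by the pixel size. Rounding is monotone, so
#' `m_px <= s_px` is preserved; `m_px >= 1` is required.
#'
#' @param p a [degradation_params()].
#' @return named integer vector `c(m_px, s_px, d_px)`.
#' @export
to_pixel_params <- function(p) {
  stop_if_not(inherits(p, "degradation_params"),
              "p must be a degradation_params")
  m_px <- as.integer(round_half_up(p$m_um / p$pixel_size_um))
  s_px <- as.integer(round_half_up(p$s_um / p$pixel_size_um))
  d_px <- as.integer(round_half_up(p$d_um / p$pixel_size_um))
  stop_if_not(m_px >= 1, "fiber diameter rounds to less than one pixel")
  stop_if_not(m_px <= s_px, "m_px must not exceed s_px after rounding")
  c(m_px = m_px, s_px = s_px, d_px = d_px)
}

#' Sample per-tile deformation offsets
#'
#' Independent integer offsets per FOV tile and axis, each uniform on
#' `{-d_px, ..., +d_px}`; deterministic under `seed`.
#'
#' @param n_blocks_y,n_blocks_x tile grid size.
#' @param d_px maximum offset per axis, pixels (`>= 0`).
#' @param seed integer seed.
#' @return list with integer matrices `dy` and `dx` (`n_blocks_y` x
#'   `n_blocks_x`).
#' @export
sample_offsets <- function(n_blocks_y, n_blocks_x, d_px, seed = 1L) {
  stop_if_not(is_count(n_blocks_y) && is_count(n_blocks_x),
              "block counts must be positive integers")
  stop_if_not(is_number(d_px) && d_px >= 0 && d_px == round(d_px),
              "d_px must be a non-negative integer")
  n <- n_blocks_y * n_blocks_x
  if (d_px == 0) {
    z <- matrix(0L, n_blocks_y, n_blocks_x)
    return(list(dy = z, dx = z))
  }
  withr::with_seed(seed, {
    vals <- (-d_px):d_px
    list(dy = matrix(sample(vals, n, replace = TRUE), n_blocks_y, n_blocks_x),
         dx = matrix(sample(vals, n, replace = TRUE), n_blocks_y, n_blocks_x))
  })
}

#' Simulate sparse brush acquisition and LR reconstitution
#'
#' Tiles the image into `s_px x s_px` FOV blocks anchored at the top-left
#' corner (rectangular tiling). In each block an `m_px x m_px` ROI is centered
#' within the block's clipped extent (top-left at `floor((ext - m_px)/2)`,
#' which may be negative for thin edge blocks), shifted by the block's sampled
#' offset, and intersected with the image bounds. The mean over the surviving
#' ROI pixels fills the whole FOV block of the reconstituted LR image. Edge
#' blocks of images not divisible by `s_px` are processed with their clipped
#' extents. In the degenerate case of an offset pushing a ROI entirely outside
#' the image, the block falls back to the mean over its clipped FOV extent.
#'
#' @param hr numeric matrix in `[0, 1]`, both dimensions `>= s_px`.
#' @param params a [degradation_params()].
#' @param offsets optional precomputed offsets (as from [sample_offsets()]),
#'   e.g. to freeze one simulated probe across a dataset; default draws fresh
#'   offsets from `params$seed`.
#' @return object of class `sparse_acquisition`: list with `sparse_values`
#'   (matrix, non-sampled pixels `NA`), `mask` (logical matrix of populated
#'   pixels), `offsets`, `lr_image` (fully populated matrix, constant within
#'   each FOV block), `block_means`, and `pixel_params`.
#' @export
degrade <- function(hr, params, offsets = NULL) {
  assert_gray(hr)
  pp <- to_pixel_params(params)
  m <- pp[["m_px"]]; s <- pp[["s_px"]]; d <- pp[["d_px"]]
  h <- nrow(hr); w <- ncol(hr)
  stop_if_not(s <= h && s <= w,
              "inter-fiber distance exceeds an image dimension")
  nby <- as.integer(ceiling(h / s)); nbx <- as.integer(ceiling(w / s))
  if (is.null(offsets)) offsets <- sample_offsets(nby, nbx, d, params$seed)
  stop_if_not(all(dim(offsets$dy) == c(nby, nbx)) &&
                all(dim(offsets$dx) == c(nby, nbx)),
              "offsets table does not match the tile grid")

  y0 <- matrix((seq_len(nby) - 1L) * s + 1L, nby, nbx)        # block origin
  x0 <- matrix(rep((seq_len(nbx) - 1L) * s + 1L, each = nby), nby, nbx)
  ext_y <- pmin(y0 + s - 1L, h) - y0 + 1L                     # clipped extent
  ext_x <- pmin(x0 + s - 1L, w) - x0 + 1L
  ry0 <- y0 + floor((ext_y - m) / 2) + offsets$dy             # ROI top-left
  rx0 <- x0 + floor((ext_x - m) / 2) + offsets$dx

  sums <- matrix(0, nby, nbx)
  cnts <- matrix(0L, nby, nbx)
  mask <- matrix(FALSE, h, w)
  roi_lin <- vector("list", m * m)
  roi_ok <- vector("list", m * m)
  t <- 0L
  for (l in 0:(m - 1L)) {
    for (k in 0:(m - 1L)) {
      rr <- ry0 + k; cc <- rx0 + l
      ok <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
      lin <- (pmin(pmax(cc, 1L), w) - 1L) * h + pmin(pmax(rr, 1L), h)
      vals <- hr[as.vector(lin)]     # linear indexing (lin may be 2-column)
      dim(vals) <- dim(lin)
      vals[!ok] <- 0
      sums <- sums + vals
      cnts <- cnts + ok
      mask[lin[ok]] <- TRUE
      t <- t + 1L
      roi_lin[[t]] <- lin
      roi_ok[[t]] <- ok
    }
  }
  means <- sums / cnts
  if (any(empty <- cnts == 0L)) {
    # offset pushed the whole ROI outside the image: fall back to the mean
    # over the clipped FOV extent
    idx <- which(empty)
    for (b in idx) {
      rows <- y0[b]:(y0[b] + ext_y[b] - 1L)
      cols <- x0[b]:(x0[b] + ext_x[b] - 1L)
      means[b] <- mean(hr[rows, cols])
    }
  }

  sparse_values <- matrix(NA_real_, h, w)
  for (t in seq_len(m * m)) {
    ok <- as.vector(roi_ok[[t]])
    sparse_values[as.vector(roi_lin[[t]])[ok]] <- means[ok]
  }
  rowmap <- rep(seq_len(nby), each = s)[1:h]
  colmap <- rep(seq_len(nbx), each = s)[1:w]
  lr_image <- means[rowmap, colmap, drop = FALSE]
  dimnames(lr_image) <- NULL

  structure(list(sparse_values = sparse_values, mask = mask,
                 offsets = offsets, lr_image = lr_image, block_means = means,
                 pixel_params = pp, params = params),
            class = "sparse_acquisition")
}

#' Reconstitute a full image from a sparse acquisition
#'
#' `"block_fill"` (the probe's reconstitution rule) fills each FOV tile with
#' its fiber's value and reproduces the acquisition's `lr_image` exactly.
#' `"bilinear"` is a comparison baseline that interpolates bilinearly between
#' nominal FOV block centers (edges clamped).
#'
#' @param sparse a `sparse_acquisition` from [degrade()].
#' @param method `"block_fill"` or `"bilinear"`.
#' @return numeric matrix of the acquisition's full image size.
#' @export
interpolate_sparse <- function(sparse, method = c("block_fill", "bilinear")) {
  stop_if_not(inherits(sparse, "sparse_acquisition"),
              "sparse must be a sparse_acquisition")
  stop_if_not(any(sparse$mask), "mask is empty")
  method <- match.arg(method)
  if (method == "block_fill") return(sparse$lr_image)
  s <- sparse$pixel_params[["s_px"]]
  B <- sparse$block_means
  h <- nrow(sparse$lr_image); w <- ncol(sparse$lr_image)
  centers_y <- (seq_len(nrow(B)) - 0.5) * s
  centers_x <- (seq_len(ncol(B)) - 0.5) * s
  interp_1d <- function(centers, vals_mat, at) {
    # linear interpolation of each column of vals_mat at positions `at`,
    # clamped beyond the outermost centers
    apply(vals_mat, 2, function(v) {
      if (length(centers) == 1L) rep(v, length(at))
      else stats::approx(centers, v, xout = at, rule = 2)$y
    })
  }
  rows_at <- seq_len(h) - 0.5
  cols_at <- seq_len(w) - 0.5
  tmp <- interp_1d(centers_y, B, rows_at)                 # h x nbx
  tmp <- matrix(tmp, nrow = h)
  out <- t(interp_1d(centers_x, t(tmp), cols_at))         # h x w
  matrix(out, h, w)
}
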