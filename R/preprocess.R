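# Standard microendoscopy preprocessing chain: size standardization,
# Gaussian de-combing, contrast-limited adaptive histogram equalization.

#' Preprocessing configuration
#'
#' @param target_height_px,target_width_px standardized frame size
#'   (defaults 960 x 1280).
#' @param gaussian_sigma_px standard deviation of the de-combing Gaussian in
#'   pixels (default 2, which suppresses the core-lattice spatial frequency of
#'   fused bundles).
#' @param clahe_clip_limit CLAHE clip limit as a fraction of each tile's pixel
#'   count at which the normalized histogram is clipped; in `(0, 1]`, default
#'   0.005.
#' @param clahe_tile_grid integer vector `c(nx, ny)` of tiles (default 8 x 8).
#' @return object of class `preprocess_config`.
#' @export
preprocess_config <- function(target_height_px = 960L, target_width_px = 1280L,
                              gaussian_sigma_px = 2,
                              clahe_clip_limit = 0.005,
                              clahe_tile_grid = c(8L, 8L)) {
  stop_if_not(is_count(target_height_px) && is_count(target_width_px),
              "target sizes must be positive integers")
  stop_if_not(is_number(gaussian_sigma_px) && gaussian_sigma_px >= 0,
              "gaussian_sigma_px must be >= 0")
  stop_if_not(is_number(clahe_clip_limit) &&
                clahe_clip_limit > 0 && clahe_clip_limit <= 1,
              "clahe_clip_limit must be in (0, 1]")
  stop_if_not(length(clahe_tile_grid) == 2L && all(clahe_tile_grid >= 1),
              "clahe_tile_grid must be two positive integers")
  structure(list(target_height_px = as.integer(target_height_px),
                 target_width_px = as.integer(target_width_px),
                 gaussian_sigma_px = gaussian_sigma_px,
                 clahe_clip_limit = clahe_clip_limit,
                 clahe_tile_grid = as.integer(clahe_tile_grid)),
            class = "preprocess_config")
}

#' Standardize image size
#'
#' Brings an image to exactly `height x width`: larger inputs are
#' center-cropped, smaller inputs reflect-padded (symmetric mirror including
#' the edge sample). Intensity values are untouched; no resampling occurs, so
#' the physical pixel size is preserved.
#'
#' @param image numeric matrix.
#' @param height,width target size (defaults 960 x 1280).
#' @return matrix of exactly `height x width`.
#' @export
standardize_size <- function(image, height = 960L, width = 1280L) {
  assert_gray(image, unit_range = FALSE)
  stop_if_not(is_count(height) && is_count(width),
              "height and width must be positive integers")
  dim_index <- function(src, target) {
    if (src >= target) {
      start <- floor((src - target) / 2) + 1L
      start:(start + target - 1L)
    } else {
      pad_l <- floor((target - src) / 2)
      reflect_index((1L - pad_l):(target - pad_l), src)
    }
  }
  image[dim_index(nrow(image), height), dim_index(ncol(image), width),
        drop = FALSE]
}

#' Gaussian de-combing filter
#'
#' 2-D Gaussian convolution (separable, reflect boundary, kernel truncated at
#' 4 standard deviations) used to remove the fiber-core comb pattern from raw
#' bundle images. `sigma_px = 0` is the identity. The filter is linear and,
#' thanks to the reflect boundary and normalized kernel, preserves the global
#' image mean.
#'
#' @param image numeric matrix.
#' @param sigma_px Gaussian standard deviation in pixels (default 2).
#' @return filtered matrix, same shape.
#' @export
gaussian_decomb <- function(image, sigma_px = 2) {
  assert_gray(image, unit_range = FALSE)
  stop_if_not(is_number(sigma_px) && sigma_px >= 0, "sigma_px must be >= 0")
  sep_gaussian_filter(image, sigma_px, truncate = 4)
}

#' Contrast-limited adaptive histogram equalization
#'
#' Tile-wise clipped-histogram equalization with bilinear interpolation
#' between tile mappings (Zuiderveld's algorithm, via EBImage). The clip limit
#' is expressed as the fraction of a tile's pixel count at which the
#' normalized histogram is clipped (so 0.005 caps every histogram bin at 0.5%
#' of the tile's pixels). Images whose dimensions are not divisible by the
#' tile grid are reflect-padded to a multiple and cropped back. Constant
#' images are returned unchanged (a degenerate histogram has no contrast to
#' amplify).
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param clip_limit normalized clip limit in `(0, 1]` (default 0.005).
#' @param tile_grid integer `c(nx, ny)` tile counts (default 8 x 8).
#' @param bins number of histogram bins (default 256).
#' @return equalized matrix in `[0, 1]`, same shape.
#' @export
clahe <- function(image, clip_limit = 0.005, tile_grid = c(8L, 8L),
                  bins = 256L) {
  assert_gray(image)
  stop_if_not(is_number(clip_limit) && clip_limit > 0 && clip_limit <= 1,
              "clip_limit must be in (0, 1]")
  stop_if_not(length(tile_grid) == 2L && all(tile_grid >= 1),
              "tile_grid must be two positive integers")
  if (diff(range(image)) == 0) return(image)
  h <- nrow(image); w <- ncol(image)
  nx <- as.integer(tile_grid[1]); ny <- as.integer(tile_grid[2])
  hp <- as.integer(ceiling(h / ny) * ny)
  wp <- as.integer(ceiling(w / nx) * nx)
  padded <- image[reflect_index(1:hp, h), reflect_index(1:wp, w), drop = FALSE]
  # EBImage's limit is a multiple of the uniform bin height (tile_px / bins);
  # a clip fraction f of the tile pixel count corresponds to limit = f * bins.
  eq <- EBImage::clahe(padded, nx = nx, ny = ny, bins = bins,
                       limit = clip_limit * bins)
  clamp01(matrix(as.numeric(eq), hp, wp)[1:h, 1:w, drop = FALSE])
}

#' Run the full preprocessing chain
#'
#' Size standardization, Gaussian de-combing, then CLAHE, in that order.
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param cfg a [preprocess_config()].
#' @return preprocessed matrix in `[0, 1]` of the configured target size.
#' @export
preprocess_image <- function(image, cfg = preprocess_config()) {
  stop_if_not(inherits(cfg, "preprocess_config"),
              "cfg must be a preprocess_config")
  out <- standardize_size(image, cfg$target_height_px, cfg$target_width_px)
  out <- gaussian_decomb(out, cfg$gaussian_sigma_px)
  clahe(clamp01(out), cfg$clahe_clip_limit, cfg$clahe_tile_grid)
}
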