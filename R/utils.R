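# Shared internal helpers: argument validation, reflect indexing, separable
# Gaussian filtering. All image rasters in this package are plain numeric
# matrices with values in [0, 1]; physical scale is carried by the spec or
# parameter objects (pixel_size_um), not by the matrix itself.

stop_if_not <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

is_count <- function(x) is_number(x) && x > 0 && x == round(x)

assert_gray <- function(x, name = "image", unit_range = TRUE) {
  stop_if_not(is.matrix(x) && is.numeric(x) && length(x) > 0,
              sprintf("%s must be a nonempty numeric matrix", name))
  if (unit_range) {
    stop_if_not(all(is.finite(x)) && min(x) >= 0 && max(x) <= 1,
                sprintf("%s values must lie in [0, 1]", name))
  }
  invisible(x)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

round_half_up <- function(x) floor(x + 0.5)

#' Reflect (symmetric) index mapping
#'
#' Maps arbitrary integer indices onto `1:n` by repeated mirror reflection
#' about the array boundaries, with the edge sample included in the mirror
#' (the "symmetric" convention: `0 -> 1`, `-1 -> 2`, `n+1 -> n`). Used for
#' reflect padding and reflect-boundary filtering.
#'
#' @param i integer vector of (possibly out-of-range) indices.
#' @param n array extent.
#' @return integer vector of indices in `1:n`.
#' @keywords internal
reflect_index <- function(i, n) {
  stop_if_not(is_count(n), "n must be a positive integer")
  j <- (i - 1L) %% (2L * n)
  ifelse(j >= n, 2L * n - 1L - j, j) + 1L
}

gaussian_kernel_1d <- function(sigma, truncate = 4) {
  stop_if_not(is_number(sigma) && sigma >= 0, "sigma must be >= 0")
  if (sigma == 0) return(1)
  r <- ceiling(truncate * sigma)
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian convolution with reflect (symmetric) boundary handling,
# kernel truncated at `truncate` standard deviations. sigma = 0 is the identity.
sep_gaussian_filter <- function(x, sigma, truncate = 4) {
  assert_gray(x, unit_range = FALSE)
  k <- gaussian_kernel_1d(sigma, truncate)
  if (length(k) == 1L) return(x)
  r <- (length(k) - 1L) %/% 2L
  h <- nrow(x); w <- ncol(x)
  xp <- x[reflect_index((1L - r):(h + r), h), , drop = FALSE]
  out <- matrix(0, h, w)
  for (t in seq_along(k)) {
    out <- out + k[t] * xp[t:(t + h - 1L), , drop = FALSE]
  }
  xp <- out[, reflect_index((1L - r):(w + r), w), drop = FALSE]
  out <- matrix(0, h, w)
  for (t in seq_along(k)) {
    out <- out + k[t] * xp[, t:(t + w - 1L), drop = FALSE]
  }
  out
}

# Derive a stream of sub-seeds from one master seed, each a valid 32-bit R seed.
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
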