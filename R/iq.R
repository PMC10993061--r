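# Traditional image-quality assessment (PSNR, SSIM) and the degradation
# parameter-sweep harness (offset, inter-fiber distance, fiber diameter).

#' Peak signal-to-noise ratio
#'
#' `10 * log10(peak^2 / MSE)` in decibels; identical images (`MSE = 0`) return
#' `Inf`.
#'
#' @param ref,test numeric matrices of identical shape.
#' @param peak peak signal value (default 1 for normalized floats).
#' @return PSNR in dB.
#' @export
psnr <- function(ref, test, peak = 1) {
  stop_if_not(is.matrix(ref) && is.matrix(test) && all(dim(ref) == dim(test)),
              "ref and test must be matrices of identical shape")
  stop_if_not(is_number(peak) && peak > 0, "peak must be > 0")
  mse <- mean((ref - test)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

#' Structural similarity index
#'
#' Mean local SSIM with an 11 x 11 Gaussian window (sigma = 1.5) and
#' stabilizers `C1 = (K1 * L)^2`, `C2 = (K2 * L)^2` on the declared dynamic
#' range `L` (Wang et al. defaults `K1 = 0.01`, `K2 = 0.03`). Local moments
#' are Gaussian-weighted population moments; a border of half the window is
#' cropped before averaging, so the result is boundary-independent.
#'
#' @param ref,test numeric matrices of identical shape, at least 11 x 11.
#' @param dynamic_range declared dynamic range `L` (default 1).
#' @param sigma Gaussian window standard deviation (default 1.5).
#' @param K1,K2 stabilizer constants.
#' @return scalar SSIM in `[-1, 1]`; exactly 1 iff the images are identical.
#' @export
ssim <- function(ref, test, dynamic_range = 1, sigma = 1.5,
                 K1 = 0.01, K2 = 0.03) {
  stop_if_not(is.matrix(ref) && is.matrix(test) && all(dim(ref) == dim(test)),
              "ref and test must be matrices of identical shape")
  r <- ceiling(3.5 * sigma - 0.5)       # 11 x 11 window at sigma = 1.5
  win <- 2L * r + 1L
  stop_if_not(min(dim(ref)) >= win,
              sprintf("images must be at least %d x %d", win, win))
  if (identical(dim(ref), dim(test)) && all(ref == test)) return(1)
  k <- gaussian_kernel_1d(sigma, truncate = r / sigma)
  stopifnot(length(k) == win)
  f <- function(x) sep_gaussian_filter(x, sigma, truncate = r / sigma)
  mu1 <- f(ref); mu2 <- f(test)
  s11 <- f(ref * ref) - mu1 * mu1
  s22 <- f(test * test) - mu2 * mu2
  s12 <- f(ref * test) - mu1 * mu2
  C1 <- (K1 * dynamic_range)^2
  C2 <- (K2 * dynamic_range)^2
  smap <- ((2 * mu1 * mu2 + C1) * (2 * s12 + C2)) /
    ((mu1^2 + mu2^2 + C1) * (s11 + s22 + C2))
  h <- nrow(ref); w <- ncol(ref)
  mean(smap[(r + 1):(h - r), (r + 1):(w - r)])
}

#' Evaluate LR and SR conditions against HR references
#'
#' Computes per-image PSNR and SSIM of the LR and SR estimates against their
#' HR references, plus per-condition aggregates (mean, SD, two-sided 95%
#' t-interval of the mean).
#'
#' @param hr_set,lr_set,sr_set lists of matrices aligned by position or by
#'   name; `sr_set` may be `NULL` to evaluate LR only.
#' @param peak,dynamic_range forwarded to [psnr()] and [ssim()].
#' @return list with `per_image` (data.frame: image_id, condition, psnr_db,
#'   ssim) and `summary` (data.frame: condition, metric, n, mean, sd, ci_lo,
#'   ci_hi).
#' @export
evaluate_conditions <- function(hr_set, lr_set, sr_set = NULL, peak = 1,
                                dynamic_range = 1) {
  stop_if_not(length(hr_set) == length(lr_set),
              "hr_set and lr_set must have equal length")
  ids <- names(hr_set)
  if (is.null(ids)) ids <- sprintf("img_%04d", seq_along(hr_set))
  check_ids <- function(set, nm) {
    if (!is.null(names(set)) && !is.null(names(hr_set)) &&
        !identical(names(set), names(hr_set))) {
      stop(sprintf("%s ids do not match hr_set ids", nm), call. = FALSE)
    }
  }
  check_ids(lr_set, "lr_set")
  conds <- list(LR = lr_set)
  if (!is.null(sr_set)) {
    stop_if_not(length(sr_set) == length(hr_set),
                "sr_set and hr_set must have equal length")
    check_ids(sr_set, "sr_set")
    conds$SR <- sr_set
  }
  rows <- do.call(rbind, lapply(names(conds), function(cn) {
    set <- conds[[cn]]
    data.frame(
      image_id = ids, condition = cn,
      psnr_db = vapply(seq_along(set),
                       function(i) psnr(hr_set[[i]], set[[i]], peak), 0),
      ssim = vapply(seq_along(set),
                    function(i) ssim(hr_set[[i]], set[[i]], dynamic_range), 0),
      stringsAsFactors = FALSE
    )
  }))
  summ <- do.call(rbind, lapply(unique(rows$condition), function(cn) {
    do.call(rbind, lapply(c("psnr_db", "ssim"), function(m) {
      v <- rows[[m]][rows$condition == cn]
      n <- length(v)
      mu <- mean(v); s <- sd(v)
      half <- if (n > 1 && is.finite(s)) qt(0.975, n - 1) * s / sqrt(n) else NA_real_
      data.frame(condition = cn, metric = m, n = n, mean = mu, sd = s,
                 ci_lo = mu - half, ci_hi = mu + half,
                 stringsAsFactors = FALSE)
    }))
  }))
  list(per_image = rows, summary = summ)
}

#' Degradation parameter sweep grid
#'
#' One-at-a-time sweep around a fixed baseline, mirroring the three panels of
#' the design study: deformation offset, inter-fiber distance, and fiber
#' diameter, each in micrometres.
#'
#' @param offsets_um offsets to sweep (default 0..10).
#' @param inter_fiber_um inter-fiber distances (default 4..24).
#' @param diameters_um fiber diameters (default 4..12).
#' @param baseline a [degradation_params()]; defaults to the demonstration
#'   configuration m = 4 um, s = 8 um, d = 0.
#' @return object of class `sweep_grid`.
#' @export
sweep_grid <- function(offsets_um = 0:10, inter_fiber_um = seq(4, 24, by = 2),
                       diameters_um = seq(4, 12, by = 2),
                       baseline = degradation_params(4, 8, 0)) {
  stop_if_not(inherits(baseline, "degradation_params"),
              "baseline must be a degradation_params")
  structure(list(offsets_um = offsets_um, inter_fiber_um = inter_fiber_um,
                 diameters_um = diameters_um, baseline = baseline),
            class = "sweep_grid")
}

sweep_points <- function(grid) {
  b <- grid$baseline
  panel <- function(parameter, values, m_um, s_um, d_um) {
    if (length(values) == 0) return(NULL)
    data.frame(parameter = parameter, value_um = values, m_um = m_um,
               s_um = s_um, d_um = d_um)
  }
  pts <- rbind(
    panel("offset", grid$offsets_um, b$m_um, b$s_um, grid$offsets_um),
    panel("inter_fiber_distance", grid$inter_fiber_um, b$m_um,
          grid$inter_fiber_um, b$d_um),
    panel("fiber_diameter", grid$diameters_um, grid$diameters_um, b$s_um,
          b$d_um)
  )
  stop_if_not(!is.null(pts), "sweep grid is empty")
  pts$feasible <- pts$m_um <= pts$s_um
  pts
}

#' Run a degradation parameter sweep
#'
#' For each grid point (one parameter varied from the baseline at a time):
#' degrade the HR test set, optionally retrain an SRCNN on degraded training
#' pairs at desk-scale settings, and record LR (and SR) image-quality
#' aggregates. Infeasible points (`m > s`) are skipped with a warning and
#' recorded.
#'
#' @param grid a [sweep_grid()].
#' @param hr_train,hr_test lists of HR matrices; `hr_train` is only needed
#'   when `train_cfg` is given.
#' @param train_cfg optional [train_config()]; `NULL` runs an LR-only sweep
#'   (no training).
#' @param model_cfg an [srcnn_config()].
#' @param seed master seed for per-point offset sampling and training.
#' @return data.frame with one row per (parameter, value, condition):
#'   `parameter`, `value_um`, `condition`, `n`, `mean_psnr_db`, `sd_psnr_db`,
#'   `mean_ssim`, `sd_ssim`, `skipped`.
#' @export
run_sweep <- function(grid, hr_test, hr_train = NULL, train_cfg = NULL,
                      model_cfg = srcnn_config(), seed = 1L) {
  stop_if_not(inherits(grid, "sweep_grid"), "grid must be a sweep_grid")
  stop_if_not(length(hr_test) > 0, "hr_test must be nonempty")
  if (!is.null(train_cfg)) {
    stop_if_not(length(hr_train) > 0,
                "hr_train is required when train_cfg is given")
  }
  pts <- sweep_points(grid)
  seeds <- derive_seeds(seed, nrow(pts))
  out <- list()
  for (i in seq_len(nrow(pts))) {
    pt <- pts[i, ]
    if (!pt$feasible) {
      warning(sprintf("skipping infeasible grid point %s = %g um (m > s)",
                      pt$parameter, pt$value_um), call. = FALSE)
      out[[length(out) + 1]] <- data.frame(
        parameter = pt$parameter, value_um = pt$value_um, condition = "LR",
        n = 0L, mean_psnr_db = NA_real_, sd_psnr_db = NA_real_,
        mean_ssim = NA_real_, sd_ssim = NA_real_, skipped = TRUE)
      next
    }
    params <- degradation_params(pt$m_um, pt$s_um, pt$d_um,
                                 grid$baseline$pixel_size_um, seed = seeds[i])
    img_seeds <- derive_seeds(seeds[i], length(hr_test) +
                                if (is.null(hr_train)) 0L else length(hr_train))
    deg_one <- function(img, sd) {
      p <- params; p$seed <- sd
      degrade(img, p)$lr_image
    }
    lr_test <- lapply(seq_along(hr_test), function(j)
      deg_one(hr_test[[j]], img_seeds[j]))
    sr_test <- NULL
    if (!is.null(train_cfg)) {
      lr_train <- lapply(seq_along(hr_train), function(j)
        deg_one(hr_train[[j]], img_seeds[length(hr_test) + j]))
      pairs <- Map(function(l, h) list(lr = l, hr = h), lr_train, hr_train)
      n_val <- max(1L, floor(length(pairs) / 5))
      val_idx <- seq_len(n_val)
      model <- build_model(model_cfg, seed = seeds[i])
      model <- train_srcnn(model, pairs[-val_idx], pairs[val_idx], train_cfg)
      sr_test <- lapply(lr_test, function(l) super_resolve(model, l))
    }
    ev <- evaluate_conditions(hr_test, lr_test, sr_test)
    agg <- ev$summary
    for (cn in unique(agg$condition)) {
      a <- agg[agg$condition == cn, ]
      out[[length(out) + 1]] <- data.frame(
        parameter = pt$parameter, value_um = pt$value_um, condition = cn,
        n = a$n[1],
        mean_psnr_db = a$mean[a$metric == "psnr_db"],
        sd_psnr_db = a$sd[a$metric == "psnr_db"],
        mean_ssim = a$mean[a$metric == "ssim"],
        sd_ssim = a$sd[a$metric == "ssim"], skipped = FALSE)
    }
  }
  do.call(rbind, out)
}
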