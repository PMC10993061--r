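# Synthetic microendoscopy phantoms.
#
# High-resolution microendoscopy of proflavine-stained epithelium shows bright
# nuclei on a dim cytoplasmic background, and the density of nuclei is the
# cue that separates neoplastic from non-neoplastic mucosa. The phantom module
# emulates exactly that statistical structure -- a homogeneous spatial Poisson
# process of elliptical nuclei with class-dependent density and pleomorphism --
# so every downstream stage (preprocessing, sparse-fiber degradation,
# super-resolution, image-quality and reader statistics) can be exercised and
# tested without clinical data.

#' Phantom specification
#'
#' Parameters of a synthetic microendoscopy phantom: field geometry, nuclear
#' density and morphology, intensities and sensor noise. Intensities are
#' fractions of the dynamic range (images are generated in `[0, 1]`).
#'
#' @param height_px,width_px field size in pixels (defaults 960 x 1280, the
#'   standardized microendoscopy frame).
#' @param pixel_size_um physical pixel size in micrometres (default 2).
#' @param nucleus_density_per_mm2 expected number of nuclei per square
#'   millimetre (intensity of the spatial Poisson process).
#' @param nucleus_radius_mean_um,nucleus_radius_sd_um mean and SD of the
#'   equivalent-circle nucleus radius in micrometres (truncated normal,
#'   truncated below at 0.5 um).
#' @param nucleus_eccentricity_max maximum ellipse eccentricity in `[0, 1)`;
#'   per-nucleus eccentricity is uniform on `[0, max]`.
#' @param nucleus_intensity,background_intensity nuclear and background
#'   intensity as fractions of the dynamic range; nuclei must be brighter.
#' @param noise_sd standard deviation of additive zero-mean Gaussian sensor
#'   noise, as a fraction of the dynamic range.
#' @param class_label `"neoplastic"` or `"non_neoplastic"`.
#' @param seed integer seed; the phantom is a pure function of spec + seed.
#' @return An object of class `phantom_spec`.
#' @seealso [phantom_preset()], [generate_phantom()]
#' @export
phantom_spec <- function(height_px = 960L, width_px = 1280L, pixel_size_um = 2,
                         nucleus_density_per_mm2 = 150,
                         nucleus_radius_mean_um = 6,
                         nucleus_radius_sd_um = 1.5,
                         nucleus_eccentricity_max = 0.4,
                         nucleus_intensity = 0.8,
                         background_intensity = 0.15,
                         noise_sd = 0.02,
                         class_label = c("non_neoplastic", "neoplastic"),
                         seed = 1L) {
  class_label <- match.arg(class_label)
  stop_if_not(is_count(height_px) && is_count(width_px),
              "height_px and width_px must be positive integers")
  stop_if_not(is_number(pixel_size_um) && pixel_size_um > 0,
              "pixel_size_um must be > 0")
  stop_if_not(is_number(nucleus_density_per_mm2) && nucleus_density_per_mm2 >= 0,
              "nucleus_density_per_mm2 must be >= 0")
  stop_if_not(is_number(nucleus_radius_mean_um) && nucleus_radius_mean_um > 0,
              "nucleus_radius_mean_um must be > 0")
  stop_if_not(is_number(nucleus_radius_sd_um) && nucleus_radius_sd_um >= 0,
              "nucleus_radius_sd_um must be >= 0")
  stop_if_not(is_number(nucleus_eccentricity_max) &&
                nucleus_eccentricity_max >= 0 && nucleus_eccentricity_max < 1,
              "nucleus_eccentricity_max must be in [0, 1)")
  for (v in c(nucleus_intensity, background_intensity, noise_sd)) {
    stop_if_not(is_number(v) && v >= 0 && v <= 1,
                "intensity and noise fields must be in [0, 1]")
  }
  stop_if_not(nucleus_intensity > background_intensity,
              "nucleus_intensity must exceed background_intensity (stained nuclei are bright)")
  field_um <- min(height_px, width_px) * pixel_size_um
  stop_if_not(field_um >= nucleus_radius_mean_um,
              "field is smaller than one mean nucleus radius")
  stop_if_not(is_count(seed + 1), "seed must be a non-negative integer")
  structure(list(
    height_px = as.integer(height_px), width_px = as.integer(width_px),
    pixel_size_um = pixel_size_um,
    nucleus_density_per_mm2 = nucleus_density_per_mm2,
    nucleus_radius_mean_um = nucleus_radius_mean_um,
    nucleus_radius_sd_um = nucleus_radius_sd_um,
    nucleus_eccentricity_max = nucleus_eccentricity_max,
    nucleus_intensity = nucleus_intensity,
    background_intensity = background_intensity,
    noise_sd = noise_sd, class_label = class_label, seed = as.integer(seed)
  ), class = "phantom_spec")
}

#' Class presets for phantom generation
#'
#' Preset phantom specifications for the two diagnostic classes. The
#' neoplastic preset has a 3x higher nuclear density (crowding), a doubled
#' radius SD and a higher eccentricity ceiling (pleomorphism) than the
#' non-neoplastic preset. Nuclear density is the diagnostic cue; the absolute
#' preset values are free parameters of the simulation, not claims about
#' esophageal biology.
#'
#' @param class_label `"neoplastic"` or `"non_neoplastic"`.
#' @param ... overrides passed on to [phantom_spec()] (e.g. `height_px`,
#'   `seed`).
#' @return A `phantom_spec`.
#' @export
phantom_preset <- function(class_label = c("non_neoplastic", "neoplastic"), ...) {
  class_label <- match.arg(class_label)
  base <- if (class_label == "neoplastic") {
    list(nucleus_density_per_mm2 = 450, nucleus_radius_mean_um = 6.5,
         nucleus_radius_sd_um = 3, nucleus_eccentricity_max = 0.7)
  } else {
    list(nucleus_density_per_mm2 = 150, nucleus_radius_mean_um = 6,
         nucleus_radius_sd_um = 1.5, nucleus_eccentricity_max = 0.4)
  }
  args <- utils::modifyList(c(base, list(class_label = class_label)), list(...))
  do.call(phantom_spec, args)
}

#' Generate a synthetic microendoscopy phantom
#'
#' Nuclei are placed by a homogeneous spatial Poisson process with intensity
#' `nucleus_density_per_mm2` over the field area. Each nucleus is a filled
#' ellipse (equivalent-circle radius from a truncated normal, orientation
#' uniform) rendered into a binary layer; overlapping nuclei combine by
#' maximum, the layer is smoothed with a 1-pixel Gaussian to give anti-aliased
#' edges, scaled between background and nuclear intensity, and degraded with
#' additive zero-mean Gaussian noise. The result is clipped to `[0, 1]` and is
#' a pure function of `spec` (including its seed).
#'
#' @param spec a [phantom_spec()].
#' @param render if `FALSE`, skip rasterization and return only the sampled
#'   nucleus population (fast path for statistical checks on counts).
#' @return A `labeled_image`: list with `image` (matrix in `[0,1]`, or `NULL`
#'   when `render = FALSE`), `label`, `quality` (`"good"`), `n_nuclei` (number
#'   of placed nucleus centers), and `spec` (provenance).
#' @export
generate_phantom <- function(spec, render = TRUE) {
  stop_if_not(inherits(spec, "phantom_spec"), "spec must be a phantom_spec")
  h <- spec$height_px; w <- spec$width_px; px <- spec$pixel_size_um
  area_mm2 <- h * w * px^2 / 1e6
  res <- withr::with_seed(spec$seed, {
    n <- rpois(1L, spec$nucleus_density_per_mm2 * area_mm2)
    cy <- runif(n, 0.5, h + 0.5)
    cx <- runif(n, 0.5, w + 0.5)
    r_um <- numeric(n)
    if (n > 0) {
      r_um <- rnorm(n, spec$nucleus_radius_mean_um, spec$nucleus_radius_sd_um)
      while (any(bad <- r_um < 0.5)) {
        r_um[bad] <- rnorm(sum(bad), spec$nucleus_radius_mean_um,
                           spec$nucleus_radius_sd_um)
      }
    }
    ecc <- runif(n, 0, spec$nucleus_eccentricity_max)
    theta <- runif(n, 0, pi)
    noise <- if (render && spec$noise_sd > 0) rnorm(h * w, 0, spec$noise_sd) else NULL
    list(n = n, cy = cy, cx = cx, r_px = r_um / px, ecc = ecc, theta = theta,
         noise = noise)
  })
  img <- NULL
  if (render) {
    layer <- matrix(0, h, w)
    if (res$n > 0) {
      # semi-axes preserving the equivalent-circle area pi * r^2
      a <- res$r_px / (1 - res$ecc^2)^0.25
      b <- res$r_px * (1 - res$ecc^2)^0.25
      ct <- cos(res$theta); st <- sin(res$theta)
      for (i in seq_len(res$n)) {
        m <- ceiling(a[i]) + 1L
        r0 <- max(1L, floor(res$cy[i] - m)); r1 <- min(h, ceiling(res$cy[i] + m))
        c0 <- max(1L, floor(res$cx[i] - m)); c1 <- min(w, ceiling(res$cx[i] + m))
        if (r0 > r1 || c0 > c1) next
        yy <- (r0:r1) - res$cy[i]
        xx <- (c0:c1) - res$cx[i]
        u <- outer(yy, xx * 0, "+") * ct[i] + outer(yy * 0, xx, "+") * st[i]
        v <- -outer(yy, xx * 0, "+") * st[i] + outer(yy * 0, xx, "+") * ct[i]
        q <- (u / a[i])^2 + (v / b[i])^2
        sub <- layer[r0:r1, c0:c1, drop = FALSE]
        layer[r0:r1, c0:c1] <- pmax(sub, (q <= 1) * 1)
      }
      layer <- clamp01(sep_gaussian_filter(layer, sigma = 1))
    }
    img <- spec$background_intensity +
      (spec$nucleus_intensity - spec$background_intensity) * layer
    if (!is.null(res$noise)) img <- img + res$noise
    img <- clamp01(img)
  }
  structure(list(image = img, label = spec$class_label, quality = "good",
                 n_nuclei = res$n, spec = spec),
            class = "labeled_image")
}

#' Fused-bundle comb pattern specification
#'
#' Geometry of the honeycomb artifact imprinted by discrete fiber cores in raw
#' bundle images: a hexagonal lattice of circular cores. Single fiber strands
#' in clinical bundles are 4-6 um in diameter; the default core is 4 um on a
#' 6 um pitch.
#'
#' @param core_diameter_um fiber-core diameter (um).
#' @param core_pitch_um center-to-center core spacing (um); must be >= the
#'   core diameter.
#' @param cladding_attenuation fraction in `[0, 1]` by which intensity between
#'   cores (the cladding) is attenuated.
#' @return An object of class `comb_spec`.
#' @export
comb_spec <- function(core_diameter_um = 4, core_pitch_um = 6,
                      cladding_attenuation = 0.5) {
  stop_if_not(is_number(core_diameter_um) && core_diameter_um > 0,
              "core_diameter_um must be > 0")
  stop_if_not(is_number(core_pitch_um) && core_pitch_um >= core_diameter_um,
              "core_pitch_um must be >= core_diameter_um")
  stop_if_not(is_number(cladding_attenuation) &&
                cladding_attenuation >= 0 && cladding_attenuation <= 1,
              "cladding_attenuation must be in [0, 1]")
  structure(list(core_diameter_um = core_diameter_um,
                 core_pitch_um = core_pitch_um, lattice = "hexagonal",
                 cladding_attenuation = cladding_attenuation),
            class = "comb_spec")
}

#' Imprint a fused-bundle comb pattern
#'
#' Overlays the honeycomb sampling artifact of a fused fiber bundle: each
#' circular core on a hexagonal lattice is filled with the mean of the
#' underlying image inside the core, and inter-core (cladding) pixels are
#' multiplied by `1 - cladding_attenuation`. Core centers sit at
#' `(x, y) = ((i + (j %% 2) / 2) * pitch, j * pitch * sqrt(3) / 2)` in 0-based
#' pixel units (rows `j >= 0`, columns `i` any integer); a pixel belongs to the
#' nearest center if its distance is at most the core radius.
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param comb a [comb_spec()].
#' @param pixel_size_um physical pixel size (um), default 2.
#' @return Matrix of the same shape, values in `[0, 1]`.
#' @export
apply_comb_pattern <- function(image, comb, pixel_size_um = 2) {
  assert_gray(image)
  stop_if_not(inherits(comb, "comb_spec"), "comb must be a comb_spec")
  h <- nrow(image); w <- ncol(image)
  pitch_px <- comb$core_pitch_um / pixel_size_um
  stop_if_not(pitch_px >= 1, "core pitch is smaller than one pixel")
  r_px <- comb$core_diameter_um / pixel_size_um / 2
  # nearest core center per pixel: candidate rows floor/ceil of y/dy, nearest
  # column within each row
  dy <- pitch_px * sqrt(3) / 2
  py <- rep(0:(h - 1), times = w)
  px <- rep(0:(w - 1), each = h)
  best_d2 <- rep(Inf, h * w)
  best_id <- numeric(h * w)
  jcand <- cbind(floor(py / dy), floor(py / dy) + 1)
  for (s in 1:2) {
    j <- jcand[, s]
    off <- (j %% 2) * pitch_px / 2
    i <- round((px - off) / pitch_px)
    cyc <- j * dy; cxc <- i * pitch_px + off
    d2 <- (py - cyc)^2 + (px - cxc)^2
    id <- j * 1e6 + (i + 1e5)  # unique center key
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_id[upd] <- id[upd]
  }
  in_core <- best_d2 <= r_px^2
  out <- image * (1 - comb$cladding_attenuation)
  if (any(in_core)) {
    vals <- as.vector(image)[in_core]
    grp <- best_id[in_core]
    sums <- rowsum(vals, grp)
    cnts <- rowsum(rep(1, length(vals)), grp)
    out[in_core] <- (sums / cnts)[match(as.character(grp), rownames(sums))]
  }
  clamp01(matrix(out, h, w))
}

#' Generate a labeled phantom dataset
#'
#' Generates `n` phantoms with `round(n * neoplastic_fraction)` drawn from the
#' neoplastic preset and the rest from the non-neoplastic preset, each with its
#' own derived seed. The whole dataset is a pure function of `seed`.
#'
#' @param n number of images (> 0).
#' @param neoplastic_fraction fraction of neoplastic images in `[0, 1]`.
#' @param seed master seed.
#' @param presets named list with elements `neoplastic` and `non_neoplastic`,
#'   each a list of overrides forwarded to [phantom_preset()] (e.g. reduced
#'   `height_px`/`width_px` for desk-scale runs).
#' @param render passed to [generate_phantom()].
#' @param out_dir if non-`NULL`, write 8-bit PNGs and a JSON-lines manifest.
#' @return list with `images` (list of `labeled_image`) and `manifest`
#'   (data.frame: `image_id`, `label`, `quality`, `seed`, `density_per_mm2`).
#' @export
generate_dataset <- function(n, neoplastic_fraction, seed = 1L,
                             presets = list(neoplastic = list(),
                                            non_neoplastic = list()),
                             render = TRUE, out_dir = NULL) {
  stop_if_not(is_count(n), "n must be a positive integer")
  stop_if_not(is_number(neoplastic_fraction) &&
                neoplastic_fraction >= 0 && neoplastic_fraction <= 1,
              "neoplastic_fraction must be in [0, 1]")
  n_neo <- round_half_up(n * neoplastic_fraction)
  labels <- rep(c("neoplastic", "non_neoplastic"), c(n_neo, n - n_neo))
  seeds <- derive_seeds(seed, n)
  images <- vector("list", n)
  for (i in seq_len(n)) {
    over <- presets[[labels[i]]]
    spec <- do.call(phantom_preset,
                    c(list(class_label = labels[i]), over, list(seed = seeds[i])))
    images[[i]] <- generate_phantom(spec, render = render)
  }
  ids <- sprintf("phantom_%04d", seq_len(n))
  manifest <- data.frame(
    image_id = ids, label = labels,
    quality = vapply(images, `[[`, "", "quality"),
    seed = seeds,
    density_per_mm2 = vapply(images, function(im) im$spec$nucleus_density_per_mm2, 0),
    n_nuclei = vapply(images, `[[`, 0L, "n_nuclei"),
    stringsAsFactors = FALSE
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    manifest$path <- file.path(out_dir, paste0(ids, ".png"))
    for (i in seq_len(n)) {
      if (render) write_gray_image(images[[i]]$image, manifest$path[i])
    }
    write_manifest(manifest, file.path(out_dir, "manifest.jsonl"),
                   specs = lapply(images, `[[`, "spec"))
  }
  list(images = images, manifest = manifest)
}
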