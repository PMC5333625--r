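#' Render an FM image of a CL pointer array
#'
#' Maps the commanded EM beam grid through the ground-truth transform and
#' distortion field into the FM pixel frame, renders each pointer as an
#' isotropic 2D Gaussian (a CL pointer's intensity profile is circularly
#' symmetric; default FWHM 300 nm, the optical diffraction limit), adds
#' the background, and applies Poisson shot noise on (signal + background)
#' plus additive Gaussian read noise.
#'
#' @param grid A [pointer_grid()] of commanded beam positions (EM frame).
#' @param gt A [scene_ground_truth()].
#' @param image_shape Length-2 integer: FM image size c(rows, cols).
#' @param noise Logical; set `FALSE` for a noiseless render (no Poisson,
#'   no read noise; background still added).
#' @param seed RNG seed; defaults to `gt$seed`.
#' @return A list: `image` (a [raster_image()], FM frame) and `truth`
#'   (tibble of true spot centers: `pointer_index`, `em_x`, `em_y`,
#'   `x`, `y` in FM px).
#' @examples
#' gt <- scene_ground_truth(seed = 2)
#' sc <- render_pointer_image(pointer_grid(4, 4, 800, origin = c(400, 400)),
#'                            gt, image_shape = c(260, 260))
#' nrow(sc$truth) # 16
#' @export
render_pointer_image <- function(grid, gt, image_shape = c(1040, 1040),
                                 noise = TRUE, seed = gt$seed) {
  stopifnot(inherits(grid, "pointer_grid"), inherits(gt, "scene_ground_truth"))
  ny <- assert_count(image_shape[1], "image_shape[1]")
  nx <- assert_count(image_shape[2], "image_shape[2]")
  gp <- grid_points(grid)
  p <- true_fm_positions(gt, gp$em_x, gp$em_y)
  fwhm_px <- gt$spot_fwhm_nm / gt$fm_pixel_size_nm
  margin <- 2 * fwhm_px
  if (any(p$x < margin | p$x > nx - 1 - margin | p$y < margin | p$y > ny - 1 - margin)) {
    abort(sprintf(
      "Mapped pointer grid leaves the %d x %d FM image (needs x in [%.1f, %.1f], y in [%.1f, %.1f]; got x in [%.1f, %.1f], y in [%.1f, %.1f]).",
      nx, ny, margin, nx - 1 - margin, margin, ny - 1 - margin,
      min(p$x), max(p$x), min(p$y), max(p$y)
    ))
  }
  img <- render_spots(nx, ny, p$x, p$y, gt$amplitude, fwhm_px)
  img <- img + gt$background
  if (noise) {
    img <- with_seed_if(seed, add_camera_noise(img, gt$read_noise_sd))
  }
  truth <- tibble(
    pointer_index = gp$pointer_index, em_x = gp$em_x, em_y = gp$em_y,
    x = p$x, y = p$y
  )
  list(image = raster_image(img, gt$fm_pixel_size_nm, "FM"), truth = truth)
}

# sum of isotropic Gaussians, each rendered only on a local patch
render_spots <- function(nx, ny, cx, cy, amplitude, fwhm_px) {
  img <- matrix(0, ny, nx)
  if (amplitude == 0) return(img)
  sigma <- fwhm_px / (2 * sqrt(2 * log(2)))
  r <- ceiling(4 * sigma)
  for (k in seq_along(cx)) {
    x0 <- max(0L, floor(cx[k]) - r); x1 <- min(nx - 1L, ceiling(cx[k]) + r)
    y0 <- max(0L, floor(cy[k]) - r); y1 <- min(ny - 1L, ceiling(cy[k]) + r)
    gx <- exp(-((x0:x1) - cx[k])^2 / (2 * sigma^2))
    gy <- exp(-((y0:y1) - cy[k])^2 / (2 * sigma^2))
    img[(y0:y1) + 1L, (x0:x1) + 1L] <- img[(y0:y1) + 1L, (x0:x1) + 1L] +
      amplitude * outer(gy, gx)
  }
  img
}

add_camera_noise <- function(expected, read_noise_sd) {
  n <- length(expected)
  noisy <- stats::rpois(n, lambda = as.vector(expected))
  if (read_noise_sd > 0) noisy <- noisy + stats::rnorm(n, 0, read_noise_sd)
  matrix(pmax(noisy, 0), nrow(expected), ncol(expected))
}

#' Simulate pointer-array coordinates directly (coordinate mode)
#'
#' Fast shortcut that skips image rendering and camera noise: each
#' pointer's observed FM position is its true mapped position plus
#' isotropic Gaussian localization jitter of the stated sigma. This
#' decouples accuracy studies from image-rendering cost and lets the
#' localization-noise level be set exactly.
#'
#' @inheritParams render_pointer_image
#' @param n_arrays Number of sequential array exposures.
#' @param jitter_sigma_nm Per-pointer localization jitter sigma, nm;
#'   defaults to the ground truth's.
#' @return A tibble of matched pairs: `array_id` (1-based), `pointer_index`,
#'   `em_x`, `em_y` (commanded, EM frame), `fm_x`, `fm_y` (observed, FM px),
#'   `true_x`, `true_y` (noise-free FM px).
#' @export
simulate_pointer_pool <- function(grid, gt, n_arrays = 1,
                                  jitter_sigma_nm = gt$jitter_sigma_nm,
                                  seed = gt$seed) {
  stopifnot(inherits(grid, "pointer_grid"), inherits(gt, "scene_ground_truth"))
  n_arrays <- assert_count(n_arrays, "n_arrays")
  assert_scalar_num(jitter_sigma_nm, "jitter_sigma_nm", lower = 0)
  gp <- grid_points(grid)
  p <- true_fm_positions(gt, gp$em_x, gp$em_y)
  n <- nrow(gp)
  sig_px <- jitter_sigma_nm / gt$fm_pixel_size_nm
  out <- with_seed_if(seed, {
    tibble(
      array_id = rep(seq_len(n_arrays), each = n),
      pointer_index = rep(gp$pointer_index, n_arrays),
      em_x = rep(gp$em_x, n_arrays), em_y = rep(gp$em_y, n_arrays),
      fm_x = rep(p$x, n_arrays) + stats::rnorm(n * n_arrays, 0, sig_px),
      fm_y = rep(p$y, n_arrays) + stats::rnorm(n * n_arrays, 0, sig_px),
      true_x = rep(p$x, n_arrays), true_y = rep(p$y, n_arrays)
    )
  })
  attr(out, "fm_pixel_size_nm") <- gt$fm_pixel_size_nm
  out
}

#' Render a correlative fiducial (nanosphere) scene
#'
#' Places dye-doped nanospheres at random non-overlapping positions and
#' renders them in both frames: in FM as diffraction-limited Gaussian
#' spots, in EM as uniform disks of the physical sphere diameter (default
#' 40 nm) with a soft (half-pixel) edge and configurable
#' signal-to-background — the EM contrast of silica spheres is
#' characteristically low.
#'
#' @inheritParams render_pointer_image
#' @param n_spheres Number of spheres (>= 1).
#' @param fm_shape,em_shape Image sizes c(rows, cols).
#' @param sphere_diameter_nm Physical sphere diameter (default 40 nm).
#' @param min_separation_nm Minimum center-to-center distance; default
#'   3x the FM spot FWHM so spots stay resolvable.
#' @param em_signal,em_background EM disk signal and background, counts.
#' @param max_tries Placement retries before giving up with an error.
#' @return List with `fm`, `em` ([raster_image()]s) and `truth` (tibble
#'   `id`, `em_x`, `em_y`, `fm_x`, `fm_y` of true centers).
#' @export
render_fiducial_scene <- function(n_spheres, gt,
                                  fm_shape = c(220, 220), em_shape = c(2048, 2048),
                                  sphere_diameter_nm = 40,
                                  min_separation_nm = 3 * gt$spot_fwhm_nm,
                                  em_signal = 60, em_background = 100,
                                  noise = TRUE, max_tries = 1000L,
                                  seed = gt$seed) {
  stopifnot(inherits(gt, "scene_ground_truth"))
  n_spheres <- assert_count(n_spheres, "n_spheres")
  ny_e <- em_shape[1]; nx_e <- em_shape[2]
  with_seed_if(seed, {
    # place in EM frame with a margin, honoring min separation
    margin_em <- max(min_separation_nm, 2 * gt$spot_fwhm_nm) / gt$em_pixel_size_nm
    min_sep_em <- min_separation_nm / gt$em_pixel_size_nm
    if (2 * margin_em >= min(nx_e, ny_e) - 1) {
      abort(sprintf(
        "Could not place %d non-overlapping spheres: the %d x %d EM image leaves no room at %.0f px margin.",
        n_spheres, nx_e, ny_e, margin_em
      ))
    }
    ex <- numeric(0); ey <- numeric(0); tries <- 0L
    while (length(ex) < n_spheres) {
      cand_x <- stats::runif(1, margin_em, nx_e - 1 - margin_em)
      cand_y <- stats::runif(1, margin_em, ny_e - 1 - margin_em)
      if (length(ex) == 0 || min(sqrt((ex - cand_x)^2 + (ey - cand_y)^2)) >= min_sep_em) {
        ex <- c(ex, cand_x); ey <- c(ey, cand_y)
      }
      tries <- tries + 1L
      if (tries > max_tries) {
        abort(sprintf("Could not place %d non-overlapping spheres in %d tries.",
                      n_spheres, max_tries))
      }
    }
    p <- true_fm_positions(gt, ex, ey)
    fwhm_px <- gt$spot_fwhm_nm / gt$fm_pixel_size_nm
    if (any(p$x < 2 * fwhm_px | p$x > fm_shape[2] - 1 - 2 * fwhm_px |
              p$y < 2 * fwhm_px | p$y > fm_shape[1] - 1 - 2 * fwhm_px)) {
      abort("Mapped sphere positions leave the FM image; enlarge `fm_shape` or adjust the transform.")
    }
    fm <- render_spots(fm_shape[2], fm_shape[1], p$x, p$y, gt$amplitude, fwhm_px) +
      gt$background
    em <- render_disks(nx_e, ny_e, ex, ey,
                       radius_px = sphere_diameter_nm / 2 / gt$em_pixel_size_nm,
                       signal = em_signal) + em_background
    if (noise) {
      fm <- add_camera_noise(fm, gt$read_noise_sd)
      em <- add_camera_noise(em, gt$read_noise_sd)
    }
    list(
      fm = raster_image(fm, gt$fm_pixel_size_nm, "FM"),
      em = raster_image(em, gt$em_pixel_size_nm, "EM"),
      truth = tibble(id = seq_len(n_spheres), em_x = ex, em_y = ey,
                     fm_x = p$x, fm_y = p$y)
    )
  })
}

# uniform disks with a half-pixel soft edge (area-coverage approximation)
render_disks <- function(nx, ny, cx, cy, radius_px, signal, edge_px = 0.5) {
  img <- matrix(0, ny, nx)
  r <- ceiling(radius_px + 3 * edge_px)
  for (k in seq_along(cx)) {
    x0 <- max(0L, floor(cx[k]) - r); x1 <- min(nx - 1L, ceiling(cx[k]) + r)
    y0 <- max(0L, floor(cy[k]) - r); y1 <- min(ny - 1L, ceiling(cy[k]) + r)
    dx <- (x0:x1) - cx[k]; dy <- (y0:y1) - cy[k]
    rad <- sqrt(outer(dy^2, dx^2, `+`))
    img[(y0:y1) + 1L, (x0:x1) + 1L] <- img[(y0:y1) + 1L, (x0:x1) + 1L] +
      signal * stats::pnorm((radius_px - rad) / edge_px)
  }
  img
}

#' Simulate fiducial localizations directly (coordinate mode)
#'
#' Coordinate-mode companion of [render_fiducial_scene()]: sphere centers
#' are placed uniformly inside a stated EM region and the per-frame
#' localizations carry stated isotropic Gaussian noise, skipping image
#' rendering.
#'
#' @inheritParams render_fiducial_scene
#' @param region_em Length-4 numeric c(x0, x1, y0, y1): EM-frame placement
#'   region.
#' @param loc_noise_fm_nm,loc_noise_em_nm Localization noise sigma per
#'   frame, nm.
#' @return Tibble with true centers and noisy localizations in both
#'   frames: `id`, `em_x`, `em_y`, `fm_x`, `fm_y` (noisy) and
#'   `true_em_x`, `true_em_y`, `true_fm_x`, `true_fm_y`.
#' @export
simulate_fiducial_pool <- function(n_spheres, gt, region_em,
                                   loc_noise_fm_nm = 5, loc_noise_em_nm = 5,
                                   min_separation_nm = 3 * gt$spot_fwhm_nm,
                                   max_tries = 1000L, seed = gt$seed) {
  stopifnot(inherits(gt, "scene_ground_truth"))
  n_spheres <- assert_count(n_spheres, "n_spheres")
  assert_scalar_num(loc_noise_fm_nm, "loc_noise_fm_nm", lower = 0)
  assert_scalar_num(loc_noise_em_nm, "loc_noise_em_nm", lower = 0)
  min_sep_em <- min_separation_nm / gt$em_pixel_size_nm
  with_seed_if(seed, {
    ex <- numeric(0); ey <- numeric(0); tries <- 0L
    while (length(ex) < n_spheres) {
      cand_x <- stats::runif(1, region_em[1], region_em[2])
      cand_y <- stats::runif(1, region_em[3], region_em[4])
      if (length(ex) == 0 || min(sqrt((ex - cand_x)^2 + (ey - cand_y)^2)) >= min_sep_em) {
        ex <- c(ex, cand_x); ey <- c(ey, cand_y)
      }
      tries <- tries + 1L
      if (tries > max_tries) {
        abort(sprintf("Could not place %d non-overlapping spheres in %d tries.",
                      n_spheres, max_tries))
      }
    }
    p <- true_fm_positions(gt, ex, ey)
    tibble(
      id = seq_len(n_spheres),
      true_em_x = ex, true_em_y = ey, true_fm_x = p$x, true_fm_y = p$y,
      em_x = ex + stats::rnorm(n_spheres, 0, loc_noise_em_nm / gt$em_pixel_size_nm),
      em_y = ey + stats::rnorm(n_spheres, 0, loc_noise_em_nm / gt$em_pixel_size_nm),
      fm_x = p$x + stats::rnorm(n_spheres, 0, loc_noise_fm_nm / gt$fm_pixel_size_nm),
      fm_y = p$y + stats::rnorm(n_spheres, 0, loc_noise_fm_nm / gt$fm_pixel_size_nm)
    )
  })
}
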