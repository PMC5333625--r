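#' Commanded CL pointer grid
#'
#' Specification of a rectangular array of commanded electron-beam
#' positions (CL pointers) in the EM coordinate frame. A dense calibration
#' array is typically 25 x 25 pointers at 4 um spacing (625 pointers); a
#' per-image registration array is 4 x 4 (16 pointers).
#'
#' @param rows,cols Grid dimensions (positive integers).
#' @param spacing Pointer spacing in EM-frame units (EM pixels here; > 0).
#' @param origin Length-2 numeric, EM coordinates of the (row 0, col 0)
#'   pointer.
#' @param exposure_count Number of sequential array exposures this spec
#'   describes (metadata; default 1).
#' @return A `pointer_grid` object. `grid_points()` expands it to a tibble
#'   with `pointer_index` (0-based, row-major), `row`, `col`, `em_x`, `em_y`.
#' @examples
#' g <- pointer_grid(25, 25, spacing = 800)
#' nrow(grid_points(g)) # 625
#' @export
pointer_grid <- function(rows, cols, spacing, origin = c(0, 0), exposure_count = 1L) {
  rows <- assert_count(rows, "rows")
  cols <- assert_count(cols, "cols")
  assert_scalar_num(spacing, "spacing", positive = TRUE)
  exposure_count <- assert_count(exposure_count, "exposure_count")
  if (!is.numeric(origin) || length(origin) != 2L || any(!is.finite(origin))) {
    abort("`origin` must be two finite numbers.")
  }
  structure(
    list(rows = rows, cols = cols, spacing = spacing,
         origin = as.numeric(origin), exposure_count = exposure_count),
    class = "pointer_grid"
  )
}

#' @export
print.pointer_grid <- function(x, ...) {
  cat(sprintf("<pointer_grid> %d x %d = %d pointers, spacing %.4g, origin (%.4g, %.4g)\n",
              x$rows, x$cols, x$rows * x$cols, x$spacing, x$origin[1], x$origin[2]))
  invisible(x)
}

#' @rdname pointer_grid
#' @param grid A `pointer_grid`.
#' @export
grid_points <- function(grid) {
  stopifnot(inherits(grid, "pointer_grid"))
  df <- tidyr::expand_grid(row = seq_len(grid$rows) - 1L, col = seq_len(grid$cols) - 1L)
  tibble(
    pointer_index = df$row * grid$cols + df$col,
    row = df$row, col = df$col,
    em_x = grid$origin[1] + df$col * grid$spacing,
    em_y = grid$origin[2] + df$row * grid$spacing
  )
}

grid_corners_em <- function(grid) {
  # cyclic order: (0,0) -> (0, cols-1) -> (rows-1, cols-1) -> (rows-1, 0)
  rc <- cbind(
    row = c(0L, 0L, grid$rows - 1L, grid$rows - 1L),
    col = c(0L, grid$cols - 1L, grid$cols - 1L, 0L)
  )
  tibble(
    row = rc[, "row"], col = rc[, "col"],
    em_x = grid$origin[1] + rc[, "col"] * grid$spacing,
    em_y = grid$origin[2] + rc[, "row"] * grid$spacing
  )
}

#' Ground truth for a simulated integrated-microscope scene
#'
#' Bundles everything the virtual microscope needs to generate data and
#' everything downstream scoring needs to know: the true EM-to-FM
#' similarity transform, an optional true distortion field (FM frame, nm),
#' pixel sizes, the camera noise model and the RNG seed. The generative
#' model for an observed pointer position is
#' \deqn{FM_{obs} = T(EM) + D(T(EM)) + noise,}
#' i.e. the distortion is defined in the FM frame and added at the
#' similarity-mapped position.
#'
#' @param transform True EM-to-FM [similarity_transform()]. The default
#'   scale equals `em_pixel_size_nm / fm_pixel_size_nm` (same physical
#'   magnification seen by both frames) with a small rotation and offset.
#' @param distortion Optional true [make_distortion_field()] (FM frame, nm),
#'   or `NULL` for no distortion.
#' @param fm_pixel_size_nm,em_pixel_size_nm Pixel sizes, nm.
#' @param spot_fwhm_nm FWHM of a CL pointer / fluorescent sphere in the FM
#'   image; default 300 nm (the optical diffraction limit at low beam
#'   energy).
#' @param amplitude Peak spot signal above background, counts.
#' @param background Background level, counts.
#' @param read_noise_sd Gaussian read-noise sigma, counts.
#' @param jitter_sigma_nm Isotropic per-pointer localization jitter used by
#'   the fast coordinate mode (nm, >= 0).
#' @param seed Integer RNG seed; a fixed seed gives byte-identical outputs.
#' @return A `scene_ground_truth` list.
#' @export
scene_ground_truth <- function(transform = NULL,
                               distortion = NULL,
                               fm_pixel_size_nm = 100,
                               em_pixel_size_nm = 5,
                               spot_fwhm_nm = 300,
                               amplitude = 300,
                               background = 100,
                               read_noise_sd = 5,
                               jitter_sigma_nm = 0,
                               seed = 1L) {
  assert_scalar_num(fm_pixel_size_nm, "fm_pixel_size_nm", positive = TRUE)
  assert_scalar_num(em_pixel_size_nm, "em_pixel_size_nm", positive = TRUE)
  assert_scalar_num(spot_fwhm_nm, "spot_fwhm_nm", positive = TRUE)
  assert_scalar_num(amplitude, "amplitude", lower = 0)
  assert_scalar_num(background, "background", lower = 0)
  assert_scalar_num(read_noise_sd, "read_noise_sd", lower = 0)
  assert_scalar_num(jitter_sigma_nm, "jitter_sigma_nm", lower = 0)
  seed <- assert_count(seed, "seed", lower = 0L)
  if (is.null(transform)) {
    transform <- similarity_transform(
      s = em_pixel_size_nm / fm_pixel_size_nm, theta = 0.02, t_x = 40, t_y = 36
    )
  }
  stopifnot(inherits(transform, "similarity_transform"))
  if (!is.null(distortion)) stopifnot(inherits(distortion, "distortion_field"))
  structure(
    list(
      transform = transform, distortion = distortion,
      fm_pixel_size_nm = fm_pixel_size_nm, em_pixel_size_nm = em_pixel_size_nm,
      spot_fwhm_nm = spot_fwhm_nm, amplitude = amplitude, background = background,
      read_noise_sd = read_noise_sd, jitter_sigma_nm = jitter_sigma_nm,
      seed = seed
    ),
    class = "scene_ground_truth"
  )
}

# True (noise-free) FM positions of a set of EM coordinates under the
# ground truth: T(EM) + D(T(EM)) in FM px.
true_fm_positions <- function(gt, em_x, em_y) {
  p <- tf_apply_xy(gt$transform, em_x, em_y)
  if (!is.null(gt$distortion)) {
    d <- interp_field(gt$distortion, p$x, p$y, warn_outside = FALSE)
    p$x <- p$x + d$dx_nm / gt$fm_pixel_size_nm
    p$y <- p$y + d$dy_nm / gt$fm_pixel_size_nm
  }
  p
}
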