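#' Resample the EM image into the FM frame and compose an overlay
#'
#' Inverse-maps every FM pixel through the EM-to-FM transform (with
#' one-pass distortion correction when a field is supplied) and samples
#' the EM image by bilinear interpolation; pixels falling outside the EM
#' footprint are zero. A blended RGB composite is produced with the FM
#' channel in a configurable color (orange by default) and the
#' registered EM image in grayscale, additively blended.
#'
#' @param fm FM [raster_image()].
#' @param em EM [raster_image()].
#' @param transform EM-to-FM [similarity_transform()] in pixel
#'   coordinates.
#' @param field Optional `distortion_field` (FM frame, nm).
#' @param fm_color Length-3 RGB weights for the FM channel.
#' @param alpha Blend weight of the EM channel (0..1).
#' @return An `overlay_result` list: `registered_em` (a [raster_image()]
#'   on the FM pixel grid), `composite` (H x W x 3 array in [0, 1]),
#'   `transform`, and `coverage` (fraction of FM pixels inside the EM
#'   footprint).
#' @export
build_overlay <- function(fm, em, transform, field = NULL,
                          fm_color = c(1, 0.6, 0), alpha = 1) {
  stopifnot(inherits(fm, "raster_image"), inherits(em, "raster_image"),
            inherits(transform, "similarity_transform"))
  ny <- nrow(fm); nx <- ncol(fm)
  xs <- rep(seq_len(nx) - 1, each = ny)
  ys <- rep(seq_len(ny) - 1, nx)
  if (!is.null(field)) {
    d <- interp_field(field, xs, ys, warn_outside = FALSE)
    px <- attr(field, "fm_pixel_size_nm") %||% pixel_size(fm)
    xs <- xs - d$dx_nm / px
    ys <- ys - d$dy_nm / px
  }
  inv <- invert_transform(transform)
  pe <- tf_apply_xy(inv, xs, ys)
  vals <- bilinear_sample(unclass(em), pe$x, pe$y, fill = NA_real_)
  inside <- !is.na(vals)
  if (!any(inside)) {
    abort("The transform places the EM footprint entirely outside the FM frame.")
  }
  vals[!inside] <- 0
  reg <- matrix(vals, ny, nx)
  fmn <- unclass(fm) / max(max(fm), 1)
  emn <- reg / max(max(reg), 1)
  composite <- array(0, c(ny, nx, 3))
  for (ch in 1:3) {
    composite[, , ch] <- pmin(fmn * fm_color[ch] + alpha * emn, 1)
  }
  structure(
    list(
      registered_em = raster_image(reg, pixel_size(fm), "FM"),
      composite = composite,
      transform = transform,
      coverage = mean(inside)
    ),
    class = "overlay_result"
  )
}

#' @export
print.overlay_result <- function(x, ...) {
  cat(sprintf("<overlay_result> %d x %d px, EM footprint covers %.1f%% of the FM frame\n",
              ncol(x$registered_em), nrow(x$registered_em), 100 * x$coverage))
  invisible(x)
}

#' @rdname build_overlay
#' @param x An `overlay_result`.
#' @param path PNG output path.
#' @export
write_overlay_png <- function(x, path) {
  stopifnot(inherits(x, "overlay_result"))
  png::writePNG(x$composite, path)
  invisible(path)
}

#' Compare CL-pointer-based and fiducial-based registration
#'
#' The conventional registration route uses fiducial markers visible in
#' both frames; the CL-pointer route needs none. Given fiducial
#' localizations in both frames and a CL-pointer-derived transform, this
#' fits a second similarity transform on the fiducial pairs and, for
#' every fiducial, maps its EM position under both registrations. The
#' per-fiducial difference vectors under each registration and the
#' mapping difference between the two routes (in nm) quantify how closely
#' the pointer-based overlay reproduces the fiducial-based one.
#'
#' @param fiducials Data frame of fiducial localizations with columns
#'   `em_x`, `em_y`, `fm_x`, `fm_y` (>= 2 rows).
#' @param cl_transform CL-pointer-derived [similarity_transform()].
#' @param field Optional `distortion_field` applied (in the CL route) at
#'   the mapped position.
#' @param fm_pixel_size_nm FM pixel size, nm.
#' @return A tibble with, per fiducial: mapped positions under both
#'   registrations (`cl_x`, `cl_y`, `fid_x`, `fid_y`, FM px), residual
#'   difference vectors against the observed FM localization
#'   (`dx_cl_nm`, `dy_cl_nm`, `dx_fid_nm`, `dy_fid_nm`), and
#'   `mapping_diff_nm`, the magnitude of the difference between the two
#'   mappings. The fiducial-fit transform rides along as attribute
#'   `fiducial_transform`.
#' @export
compare_fiducial_registration <- function(fiducials, cl_transform, field = NULL,
                                          fm_pixel_size_nm = 100) {
  assert_df_cols(fiducials, c("em_x", "em_y", "fm_x", "fm_y"), "fiducials")
  stopifnot(inherits(cl_transform, "similarity_transform"))
  if (nrow(fiducials) < 2L) abort("Need at least 2 fiducials localizable in both frames.")
  fid_tf <- fit_similarity(fiducials)
  cl <- tf_apply_xy(cl_transform, fiducials$em_x, fiducials$em_y)
  if (!is.null(field)) {
    d <- interp_field(field, cl$x, cl$y, warn_outside = FALSE)
    px_f <- attr(field, "fm_pixel_size_nm") %||% fm_pixel_size_nm
    cl$x <- cl$x + d$dx_nm / px_f
    cl$y <- cl$y + d$dy_nm / px_f
  }
  fid <- tf_apply_xy(fid_tf, fiducials$em_x, fiducials$em_y)
  out <- tibble(
    id = if ("id" %in% names(fiducials)) fiducials$id else seq_len(nrow(fiducials)),
    cl_x = cl$x, cl_y = cl$y, fid_x = fid$x, fid_y = fid$y,
    dx_cl_nm = (fiducials$fm_x - cl$x) * fm_pixel_size_nm,
    dy_cl_nm = (fiducials$fm_y - cl$y) * fm_pixel_size_nm,
    dx_fid_nm = (fiducials$fm_x - fid$x) * fm_pixel_size_nm,
    dy_fid_nm = (fiducials$fm_y - fid$y) * fm_pixel_size_nm,
    mapping_diff_nm = sqrt((cl$x - fid$x)^2 + (cl$y - fid$y)^2) * fm_pixel_size_nm
  )
  attr(out, "fiducial_transform") <- fid_tf
  out
}

#' One full CL-versus-fiducial comparison experiment (coordinate mode)
#'
#' Convenience wrapper reproducing the validation experiment on synthetic
#' data: a 4x4 CL pointer array with per-pointer localization jitter
#' registers the frames; independently, nanosphere fiducials with stated
#' per-frame localization noise provide the conventional registration;
#' both mappings are evaluated at every fiducial. Default geometry mirrors
#' a typical validation acquisition: the pointer array spans the full FM
#' field of view (~80 um), while the spheres sit inside the much smaller
#' EM image area (~10 um, 2048 px at 5 nm/px) at its center — the beam can
#' be deflected across the whole FM field even when the recorded EM image
#' covers only a sub-region.
#'
#' @param seed RNG seed.
#' @param n_fiducials Number of spheres (default 14).
#' @param pointer_jitter_nm CL pointer localization jitter (default 12 nm).
#' @param fiducial_noise_nm Per-frame fiducial localization noise
#'   (default 5 nm each in FM and EM).
#' @param grid Pointer array (default 4x4 spanning 80% of the EM FOV).
#' @param gt Scene ground truth; default [scene_ground_truth()].
#' @return The [compare_fiducial_registration()] table, with the maximum
#'   `mapping_diff_nm` as attribute `max_diff_nm`.
#' @export
fiducial_comparison_experiment <- function(seed = 1L, n_fiducials = 14,
                                           pointer_jitter_nm = 12,
                                           fiducial_noise_nm = 5,
                                           grid = NULL, gt = NULL) {
  if (is.null(gt)) gt <- scene_ground_truth(seed = seed)
  # beam-deflection span covering the FM field of view (80 um at 5 nm/px)
  array_span_em <- 16000
  # recorded EM image: 2048 px, centered in the deflection range
  em_image_px <- 2048
  if (is.null(grid)) {
    grid <- pointer_grid(4, 4, spacing = array_span_em / 3, origin = c(0, 0))
  }
  pool <- simulate_pointer_pool(grid, gt, n_arrays = 1,
                                jitter_sigma_nm = pointer_jitter_nm, seed = seed)
  cl_tf <- fit_similarity(pool)
  gp <- grid_points(grid)
  ctr <- c(mean(gp$em_x), mean(gp$em_y))
  fid <- simulate_fiducial_pool(
    n_fiducials, gt,
    region_em = c(ctr[1] - em_image_px / 2, ctr[1] + em_image_px / 2,
                  ctr[2] - em_image_px / 2, ctr[2] + em_image_px / 2),
    loc_noise_fm_nm = fiducial_noise_nm, loc_noise_em_nm = fiducial_noise_nm,
    seed = seed + 104729L
  )
  cmp <- compare_fiducial_registration(fid, cl_tf,
                                       fm_pixel_size_nm = gt$fm_pixel_size_nm)
  attr(cmp, "max_diff_nm") <- max(cmp$mapping_diff_nm)
  attr(cmp, "cl_transform") <- cl_tf
  cmp
}
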