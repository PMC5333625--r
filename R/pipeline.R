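#' Run the full registration pipeline from a config
#'
#' End-to-end orchestration of a single correlative acquisition:
#' localize the CL pointer spots in the pointer-array FM image, sort them
#' into pairs with the commanded beam grid, fit the EM-to-FM similarity
#' transform (correcting with a previously calibrated distortion field
#' when one is given), resample the EM image into the FM frame, and
#' write the overlay plus machine-readable reports (transform JSON, pair
#' and residual CSVs, log).
#'
#' @param config A YAML file path or a named list. Required keys:
#'   `fm_image`, `em_image`, `pointer_image` (TIFF paths or
#'   [raster_image()] objects), `fm_pixel_size_nm`, `em_pixel_size_nm`,
#'   and `grid` (with `rows`, `cols`, `spacing`, and optionally
#'   `origin`). Optional: `distortion_field` (JSON path or
#'   `distortion_field` object), `out_dir`, `fwhm_px`, `strict`, `seed`.
#' @return An `overlay_result` with the registration attached:
#'   attributes `pairs`, `transform`, `residuals`, `config`, plus paths
#'   of everything written when `out_dir` is set.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  config <- validate_pipeline_config(config)
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(paste0("[%s] ", fmt), format(Sys.time(), "%H:%M:%S"), ...)
    log_lines <<- c(log_lines, line)
    inform(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  grid <- pointer_grid(config$grid$rows, config$grid$cols, config$grid$spacing,
                       origin = config$grid$origin %||% c(0, 0))
  n_exp <- grid$rows * grid$cols

  load_img <- function(x, pixel_size, frame) {
    if (inherits(x, "raster_image")) x else read_raster_tiff(x, pixel_size, frame,
                                                            scale = config$tiff_scale %||% 1)
  }
  fm <- stage("load-fm", load_img(config$fm_image, config$fm_pixel_size_nm, "FM"))
  em <- stage("load-em", load_img(config$em_image, config$em_pixel_size_nm, "EM"))
  pimg <- stage("load-pointers", load_img(config$pointer_image, config$fm_pixel_size_nm, "FM"))
  say("loaded images: FM %dx%d, EM %dx%d, pointer image %dx%d",
      ncol(fm), nrow(fm), ncol(em), nrow(em), ncol(pimg), nrow(pimg))

  fwhm_px <- config$fwhm_px %||% 3
  detections <- stage("localize",
                      localize_all(pimg, expected_count = n_exp, fwhm_px = fwhm_px))
  say("localized %d pointer spots (expected %d)", nrow(detections), n_exp)

  pairs <- stage("pair", pair_by_iterative_nn(detections, grid))
  say("paired %d pointers (%d detections unmatched, %d grid nodes unmatched)",
      nrow(pairs), length(attr(pairs, "unmatched_fm")), length(attr(pairs, "unmatched_em")))

  field <- config$distortion_field
  if (is.character(field)) field <- stage("load-field", read_field_json(field))
  if (is.null(field)) {
    tf <- stage("register", fit_similarity(pairs))
    residuals <- difference_vectors(pairs, tf, fm_pixel_size_nm = config$fm_pixel_size_nm)
  } else {
    reg <- stage("register", register_with_distortion(
      pairs, field, fm_pixel_size_nm = config$fm_pixel_size_nm,
      strict = isTRUE(config$strict)
    ))
    tf <- reg$transform
    residuals <- reg$corrected
  }
  g <- glance(tf)
  say("registration: s = %.6g, theta = %.6g rad, t = (%.4g, %.4g) px, RMS residual %.4g px",
      g$s, g$theta_rad, g$t_x_px, g$t_y_px, g$rms_residual_px)

  overlay <- stage("overlay", build_overlay(fm, em, tf, field = field))
  say("overlay: EM footprint covers %.1f%% of the FM frame", 100 * overlay$coverage)

  attr(overlay, "pairs") <- pairs
  attr(overlay, "residuals") <- residuals
  attr(overlay, "config") <- config

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(config$out_dir, f)
    write_transform_json(tf, p("transform.json"),
                         fm_pixel_size_nm = config$fm_pixel_size_nm,
                         em_pixel_size_nm = config$em_pixel_size_nm)
    utils::write.csv(as.data.frame(pairs), p("pairs.csv"), row.names = FALSE, quote = FALSE)
    utils::write.csv(
      as.data.frame(residuals)[, c("pointer_index", "map_x", "map_y",
                                   "dx_px", "dy_px", "dx_nm", "dy_nm")],
      p("residuals.csv"), row.names = FALSE, quote = FALSE
    )
    write_raster_tiff(overlay$registered_em, p("registered_em.tiff"))
    write_overlay_png(overlay, p("overlay.png"))
    writeLines(log_lines, p("log.txt"))
    attr(overlay, "paths") <- list(
      transform = p("transform.json"), pairs = p("pairs.csv"),
      residuals = p("residuals.csv"), registered_em = p("registered_em.tiff"),
      overlay = p("overlay.png"), log = p("log.txt")
    )
    say("wrote outputs to %s", config$out_dir)
  }
  overlay
}

validate_pipeline_config <- function(config) {
  if (!is.list(config)) abort("`config` must be a list or a YAML file path.")
  required <- c("fm_image", "em_image", "pointer_image",
                "fm_pixel_size_nm", "em_pixel_size_nm", "grid")
  missing <- required[!vapply(required, function(k) !is.null(config[[k]]), logical(1))]
  if (length(missing) > 0) {
    abort(sprintf("Pipeline config is missing required key(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  for (k in c("rows", "cols", "spacing")) {
    if (is.null(config$grid[[k]])) {
      abort(sprintf("Pipeline config `grid` is missing required key `%s`.", k))
    }
  }
  for (k in c("fm_image", "em_image", "pointer_image")) {
    v <- config[[k]]
    if (is.character(v) && !file.exists(v)) {
      abort(sprintf("Pipeline config `%s` points to a missing file: %s", k, v))
    }
  }
  config
}
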