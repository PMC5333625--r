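#' Raster image with pixel size and frame label
#'
#' Thin wrapper around a numeric matrix (rows = y, columns = x) carrying
#' the physical pixel size in nm and the coordinate frame it lives in
#' (`"FM"` for the fluorescence camera, `"EM"` for the electron image).
#' Intensities are finite, nonnegative counts.
#'
#' @param pixels Numeric matrix of nonnegative intensities.
#' @param pixel_size_nm Pixel size, nm (> 0).
#' @param frame `"FM"` or `"EM"`.
#' @return A `raster_image` (matrix subclass).
#' @export
raster_image <- function(pixels, pixel_size_nm, frame = c("FM", "EM")) {
  frame <- match.arg(frame)
  if (!is.matrix(pixels) || !is.numeric(pixels)) abort("`pixels` must be a numeric matrix.")
  if (any(!is.finite(pixels)) || any(pixels < 0)) {
    abort("`pixels` must be finite and nonnegative.")
  }
  assert_scalar_num(pixel_size_nm, "pixel_size_nm", positive = TRUE)
  structure(pixels,
    pixel_size_nm = pixel_size_nm, frame = frame,
    class = c("raster_image", "matrix", "array")
  )
}

#' @export
print.raster_image <- function(x, ...) {
  cat(sprintf(
    "<raster_image> %d x %d px (%s frame, %.4g nm/px), intensity range [%.4g, %.4g]\n",
    ncol(x), nrow(x), attr(x, "frame"), attr(x, "pixel_size_nm"), min(x), max(x)
  ))
  invisible(x)
}

pixel_size <- function(img) attr(img, "pixel_size_nm")

#' Read and write raster images as grayscale TIFF
#'
#' Images are written as 16-bit grayscale TIFF; intensities are scaled by
#' `scale` (counts per full range) so that `scale` maps to the maximum
#' 16-bit value. Metadata (pixel size, frame) travels in a JSON sidecar
#' only when the pipeline writes it; `read_raster_tiff()` therefore takes
#' the pixel size and frame explicitly.
#'
#' @param img A [raster_image()].
#' @param path TIFF path.
#' @param scale Counts mapped to the top of the 16-bit range; default the
#'   image maximum (or 1 for an all-zero image).
#' @return `write_raster_tiff()`: `path`, invisibly. `read_raster_tiff()`:
#'   a [raster_image()] in counts (i.e. value * `scale`).
#' @export
write_raster_tiff <- function(img, path, scale = NULL) {
  stopifnot(inherits(img, "raster_image"))
  if (is.null(scale)) scale <- max(max(img), 1)
  m <- unclass(img) / scale
  m[m > 1] <- 1
  tiff::writeTIFF(m, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_raster_tiff
#' @param pixel_size_nm,frame Metadata to attach on read.
#' @export
read_raster_tiff <- function(path, pixel_size_nm, frame = c("FM", "EM"), scale = 1) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L] # tolerate RGB input, take first channel
  raster_image(m * scale, pixel_size_nm, frame)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a raster image
#'
#' @param object A [raster_image()].
#' @param ... Unused.
#' @return A ggplot: intensity raster with y pointing down, as on the camera.
#' @export
autoplot.raster_image <- function(object, ...) {
  df <- tidyr::expand_grid(
    y = seq_len(nrow(object)) - 1,
    x = seq_len(ncol(object)) - 1
  )
  df$intensity <- as.vector(t(unclass(object)))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = "x (px)", y = "y (px)",
      title = sprintf("%s image, %.3g nm/px", attr(object, "frame"), pixel_size(object))
    )
}

#' Coordinate-table CSV helpers
#'
#' Coordinates use the package-wide convention: 0-based pixel indices, a
#' coordinate is the center of its pixel. The CSV schema is
#' `id,x_px,y_px,frame`.
#'
#' @param coords Data frame with columns `x`, `y` and optionally `id`.
#' @param path CSV path.
#' @param frame Frame label recorded per row.
#' @export
write_coords_csv <- function(coords, path, frame = "FM") {
  assert_df_cols(coords, c("x", "y"), "coords")
  out <- tibble(
    id = if ("id" %in% names(coords)) coords$id else seq_len(nrow(coords)),
    x_px = coords$x, y_px = coords$y, frame = frame
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_coords_csv
#' @export
read_coords_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_df_cols(df, c("id", "x_px", "y_px"), "coordinate CSV")
  tibble(id = df$id, x = df$x_px, y = df$y_px,
         frame = if ("frame" %in% names(df)) df$frame else NA_character_)
}
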