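#' Similarity transform between the EM and FM coordinate frames
#'
#' A similarity transform maps electron-microscope (EM) coordinates
#' \eqn{(x^E, y^E)} into the fluorescence-microscope (FM) pixel frame by a
#' scaling \eqn{s}, a rotation \eqn{\theta} and a translation
#' \eqn{(t_x, t_y)}:
#' \deqn{x^F = a x^E - b y^E + t_x, \quad y^F = b x^E + a y^E + t_y}
#' with \eqn{a = s\cos\theta}, \eqn{b = s\sin\theta}. Reflections are
#' unrepresentable by construction: a mirrored point set simply fits poorly
#' and shows up in the residuals.
#'
#' Coordinates follow the pixel convention used throughout the package:
#' 0-based indices, a coordinate is the center of its pixel, x along columns
#' (rightward), y along rows (downward). \eqn{\theta} is counter-clockwise
#' in that frame and reported in \eqn{(-\pi, \pi]}.
#'
#' @param s Scale factor (dimensionless, > 0).
#' @param theta Rotation angle in radians.
#' @param t_x,t_y Translation, FM pixels.
#' @return An object of class `similarity_transform`.
#' @examples
#' tf <- similarity_transform(s = 2, theta = pi / 2, t_x = 3, t_y = 4)
#' apply_transform(data.frame(x = 1, y = 0), tf)
#' @export
similarity_transform <- function(s = 1, theta = 0, t_x = 0, t_y = 0) {
  assert_scalar_num(s, "s", positive = TRUE)
  assert_scalar_num(theta, "theta")
  assert_scalar_num(t_x, "t_x")
  assert_scalar_num(t_y, "t_y")
  # wrap into (-pi, pi]
  theta <- -((-theta + pi) %% (2 * pi) - pi)
  structure(
    list(s = s, theta = theta, t_x = t_x, t_y = t_y),
    class = "similarity_transform"
  )
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf(
    "<similarity_transform> s = %.6g, theta = %.6g rad (%.4g deg), t = (%.6g, %.6g) px\n",
    x$s, x$theta, x$theta * 180 / pi, x$t_x, x$t_y
  ))
  fit <- attr(x, "fit")
  if (!is.null(fit)) {
    cat(sprintf("  fitted on %d pairs, RMS residual %.4g px\n", fit$n_pairs, fit$rms_px))
  }
  invisible(x)
}

tf_ab <- function(tf) c(a = tf$s * cos(tf$theta), b = tf$s * sin(tf$theta))

# vector core used by everything else
tf_apply_xy <- function(tf, x, y) {
  ab <- tf_ab(tf)
  list(x = ab[["a"]] * x - ab[["b"]] * y + tf$t_x,
       y = ab[["b"]] * x + ab[["a"]] * y + tf$t_y)
}

#' Apply or invert a similarity transform
#'
#' `apply_transform()` maps points through the transform;
#' `invert_transform()` returns the exact inverse transform
#' (scale \eqn{1/s}, rotation \eqn{-\theta}).
#'
#' @param points Data frame with columns `x`, `y`.
#' @param transform A [similarity_transform()].
#' @return A tibble with transformed `x`, `y` (other columns preserved).
#' @export
apply_transform <- function(points, transform) {
  assert_df_cols(points, c("x", "y"), "points")
  stopifnot(inherits(transform, "similarity_transform"))
  out <- as_tibble(points)
  p <- tf_apply_xy(transform, out$x, out$y)
  out$x <- p$x
  out$y <- p$y
  out
}

#' @rdname apply_transform
#' @export
invert_transform <- function(transform) {
  stopifnot(inherits(transform, "similarity_transform"))
  ab <- tf_ab(transform)
  s2 <- transform$s^2
  similarity_transform(
    s = 1 / transform$s,
    theta = -transform$theta,
    t_x = (-ab[["a"]] * transform$t_x - ab[["b"]] * transform$t_y) / s2,
    t_y = (ab[["b"]] * transform$t_x - ab[["a"]] * transform$t_y) / s2
  )
}

#' Fit the EM-to-FM similarity transform by least squares
#'
#' Solves, in closed form, the linear least-squares problem in
#' \eqn{(a, b, t_x, t_y)} for the model
#' \eqn{x^F = a x^E - b y^E + t_x}, \eqn{y^F = b x^E + a y^E + t_y}
#' over a set of matched pointer pairs, then reports
#' \eqn{s = \sqrt{a^2+b^2}}, \eqn{\theta = \mathrm{atan2}(b, a)}.
#' At least 2 pointer pairs in general position are required; with exactly
#' 2 non-coincident pairs the solution is unique with zero residual.
#'
#' @param pairs Data frame of matched pairs with columns `em_x`, `em_y`
#'   (EM frame) and `fm_x`, `fm_y` (FM pixels).
#' @return A [similarity_transform()] carrying a `fit` attribute with the
#'   pair count and residual summary (RMS in FM px).
#' @examples
#' pairs <- tibble::tibble(em_x = c(0, 1, 0), em_y = c(0, 0, 1),
#'                         fm_x = c(3, 3, 1),  fm_y = c(4, 6, 4))
#' fit_similarity(pairs)
#' @export
fit_similarity <- function(pairs) {
  assert_df_cols(pairs, c("em_x", "em_y", "fm_x", "fm_y"), "pairs")
  n <- nrow(pairs)
  if (n < 2L) {
    abort(sprintf(
      "fit_similarity() needs at least 2 pointer pairs to determine scaling, rotation and translation; got %d.", n
    ))
  }
  fit <- fit_similarity_core(pairs$em_x, pairs$em_y, pairs$fm_x, pairs$fm_y)
  if (is.null(fit)) {
    abort("All EM points coincide: the similarity fit is singular.")
  }
  tf <- similarity_transform(
    s = sqrt(fit$a^2 + fit$b^2), theta = atan2(fit$b, fit$a),
    t_x = fit$t_x, t_y = fit$t_y
  )
  p <- tf_apply_xy(tf, pairs$em_x, pairs$em_y)
  res2 <- (pairs$fm_x - p$x)^2 + (pairs$fm_y - p$y)^2
  attr(tf, "fit") <- list(
    n_pairs = n,
    rms_px = sqrt(mean(res2)),
    max_px = sqrt(max(res2))
  )
  tf
}

# Closed-form normal-equation solve; returns NULL when singular.
# Centering the EM and FM clouds decouples (a, b) from (t_x, t_y):
#   a = sum(e . f) / sum|e|^2 , b = sum(e x f) / sum|e|^2   (centered coords)
fit_similarity_core <- function(ex, ey, fx, fy) {
  mex <- mean(ex); mey <- mean(ey); mfx <- mean(fx); mfy <- mean(fy)
  cex <- ex - mex; cey <- ey - mey
  cfx <- fx - mfx; cfy <- fy - mfy
  denom <- sum(cex^2 + cey^2)
  if (denom <= 0 || !is.finite(denom)) return(NULL)
  a <- sum(cex * cfx + cey * cfy) / denom
  b <- sum(cex * cfy - cey * cfx) / denom
  if (a == 0 && b == 0) return(NULL) # degenerate: zero scale
  list(a = a, b = b,
       t_x = mfx - (a * mex - b * mey),
       t_y = mfy - (b * mex + a * mey))
}

#' Residual difference vectors after registration
#'
#' For each matched pointer pair \eqn{i}, the difference vector is the
#' residual between the observed FM position and the transformed EM
#' position:
#' \deqn{\delta_i = (x^F_i, y^F_i) - T(x^E_i, y^E_i).}
#' When `transform` is the least-squares fit of the same pairs the
#' residuals satisfy \eqn{\sum_i \delta_i = 0} and are orthogonal to the
#' scale and rotation degrees of freedom.
#'
#' @inheritParams fit_similarity
#' @param transform The transform to evaluate; defaults to the
#'   least-squares fit of `pairs` themselves.
#' @param fm_pixel_size_nm FM pixel size in nm; when given, `dx_nm`/`dy_nm`
#'   columns are added.
#' @return A tibble with the mapped FM position (`fm_x`, `fm_y` observed,
#'   `map_x`, `map_y` mapped) and residual components `dx_px`, `dy_px`
#'   (plus nm columns when the pixel size is known). Carries the transform
#'   as attribute `transform`.
#' @export
difference_vectors <- function(pairs, transform = NULL, fm_pixel_size_nm = NULL) {
  assert_df_cols(pairs, c("em_x", "em_y", "fm_x", "fm_y"), "pairs")
  if (is.null(transform)) transform <- fit_similarity(pairs)
  p <- tf_apply_xy(transform, pairs$em_x, pairs$em_y)
  out <- as_tibble(pairs)
  out$map_x <- p$x
  out$map_y <- p$y
  out$dx_px <- out$fm_x - p$x
  out$dy_px <- out$fm_y - p$y
  if (!is.null(fm_pixel_size_nm)) {
    assert_scalar_num(fm_pixel_size_nm, "fm_pixel_size_nm", positive = TRUE)
    out$dx_nm <- out$dx_px * fm_pixel_size_nm
    out$dy_nm <- out$dy_px * fm_pixel_size_nm
    attr(out, "fm_pixel_size_nm") <- fm_pixel_size_nm
  }
  attr(out, "transform") <- transform
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a similarity transform
#'
#' @param x A `similarity_transform`.
#' @param ... Unused.
#' @return One row per parameter (`s`, `theta_rad`, `t_x_px`, `t_y_px`).
#' @export
tidy.similarity_transform <- function(x, ...) {
  tibble(
    term = c("s", "theta_rad", "t_x_px", "t_y_px"),
    estimate = c(x$s, x$theta, x$t_x, x$t_y)
  )
}

#' @rdname tidy.similarity_transform
#' @export
glance.similarity_transform <- function(x, ...) {
  fit <- attr(x, "fit") %||% list(n_pairs = NA_integer_, rms_px = NA_real_, max_px = NA_real_)
  tibble(
    s = x$s, theta_rad = x$theta, t_x_px = x$t_x, t_y_px = x$t_y,
    n_pairs = fit$n_pairs, rms_residual_px = fit$rms_px, max_residual_px = fit$max_px
  )
}

#' Read/write a similarity transform as JSON
#'
#' @param transform A [similarity_transform()].
#' @param path File path.
#' @param fm_pixel_size_nm,em_pixel_size_nm Optional pixel sizes recorded
#'   alongside the parameters.
#' @return `write_transform_json()` returns `path` invisibly;
#'   `read_transform_json()` returns the transform.
#' @export
write_transform_json <- function(transform, path, fm_pixel_size_nm = NULL,
                                 em_pixel_size_nm = NULL) {
  stopifnot(inherits(transform, "similarity_transform"))
  obj <- list(
    s = transform$s, theta_rad = transform$theta,
    t_x_px = transform$t_x, t_y_px = transform$t_y
  )
  if (!is.null(fm_pixel_size_nm)) obj$fm_pixel_size_nm <- fm_pixel_size_nm
  if (!is.null(em_pixel_size_nm)) obj$em_pixel_size_nm <- em_pixel_size_nm
  fit <- attr(transform, "fit")
  if (!is.null(fit)) obj$fit <- fit
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tf <- similarity_transform(obj$s, obj$theta_rad, obj$t_x_px, obj$t_y_px)
  if (!is.null(obj$fit)) attr(tf, "fit") <- obj$fit
  tf
}
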