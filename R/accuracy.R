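#' Bootstrap estimate of overlay accuracy for N pointers
#'
#' Repeatedly draws a random subset of `n_pointers` distinct pointer
#' pairs from the (distortion-corrected) pool, fits the EM-to-FM
#' similarity transform on the subset, and maps the EM image center into
#' FM coordinates. The spread of the mapped center positions over the
#' resamples estimates the overlay accuracy achievable with that many
#' pointers.
#'
#' Subsets are drawn without replacement within a draw and independently
#' across draws (the same subset may recur). The headline `accuracy_nm`
#' is the per-axis (pooled) standard deviation
#' \eqn{\sqrt{(sd_x^2 + sd_y^2)/2}}; the radial 2D value
#' \eqn{\sqrt{sd_x^2 + sd_y^2}} is reported alongside.
#'
#' @param pool Data frame of matched pairs (`em_x`, `em_y`, `fm_x`,
#'   `fm_y`), e.g. from [simulate_pointer_pool()] or the corrected pairs
#'   of [register_with_distortion()].
#' @param n_pointers Subset size N (2 <= N <= pool size).
#' @param repeats Number of resamples (>= 2; 5000 is typical).
#' @param em_center EM coordinates of the probe point mapped on every
#'   draw, length-2 numeric; default the centroid of the pool's EM
#'   coordinates (the EM image center for a centered grid). Accuracy
#'   grows with the lever arm from the pointer centroid, so the probe
#'   point is configurable.
#' @param fm_pixel_size_nm FM pixel size used to express the spread in
#'   nm; defaults to the pool's `fm_pixel_size_nm` attribute, else 1
#'   (results in px).
#' @param seed RNG seed.
#' @return A `center_spread` tibble with one mapped FM position per
#'   resample (`x_nm`, `y_nm`, relative to the mean), carrying summary
#'   attributes; `glance()` returns `accuracy_nm`, `sd_x_nm`, `sd_y_nm`,
#'   `sd_radial_nm`, `n_pointers`, `repeats`.
#' @export
bootstrap_accuracy <- function(pool, n_pointers, repeats = 5000L,
                               em_center = NULL, fm_pixel_size_nm = NULL,
                               seed = NULL) {
  assert_df_cols(pool, c("em_x", "em_y", "fm_x", "fm_y"), "pool")
  n_pointers <- assert_count(n_pointers, "n_pointers")
  repeats <- assert_count(repeats, "repeats", lower = 2L)
  npool <- nrow(pool)
  if (n_pointers < 2L) {
    abort("`n_pointers` must be at least 2: at least 2 pointer pairs are needed for the similarity fit.")
  }
  if (n_pointers > npool) {
    abort(sprintf("`n_pointers` (%d) exceeds the pool size (%d).", n_pointers, npool))
  }
  px <- fm_pixel_size_nm %||% attr(pool, "fm_pixel_size_nm") %||% 1
  if (is.null(em_center)) em_center <- c(mean(pool$em_x), mean(pool$em_y))
  ex <- pool$em_x; ey <- pool$em_y; fx <- pool$fm_x; fy <- pool$fm_y
  cxy <- with_seed_if(seed, {
    out <- matrix(NA_real_, repeats, 2L)
    for (r in seq_len(repeats)) {
      idx <- sample.int(npool, n_pointers)
      fit <- fit_similarity_core(ex[idx], ey[idx], fx[idx], fy[idx])
      if (is.null(fit)) next # coincident draw; astronomically unlikely, skip
      out[r, 1L] <- fit$a * em_center[1] - fit$b * em_center[2] + fit$t_x
      out[r, 2L] <- fit$b * em_center[1] + fit$a * em_center[2] + fit$t_y
    }
    out
  })
  cxy <- cxy[stats::complete.cases(cxy), , drop = FALSE]
  sd_x <- stats::sd(cxy[, 1]) * px
  sd_y <- stats::sd(cxy[, 2]) * px
  spread <- tibble(
    x_nm = (cxy[, 1] - mean(cxy[, 1])) * px,
    y_nm = (cxy[, 2] - mean(cxy[, 2])) * px
  )
  structure(
    spread,
    n_pointers = n_pointers, repeats = repeats,
    sd_x_nm = sd_x, sd_y_nm = sd_y,
    sd_radial_nm = sqrt(sd_x^2 + sd_y^2),
    accuracy_nm = sqrt((sd_x^2 + sd_y^2) / 2),
    em_center = em_center, fm_pixel_size_nm = px,
    class = c("center_spread", class(tibble()))
  )
}

#' @rdname bootstrap_accuracy
#' @param x A `center_spread`.
#' @param ... Unused.
#' @export
glance.center_spread <- function(x, ...) {
  tibble(
    n_pointers = attr(x, "n_pointers"), repeats = attr(x, "repeats"),
    accuracy_nm = attr(x, "accuracy_nm"),
    sd_x_nm = attr(x, "sd_x_nm"), sd_y_nm = attr(x, "sd_y_nm"),
    sd_radial_nm = attr(x, "sd_radial_nm")
  )
}

#' @export
print.center_spread <- function(x, ...) {
  cat(sprintf(
    "<center_spread> N = %d pointers, %d resamples: accuracy %.3g nm/axis (radial %.3g nm)\n",
    attr(x, "n_pointers"), attr(x, "repeats"), attr(x, "accuracy_nm"), attr(x, "sd_radial_nm")
  ))
  invisible(x)
}

#' Plot the overlay-error scatter for one pointer count
#'
#' @param object A `center_spread`.
#' @param ... Unused.
#' @export
autoplot.center_spread <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(.data$x_nm, .data$y_nm)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.5) +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = "overlay error x (nm)", y = "overlay error y (nm)",
      title = sprintf("Overlay errors, N = %d pointers (%.3g nm/axis)",
                      attr(object, "n_pointers"), attr(object, "accuracy_nm"))
    )
}

#' Overlay accuracy as a function of pointer count
#'
#' Runs [bootstrap_accuracy()] for each pointer count in `n_list` and fits
#' the power law \eqn{accuracy = c N^{p}} by ordinary least squares on
#' \eqn{\log accuracy = \log c + p \log N}. With i.i.d. localization
#' noise the expected exponent is \eqn{p = -1/2}.
#'
#' @inheritParams bootstrap_accuracy
#' @param n_list Pointer counts N to evaluate.
#' @return An `accuracy_curve` tibble (`n_pointers`, `accuracy_nm`,
#'   `sd_x_nm`, `sd_y_nm`, `sd_radial_nm`, `repeats`) with the fitted
#'   `c` (prefactor, nm) and `p` (exponent) in attributes; see
#'   `glance()`/`tidy()`/`autoplot()` methods.
#' @export
accuracy_curve <- function(pool, n_list = c(4, 9, 16, 25, 64, 100, 256),
                           repeats = 5000L, em_center = NULL,
                           fm_pixel_size_nm = NULL, seed = NULL) {
  n_list <- sort(unique(as.integer(n_list)))
  rows <- purrr::imap(n_list, function(n, i) {
    sub_seed <- if (is.null(seed)) NULL else (as.integer(seed) + i)
    glance(bootstrap_accuracy(pool, n, repeats, em_center, fm_pixel_size_nm,
                              seed = sub_seed))
  })
  curve <- dplyr::bind_rows(rows)
  ols <- stats::lm(log(accuracy_nm) ~ log(n_pointers), data = curve)
  structure(
    curve,
    prefactor_nm = exp(stats::coef(ols)[[1]]),
    exponent = stats::coef(ols)[[2]],
    r_squared = summary(ols)$r.squared,
    class = c("accuracy_curve", class(tibble()))
  )
}

#' @rdname accuracy_curve
#' @param x An `accuracy_curve`.
#' @param ... Unused.
#' @export
glance.accuracy_curve <- function(x, ...) {
  tibble(
    prefactor_nm = attr(x, "prefactor_nm"),
    exponent = attr(x, "exponent"),
    r_squared = attr(x, "r_squared"),
    n_counts = nrow(x)
  )
}

#' @rdname accuracy_curve
#' @export
tidy.accuracy_curve <- function(x, ...) as_tibble(x)

#' @export
print.accuracy_curve <- function(x, ...) {
  cat(sprintf("<accuracy_curve> %d pointer counts; fitted accuracy = %.3g * N^%.3f nm\n",
              nrow(x), attr(x, "prefactor_nm"), attr(x, "exponent")))
  print(as_tibble(x))
  invisible(x)
}

#' Plot an overlay-accuracy curve on log-log axes
#'
#' @param object An `accuracy_curve`.
#' @param ... Unused.
#' @export
autoplot.accuracy_curve <- function(object, ...) {
  cfit <- attr(object, "prefactor_nm"); p <- attr(object, "exponent")
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$n_pointers, .data$accuracy_nm)) +
    ggplot2::geom_function(
      fun = function(n) cfit * n^p, color = "grey50", linetype = 2
    ) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "number of CL pointers N", y = "overlay accuracy (nm)",
      title = sprintf("accuracy = %.3g nm * N^%.3f", cfit, p)
    )
}
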