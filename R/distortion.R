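#' Generate a smooth ground-truth distortion field
#'
#' Builds a grid-sampled vector field over the FM field of view emulating
#' the residual (non-similarity) distortion between the EM and FM
#' coordinate frames: a smooth low-order (cubic) 2D polynomial field, with
#' optional localized anomalous vectors deviant in magnitude and
#' orientation (such anomalies are seen consistently on real cameras and
#' attributed to the pixel array).
#'
#' The field is constructed orthogonal to the similarity-transform degrees
#' of freedom: it has zero mean and zero net scale/rotation projection, so
#' refitting a similarity transform on (node, node + vector) pairs returns
#' the identity. Given the same seed, the field scales exactly linearly in
#' `max_magnitude`.
#'
#' @param field_shape Length-2 integer, nodes as c(rows, cols).
#' @param max_magnitude Peak magnitude of the smooth component, nm
#'   (default 200, the scale bar of a typical measured profile).
#' @param anomaly_count Number of anomalous nodes (default 0).
#' @param seed RNG seed.
#' @param origin_px,extent_px FM-pixel position of the first node and the
#'   spanned extent c(x, y); nodes are laid out on an axis-aligned lattice.
#' @param fm_pixel_size_nm FM pixel size carried for unit conversions.
#' @return A `distortion_field`: a tibble with `node_id`, `row`, `col`,
#'   `x_px`, `y_px`, `dx_nm`, `dy_nm`, `n`, `sd_nm`, `anomaly`, plus
#'   lattice metadata in attributes.
#' @examples
#' f <- make_distortion_field(c(9, 9), max_magnitude = 200, anomaly_count = 3, seed = 7)
#' sum(f$anomaly)
#' @export
make_distortion_field <- function(field_shape = c(25, 25), max_magnitude = 200,
                                  anomaly_count = 0, seed = 1L,
                                  origin_px = c(40, 40), extent_px = c(960, 960),
                                  fm_pixel_size_nm = 100) {
  rows <- assert_count(field_shape[1], "field_shape[1]", lower = 2L)
  cols <- assert_count(field_shape[2], "field_shape[2]", lower = 2L)
  assert_scalar_num(max_magnitude, "max_magnitude", lower = 0)
  anomaly_count <- assert_count(anomaly_count, "anomaly_count", lower = 0L)
  assert_scalar_num(fm_pixel_size_nm, "fm_pixel_size_nm", positive = TRUE)

  df <- tidyr::expand_grid(row = seq_len(rows) - 1L, col = seq_len(cols) - 1L)
  dx_node <- extent_px[1] / (cols - 1)
  dy_node <- extent_px[2] / (rows - 1)
  x <- origin_px[1] + df$col * dx_node
  y <- origin_px[2] + df$row * dy_node
  # normalized coordinates in [-1, 1] for a well-conditioned polynomial basis
  u <- 2 * (df$col / (cols - 1)) - 1
  v <- 2 * (df$row / (rows - 1)) - 1

  base <- with_seed_if(seed, {
    terms <- cbind(1, u, v, u * v, u^2, v^2, u^2 * v, u * v^2, u^3, v^3)
    cdx <- stats::runif(ncol(terms), -1, 1)
    cdy <- stats::runif(ncol(terms), -1, 1)
    vec <- list(dx = as.vector(terms %*% cdx), dy = as.vector(terms %*% cdy))
    vec <- project_out_similarity(x, y, vec$dx, vec$dy)
    peak <- max(sqrt(vec$dx^2 + vec$dy^2))
    if (peak > 0) {
      vec$dx <- vec$dx / peak
      vec$dy <- vec$dy / peak
    }
    anom <- rep(FALSE, rows * cols)
    if (anomaly_count > 0) {
      interior <- which(df$row > 0 & df$row < rows - 1 & df$col > 0 & df$col < cols - 1)
      if (length(interior) < anomaly_count) interior <- seq_len(rows * cols)
      idx <- sample(interior, anomaly_count)
      ang <- atan2(vec$dy[idx], vec$dx[idx]) +
        stats::runif(anomaly_count, pi / 2, 3 * pi / 2) # deviant orientation
      vec$dx[idx] <- vec$dx[idx] + cos(ang)
      vec$dy[idx] <- vec$dy[idx] + sin(ang)
      anom[idx] <- TRUE
      # keep the full field (anomalies included) orthogonal to the
      # similarity degrees of freedom
      vec <- project_out_similarity(x, y, vec$dx, vec$dy)
    }
    list(dx = vec$dx, dy = vec$dy, anomaly = anom)
  })

  out <- tibble(
    node_id = seq_len(rows * cols) - 1L,
    row = df$row, col = df$col, x_px = x, y_px = y,
    dx_nm = base$dx * max_magnitude, dy_nm = base$dy * max_magnitude,
    n = 1L, sd_nm = 0, anomaly = base$anomaly
  )
  new_distortion_field(out,
    kind = "truth", rows = rows, cols = cols,
    lattice = list(type = "axis", x0 = origin_px[1], dx = dx_node,
                   y0 = origin_px[2], dy = dy_node),
    fm_pixel_size_nm = fm_pixel_size_nm
  )
}

new_distortion_field <- function(df, kind, rows, cols, lattice, fm_pixel_size_nm) {
  structure(
    df,
    kind = kind, rows = rows, cols = cols, lattice = lattice,
    fm_pixel_size_nm = fm_pixel_size_nm,
    class = c("distortion_field", class(tibble()))
  )
}

# Remove the components of a node vector field that a similarity fit can
# absorb: translation (x, y), isotropic scale, and rotation about the node
# centroid. Linear least-squares projection onto that 4-dim subspace.
project_out_similarity <- function(x, y, dx, dy) {
  cx <- x - mean(x); cy <- y - mean(y)
  n <- length(x)
  zero <- rep(0, n); one <- rep(1, n)
  # stacked (dx; dy) representation
  B <- cbind(
    c(one, zero),  # t_x
    c(zero, one),  # t_y
    c(cx, cy),     # scale
    c(-cy, cx)     # rotation
  )
  vv <- c(dx, dy)
  coef <- solve(crossprod(B), crossprod(B, vv))
  res <- vv - B %*% coef
  list(dx = res[seq_len(n)], dy = res[n + seq_len(n)])
}

#' Evaluate a distortion field at FM positions
#'
#' Bilinear interpolation on the calibration lattice. For a ground-truth
#' field the lattice is axis-aligned in FM pixels; for an estimated field
#' queries are mapped into lattice index space through the inverse of the
#' calibration transform. Queries outside the lattice coverage use the
#' nearest node (with a warning), or raise an error in strict mode — the
#' field is never meant to be extrapolated beyond the calibrated field of
#' view.
#'
#' @param field A `distortion_field`.
#' @param x,y FM-pixel query coordinates (vectors).
#' @param strict Error instead of nearest-node fallback outside coverage.
#' @param warn_outside Emit the out-of-coverage warning (default TRUE).
#' @return List with components `dx_nm`, `dy_nm`.
#' @export
interp_field <- function(field, x, y, strict = FALSE, warn_outside = TRUE) {
  stopifnot(inherits(field, "distortion_field"))
  lat <- attr(field, "lattice")
  rows <- attr(field, "rows"); cols <- attr(field, "cols")
  if (lat$type == "axis") {
    uf <- (x - lat$x0) / lat$dx
    vf <- (y - lat$y0) / lat$dy
  } else {
    inv <- invert_transform(lat$transform)
    p <- tf_apply_xy(inv, x, y)
    uf <- (p$x - lat$grid$origin[1]) / lat$grid$spacing
    vf <- (p$y - lat$grid$origin[2]) / lat$grid$spacing
  }
  outside <- uf < 0 | vf < 0 | uf > cols - 1 | vf > rows - 1
  if (any(outside)) {
    if (strict) {
      abort(sprintf("%d point(s) fall outside the distortion-field coverage.", sum(outside)))
    }
    if (warn_outside) {
      warn(sprintf("%d point(s) outside distortion-field coverage; using nearest node.",
                   sum(outside)))
    }
    uf <- pmin(pmax(uf, 0), cols - 1)
    vf <- pmin(pmax(vf, 0), rows - 1)
  }
  # node tables are row-major in (row, col)
  mx <- matrix(NA_real_, rows, cols)
  my <- matrix(NA_real_, rows, cols)
  mx[cbind(field$row + 1L, field$col + 1L)] <- field$dx_nm
  my[cbind(field$row + 1L, field$col + 1L)] <- field$dy_nm
  list(dx_nm = bilinear_sample(mx, uf, vf), dy_nm = bilinear_sample(my, uf, vf))
}

#' Estimate the distortion profile by averaging repeated pointer arrays
#'
#' The residual difference vectors of a single pointer-array exposure mix
#' localization noise with the systematic frame distortion. Averaging the
#' per-pointer difference vectors over a stack of sequentially exposed
#' arrays isolates the distortion profile over the full FM field of view;
#' the per-node standard error shrinks as \eqn{M^{-1/2}} in the number of
#' arrays M.
#'
#' Nodes whose mean vector deviates from a local-median smoothed field by
#' more than `k_anomaly` standard errors are flagged anomalous but
#' retained: anomalous vectors are a real, reproducible feature of the
#' camera, not outliers to delete.
#'
#' @param array_stack List of difference-vector tibbles (from
#'   [difference_vectors()] with `fm_pixel_size_nm` set), one per exposed
#'   array, all aligned to the same pointer grid.
#' @param grid The shared [pointer_grid()].
#' @param k_anomaly Anomaly threshold in units of the per-node standard
#'   error (default 10).
#' @return A `distortion_field` of kind `"estimated"`: per-node mean vector
#'   (nm), sample count `n`, per-axis pooled standard deviation `sd_nm`,
#'   and anomaly flag.
#' @export
estimate_distortion_field <- function(array_stack, grid, k_anomaly = 10) {
  stopifnot(inherits(grid, "pointer_grid"))
  if (!is.list(array_stack) || length(array_stack) < 1L) {
    abort("`array_stack` must be a non-empty list of difference-vector tables.")
  }
  if (inherits(array_stack, "data.frame")) array_stack <- list(array_stack)
  gp <- grid_points(grid)
  idx_ref <- sort(gp$pointer_index)
  px_nm <- NULL
  for (a in array_stack) {
    assert_df_cols(a, c("pointer_index", "map_x", "map_y", "dx_nm", "dy_nm"), "array_stack element")
    if (!identical(sort(unique(a$pointer_index)), idx_ref)) {
      abort("All arrays in `array_stack` must cover the same pointer grid.")
    }
    px_nm <- px_nm %||% attr(a, "fm_pixel_size_nm")
  }
  all_df <- dplyr::bind_rows(array_stack)
  nodes <- all_df |>
    dplyr::group_by(.data$pointer_index) |>
    dplyr::summarise(
      x_px = mean(.data$map_x), y_px = mean(.data$map_y),
      n = dplyr::n(),
      sd_nm = sqrt((stats::var(.data$dx_nm) + stats::var(.data$dy_nm)) / 2),
      dx_nm = mean(.data$dx_nm), dy_nm = mean(.data$dy_nm),
      .groups = "drop"
    ) |>
    dplyr::mutate(sd_nm = ifelse(is.na(.data$sd_nm), 0, .data$sd_nm)) |>
    dplyr::left_join(gp[, c("pointer_index", "row", "col")], by = "pointer_index") |>
    dplyr::arrange(.data$row, .data$col)
  nodes <- tibble(
    node_id = nodes$pointer_index, row = nodes$row, col = nodes$col,
    x_px = nodes$x_px, y_px = nodes$y_px,
    dx_nm = nodes$dx_nm, dy_nm = nodes$dy_nm,
    n = nodes$n, sd_nm = nodes$sd_nm
  )
  nodes$anomaly <- flag_anomalies(nodes, grid$rows, grid$cols, k_anomaly)

  # lattice metadata: node FM positions vs commanded EM grid define the
  # index mapping used for interpolation
  lat_tf <- fit_similarity(tibble(
    em_x = gp$em_x[match(nodes$node_id, gp$pointer_index)],
    em_y = gp$em_y[match(nodes$node_id, gp$pointer_index)],
    fm_x = nodes$x_px, fm_y = nodes$y_px
  ))
  new_distortion_field(nodes,
    kind = "estimated", rows = grid$rows, cols = grid$cols,
    lattice = list(type = "grid", grid = grid, transform = lat_tf),
    fm_pixel_size_nm = px_nm %||% NA_real_
  )
}

# Deviation of each node's mean vector from the median of its 3x3 lattice
# neighbors (excluding itself). A node is anomalous when the deviation
# exceeds k standard errors of its mean AND stands out of the deviation
# distribution of the whole lattice (median + 5 MAD): on a coarse
# calibration lattice the smooth field's own curvature produces nonzero
# neighbor-median deviations everywhere, and only clear outliers against
# that baseline are camera anomalies.
flag_anomalies <- function(nodes, rows, cols, k) {
  mx <- matrix(NA_real_, rows, cols)
  my <- matrix(NA_real_, rows, cols)
  mx[cbind(nodes$row + 1L, nodes$col + 1L)] <- nodes$dx_nm
  my[cbind(nodes$row + 1L, nodes$col + 1L)] <- nodes$dy_nm
  se <- pmax(nodes$sd_nm / sqrt(nodes$n), 1e-9)
  dev <- vapply(seq_len(nrow(nodes)), function(i) {
    r <- nodes$row[i] + 1L; c <- nodes$col[i] + 1L
    rr <- max(1L, r - 1L):min(rows, r + 1L)
    cc <- max(1L, c - 1L):min(cols, c + 1L)
    keep <- !outer(rr, cc, function(a, b) a == r & b == c)
    med_x <- stats::median(mx[rr, cc][keep], na.rm = TRUE)
    med_y <- stats::median(my[rr, cc][keep], na.rm = TRUE)
    sqrt((nodes$dx_nm[i] - med_x)^2 + (nodes$dy_nm[i] - med_y)^2)
  }, numeric(1))
  dev > pmax(k * se, stats::median(dev) + 5 * stats::mad(dev))
}

#' Distortion-corrected registration
#'
#' Two-pass registration: fit the similarity transform on the raw pairs,
#' evaluate the distortion field at each mapped EM position, subtract the
#' interpolated vector from the observed FM position, and refit on the
#' corrected pairs. A single correction pass suffices because the
#' distortion (at most a couple hundred nm over a tens-of-um field) makes
#' second-order terms negligible.
#'
#' @inheritParams fit_similarity
#' @param field A `distortion_field` (estimated or ground truth).
#' @param fm_pixel_size_nm FM pixel size; defaults to the field's.
#' @param strict Error when pairs fall outside the field coverage instead
#'   of using the nearest node.
#' @return A list of class `distortion_registration`: `transform` (the
#'   corrected fit), `raw_transform`, `corrected` and `raw`
#'   difference-vector tibbles.
#' @export
register_with_distortion <- function(pairs, field, fm_pixel_size_nm = NULL,
                                     strict = FALSE) {
  stopifnot(inherits(field, "distortion_field"))
  px <- fm_pixel_size_nm %||% attr(field, "fm_pixel_size_nm")
  if (is.null(px) || is.na(px)) abort("FM pixel size is required (field carries none).")
  raw_tf <- fit_similarity(pairs)
  p <- tf_apply_xy(raw_tf, pairs$em_x, pairs$em_y)
  d <- interp_field(field, p$x, p$y, strict = strict)
  corrected_pairs <- as_tibble(pairs)
  corrected_pairs$fm_x <- pairs$fm_x - d$dx_nm / px
  corrected_pairs$fm_y <- pairs$fm_y - d$dy_nm / px
  tf <- fit_similarity(corrected_pairs)
  structure(
    list(
      transform = tf,
      raw_transform = raw_tf,
      corrected = difference_vectors(corrected_pairs, tf, fm_pixel_size_nm = px),
      raw = difference_vectors(pairs, raw_tf, fm_pixel_size_nm = px)
    ),
    class = "distortion_registration"
  )
}

#' @export
print.distortion_registration <- function(x, ...) {
  g_raw <- glance(x$raw_transform); g_cor <- glance(x$transform)
  cat(sprintf(
    "<distortion_registration> raw RMS %.4g px -> corrected RMS %.4g px (%d pairs)\n",
    g_raw$rms_residual_px, g_cor$rms_residual_px, g_cor$n_pairs
  ))
  invisible(x)
}

#' @rdname estimate_distortion_field
#' @param x A `distortion_field`.
#' @param path Output path.
#' @export
write_field_csv <- function(x, path) {
  stopifnot(inherits(x, "distortion_field"))
  utils::write.csv(
    as.data.frame(x)[, c("node_id", "x_px", "y_px", "dx_nm", "dy_nm", "n", "sd_nm", "anomaly")],
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' @rdname estimate_distortion_field
#' @export
write_field_json <- function(x, path) {
  stopifnot(inherits(x, "distortion_field"))
  lat <- attr(x, "lattice")
  obj <- list(
    kind = attr(x, "kind"), rows = attr(x, "rows"), cols = attr(x, "cols"),
    fm_pixel_size_nm = attr(x, "fm_pixel_size_nm"),
    lattice = if (lat$type == "axis") {
      lat
    } else {
      list(type = "grid",
           grid = lat$grid[c("rows", "cols", "spacing", "origin")],
           transform = list(s = lat$transform$s, theta_rad = lat$transform$theta,
                            t_x_px = lat$transform$t_x, t_y_px = lat$transform$t_y))
    },
    nodes = as.data.frame(x)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname estimate_distortion_field
#' @export
read_field_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodes <- as_tibble(obj$nodes)
  lat <- obj$lattice
  if (lat$type == "grid") {
    lat <- list(
      type = "grid",
      grid = pointer_grid(lat$grid$rows, lat$grid$cols, lat$grid$spacing, lat$grid$origin),
      transform = similarity_transform(lat$transform$s, lat$transform$theta_rad,
                                       lat$transform$t_x_px, lat$transform$t_y_px)
    )
  }
  new_distortion_field(nodes, obj$kind, obj$rows, obj$cols, lat, obj$fm_pixel_size_nm)
}

#' Plot a distortion field as a vector map
#'
#' @param object A `distortion_field`.
#' @param scale Display magnification of the vectors (px per nm); default
#'   chosen so the largest vector spans about two node spacings.
#' @param ... Unused.
#' @export
autoplot.distortion_field <- function(object, scale = NULL, ...) {
  mag <- sqrt(object$dx_nm^2 + object$dy_nm^2)
  if (is.null(scale)) {
    spacing <- max(diff(sort(unique(object$x_px)))[1], 1)
    scale <- if (max(mag) > 0) 2 * spacing / max(mag) else 1
  }
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x_px, .data$y_px)) +
    ggplot2::geom_segment(
      ggplot2::aes(xend = .data$x_px + .data$dx_nm * scale,
                   yend = .data$y_px + .data$dy_nm * scale,
                   color = .data$anomaly),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.1, "cm"))
    ) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey30", `TRUE` = "red")) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (FM px)", y = "y (FM px)",
                  title = sprintf("Distortion field (max %.3g nm)", max(mag)))
}
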