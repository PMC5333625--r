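#' Initial transform guess from the outer edges of the grid
#'
#' Identifies four extreme detections on the convex hull of the detected
#' spot cloud, matches them to the four commanded grid corners (trying
#' every cyclic corner assignment and keeping the least-squares best),
#' and returns the corner-fit similarity transform. This gives a starting
#' transform that is insensitive to the unknown translation, rotation and
#' scaling between the commanded grid and the detections.
#'
#' A square (or near-square) grid is rotationally degenerate: corner
#' assignments 90 or 180 degrees apart fit equally well. Among
#' assignments whose corner cost is within a factor of two of the best,
#' the one whose fitted rotation is closest to `prefer_theta` wins — in
#' an integrated microscope the two frames are nearly rotation-aligned,
#' so the expected orientation is known a priori (default 0).
#'
#' @param detections Data frame of detected FM centers with columns `x`,
#'   `y`.
#' @param grid The commanded [pointer_grid()].
#' @param prefer_theta Expected rotation (radians) used only to break
#'   near-ties between degenerate corner assignments.
#' @return A [similarity_transform()] (EM to FM).
#' @export
initial_guess_from_edges <- function(detections, grid, prefer_theta = 0) {
  assert_df_cols(detections, c("x", "y"), "detections")
  stopifnot(inherits(grid, "pointer_grid"))
  if (nrow(detections) < 4L) abort("Need at least 4 detections for a corner-based initial guess.")
  hull <- grDevices::chull(detections$x, detections$y)
  if (length(hull) < 3L) abort("Detections are collinear: convex hull is degenerate.")
  hx <- detections$x[hull]; hy <- detections$y[hull]
  # pick 4 well-spread hull vertices as corner candidates:
  # farthest from centroid, farthest from it, then extremes on both sides
  # of the joining line
  cx <- mean(detections$x); cy <- mean(detections$y)
  i1 <- which.max((hx - cx)^2 + (hy - cy)^2)
  i2 <- which.max((hx - hx[i1])^2 + (hy - hy[i1])^2)
  nx_ <- hy[i2] - hy[i1]; ny_ <- hx[i1] - hx[i2]
  side <- (hx - hx[i1]) * nx_ + (hy - hy[i1]) * ny_
  if (max(side) <= 0 || min(side) >= 0) {
    abort("Detections are collinear: convex hull is degenerate.")
  }
  i3 <- which.max(side)
  i4 <- which.min(side)
  # order the four candidates by angle around the centroid so that they
  # form a cyclic sequence comparable with the grid corners
  cand <- unique(c(i1, i3, i2, i4))
  if (length(cand) < 4L) abort("Could not identify four distinct corner detections.")
  ang <- atan2(hy[cand] - cy, hx[cand] - cx)
  cand <- cand[order(ang)]
  corners_det <- tibble(x = hx[cand], y = hy[cand])
  corners_em <- grid_corners_em(grid)
  cands <- list()
  for (rev_ in c(FALSE, TRUE)) {
    ord0 <- if (rev_) 4:1 else 1:4
    for (shift in 0:3) {
      ord <- ord0[((seq_len(4) - 1 + shift) %% 4) + 1]
      pairs <- tibble(
        em_x = corners_em$em_x, em_y = corners_em$em_y,
        fm_x = corners_det$x[ord], fm_y = corners_det$y[ord]
      )
      tf <- tryCatch(fit_similarity(pairs), error = function(e) NULL)
      if (is.null(tf)) next
      cands[[length(cands) + 1L]] <- list(tf = tf, cost = attr(tf, "fit")$rms_px)
    }
  }
  if (length(cands) == 0) abort("Corner fitting failed for every corner assignment.")
  costs <- vapply(cands, `[[`, numeric(1), "cost")
  near_best <- which(costs <= 2 * min(costs) + 1e-9)
  ang_diff <- vapply(cands[near_best], function(cc) {
    d <- abs(cc$tf$theta - prefer_theta) %% (2 * pi)
    min(d, 2 * pi - d)
  }, numeric(1))
  cands[[near_best[which.min(ang_diff)]]]$tf
}

#' Pair detections with the commanded grid by iterative nearest neighbors
#'
#' Starting from an initial transform guess, iterates: map the commanded
#' grid into the FM frame; form mutual-nearest-neighbor pairs between
#' mapped grid nodes and detections; discard pairs whose residual exceeds
#' the adaptive threshold (a multiple of the median pair residual, capped
#' at half the mapped grid spacing); refit the similarity transform on
#' the survivors; repeat until the pair set is stable. The procedure is
#' insensitive to initial translation, rotation and scaling errors.
#'
#' Mutuality (each partner is the other's nearest neighbor) prevents two
#' grid nodes from claiming the same detection, keeping the pairing
#' one-to-one.
#'
#' @inheritParams initial_guess_from_edges
#' @param init Initial [similarity_transform()]; defaults to
#'   [initial_guess_from_edges()].
#' @param discard_k Residual threshold as a multiple of the current
#'   median pair residual (default 3).
#' @param noise_floor_px Lower bound on the discard threshold so that
#'   ordinary localization noise is never discarded (default 0.5 px).
#' @param max_iter Maximum iterations (default 20).
#' @return A `point_pairs` tibble: `pointer_index`, `em_x`, `em_y`,
#'   `fm_x`, `fm_y`, `detection_id`, with attributes `transform` (final
#'   fit), `unmatched_fm` (detection row indices left unmatched) and
#'   `unmatched_em` (pointer indices left unmatched).
#' @export
pair_by_iterative_nn <- function(detections, grid, init = NULL,
                                 discard_k = 3, noise_floor_px = 0.5,
                                 max_iter = 20L) {
  assert_df_cols(detections, c("x", "y"), "detections")
  stopifnot(inherits(grid, "pointer_grid"))
  if (is.null(init)) init <- initial_guess_from_edges(detections, grid)
  stopifnot(inherits(init, "similarity_transform"))
  gp <- grid_points(grid)
  base <- nn_iterate(detections, gp, grid, init, discard_k, noise_floor_px, max_iter)
  if (is.character(base)) abort(base)
  # A periodic lattice admits shifted self-consistent registrations that
  # leave a row or column of grid nodes unmatched. When nodes are left
  # over, probe the single-step lattice shifts and keep the registration
  # pairing the most nodes (ties: lowest residual).
  if (length(attr(base, "unmatched_em")) > 0) {
    best <- base
    tf0 <- attr(base, "transform")
    ab <- tf_ab(tf0)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      shift_em <- c(dc, dr) * grid$spacing
      tf_try <- similarity_transform(
        tf0$s, tf0$theta,
        tf0$t_x + ab[["a"]] * shift_em[1] - ab[["b"]] * shift_em[2],
        tf0$t_y + ab[["b"]] * shift_em[1] + ab[["a"]] * shift_em[2]
      )
      cand <- nn_iterate(detections, gp, grid, tf_try, discard_k, noise_floor_px, max_iter)
      if (is.character(cand)) next
      better <- nrow(cand) > nrow(best) ||
        (nrow(cand) == nrow(best) &&
           attr(attr(cand, "transform"), "fit")$rms_px <
             attr(attr(best, "transform"), "fit")$rms_px - 1e-12)
      if (better) best <- cand
    }
    base <- best
  }
  base
}

# One run of the map / mutual-NN / discard / refit loop. Returns the pair
# table on convergence, or a diagnostic string on failure.
nn_iterate <- function(detections, gp, grid, tf, discard_k, noise_floor_px, max_iter) {
  prev_key <- NULL
  pairs <- NULL
  for (iter in seq_len(max_iter)) {
    p <- tf_apply_xy(tf, gp$em_x, gp$em_y)
    spacing_fm <- grid$spacing * tf$s
    # mutual nearest neighbors between mapped nodes and detections
    d2 <- outer(p$x, detections$x, `-`)^2 + outer(p$y, detections$y, `-`)^2
    nn_det <- max.col(-d2, ties.method = "first")            # per node
    nn_node <- max.col(-t(d2), ties.method = "first")        # per detection
    node_idx <- which(nn_node[nn_det] == seq_len(nrow(gp)))
    det_idx <- nn_det[node_idx]
    res <- sqrt(d2[cbind(node_idx, det_idx)])
    thr <- min(max(discard_k * stats::median(res), noise_floor_px), 0.5 * spacing_fm)
    keep <- res <= thr
    node_idx <- node_idx[keep]; det_idx <- det_idx[keep]
    if (length(node_idx) < 2L) {
      return("Fewer than 2 surviving pointer pairs: at least 2 pointer pairs are needed to calculate the transformation.")
    }
    pairs <- tibble(
      pointer_index = gp$pointer_index[node_idx],
      em_x = gp$em_x[node_idx], em_y = gp$em_y[node_idx],
      fm_x = detections$x[det_idx], fm_y = detections$y[det_idx],
      detection_id = det_idx
    )
    tf <- fit_similarity(pairs)
    key <- paste(node_idx, det_idx, collapse = ";")
    if (identical(key, prev_key)) {
      pairs <- pairs[order(pairs$pointer_index), ]
      attr(pairs, "transform") <- tf
      attr(pairs, "unmatched_fm") <- setdiff(seq_len(nrow(detections)), det_idx)
      attr(pairs, "unmatched_em") <- setdiff(gp$pointer_index, pairs$pointer_index)
      attr(pairs, "iterations") <- iter
      return(pairs)
    }
    prev_key <- key
  }
  sprintf(
    "Grid pairing did not converge in %d iterations (last iteration kept %d pairs, RMS residual %.3g px).",
    max_iter, nrow(pairs), attr(tf, "fit")$rms_px
  )
}
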