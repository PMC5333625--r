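# Distortion-field estimation from repeated arrays and corrected registration.

# build a stack of per-array difference-vector tables from a pool
dv_stack <- function(pool, px_nm = 100) {
  lapply(split(as.data.frame(pool), pool$array_id), function(a) {
    difference_vectors(a, fm_pixel_size_nm = px_nm)
  })
}

test_that("a single zero-noise array reproduces its own difference vectors", {
  field_true <- make_distortion_field(c(5, 5), 150, seed = 2,
                                      origin_px = c(50, 50), extent_px = c(260, 260))
  gt <- scene_ground_truth(distortion = field_true, seed = 2)
  g <- pointer_grid(5, 5, spacing = 1000, origin = c(1000, 1000))
  pool <- simulate_pointer_pool(g, gt, n_arrays = 1, jitter_sigma_nm = 0)
  dv <- difference_vectors(pool, fm_pixel_size_nm = 100)
  est <- estimate_distortion_field(list(dv), g)
  j <- match(est$node_id, dv$pointer_index)
  expect_equal(est$dx_nm, dv$dx_nm[j], tolerance = 1e-9)
  expect_equal(est$dy_nm, dv$dy_nm[j], tolerance = 1e-9)
  expect_true(all(est$n == 1L))
})

test_that("node means recover an injected smooth field within two standard errors", {
  field_true <- make_distortion_field(c(9, 9), 200, seed = 5,
                                      origin_px = c(40, 40), extent_px = c(440, 440))
  gt <- scene_ground_truth(distortion = field_true, seed = 5)
  g <- pointer_grid(9, 9, spacing = 1000, origin = c(500, 500))
  pool <- simulate_pointer_pool(g, gt, n_arrays = 50, jitter_sigma_nm = 15, seed = 5)
  est <- estimate_distortion_field(dv_stack(pool), g)
  # the similarity component of the field evaluated at the pointer nodes is
  # absorbed by each array's fit and is unobservable in the residuals, so
  # the recoverable target is the similarity-projected truth
  tr <- interp_field(field_true, est$x_px, est$y_px, warn_outside = FALSE)
  trp <- clpointer:::project_out_similarity(est$x_px, est$y_px, tr$dx_nm, tr$dy_nm)
  dev <- sqrt((est$dx_nm - trp$dx)^2 + (est$dy_nm - trp$dy)^2)
  se_vec <- est$sd_nm * sqrt(2) / sqrt(est$n) # SE of the 2D mean vector
  expect_gte(mean(dev <= 2 * se_vec), 0.95)
})

test_that("per-node standard error shrinks as M^(-1/2) in the array count", {
  field_true <- make_distortion_field(c(6, 6), 180, seed = 8,
                                      origin_px = c(60, 60), extent_px = c(280, 280))
  gt <- scene_ground_truth(distortion = field_true, seed = 8)
  g <- pointer_grid(6, 6, spacing = 800, origin = c(1200, 1200))
  m_list <- c(1, 4, 16, 64)
  # standard error of the node mean, measured empirically over repetitions
  err <- sapply(m_list, function(m) {
    devs <- sapply(1:30, function(r) {
      pool <- simulate_pointer_pool(g, gt, n_arrays = m, jitter_sigma_nm = 15,
                                    seed = 1000 * m + r)
      est <- estimate_distortion_field(dv_stack(pool), g)
      tr <- interp_field(field_true, est$x_px, est$y_px, warn_outside = FALSE)
      trp <- clpointer:::project_out_similarity(est$x_px, est$y_px, tr$dx_nm, tr$dy_nm)
      mean((est$dx_nm - trp$dx)^2 + (est$dy_nm - trp$dy)^2) / 2
    })
    sqrt(mean(devs))
  })
  slope <- coef(lm(log(err) ~ log(m_list)))[[2]]
  expect_lt(abs(slope + 0.5), 0.1)
})

test_that("anomalous nodes are flagged but retained", {
  field_true <- make_distortion_field(c(9, 9), 200, anomaly_count = 3, seed = 11,
                                      origin_px = c(40, 40), extent_px = c(440, 440))
  gt <- scene_ground_truth(distortion = field_true, seed = 11)
  g <- pointer_grid(9, 9, spacing = 1000, origin = c(500, 500))
  pool <- simulate_pointer_pool(g, gt, n_arrays = 50, jitter_sigma_nm = 10, seed = 11)
  est <- estimate_distortion_field(dv_stack(pool), g)
  expect_equal(nrow(est), 81) # all nodes retained
  # nodes sitting on an injected anomaly should dominate the flags: the
  # deviation-vs-neighbor-median statistic is largest exactly there
  truth_at_nodes <- interp_field(field_true, est$x_px, est$y_px, warn_outside = FALSE)
  mag_true <- sqrt(truth_at_nodes$dx_nm^2 + truth_at_nodes$dy_nm^2)
  expect_gte(sum(est$anomaly), 1)
  expect_lte(sum(est$anomaly), 8)
  expect_gt(mean(mag_true[est$anomaly]), mean(mag_true[!est$anomaly]))
})

test_that("arrays on mismatched grids are rejected", {
  gt <- default_gt(seed = 1)
  g1 <- pointer_grid(4, 4, spacing = 800, origin = c(400, 400))
  g2 <- pointer_grid(5, 5, spacing = 800, origin = c(400, 400))
  p1 <- simulate_pointer_pool(g1, gt, jitter_sigma_nm = 5)
  dv <- difference_vectors(p1, fm_pixel_size_nm = 100)
  expect_error(estimate_distortion_field(list(dv), g2), "same pointer grid")
})

test_that("register_with_distortion with a zero field equals the plain fit", {
  zero <- make_distortion_field(c(5, 5), 0, seed = 1,
                                origin_px = c(0, 0), extent_px = c(400, 400))
  gt <- default_gt(seed = 13)
  pool <- simulate_pointer_pool(small_grid(), gt, jitter_sigma_nm = 10, seed = 13)
  reg <- register_with_distortion(pool, zero, fm_pixel_size_nm = 100)
  plain <- fit_similarity(pool)
  expect_equal(reg$transform$s, plain$s, tolerance = 1e-12)
  expect_equal(reg$transform$theta, plain$theta, tolerance = 1e-12)
})

test_that("correcting a zero-noise distorted scene removes the residuals", {
  field_true <- make_distortion_field(c(7, 7), 200, seed = 17,
                                      origin_px = c(40, 40), extent_px = c(300, 300))
  gt <- scene_ground_truth(distortion = field_true, seed = 17)
  g <- pointer_grid(7, 7, spacing = 800, origin = c(400, 400))
  pool <- simulate_pointer_pool(g, gt, jitter_sigma_nm = 0)
  raw <- difference_vectors(pool, fm_pixel_size_nm = 100)
  # uncorrected residuals show the injected distortion
  expect_gt(max(sqrt(raw$dx_px^2 + raw$dy_px^2)), 0.5)
  reg <- register_with_distortion(pool, field_true, fm_pixel_size_nm = 100)
  expect_lt(max(sqrt(reg$corrected$dx_px^2 + reg$corrected$dy_px^2)), 0.02)
})

test_that("distortion correction reduces the residual RMS under noise", {
  field_true <- make_distortion_field(c(7, 7), 200, seed = 19,
                                      origin_px = c(40, 40), extent_px = c(300, 300))
  g <- pointer_grid(4, 4, spacing = 1600, origin = c(500, 500))
  wins <- sapply(1:20, function(s) {
    gt <- scene_ground_truth(distortion = field_true, seed = s)
    pool <- simulate_pointer_pool(g, gt, jitter_sigma_nm = 12, seed = s)
    reg <- register_with_distortion(pool, field_true, fm_pixel_size_nm = 100)
    raw_rms <- sqrt(mean(reg$raw$dx_px^2 + reg$raw$dy_px^2))
    cor_rms <- sqrt(mean(reg$corrected$dx_px^2 + reg$corrected$dy_px^2))
    cor_rms < raw_rms
  })
  expect_gte(mean(wins), 0.95)
})

test_that("field JSON and CSV outputs round-trip the node table", {
  field <- make_distortion_field(c(5, 5), 120, anomaly_count = 2, seed = 21)
  jp <- withr::local_tempfile(fileext = ".json")
  write_field_json(field, jp)
  back <- read_field_json(jp)
  expect_equal(back$dx_nm, field$dx_nm, tolerance = 1e-12)
  expect_equal(back$anomaly, field$anomaly)
  d <- interp_field(back, c(100, 200), c(100, 150), warn_outside = FALSE)
  d0 <- interp_field(field, c(100, 200), c(100, 150), warn_outside = FALSE)
  expect_equal(d, d0, tolerance = 1e-12)
  cp <- withr::local_tempfile(fileext = ".csv")
  write_field_csv(field, cp)
  expect_equal(nrow(read.csv(cp)), 25)
})

test_that("out-of-coverage queries warn (or error in strict mode)", {
  field <- make_distortion_field(c(5, 5), 100, seed = 1,
                                 origin_px = c(50, 50), extent_px = c(100, 100))
  expect_warning(interp_field(field, 0, 0), "outside")
  expect_error(interp_field(field, 0, 0, strict = TRUE), "outside")
  # nearest-node fallback returns the corner value
  v <- suppressWarnings(interp_field(field, 0, 0))
  corner <- field[field$row == 0 & field$col == 0, ]
  expect_equal(v$dx_nm, corner$dx_nm)
})
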