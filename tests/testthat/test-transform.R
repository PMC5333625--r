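# Similarity-transform fitting, application and residual identities.

test_that("fit recovers a forward-constructed transform exactly", {
  cases <- list(
    list(s = 2, theta = pi / 2, t = c(3, 4)),
    list(s = 0.05, theta = 0.02, t = c(40, 36)),
    list(s = 1.7, theta = -2.5, t = c(-12, 7))
  )
  em <- tibble::tibble(em_x = c(0, 1, 0, 2.5), em_y = c(0, 0, 1, -1.3))
  for (cs in cases) {
    tf0 <- similarity_transform(cs$s, cs$theta, cs$t[1], cs$t[2])
    fm <- apply_transform(data.frame(x = em$em_x, y = em$em_y), tf0)
    fit <- fit_similarity(dplyr::bind_cols(em, fm_x = fm$x, fm_y = fm$y))
    expect_equal(fit$s, cs$s, tolerance = 1e-12)
    expect_equal(fit$theta, cs$theta, tolerance = 1e-12)
    expect_equal(c(fit$t_x, fit$t_y), cs$t, tolerance = 1e-10)
    expect_lt(attr(fit, "fit")$rms_px, 1e-9)
  }
})

test_that("identity pairs give the identity transform", {
  pairs <- tibble::tibble(em_x = c(0, 3, 1), em_y = c(0, 1, 4),
                          fm_x = c(0, 3, 1), fm_y = c(0, 1, 4))
  fit <- fit_similarity(pairs)
  expect_equal(fit$s, 1, tolerance = 1e-12)
  expect_equal(fit$theta, 0, tolerance = 1e-12)
  expect_equal(c(fit$t_x, fit$t_y), c(0, 0), tolerance = 1e-12)
})

test_that("exactly two non-coincident pairs give a unique zero-residual fit", {
  tf0 <- similarity_transform(1.3, 0.7, 5, -2)
  em <- data.frame(x = c(0, 2), y = c(1, -1))
  fm <- apply_transform(em, tf0)
  fit <- fit_similarity(tibble::tibble(em_x = em$x, em_y = em$y,
                                       fm_x = fm$x, fm_y = fm$y))
  expect_lt(attr(fit, "fit")$rms_px, 1e-10)
  expect_equal(fit$s, tf0$s, tolerance = 1e-12)
  expect_equal(fit$theta, tf0$theta, tolerance = 1e-12)
})

test_that("underdetermined or degenerate inputs are rejected", {
  one <- tibble::tibble(em_x = 1, em_y = 2, fm_x = 3, fm_y = 4)
  expect_error(fit_similarity(one), "2 pointer pairs")
  coincident <- tibble::tibble(em_x = c(1, 1), em_y = c(2, 2),
                               fm_x = c(0, 5), fm_y = c(0, 5))
  expect_error(fit_similarity(coincident), "coincide|singular")
})

test_that("apply_transform matches hand arithmetic and round-trips", {
  tf <- similarity_transform(2, pi / 2, 3, 4)
  expect_equal(unlist(apply_transform(data.frame(x = 1, y = 0), tf)),
               c(x = 3, y = 6), tolerance = 1e-12)
  expect_equal(unlist(apply_transform(data.frame(x = 0, y = 0), tf)),
               c(x = 3, y = 4), tolerance = 1e-12)
  # identity leaves points alone
  pts <- data.frame(x = rnorm(5), y = rnorm(5))
  expect_equal(apply_transform(pts, similarity_transform()), tibble::as_tibble(pts))
  # apply then apply-inverse
  fwd <- apply_transform(pts, tf)
  back <- apply_transform(fwd, invert_transform(tf))
  expect_equal(back$x, pts$x, tolerance = 1e-12)
  expect_equal(back$y, pts$y, tolerance = 1e-12)
})

test_that("least-squares residuals satisfy the orthogonality identities", {
  set.seed(42)
  for (rep in 1:5) {
    pairs <- tibble::tibble(
      em_x = runif(12, 0, 100), em_y = runif(12, 0, 100),
      fm_x = runif(12, 0, 100), fm_y = runif(12, 0, 100)
    )
    dv <- difference_vectors(pairs)
    # sum of residuals vanishes
    expect_lt(abs(sum(dv$dx_px)), 1e-6)
    expect_lt(abs(sum(dv$dy_px)), 1e-6)
    # projections onto the scale (dT/da) and rotation (dT/db) directions
    expect_lt(abs(sum(dv$dx_px * pairs$em_x + dv$dy_px * pairs$em_y)), 1e-6)
    expect_lt(abs(sum(-dv$dx_px * pairs$em_y + dv$dy_px * pairs$em_x)), 1e-6)
  }
})

test_that("zero-noise zero-distortion scene has vanishing difference vectors", {
  dv <- difference_vectors(noiseless_pairs())
  expect_lt(max(abs(c(dv$dx_px, dv$dy_px))), 1e-9)
})

test_that("fit agrees with a brute-force grid-search oracle", {
  set.seed(7)
  tf0 <- similarity_transform(1.8, 0.6, 10, -5)
  em <- tibble::tibble(em_x = runif(8, -5, 5), em_y = runif(8, -5, 5))
  fm <- apply_transform(data.frame(x = em$em_x, y = em$em_y), tf0)
  pairs <- tibble::tibble(em_x = em$em_x, em_y = em$em_y,
                          fm_x = fm$x + rnorm(8, 0, 0.3),
                          fm_y = fm$y + rnorm(8, 0, 0.3))
  # oracle: exhaustive search over (s, theta); translation by centroids
  s_grid <- seq(1.5, 2.1, by = 0.005)
  th_grid <- seq(0.3, 0.9, by = 0.005)
  best <- c(Inf, NA, NA)
  for (s in s_grid) for (th in th_grid) {
    a <- s * cos(th); b <- s * sin(th)
    tx <- mean(pairs$fm_x) - (a * mean(pairs$em_x) - b * mean(pairs$em_y))
    ty <- mean(pairs$fm_y) - (b * mean(pairs$em_x) + a * mean(pairs$em_y))
    ss <- sum((pairs$fm_x - (a * pairs$em_x - b * pairs$em_y + tx))^2 +
                (pairs$fm_y - (b * pairs$em_x + a * pairs$em_y + ty))^2)
    if (ss < best[1]) best <- c(ss, s, th)
  }
  fit <- fit_similarity(pairs)
  expect_lt(abs(fit$s - best[2]), 0.005)
  expect_lt(abs(fit$theta - best[3]), 0.005)
})

test_that("a rigid motion of the FM frame composes as predicted", {
  set.seed(3)
  pairs <- tibble::tibble(em_x = runif(10, 0, 50), em_y = runif(10, 0, 50))
  fm <- apply_transform(data.frame(x = pairs$em_x, y = pairs$em_y),
                        similarity_transform(1.4, 0.2, 3, 1))
  pairs$fm_x <- fm$x + rnorm(10, 0, 0.1)
  pairs$fm_y <- fm$y + rnorm(10, 0, 0.1)
  base <- fit_similarity(pairs)
  phi <- 0.5; u <- c(7, -3)
  moved <- pairs
  moved$fm_x <- cos(phi) * pairs$fm_x - sin(phi) * pairs$fm_y + u[1]
  moved$fm_y <- sin(phi) * pairs$fm_x + cos(phi) * pairs$fm_y + u[2]
  fit2 <- fit_similarity(moved)
  expect_equal(fit2$s, base$s, tolerance = 1e-10)
  expect_equal(fit2$theta, base$theta + phi, tolerance = 1e-10)
  t_pred <- c(cos(phi) * base$t_x - sin(phi) * base$t_y + u[1],
              sin(phi) * base$t_x + cos(phi) * base$t_y + u[2])
  expect_equal(c(fit2$t_x, fit2$t_y), t_pred, tolerance = 1e-9)
})

test_that("parameter errors shrink as N^(-1/2) with pointer count", {
  grid_big <- pointer_grid(16, 16, spacing = 1200, origin = c(200, 200))
  gt <- default_gt(seed = 5)
  n_list <- c(4, 16, 64, 256)
  set.seed(5)
  err <- sapply(n_list, function(n) {
    e <- replicate(150, {
      gp <- grid_points(grid_big)
      idx <- sample.int(nrow(gp), n)
      p <- apply_transform(data.frame(x = gp$em_x[idx], y = gp$em_y[idx]), gt$transform)
      pairs <- tibble::tibble(em_x = gp$em_x[idx], em_y = gp$em_y[idx],
                              fm_x = p$x + rnorm(n, 0, 0.15),
                              fm_y = p$y + rnorm(n, 0, 0.15))
      fit <- fit_similarity(pairs)
      abs(fit$s - gt$transform$s)
    })
    sqrt(mean(e^2))
  })
  slope <- coef(lm(log(err) ~ log(n_list)))[[2]]
  expect_lt(abs(slope + 0.5), 0.1)
})

test_that("tidy and glance expose the fitted parameters", {
  fit <- fit_similarity(noiseless_pairs())
  td <- tidy(fit)
  expect_equal(td$term, c("s", "theta_rad", "t_x_px", "t_y_px"))
  g <- glance(fit)
  expect_equal(g$n_pairs, 16L)
  expect_lt(g$rms_residual_px, 1e-9)
})

test_that("transform JSON round-trips losslessly", {
  tf <- similarity_transform(0.05123, -0.0213, 41.25, 36.75)
  path <- withr::local_tempfile(fileext = ".json")
  write_transform_json(tf, path, fm_pixel_size_nm = 100, em_pixel_size_nm = 5)
  back <- read_transform_json(path)
  expect_equal(unclass(back)[c("s", "theta", "t_x", "t_y")],
               unclass(tf)[c("s", "theta", "t_x", "t_y")], tolerance = 1e-15)
})
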