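# Overlay resampling, fiducial comparison, end-to-end pipeline and CLI.

test_that("identity transform with equal pixel sizes reproduces the EM image", {
  set.seed(1)
  m <- matrix(runif(80 * 80, 10, 100), 80, 80)
  em <- raster_image(m, 100, "EM")
  fm <- raster_image(matrix(50, 80, 80), 100, "FM")
  ov <- build_overlay(fm, em, similarity_transform())
  expect_equal(unclass(ov$registered_em), m, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("a whole-pixel translation shifts the registered image exactly", {
  set.seed(2)
  m <- matrix(runif(60 * 60, 0, 1), 60, 60)
  em <- raster_image(m, 100, "EM")
  fm <- raster_image(matrix(0, 60, 60), 100, "FM")
  ov <- build_overlay(fm, em, similarity_transform(t_x = 5, t_y = 3))
  reg <- matrix(as.numeric(ov$registered_em), 60, 60)
  expect_equal(reg[(1 + 3):60, (1 + 5):60], m[1:57, 1:55], tolerance = 1e-12)
  expect_true(all(reg[1:3, ] == 0)) # outside the EM footprint
})

test_that("bilinear resampling conserves mean intensity of a smooth image", {
  xs <- seq_len(100) - 1
  m <- outer(sin(xs / 15) + 2, cos(xs / 20) + 2)
  em <- raster_image(m, 100, "EM")
  fm <- raster_image(matrix(1, 100, 100), 100, "FM")
  tf <- similarity_transform(s = 1.01, theta = 0.01, t_x = 1.3, t_y = -0.7)
  ov <- build_overlay(fm, em, tf)
  inside <- unclass(ov$registered_em) > 0
  expect_equal(mean(ov$registered_em[inside]), mean(m), tolerance = 0.01)
})

test_that("an EM footprint entirely outside the FM frame errors", {
  em <- raster_image(matrix(1, 20, 20), 5, "EM")
  fm <- raster_image(matrix(1, 50, 50), 100, "FM")
  expect_error(build_overlay(fm, em, similarity_transform(t_x = 1e5, t_y = 1e5)),
               "outside the FM frame")
})

test_that("fiducial positions in a rendered overlay agree between frames", {
  gt <- default_gt(seed = 21)
  sc <- render_fiducial_scene(8, gt, em_shape = c(2048, 2048), noise = TRUE,
                              min_separation_nm = 900)
  # register from the true pointer correspondence (coordinate mode)
  pool <- simulate_pointer_pool(small_grid(), gt, jitter_sigma_nm = 5, seed = 21)
  tf <- fit_similarity(pool)
  ov <- build_overlay(sc$fm, sc$em, tf)
  # map true EM centers into the FM frame of the overlay: they must land on
  # the rendered FM spots within a few localization errors
  mapped <- apply_transform(data.frame(x = sc$truth$em_x, y = sc$truth$em_y), tf)
  err_nm <- sqrt((mapped$x - sc$truth$fm_x)^2 + (mapped$y - sc$truth$fm_y)^2) * 100
  expect_lt(max(err_nm), 3 * 15) # 3x the combined localization/jitter scale
  expect_gt(ov$coverage, 0.05)
})

test_that("zero-noise scenes make CL and fiducial registrations coincide", {
  gt <- default_gt(seed = 22)
  pool <- simulate_pointer_pool(small_grid(), gt, jitter_sigma_nm = 0)
  tf <- fit_similarity(pool)
  gp <- grid_points(small_grid())
  fid <- simulate_fiducial_pool(10, gt,
                                region_em = c(min(gp$em_x), max(gp$em_x),
                                              min(gp$em_y), max(gp$em_y)),
                                loc_noise_fm_nm = 0, loc_noise_em_nm = 0, seed = 22)
  cmp <- compare_fiducial_registration(fid, tf, fm_pixel_size_nm = 100)
  expect_lt(max(cmp$mapping_diff_nm), 1e-6)
  expect_lt(max(abs(c(cmp$dx_cl_nm, cmp$dy_cl_nm))), 1e-6)
})

test_that("fiducial-based difference vectors sum to zero", {
  cmp <- fiducial_comparison_experiment(seed = 31)
  expect_lt(abs(sum(cmp$dx_fid_nm)), 1e-6)
  expect_lt(abs(sum(cmp$dy_fid_nm)), 1e-6)
  expect_equal(nrow(cmp), 14)
})

test_that("the pipeline runs end to end and is reproducible", {
  gt <- default_gt(seed = 41)
  g <- small_grid()
  sc <- render_pointer_image(g, gt, image_shape = c(300, 300), seed = 41)
  em_img <- raster_image(matrix(100, 400, 400) +
                           40 * row(matrix(0, 400, 400)) / 400, 5, "EM")
  fm_img <- raster_image(matrix(80, 300, 300), 100, "FM")
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  cfg <- list(
    fm_image = fm_img, em_image = em_img, pointer_image = sc$image,
    fm_pixel_size_nm = 100, em_pixel_size_nm = 5,
    grid = list(rows = 4, cols = 4, spacing = 800, origin = c(400, 400)),
    out_dir = dir1
  )
  ov <- suppressMessages(run_pipeline(cfg))
  expect_s3_class(ov, "overlay_result")
  for (f in c("transform.json", "pairs.csv", "residuals.csv", "overlay.png",
              "registered_em.tiff", "log.txt")) {
    expect_true(file.exists(file.path(dir1, f)))
  }
  # the reported transform maps the commanded grid onto the true centers
  tf <- read_transform_json(file.path(dir1, "transform.json"))
  mapped <- apply_transform(data.frame(x = sc$truth$em_x, y = sc$truth$em_y), tf)
  err <- sqrt((mapped$x - sc$truth$x)^2 + (mapped$y - sc$truth$y)^2)
  expect_lt(max(err), 0.2)
  # rerun: byte-identical machine-readable outputs
  cfg$out_dir <- dir2
  suppressMessages(run_pipeline(cfg))
  for (f in c("transform.json", "pairs.csv", "residuals.csv")) {
    expect_identical(readLines(file.path(dir1, f)), readLines(file.path(dir2, f)))
  }
})

test_that("an invalid pipeline config fails fast without partial runs", {
  expect_error(run_pipeline(list(fm_image = "x.tiff")), "missing required key")
  expect_error(
    run_pipeline(list(fm_image = "nope.tiff", em_image = "nope.tiff",
                      pointer_image = "nope.tiff", fm_pixel_size_nm = 100,
                      em_pixel_size_nm = 5,
                      grid = list(rows = 4, cols = 4))),
    "grid.*missing|missing file"
  )
})

test_that("pipeline errors carry the failing stage name", {
  fm_img <- raster_image(matrix(80, 60, 60), 100, "FM")
  cfg <- list(
    fm_image = fm_img, em_image = fm_img, pointer_image = fm_img,
    fm_pixel_size_nm = 100, em_pixel_size_nm = 5,
    grid = list(rows = 4, cols = 4, spacing = 800, origin = c(400, 400))
  )
  expect_error(suppressMessages(run_pipeline(cfg)), "stage 'localize'")
})

test_that("the CLI simulates, localizes and registers from the shell surface", {
  dir <- withr::local_tempdir()
  sc <- cli_main(c("simulate", "pointers", "--rows", "4", "--cols", "4",
                   "--spacing", "800", "--origin-x", "400", "--origin-y", "400",
                   "--image-size", "300", "--seed", "5", "--out-dir", dir))
  expect_true(file.exists(file.path(dir, "pointers.tiff")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  det <- cli_main(c("localize", "--image", file.path(dir, "pointers.tiff"),
                    "--count", "16", "--scale", "1", "--out-dir", dir))
  expect_equal(nrow(det), 16)
  pairs <- cli_main(c("pair", "--coords", file.path(dir, "detections.csv"),
                      "--rows", "4", "--cols", "4", "--spacing", "800",
                      "--origin-x", "400", "--origin-y", "400", "--out-dir", dir))
  expect_equal(nrow(pairs), 16)
  tf <- cli_main(c("register", "--pairs", file.path(dir, "pairs.csv"),
                   "--out-dir", dir))
  expect_true(file.exists(file.path(dir, "transform.json")))
  # TIFF quantization rescales intensities but not geometry: the recovered
  # scale/rotation must match the simulation ground truth
  gt_json <- jsonlite::read_json(file.path(dir, "ground_truth.json"), simplifyVector = TRUE)
  expect_equal(tf$s, gt_json$transform$s, tolerance = 1e-3)
  expect_equal(tf$theta, gt_json$transform$theta, tolerance = 1e-3)
  expect_error(cli_main(c("frobnicate")), "Unknown subcommand")
})
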