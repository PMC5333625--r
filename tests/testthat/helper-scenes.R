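# Shared builders for synthetic scenes used across the suite.

# isotropic Gaussian spot patch; coordinates are 0-based pixel centers
gaussian_patch <- function(n = 21, cx = (n - 1) / 2, cy = (n - 1) / 2,
                           fwhm = 3, amplitude = 100, background = 10) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  xs <- seq_len(n) - 1
  background + amplitude * outer(exp(-(xs - cy)^2 / (2 * sigma^2)),
                                 exp(-(xs - cx)^2 / (2 * sigma^2)))
}

# nonlinear Gaussian-fit localization oracle (independent of the
# radial-symmetry path): least-squares fit of an isotropic 2D Gaussian
gaussfit_center <- function(patch) {
  n_y <- nrow(patch); n_x <- ncol(patch)
  df <- expand.grid(x = seq_len(n_x) - 1, y = seq_len(n_y) - 1)
  df$z <- as.vector(t(patch))
  i <- which.max(df$z)
  fit <- minpack.lm::nlsLM(
    z ~ b + a * exp(-((x - cx)^2 + (y - cy)^2) / (2 * s^2)),
    data = df,
    start = list(b = min(df$z), a = max(df$z) - min(df$z),
                 cx = df$x[i], cy = df$y[i], s = 1.5),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  as.list(coef(fit))[c("cx", "cy")]
}

# standard small test scene: 4x4 pointer array under the default geometry
small_grid <- function() pointer_grid(4, 4, spacing = 800, origin = c(400, 400))

default_gt <- function(seed = 1, ...) scene_ground_truth(seed = seed, ...)

# matched pairs straight from ground truth (no noise), coordinate mode
noiseless_pairs <- function(grid = small_grid(), gt = default_gt()) {
  simulate_pointer_pool(grid, gt, n_arrays = 1, jitter_sigma_nm = 0, seed = 1)
}

# match paired detections against simulator truth; returns per-pair error (px)
pairing_errors_px <- function(pairs, truth) {
  j <- match(pairs$pointer_index, truth$pointer_index)
  sqrt((pairs$fm_x - truth$x[j])^2 + (pairs$fm_y - truth$y[j])^2)
}
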