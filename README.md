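# clpointer

Fiducial-free image registration for integrated correlative light and
electron microscopy (CLEM), using **cathodoluminescence (CL) pointers**.

In an integrated FM/SEM microscope the focused electron beam excites
luminescence in the (ITO-coated glass) substrate. Parking the beam at a
commanded EM coordinate therefore lights up a diffraction-limited spot on
the fluorescence camera: a *CL pointer* that ties a known EM-frame
position to an observable FM-frame position. An array of pointers exposed
within one camera integration gives many such ties at once, anywhere on
the sample, with no fiducial markers and no user interpretation. This
package implements the full analysis chain for that registration concept,
together with a virtual-microscope simulator that provides ground truth
for every stage:

- **Spot localization** — sub-pixel CL pointer centers by the
  radial-symmetry method (closed-form, no iteration), exploiting the
  circular symmetry of the pointer profile.
- **Grid correspondence** — sorting unordered detections into one-to-one
  pairs with the commanded beam grid via a corner-based initial guess and
  iterative mutual-nearest-neighbor matching, insensitive to initial
  translation, rotation and scaling errors.
- **Similarity registration** — the linear EM→FM transform
  `x^F = a·x^E − b·y^E + t_x`, `y^F = b·x^E + a·y^E + t_y` with
  `a = s·cosθ`, `b = s·sinθ`, fitted in closed form by least squares
  (scale `s`, rotation `θ`, translation `t`; reflections unrepresentable;
  a minimum of 2 pointer pairs). Residual *difference vectors*
  `δ_i = (x^F_i, y^F_i) − T(x^E_i, y^E_i)` quantify everything the linear
  model cannot explain.
- **Distortion field** — averaging `δ` over repeated pointer arrays maps
  the static non-linear distortion between the frames over the full field
  of view; the profile is estimated once and then used to correct every
  subsequent image pair (bilinear interpolation, single correction pass).
- **Overlay accuracy** — bootstrap resampling of `N`-pointer subsets,
  refitting, and mapping the EM image center measures the overlay accuracy
  as a function of `N`; it follows the expected `N^(-1/2)` power law, with
  sub-5 nm accuracy reached near `N = 9` at realistic localization noise.
- **Overlay rendering and pipeline** — EM-image resampling into the FM
  pixel grid, blended composites, a one-call `run_pipeline()`, a
  CL-versus-fiducial comparison, and a CLI (`inst/cli/clpointer`).

## Worked example

Simulate a 4×4 pointer array (16 pointers, 4 µm spacing in the EM frame),
localize, pair, and register:

```r
library(clpointer)

gt    <- scene_ground_truth(seed = 42)    # true transform, pixel sizes, camera noise
grid  <- pointer_grid(4, 4, spacing = 800, origin = c(400, 400))   # EM px
scene <- render_pointer_image(grid, gt, image_shape = c(300, 300))
spots <- localize_all(scene$image, expected_count = 16)
pairs <- pair_by_iterative_nn(spots, grid)
fit_similarity(pairs)
#> <similarity_transform> s = 0.0499888, theta = 0.020072 rad (1.15 deg), t = (40.0258, 36.0131) px
#>   fitted on 16 pairs, RMS residual 0.05366 px
```

The ground truth was `s = 0.05` (5 nm EM px on a 100 nm FM px),
`θ = 0.02 rad`, `t = (40, 36)`: the transform is recovered to ~3 parts in
10⁴ on scale and ~0.05 FM px (≈ 5 nm) RMS residual per pointer under
default camera noise.

Overlay accuracy versus pointer count, on a 50-array × 625-pointer pool
with 12 nm per-pointer localization jitter:

```r
pool <- simulate_pointer_pool(pointer_grid(25, 25, 800, origin = c(400, 400)),
                              scene_ground_truth(seed = 1),
                              n_arrays = 50, jitter_sigma_nm = 12, seed = 1)
bootstrap_accuracy(pool, n_pointers = 9, repeats = 5000, seed = 1)
#> <center_spread> N = 9 pointers, 5000 resamples: accuracy 4.31 nm/axis (radial 6.1 nm)

glance(accuracy_curve(pool, c(4, 9, 16, 25, 64, 100, 256), repeats = 1000, seed = 1))
#> # A tibble: 1 × 4
#>   prefactor_nm exponent r_squared n_counts
#>          <dbl>    <dbl>     <dbl>    <int>
#> 1         14.6   -0.544    0.996         7
```

Nine pointers give 4.3 nm per-axis overlay accuracy — below 5 nm — and
the accuracy curve follows the `N^(-1/2)` law (fitted exponent −0.54).
`autoplot()` methods are provided for accuracy curves, center spreads,
distortion fields and raster images; `tidy()`/`glance()` for fitted
transforms and curves.

## Learning more

The methods vignette (`vignettes/cl-pointer-registration.Rmd`) documents
the generative scene model, every tunable parameter with units and
defaults, the numerical choices (tie-breaks, interpolation, degenerate
inputs), and what the synthetic validation does and does not demonstrate
about real microscope data.
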