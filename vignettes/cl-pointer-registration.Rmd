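---
title: "CL-pointer registration: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CL-pointer registration: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clpointer)
```

## The registration problem

In an integrated fluorescence / scanning-electron microscope both
modalities view the same specimen region, but their coordinate frames
differ by an unknown scaling, rotation and translation, plus small
non-linear distortions contributed by both optical paths. Conventional
CLEM registration needs fiducial markers visible in both frames; their
random placement makes the achievable overlay accuracy unpredictable.
Cathodoluminescence (CL) pointers remove that dependence: the focused
electron beam, parked at a commanded EM coordinate, generates a
luminescent spot on the fluorescence camera, so each pointer directly
ties a known EM position to a measurable FM position anywhere on the
substrate.

The analysis chain is: localize the pointer spots sub-pixel, sort them
into pairs with the commanded beam grid, fit the EM→FM similarity
transform, and (optionally) correct with a pre-calibrated distortion
field before rendering the overlay.

## Coordinate conventions

All pixel coordinates are 0-based; a coordinate is the center of its
pixel; x runs along columns (rightward), y along rows (downward); angles
are counter-clockwise in that frame and reported in (−π, π]. Physical
positions are pixel coordinate × pixel size (nm). Transform translations
are stored in FM px, with nm available through the FM pixel size.

## The similarity model

The linear registration model is
$$x^F = a x^E - b y^E + t_x,\qquad y^F = b x^E + a y^E + t_y,$$
with $a = s\cos\theta$, $b = s\sin\theta$. It is linear in
$(a, b, t_x, t_y)$, so the least-squares problem has a closed-form
solution: after centering both point clouds,
$a = \sum (e \cdot f)/\sum|e|^2$ and $b = \sum (e \times f)/\sum|e|^2$,
then $t = \bar f - M\bar e$. Two non-coincident pairs determine the four
parameters exactly (zero residual); one pair leaves the system singular
and is rejected. The $(a,b)$ parameterization cannot represent a
reflection — a physically mirrored scene fits poorly and surfaces in the
residual diagnostics instead, which is the desired behavior for an
integrated microscope whose frames cannot mirror between exposures.

The residual *difference vector* of pointer $i$ is
$\delta_i = (x^F_i, y^F_i) - T(x^E_i, y^E_i)$. When $T$ is the
least-squares fit of the same pairs, $\sum_i \delta_i = 0$ and the
residuals are orthogonal to the scale and rotation degrees of freedom
(tested to 1e−6 px).

## Sub-pixel localization by radial symmetry

A CL pointer's intensity profile is circularly symmetric (electron
interaction volume convolved with the optical PSF, FWHM from ~300 nm
upward). The radial-symmetry estimator uses that symmetry directly:
intensity gradients at inter-pixel midpoints define lines along the local
gradient direction; for a radially symmetric spot every line passes
through the center, so the center is the weighted least-squares point of
closest approach of all lines — a 2×2 linear solve, no iteration, no
model function. Weights are squared gradient magnitude, down-weighted by
distance to the gradient-weighted centroid; midpoint gradients are
smoothed with a 3×3 boxcar. The patch median is subtracted beforehand,
removing a constant background without biasing a symmetric spot.

Numerical properties covered by the test suite: exactness on centered
symmetric spots; < 0.02 px agreement with a nonlinear Gaussian-fit oracle
on noiseless spots and RMS-error agreement within 10% under shot noise;
equivariance under translation, transposition, flips and 90° rotations;
invariance under positive intensity scaling. Constant patches and
singular line systems raise "no radial structure" errors.

Detection (the coarse stage) smooths with a small Gaussian
(σ = 1 px default), collects local maxima above `median + 2·MAD`, and
applies greedy non-maximum suppression at the requested minimum
separation. Ties are broken toward the smaller (row, col) index and
output is ordered by (y, x), so detection is fully deterministic. The
refinement patch radius defaults to 1.5× the spot FWHM, clipped to 0.45×
the observed nearest-neighbor seed spacing so that patches in a dense
array (spacing down to ~1.4× FWHM) do not swallow neighbors.

## Grid correspondence

Detections arrive unordered; the commanded grid must be matched
one-to-one. The initial guess fits the four grid corners to four extreme
convex-hull detections, trying all cyclic corner assignments (both
orientations) and keeping the least-squares best. A square or rectangular
grid is rotationally degenerate (assignments 90° or 180° apart fit
identically), so among assignments within a factor of two of the best
cost the one whose rotation is closest to `prefer_theta` (default 0)
wins: in an integrated microscope the frames are nearly rotation-aligned,
so the expected orientation is known a priori.

The iterative pairing then alternates: map the grid through the current
transform; form **mutual** nearest-neighbor pairs (mutuality keeps the
pairing one-to-one); discard pairs whose residual exceeds
min(3 × median residual, 0.5 × mapped grid spacing), with a 0.5 px floor
so ordinary localization noise is never discarded; refit; stop when the
pair set repeats (max 20 iterations). A periodic lattice admits shifted
self-consistent registrations that strand one row or column; whenever
grid nodes remain unmatched, the eight single-step lattice shifts of the
converged transform are probed and the solution pairing the most nodes
(ties: lowest residual) is kept. This keeps the pairing insensitive to
initial rotation and scale errors of at least 10° / 10%, which the suite
exercises.

## Distortion field

The difference vectors of a single array mix localization noise with the
static frame distortion; averaging per-pointer vectors over a stack of
sequentially exposed arrays isolates the distortion profile across the
field of view, with per-node standard error shrinking as $M^{-1/2}$ in
the array count. The profile is estimated once per microscope alignment
and then applied to every image pair: evaluate the field by bilinear
interpolation at the similarity-mapped position, subtract, refit. A
single correction pass suffices — with ≤ 200 nm of distortion over a
tens-of-µm field, second-order terms are fractions of a nanometer.
Outside the calibrated lattice the nearest node is used with a warning
(error in strict mode); the field is never meaningfully extrapolated.

An important identity: the similarity component of any distortion field,
evaluated at the calibration nodes, is absorbed by each array's transform
fit and is therefore unobservable in the residuals. The estimated profile
converges to the similarity-*projected* truth, and the recovery tests
compare against exactly that projection. Symmetrically, the simulator's
ground-truth generator constructs fields orthogonal to the similarity
subspace (zero mean, zero net scale and rotation about the node
centroid), so that what is injected is what is recoverable.

Nodes whose mean vector deviates from the median of their 3×3 lattice
neighbors by more than `k_anomaly` (default 10) standard errors *and*
beyond median + 5·MAD of the lattice-wide deviation distribution are
flagged anomalous but retained — deviant vectors are a reproducible
camera feature, not outliers to delete. The MAD guard exists because on a
coarse calibration lattice the smooth field's own curvature produces
nonzero neighbor-median deviations everywhere; only clear outliers
against that baseline are anomalies.

## Overlay accuracy by bootstrap

To state the accuracy achievable with $N$ pointers: draw $N$ distinct
pairs from the (distortion-corrected) pool, fit, map the EM image center
to FM coordinates; repeat (5000 draws by default; subsets may recur
across draws) and take the spread of mapped centers. The headline
`accuracy_nm` is the per-axis pooled standard deviation
$\sqrt{(sd_x^2+sd_y^2)/2}$; the radial value $\sqrt{sd_x^2+sd_y^2}$ is
reported alongside so either scalarization can be used. The per-axis
reading is the one consistent with sub-5 nm accuracy at $N = 9$ under
~12 nm per-pointer jitter ($\sigma/\sqrt{N} = 4$ nm), and matches a
per-axis histogram of overlay errors.

With i.i.d. jitter the accuracy follows $c\,N^{-1/2}$. The fitted
exponent on the standard pool (625 pointers × 50 arrays, $N$ from 4 to
256) comes out slightly steeper than −0.5 (typically ≈ −0.54): at small
$N$ the subset fit's lever-arm term and the Jensen inflation of
$E[1/\sum|e|^2]$ raise the accuracy above $cN^{-1/2}$, steepening the
log–log OLS slope. This is a property of the estimator at small $N$, not
an implementation artifact; the suite verifies the exponent within
±0.05 of −1/2 and cross-checks the bootstrap against a fresh-noise
Monte-Carlo oracle (within 15%).

The probe point defaults to the EM centroid of the pool (the EM image
center for a centered grid) and is configurable, because accuracy
degrades with lever arm from the pointer centroid.

## The virtual microscope

The simulator provides every input the pipeline consumes plus the ground
truth to score it. Generative model for an observed pointer:
$$FM_{obs} = T(EM) + D(T(EM)) + \text{noise},$$
i.e. distortion lives in the FM frame and is added at the mapped
position. Defaults (chosen once as a realistic integrated-microscope
configuration; the sources do not fix camera gains or photon budgets):

| parameter | default | meaning |
|---|---|---|
| `fm_pixel_size_nm` | 100 | FM camera pixel (60× objective class) |
| `em_pixel_size_nm` | 5 | EM pixel |
| `transform` | s = 0.05, θ = 0.02 rad, t = (40, 36) px | true EM→FM mapping; s equals the pixel-size ratio |
| `spot_fwhm_nm` | 300 | CL pointer / sphere FWHM (diffraction limit) |
| `amplitude`, `background`, `read_noise_sd` | 300, 100, 5 counts | camera model: Poisson on signal+background, plus Gaussian read noise |
| `jitter_sigma_nm` | 0 | coordinate-mode localization jitter |

Dense calibration arrays are 25 × 25 pointers at 4 µm spacing (625
pointers; 800 EM px here), per-image registration arrays 4 × 4 (16
pointers). Rendered spots are isotropic Gaussians; EM nanospheres are
40 nm disks with a half-pixel soft edge and deliberately low
signal-to-background. Image rendering defaults put the full-image
localization RMS at a few nm to ~10 nm — the regime in which sub-5 nm
overlay from 9 pointers is the interesting question.

The **coordinate mode** (`simulate_pointer_pool()`,
`simulate_fiducial_pool()`) skips rendering and adds isotropic Gaussian
jitter of stated σ directly to the true coordinates. Accuracy and
comparison studies use it so the localization-noise level is an exact,
controlled input rather than a byproduct of photon statistics; image
rendering is exercised separately by the localization and pipeline tests.

What the simulator does *not* emulate: physically accurate CL yield or
interaction volumes, optical aberrations beyond a Gaussian PSF, stage
drift, detector nonuniformity, or structured backgrounds. Passing tests
therefore demonstrate the correctness and statistical behavior of the
*analysis*, not the performance of any particular instrument; on real
data the achievable numbers are set by the camera, the substrate's CL
yield and the microscope's stability.

## The CL-versus-fiducial comparison

`fiducial_comparison_experiment()` reproduces the validation experiment
in coordinate mode: a 4×4 pointer array with 12 nm jitter registers the
frames; 14 nanosphere fiducials, localized with 5 nm noise in each frame,
provide the conventional registration; both transforms are evaluated at
every fiducial EM position and the per-fiducial mapping difference is
reported. Geometry (fixed once): the beam-deflection span covers the FM
field of view (~80 µm, the array), while the recorded EM image containing
the spheres covers a central ~10 µm (2048 px at 5 nm) — the beam can be
deflected across the whole FM field even when the EM image covers only a
sub-region, which is how a validation acquisition is actually laid out.
The fiducial noise level enters directly as the stated per-frame
localization σ because that is the quantity the comparison is sensitive
to; rendering the spheres and re-localizing them would only replace the
stated σ with an uncontrolled one.

## Problem sizes and determinism

The test suite and acceptance script run the study conditions at full
size where they are cheap (625-pointer arrays, 50-array pools of 31 250
entries, 5000-resample bootstraps) and scale Monte-Carlo repetition
counts to keep the whole suite in tens of seconds; each stochastic test
fixes its seed and every simulator function takes a `seed` argument, with
fixed seeds giving byte-identical images, tables and files. The
acceptance script derives all sub-seeds from its `--seed` flag.

## Known limitations

- The similarity model deliberately excludes shear and reflection; shear
  present in a real instrument lands in the distortion field instead.
- Distortion correction assumes the profile is static between
  calibration and acquisition (true as long as the microscope alignment
  is unchanged) and covers the queried region; outside coverage the
  nearest-node fallback is a zeroth-order guess.
- The corner-based initial guess needs the four grid corners to be
  detected; with more than ~25% of the outer ring missing the lattice
  search may be needed for convergence.
- Anomaly flagging on very coarse lattices (≲ 6×6) has little
  neighborhood context and is correspondingly conservative.
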