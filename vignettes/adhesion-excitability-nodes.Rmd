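---
title: "Models and methods for intercalated-disc adhesion/excitability node analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for intercalated-disc adhesion/excitability node analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(idnodes)
```

This vignette describes the models implemented in `idnodes`, the
assumptions behind them, the tunable parameters that matter, and the
numerical decisions taken where the underlying procedures left the design
open. It states no empirical result that the package's test suite or
`scripts/acceptance.R` does not itself compute.

# Scientific setting

At the cardiac intercalated disc (ID), clusters of the sodium channel
NaV1.5 sit next to N-cadherin adhesion plaques within the folded (plicate)
membrane. Three quantitative questions recur in imaging studies of this
domain and drive the package's design:

1. Is the spatial association between the channel clusters (the *query*
   species) and the adhesion clusters (the *reference* species) random, or
   does the adhesion complex act as an attractor?
2. Does clustering of channels change how efficiently a diffusing
   regulator binds them?
3. How much membrane, and therefore how much ensemble current, does a
   patch pipette actually sample on a strongly folded surface?

# Coordinates and units

All physical coordinates are nanometres with the origin at the top-left of
the field, x rightward and y downward (image convention). Pixel `i` covers
the half-open interval `[(i-1)·p, i·p)`, so pixel centers sit at
`(i - 0.5)·p`. Rotations are degrees; with y pointing down, a positive
rotation turns `(1, 0)` toward `(0, 1)`.

# Synthetic-data generators

The generators produce every input the analysis consumes together with its
generating ground truth, so each downstream stage can be validated by
recovery rather than by fixture files.

* `gen_ellipse_field()` builds a two-channel cluster field with the *same
  placement code* as the Monte Carlo experiment, so the generating
  attraction factor is exact by construction.
* `render_localization_image()` emulates a reconstructed localization
  image: a Poisson number of points per ellipse (mean `density · area`),
  uniform inside the ellipse, jittered by an isotropic Gaussian of scale
  `precision_nm` and binned at `pixel_nm` (default 20 nm/px, the
  reconstruction scale of the imaging protocol). Out-of-field
  localizations are not recorded (camera convention); for fields generated
  wholly inside the box, pixel counts sum exactly to the number of sampled
  localizations.
* `gen_fiducial_pairs()`, `gen_height_map()` and `gen_particle_stack()`
  provide registration, surface-topology and averaging inputs with known
  affine parameters, known analytic area, and known poses respectively.

**Cluster sizes.** The original placement analysis resampled semi-axes
from its measured cluster list, which is not publicly deposited. The size
source is therefore pluggable: any data frame of `(a, b)` semi-axes is
resampled with replacement, or a `function(n)` can generate them. The
default, `lognormal_size_sampler()`, draws log-normal semi-major axes with
median 120 nm (sdlog 0.35) and axis ratios uniform in `[0.5, 1]` —
channel-cluster scales of tens to a few hundred nm, chosen once as
realistic for ID clusters (a 44-channel cluster at 33 nm pore spacing has
an equivalent-circle radius of about 120 nm) and not tuned thereafter.

**Validation-only options.** Two generator flags exist purely so that
recovery tests are well-posed, and both default to the model behaviour
(off): `query_min_edge_nm` enforces a minimum edge separation among query
ellipses (the placement model allows query–query overlap, which would
merge detected clusters and make an exact count recovery impossible), and
`margin_nm` keeps ellipse centers away from the field edge (a protruding
ellipse is clipped by the camera convention, biasing its detected
centroid). Tests of the *model's* behaviour never set them.

**What the synthetic data does not emulate.** No blinking kinetics, PSF
shape, drift, or repeated localizations of one fluorophore; noise enters
only through Poisson sampling, localization jitter and (for particle
stacks) additive Gaussian noise. Passing the round-trip tests therefore
shows the detection chain is correct on well-separated clusters at
adequate density — not that it is robust to reconstruction artifacts of
real SMLM data.

# CLEM registration

`estimate_affine()` solves `dst ≈ L src + t` by least squares on
homogeneous coordinates (normal equations). This is exact for noiseless
consistent pairs, requires at least three non-collinear fiducials, and
applies no robust weighting by default because fiducials are hand-picked;
`trim_worst` optionally drops the worst pairs and refits.
`registration_error()` reports the RMSE of the 2D residual vectors and
raises a QC flag above 20 nm, the stated mapping error of the
super-resolved reconstruction. Note that with n fiducials and isotropic
per-coordinate noise σ the expected residual RMSE is
`σ · sqrt(2 · (1 − 3/n))`, so ~6.5 nm at n = 20, σ = 5 nm — comfortably
inside the 2σ bound the acceptance check uses.

# Cluster metrics

`binarize()` rescales a channel linearly to `[0, 1]` (a deterministic
stand-in for the manual brightness/contrast adjustment of interactive
workflows), applies a mean filter of the given radius, and thresholds
either at a fixed rescaled intensity or by Otsu's method.
`detect_clusters()` labels connected components (2D default 8-connected,
3D default 26-connected, matching the common particle-analysis defaults;
both configurable) and reports centroids as pixel-center means scaled to
nm, areas/volumes as pixel counts times the pixel (and z-step) size, and
2D circularity `4πA/P²` clamped to `[0, 1]` with the perimeter taken as
the object's boundary-pixel count — a coarse perimeter that slightly
inflates circularity for small round objects (hence the clamp) while still
separating elongated from compact clusters.

Distances: for **detected** clusters the edge-to-edge distance is the
minimum boundary pixel-center distance minus one pixel diagonal, and, when
pixel sets overlap, the negative of the maximal mutual penetration (the
deepest shared pixel's distance to the nearer boundary). For
**parametric** ellipses the overlap test is exact (see below) and the
boundary distance is evaluated on 128-point boundary polygons, accurate to
well under a nanometre at cluster scales. The two conventions agree to
about one pixel. Contact means edge distance ≤ 0; diagonal pixel adjacency
therefore counts as contact. Nearest-neighbour ties break toward the
lowest reference id. The nearest-neighbour search prunes candidates with
the bound `edge ≥ centroid distance − r_max(query) − r_max(reference)`
and is tested for exact agreement with a full O(n²) scan.

`filter_by_membrane()` keeps clusters whose centroid lies within
`halfwidth_nm` (default 500 nm, the analysis band of the CLEM protocol) of
the membrane polyline by point-to-segment distance.

# Ellipse geometry

Ellipse–ellipse overlap uses the algebraic condition on the pencil of the
two conics: with interior-negative conic matrices A and B, the cubic
`det(λA + B)` has two distinct positive real roots exactly when the
ellipses are separated; an external tangency gives a positive double root
and is counted as contact-at-zero rather than overlap. Because conic
determinants mix coordinate scales (nm positions against 1/nm² shape
terms), the test first normalizes to a local frame — midpoint at the
origin, lengths divided by the mean semi-axis — which keeps the cubic well
conditioned; bounding-circle screens using `max(a, b)` and `min(a, b)`
short-circuit the easy cases. The test suite validates the condition
against a dense polygon oracle on hundreds of random pairs.

# Placement Monte Carlo

Reference ellipses are placed sequentially: uniform center, uniform
rotation, redrawn until free of overlap with previously placed reference
ellipses (rejection cap `max_tries = 1e5`, beyond which a packing-failure
error names the ellipse). Query ellipses follow the attraction scheme: a
draw overlapping any reference ellipse is accepted unconditionally; a
non-overlapping draw is accepted with probability `1/f`. With `f = 1` the
acceptance branch never rejects, so the random model is literally the same
code path. The scheme's stationary contact probability is
`p·f / (p·f + (1 − p))` where `p` is the uniform-draw overlap
probability; `overlap_probability_grid()` computes `p` by dense
enumeration for validation.

Open choices, fixed as follows: boxes are rectangles of the membrane
length × 2 × 500 nm (the analysis band); ellipse *centers* are constrained
to the box but the ellipse may protrude (the protocol is silent; the
center-in-box convention is the least informative one); query ellipses may
overlap one another (only reference–reference overlap is excluded by the
stated procedure); rotations are uniform on `[0°, 180°)`.
`reference_box_set()` provides a synthetic 11-box layout whose query
clusters sum to 118 — the structure of the original experimental
configuration, whose actual lengths and counts are not published.
`compare_distributions()` reports total-variation and chi-square
divergences without a p-value: model adequacy is judged by which candidate
lies closer, mirroring the visual comparison of histograms.

# Lattice random-walk binding

Geometry: 33 nm steps (estimated pore-to-pore channel spacing); the
footprint is the mean inter-cluster distance, 1,066 nm, giving
`nx = ny = round(1066/33) = 32` steps; height `nz = 16` steps so the far
boundary does not influence the surface; 44 channels on the z = 0 face;
2,127 ligates, which is exactly `round(c·N_A·V)` for c = 6 µM in the
`(32·33) × (32·33) × (16·33)` nm³ cuboid; 500 time steps. Moves are
6-neighbour (von Neumann — the stated "any adjacent position" is read as
the minimal lattice adjacency) with myopic reflecting boundaries:
off-lattice moves get zero weight and the rest renormalize. A move onto an
unbound channel site has its weight multiplied by the attraction factor. A
free ligate standing on an unbound channel site binds with `p_bind` per
step; a bound ligate unbinds with `p_unbind` and is displaced to a uniform
admissible neighbour. Updates are sequential in ligate order; all
randomness comes from R's RNG, so a seed fixes the trajectory.

**Site exclusion.** Whether two ligates may share a site is not specified
by the reference procedure. The engine implements both conventions behind
`walk_config(exclusion =)`. The default (`FALSE`) treats ligates as
volumeless — any number share a site, a bound channel site is passable
(weight 1, no attraction) and a channel still binds at most one ligate.
The strict variant (`TRUE`) allows at most one ligate, standing or bound,
per channel site and makes occupied channel sites impassable. The default
was chosen on mechanistic grounds: with strict exclusion a saturated
cluster walls itself off — a ligate released inside the patch cannot reach
the neighbouring channels whose sites are occupied — which suppresses
exactly the neighbour-rebinding pathway that distinguishes a clustered
from a distributed arrangement, and in our exploration it reverses the
direction of the arrangement effect. Without standing exclusion, a ligate
that unbinds next to other channels is immediately recaptured with
elevated probability, which is the physical rationale for clustering
aiding regulation; the acceptance suite verifies the resulting ordering
(clustered Kd below distributed Kd at calibrated parameters) by
simulation.

`estimate_kd()` averages the last 40% of the bound-count trace (the
equilibration window; configurable, with an optional stationarity warning
comparing the window halves) and reports
`Kd = [free ligate] · (free channels) / (bound channels)` with the free
ligate concentration computed over the cuboid volume and expressed in nM.
At exactly half occupancy this reduces to the free-ligand concentration —
a useful identity test. Zero bound channels across the window yields an
infinite-Kd flag rather than an error.

`calibrate_probabilities()` grids `(p_bind, p_unbind)`, averages Kd over
replicates per point, and flags points within a stated tolerance of the
target — by default 110 nM, the mean of the 88 nM (apo) and 132 nM
(Ca²⁺-bound) calmodulin anchors. `compare_arrangements()` then runs
paired replicates (common random numbers per repetition) for the clustered
and distributed layouts and applies a one-sided Wilcoxon signed-rank test.
The clustered layout packs the channels at 1-site pitch into the smallest
centered square (bounding box ≤ 7 × 7 sites for 44 channels); the
distributed layout spreads them on a uniform grid over the face (minimum
spacing ≥ 4 sites), dropping the grid sites farthest from the face center
when the grid has more sites than channels.

The exact-solution oracle in the test suite enumerates the full Markov
chain of a single ligate and a single channel on a 3 × 3 × 3 lattice
(28 states) with the same update rules and compares the engine's
stationary bound fraction and Kd against the stationary distribution.

# Particle averaging

Particles are 100 × 100 px (2 × 2 µm at 20 nm/px) two-channel boxes,
extracted around co-localized cluster pairs (edge-to-edge ≤ 0), zero-padded
and flagged when the box crosses the image edge. Alignment iterates
against the running average: per particle, an exhaustive rotation search
(grid 2°, then a local 0.5° refinement around the best grid angle — the
original schedule is unstated, so both are explicit parameters) with the
translation taken at the FFT cross-correlation peak; the score is the sum
of peak correlations normalized by the image norms. Iteration starts from
the unaligned stack mean and stops when the score change falls below
`tol` or `max_iter` is reached; an iteration that would lower the score is
discarded, which makes the reported score trace non-decreasing by
construction. The two-stage scheme aligns on the reference channel,
applies those poses to the secondary channel and refines on it, composing
the poses.

Rotation interpolation is nearest-neighbour by default (it preserves
binary images, matching the binarized experimental clusters); bilinear is
available and recommended for intensity images, where the smoother
correlation surface substantially improves rotation estimates. On the
bilinear path the correlation peak is refined to sub-pixel precision by
1D quadratic interpolation in each axis, since the true shifts are
continuous while the FFT correlation grid is integer.

**Frame degeneracy.** Reference-free alignment determines poses only up to
one rigid motion shared by all particles: the internal average frame need
not coincide with the frame ground-truth poses are expressed in.
`pose_recovery_errors()` estimates that common offset from the pose
differences and reports per-particle residuals after removing it; recovery
statements (shift within 1 px, rotation within 2°) and template
correlations are evaluated on these frame-corrected quantities. The
built-in template is an elongated multi-blob pattern: a near-isotropic
blob would make the rotation ill-posed for any algorithm.

# Surface topology

`amplification_factor()` triangulates each grid cell along a fixed
diagonal (two right triangles; the triangle over legs `s` with height
differences `dzb`, `dzc` has area `s/2 · sqrt(s² + dzb² + dzc²)`), sums
the 3D area over cells whose four corners are valid, and divides by their
planform area. The factor is ≥ 1, exactly 1 for flat maps, invariant to a
constant height offset, and the alternate-diagonal split is exposed as a
discretization cross-check (they agree to ≪ 1% on smooth surfaces). The
experimentally reported ~6.5× amplification of the plicate membrane
requires the undeposited segmented volume; the package covers the
computation with analytic benchmarks instead (a sinusoid of amplitude
`λ/2π` has amplification `≈ 1.216` by the arc-length integral).

`detect_peaks()` computes topographic prominence by the persistence
construction: sweeping the level down with union-find, a maximum's
prominence is its height minus the level at which its component merges
into one holding a higher maximum; the global maximum receives the full
height range. Defaults: minimum prominence 10% of the height range,
minimum separation two grid steps; ties in the separation filter resolve
toward the higher peak. `peak_spacing_stats()` gives per-peak
nearest-neighbour distances in 3D or after projecting out z.
`periodicity_spectrum()` renders the projected peaks as Gaussian spots,
takes the 2D power spectrum, averages power over radial frequency bins and
reports the interior local maximum with the highest power as the dominant
period; a pattern without an interior maximum (e.g. a single spot), or a
field shorter than two periods, is flagged.

# Ensemble current model

`channels_from_cluster_area()` divides the cluster area by the
per-channel site area (`s²` square, `√3/2·s²` hexagonal; s = 33 nm pore
spacing). `clusters_under_patch()` multiplies the flat patch area
`π(d/2)²` by the surface amplification and divides by the per-cluster
tile area. `predicted_patch_current()` is the product
`n_clusters · channels · g · V` with pS·mV → pA handling (10 pS × 60 mV =
0.6 pA per channel). Square packing is the default tiling — the simplest
consistent with a stated inter-cluster distance of ~1 µm — and both the
spacing and the packing are explicit because the rounded cluster count
under the patch (19 vs 20) depends on that unrecoverable convention; the
functions therefore report both unrounded and rounded counts.

# Problem sizes and reproducibility

Simulation-based checks in the test suite use deliberately scaled problem
sizes — e.g. 200 placement repetitions for the monotonicity scan, 100
model-recovery replicates on the 11-box layout, 30 calibration replicates
per grid point and 200 paired replicates for the arrangement comparison —
chosen to make each check statistically decisive while the full suite
stays comfortably interactive; `scripts/acceptance.R` runs the
arrangement comparison at the full 1,000-repetition protocol. Every
generator and simulation takes an integer seed, derives sub-streams
deterministically, and restores the caller's RNG state, so identical
seeds give byte-identical outputs.

# Known limitations

* Localization images are idealized (no blinking, drift or multiple
  localizations per fluorophore); detection performance on real SMLM
  reconstructions will depend on preprocessing not modelled here.
* The lattice binding model has no continuous-space diffusion, no
  reaction-rate theory and a single ligand species; its Kd should be read
  as a model readout calibrated to anchors, not a physical prediction.
* Circularity uses a boundary-pixel-count perimeter, adequate for
  separating compact from elongated clusters but not a precise shape
  statistic at small sizes.
* The edge-to-edge distance for parametric ellipses is polygonal
  (128 points); its error is far below a pixel at cluster scales but it is
  not closed-form exact.
* Pose recovery is meaningful only up to the common-frame degeneracy
  described above; reported recovery rates are frame-corrected.
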