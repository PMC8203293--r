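---
title: "Quantifying tumor mechanics and T-cell motility with mechanoscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tumor mechanics and T-cell motility with mechanoscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mechanoscape)
```

Solid tumors stiffen as they grow: lysyl-oxidase-mediated crosslinking
thickens, straightens and aligns collagen fibers, and the resulting dense
extracellular matrix correlates with poor T-cell infiltration and migration.
Studies of this mechano-immunological axis quantify the same tissue at several
scales — macroscale elastography stiffness maps, micron-scale collagen
architecture from second-harmonic generation (SHG) imaging, local elasticity
from AFM indentation, and T-cell behaviour from time-lapse imaging of fresh
tumor slices — and then correlate the per-animal summaries. `mechanoscape`
implements that quantification chain as composable, tested functions with a
seeded synthetic-data generator for every stage, so each estimator can be
validated against known ground truth.

All user-facing functions take plain data structures (matrices for images,
tidy data frames for tracks and study tables) and return tibbles, so results
chain with the pipe and drop directly into dplyr/ggplot2 workflows.

## Stiffness maps

A `stiffness_map` is a kPa grid with a pixel size (mm) and a tumor ROI mask
(supplied, as in practice, by manual contouring — the package does not
segment). `compute_roi_summary()` reports mean/min/max/SD over in-ROI pixels,
the ROI area, and the *stiff-area fraction*: the proportion of in-ROI pixels
strictly above a threshold, 40 kPa by default — the conventional cut-off for
"very stiff" tumor regions. The inequality is strict, so a pixel at exactly
40 kPa is not stiff; this choice is exercised by a dedicated boundary test.
Dropout pixels (`NaN` or negative sentinels from elastography penetration
limits) are excluded from every statistic and reported as a
`dropout_fraction`, rather than raising an error, so batch processing keeps
going on imperfect maps. The SD uses the sample (n−1) estimator.

`normalized_stiffness()` divides each timepoint by the baseline, and
`caliper_volume()` implements the xenograft ellipsoid approximation
`x * y^2 / 2` (longest times shortest-squared diameter over two).

Round-tripping maps through TIFF is constrained by the `tiff` writer, which
only stores samples in [0, 1]: `write_stiffness_map()` therefore quantises to
16 bits against a fixed 200 kPa full scale (0.003 kPa resolution, far below
elastography noise), while `read_stiffness_map()` reads third-party float32
kPa TIFFs as-is. CSV grids and JSON polygon ROIs (even-odd fill, pixel-centre
membership) are supported alongside.

## Fiber architecture

The collagen metrics are per-fiber: width, length, *curvature ratio*
(arc length over end-to-end chord, CR = A/B ≥ 1; 1 means perfectly linear)
and a per-image alignment statistic, the *orientation CV* (sample SD of
per-fiber angles divided by their mean; smaller means more aligned). The CV
deliberately uses raw angles in degrees, not circular statistics, matching
how the measure is reported in the field; it is frame-dependent, so a fixed
angular reference must be kept across images that are compared. Orientation
per fiber is the principal-axis angle of the path point cloud folded into
[0°, 180°).

`trace_fibers()` extracts the fibers themselves. Curvelet-based tracers are
standard here, but their parameters are rarely reported; this package uses a
fully specified, testable alternative:

1. Gaussian smoothing (default 0.5 µm) and Otsu thresholding over nonzero
   pixels; specks smaller than half the minimum fiber length are removed.
2. Zhang–Suen thinning to a skeleton. Parallel thinning leaves two-pixel
   staircases on diagonal bands, so a sequential simple-point pass collapses
   them; remaining unremovable zigzag pixels are handled downstream.
3. Branch pixels are removed, chains are ordered by walking from endpoints
   (ties broken by the straightest continuation), and chains are re-merged
   across junctions when their ends are near (≤ 12 px), anti-aligned
   (cos ≤ −0.25), and the gap runs over skeleton pixels — so two distinct
   fibers with nearby tips are never joined. When a component's chains cover
   far less centerline than its area/width implies (thinning can erode most
   of a band near 45°), the path is rebuilt geometrically by projecting the
   component's pixels onto their principal axis and taking the mean
   transverse position per longitudinal bin.
4. Width is twice the Euclidean distance transform sampled along the interior
   of the chain (ends, where the cap dominates, are trimmed), minus a
   quarter-pixel discretisation offset. Thinning retracts chain ends —
   strongly so near 45° — so each end is extended along its local tangent to
   the mask boundary minus the half-width cap before the arc length is taken.
5. Chains tracing the same structure twice (a closed double line left by
   thinning) are deduplicated by spatial overlap; fibers shorter than
   `min_length_um` (default 20 µm) are discarded.

On synthetic renders (5 fibers per 192 µm field, widths 3–8 µm, lengths
40–120 µm, Poisson noise) the tracer recovers counts exactly in almost all
fields, and width and length with ~1% median absolute relative error; this
is verified in the test suite and recomputed by `scripts/acceptance.R`.

Sirius-red quantification (`packed_fiber_fraction()`) classifies red-orange
birefringent pixels — thick, densely packed collagen — against tissue pixels.
The default rule works in HSV space (hue in [0°, 40°] ∪ [320°, 360°], value
above a darkness floor of 0.1 separating tissue from empty glass) because a
hue window is robust to white balance; a simple red-dominance mode
(R > G and R > B) is available for comparison. Crosslink autofluorescence
(PYD/DPD) is quantified as the background-subtracted mean inside an
SHG-positive mask (`shg_positive_mask()`, Otsu by default).

## AFM indentation

Force–indentation curves from a spherical probe follow the paraxial Hertz
model `F = (4/3) E/(1−ν²) √R δ^{3/2}`, valid for indentations small against
the bead radius; with a 4.5 µm bead and sub-micron indentations the exact
sphere correction is second order, so it is not applied. Poisson's ratio
defaults to 0.5 (incompressible tissue). Because force is linear in E, the
least-squares modulus has a closed form, `E = Σ F·g / Σ g²`; negative
solutions (possible at near-zero modulus under noise) are clipped to zero
with a warning. The default fit window is indentation in (0, R]. Curves whose
relative residual exceeds 0.5 are excluded from pooled summaries and counted.

Raw approach traces are converted by `estimate_contact_point()`: a linear
baseline fit removes drift, and the contact index maximises the ratio of
residual variance after the candidate split to variance before it. The
estimator is exercised on synthetic raw curves built by root-solving the
cantilever–Hertz force balance, and is invariant to baseline offset by
construction. Per-sample summaries pool all points across maps (typically
nine 64-point maps per sample) rather than averaging per-map means, and the
histogram uses 0.25 kPa bins.

## T-cell tracks

Track tables are tidy: one row per detection with `track_id`, `t_s`,
`x_um/y_um/z_um`, where z is depth below the slice cut surface. Two filters
reproduce standard slice-imaging practice: `depth_filter()` removes samples
down to 15 µm below the cut surface (cells there migrate artefactually), and
`duration_filter()` keeps tracks covering strictly more than 10% of the
recording. Both boundaries are exclusive — a track of exactly 10% duration or
a sample at exactly 15 µm is removed — matching the strict phrasing of the
rules they implement.

`motility_summary()` reports, per track: mean speed (3D path length over
duration, µm/min), net displacement (first to last position), and
straightness (displacement over path length; 1 for ballistic motion, 0 for a
closed loop). Statistics are 3D by default with a 2D projection mode for
planar trackers. Duration is `t_last − t_first`, robust to detection gaps.
`region_density()` divides label-wise cell counts by label areas (cells/mm²)
for stroma-versus-tumor-islet comparisons.

## Statistics and correlation

The comparison layer wraps the classical tests the field reports:
pooled-variance Student's t (Welch behind a flag), Mann–Whitney (exact for
tie-free samples of ≤ 8 per group, normal approximation with tie correction
otherwise), one-way ANOVA, and Kruskal–Wallis. ANOVA and Kruskal–Wallis are
exposed as independent omnibus tests; pairing them as omnibus + post-hoc is
statistically incoherent, so for pairwise follow-up the documented route is
`compare_two_groups()` per pair with Holm correction via `p.adjust()`. No
multiplicity correction is applied by default.

`stiffness_motility_fit()` regresses a motility statistic on mean tumor
stiffness across subjects (OLS with intercept), per treatment group or
pooled, reporting slope, intercept and Pearson r; two-subject groups are
fitted but flagged degenerate since r = ±1 by construction. `tidy()` and
`glance()` methods give broom-style access, `autoplot()` the scatter with
per-group lines.

## Synthetic data: what it emulates, and what it does not

Every generator is seeded and substreamed: one study seed fans out to
per-object streams via a fixed counter scheme (`seed · 48271 + counter ·
104729 mod 2³¹`), so adding one more object never perturbs earlier ones, and
identical seeds give bit-identical output.

- `gen_stiffness_map()`: Gaussian background (default 10 ± 3 kPa, clipped at
  0) with hard 60 kPa discs — the stiff (> 40 kPa) patches heterogeneous
  tumors show. The exact stiff fraction is returned as ground truth.
- `gen_fiber_image()`: anti-aliased sinusoidal fibers with uniform widths and
  lengths in stated ranges, optional axial alignment (normal dispersion of
  SD 1/√κ radians, the large-κ von Mises limit; uniform at κ = 0), 0.5 µm
  optical blur and Poisson shot noise. Placement is rejection sampling with a
  ≤ 10% pixel-overlap cap; the non-overlap mode additionally enforces a 2 px
  clearance so recovery experiments have junction-free ground truth.
- `gen_force_curve()`: the Hertz forward model on an even indentation grid
  with additive or multiplicative Gaussian force noise.
- `gen_tracks()`: a 3D persistent random walk at constant step length
  (speed × frame interval; defaults 3 µm/min, 30 s frames, 20 min
  recordings, matching reported T-cell regimes of roughly 2–4 µm/min) with
  per-step Gaussian turning about a random perpendicular axis and reflective
  boundaries; z is confined to the 15–80 µm imaging window.

These generators reproduce the geometric and statistical structure the
estimators depend on — not the physics. There is no polarisation-dependent
SHG response, no elastography reconstruction artefacts, no cell-shape or
detection noise in tracks, and fiber intensity is uniform. Passing recovery
tests therefore demonstrates correctness of the quantification chain, not
robustness to every artefact of real acquisitions.

Two generator/estimator interactions are worth knowing. A ballistic track
(`turning_sd_deg = 0`) has straightness exactly 1 only while it meets no
wall; reflections bend the path, so the ballistic-limit checks use an arena
wide enough that no reflection occurs. And fibers touching end-to-end can
merge into one traced fiber — the non-overlap clearance exists precisely to
keep ground truth unambiguous in validation renders.

## The end-to-end pipeline

`run_pipeline()` executes `simulate → quantify → correlate` from a single
config (`default_study_config()`): two arms of five subjects, the control arm
stiffer (16 kPa background, six stiff patches), with wider (5.4–9.4 µm,
mean 7.4) and straighter collagen fibers, stiffer AFM moduli (4 kPa vs
2.2 kPa) and slower T cells (2.5 vs 3.6 µm/min) than the treated arm —
mirroring the direction and magnitude of LOX-inhibition effects reported for
desmoplastic tumor models. Each subject yields one study-table row of scalar
summaries; the correlation stage then fits speed and displacement against
mean stiffness per group. Runs are deterministic given config and seed;
artifacts, ground truth and an md5 manifest are written when an output
directory is set. Problem sizes in the shipped config (288 px fiber fields,
30 tracks, 16 curves per subject) are chosen so a full two-arm study runs in
well under a minute while leaving every estimator enough data to be stable.

```{r, eval = FALSE}
run <- run_pipeline(default_study_config(seed = 1))
tidy(run$fits$speed)
autoplot(run$fits$speed)
```

## Numerical choices and limitations

- Coordinates are (row, col) = (y, x), 0-based at the user interface for
  pixel positions; fiber paths are in µm with x along columns.
- Otsu thresholds are computed over nonzero pixels; a constant image is a
  degenerate-threshold error, and binary images fall back to the midpoint cut.
- `orientation_cv()` errors when all fibers sit at exactly 0° (undefined CV)
  and directs the caller to rotate the reference frame.
- Curvature ratio errors on closed paths (zero chord).
- The Mann–Whitney exact/approximate switch is at n = 8 per group; with ties
  the approximation is used regardless, as exact enumeration is undefined.
- The tracer is 2D, per optical section; no 3D fiber reconstruction.
- Fiber width is reported per fiber (mean along the path), not per point;
  sub-resolution fibers (width ≲ 2 px) are floored at one pixel-pair width.
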