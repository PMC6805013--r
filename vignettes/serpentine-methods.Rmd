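---
title: "Methods: polarity, edge dynamics, bleb reversals, and the membrane Monte Carlo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polarity, edge dynamics, bleb reversals, and the membrane Monte Carlo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serpentine)
```

`serpentine` quantifies two complementary views of leading-edge biology in
motile cells — where a Rac-activity biosensor sits relative to the cell
body, and how membrane protrusions travel and reverse along the cell edge —
and pairs them with a physical model: a fluctuating, self-avoiding
triangulated vesicle carrying curved, mutually attractive, force-exerting
protein nodes. This vignette records the models, the parameters that
matter, the numerical choices, and what the synthetic-data tests do and do
not establish.

## Imaging model and segmentation

A movie is a named set of `H × W × T` intensity arrays with a pixel size
(µm) and frame interval (s); an optional camera dark frame is subtracted
(clamped at zero) before any intensity is used. Segmentation runs per
frame: Otsu's threshold on the (optionally Gaussian-smoothed) channel,
4-connected labelling, then inward erosion by `floor(erosion/pixel_size)`
pixels implemented as a Euclidean distance-transform cut. Otsu is computed
per frame, not pooled over the movie, because photobleaching drifts the
histogram; a frame whose histogram is degenerate (single-valued) segments
to empty rather than at an arbitrary cut. Erosion of "approximately 1 µm"
is fixed to the floor in pixels and exposed as a parameter.

The biosensor channel is segmented by seeded propagation
(`EBImage::propagate`, the CellProfiler secondary-object algorithm):
eroded cell bodies grow into the above-threshold biosensor region, with
contested pixels resolved by the smaller intensity-weighted geodesic cost
(regularization `lambda`, default 0.05). The propagation mask is
thresholded with a **three-class** Otsu by default (lower cut as the
foreground boundary): in a strongly polarized cell the biosensor histogram
has three modes — background, cytosolic body, and a small very bright
leading-edge focus — and the classical two-class criterion locks onto the
bright focus, throwing the cell body out of the mask. The two-class
threshold remains available (`threshold = "otsu"`).

Coordinates follow the 0-based (row, col) convention in all outputs;
physical coordinates are `index × pixel_size` with no half-pixel offset.

## Tracking, QC, and motility

Tracks are built by greedy nearest-centroid bipartite linking per frame
pair, gated at `max_step` µm (default 10; the linking gate is not dictated
by the measurement itself, so it is a visible parameter). Unlinked labels
start new tracks; a track that disappears ends — there is no gap closing.
Labelled regions that touch under 8-adjacency within a frame set a
collision flag on every track involved. QC removes tracks that (i) touch
the field border in any frame, (ii) never reach `min_max_displacement`
(default 5 µm) from their start within the observation window, or (iii)
carry any collision flag; per-rule removal counts are attached to the
result.

MSD is averaged over all start times within each track and then across
tracks, with a 95% t-interval across tracks; `MSD(0) = 0` by definition.
Instantaneous velocity is the per-step path length divided by the frame
interval (reported in µm/min); persistence is net displacement over path
length, undefined for zero path length.

## Polarity scores

Both scores act on a footprint (binary region) and an intensity image.

*Normalized distance.* `d` is the Euclidean distance between the
intensity-weighted centroid and the binary-footprint centroid; `L` is the
major-axis length (`4 sqrt(λ_max)`, with the 1/12 per-pixel variance
correction) of the ellipse with the same normalized second central moments
as the footprint; the score is `d/(0.5 L)`. `L` uses the **binary**
moments by default so the normalization does not depend on the signal
being scored; an intensity-weighted variant is exposed
(`weighted_L = TRUE`) because the source description is ambiguous on this
point. Scores are reported raw, without clamping at 1.

*Angular distribution.* The reference vector runs from the geometric
(unweighted) footprint centre to the weighted centroid; each pixel
contributes its intensity times the cosine of its angle to that reference,
normalized by total intensity. Two degenerate cases are fixed by
definition: if the weighted centroid coincides with the geometric centre
the reference direction does not exist and the score is 0 (an unpolarized
cell); a pixel exactly at the geometric centre has no direction and is
excluded from both sums (a measure-zero event off the exact grid centre).

The time-course driver applies both scores to every tracked cell at every
frame, flags frames listed in `omit_frames` (e.g. timepoints swamped by a
UV uncaging flash) and excludes them from the population summary, and
re-zeroes the time axis at the stimulus frame. Population summaries are
means with 95% t-intervals across cells.

## Boundary kymographs and cross-correlation

The cell outline is the half-level contour of the mask (marching squares),
lightly smoothed with a circular moving average (window 9 contour points,
roughly 4 px) to suppress the pixel-period staircase, fit with periodic
cubic splines, and resampled to `P = 1000` points evenly spaced in arc
length, oriented counter-clockwise. The index origin is canonicalized to
polar angle zero about the centroid so the parameterization does not
depend on where the contour tracer started. Consecutive frames are aligned
by the circular shift minimizing the summed squared point distance,
computed over all `P` shifts via FFT cross-correlation; ties break toward
the smaller absolute shift, then the negative one.

Edge velocity at boundary point `p` and frame `t` is the centred
difference `[SDT_{t+1}(p) − SDT_{t−1}(p)] / (2 Δt)`, with the signed
distance transform positive inside the mask, so outward motion is
positive. Two numerical details matter. First, the raw pixel distance
transform has no zero level — it jumps from +1 to −1 across the interface
— so the field is shifted half a pixel per side. Second, distances to
pixel centres carry up to half a pixel of anisotropy, which is large
against the ~2-pixel centred-difference signal; the magnitude of the SDT
is therefore measured to the sub-pixel spline contour of the neighbouring
frame (sign taken from the pixel field). With both corrections a disk
growing one pixel per frame reads back its front speed with a median error
under 3% and no point beyond 20%. The first and last frames of a velocity
map are `NaN`.

Edge fluorescence is bilinear interpolation of the dark-subtracted channel
at the aligned boundary points.

The lagged cross-correlation is defined as `r(k) = cor(vel[, t+k],
fluo[, t])` pooled over all valid (position, time) pairs, for integer `k`
in `[−max_offset, max_offset]`: a peak at negative `k` means the
fluorescence signal trails edge motion — shifting fluorescence back in
time aligns it with velocity. Per-cell curves are pooled as unweighted
means per offset with 95% t-intervals, and the pooled argmax is reported
in seconds. Whether correlations should pool all timepoints or use a
sliding window is genuinely open; the implementation pools all valid
entries.

## Travelling protrusions and the rotation null

Velocity maps are smoothed with a separable Gaussian (defaults 5 position
indices × 2 frames — the analysis is robust to this choice and both are
exposed), binarized at 0.15 µm/s, and labelled as 8-connected components
with periodic wrap in the position axis, so a band crossing the seam stays
one component. Each component's per-frame circular mean position is
unwrapped into a continuous trajectory; reversals are sign changes of
consecutive displacements, placed at the turning frame and position, with
zero displacement inheriting the previous direction so plateaus do not
chatter. Only components with at least 3 reversals contribute events.

Rac-zone edges come from the fluorescence map: smoothed, binarized with a
single Otsu threshold computed on the whole map (one threshold per map,
not per frame), and per-frame state changes along the periodic position
axis localized at the boundary between unlike neighbours. Each reversal is
scored by its circular distance to the nearest zone edge at its frame, as
percent of perimeter (at most 50%); the summary reports the median with
both SD and MAD, since summaries of this quantity appear in either form.
The null distribution repeats the measurement after rotating the zone by a
uniform random integer position offset (default 20 rotations, pooled);
integer offsets were chosen over continuous ones to keep the rotated edges
on the map's own grid.

## Synthetic data: what it emulates and what it does not

The movie generator renders a moving disk-shaped cell in two channels:
a body marker (filled disk) and a biosensor carrying camera background,
a cytosolic level, an unpolarized rim ring, and a von-Mises-shaped rim
focus whose amplitude is solved per frame so the noise-free
normalized-distance score of the rendered footprint **equals the requested
target exactly** (the focus width stays free, and maps monotonically onto
both scores). Motion models are stationary, straight, or Gaussian random
walk; a spec whose cell would come within one radius of the border is
rejected. Additive Gaussian noise and optional transient rim bumps
(protrusion events) complete the picture. The generator does not emulate
a PSF, shot noise, cytoskeletal texture, or 3-D cell bodies, so passing
round trips demonstrate the correctness of the measurement chain, not
robustness to real microscopy artefacts.

The kymograph generator plants a Gaussian band of edge velocity
(amplitude 0.3 µm/s, width 4% of perimeter by default) whose centre
drifts at constant speed and reverses at planned frames; the fluorescence
map is the smoothed band delayed by a known number of frames plus noise.
Ground truth carries the lag, the band trajectory, reversal times and
positions, and the per-frame band extent.

The mesh generator is described below. All generators take one explicit
seed and are bit-reproducible; no global RNG state leaks.

## Membrane Monte Carlo

*Model.* Lengths are in units of the hard-core bond minimum `l_min`,
energies in `kT0` (room temperature). A closed genus-0 triangulation with
`F = 2V − 4` faces carries the energy

\[ W = W_A + W_b + W_d + W_F \]

with stretching `W_A = (k_A/2) Σ (a_i/a_0 − 1)²` over faces
(`a_0 = √3 l_0²/4`, `l_0 = (l_min + l_max)/2`, `l_max = 1.7 l_min`);
bending `W_b = (κ/2) Σ A_i (2H_i − C0_i)²` over vertices, where `C0_i`
is `c0` on protein-occupied nodes and zero otherwise; protein binding
`W_d = −w · #{protein pairs within r_0}` (`r_0 = l_max`); and the active
term `W_F = −F Σ n̂_i·x_i` over protein nodes, evaluated as a state
function with normals recomputed for each proposed state. Defaults follow
the reference parameter point: `κ = 20`, `k_A = 1`, `w = 1`, `F = 1`,
`ρ = 0.11`, `T/T0 = 0.7`. The provided description does not fix `c0`
numerically; the package default is `c0 = 1/l_min`, chosen so a protein
node prefers a curvature radius of order the bond length — comparable to
the strongly curved rims it is meant to drive — and it is a visible
parameter everywhere.

*Discretization.* `H_i` is the cotangent Laplace–Beltrami mean curvature
with Meyer mixed-Voronoi vertex areas, signed positive for outward-normal
spheres. Barycentric one-third areas were tried first and reproduce the
closed-sphere limit in aggregate, but carry ~6% pointwise error at
valence-5/7 defects; the mixed areas bring every vertex of a relaxed
642-vertex sphere within 5% of `1/R` while still tiling the surface, so
`W_b → 8πκ` for a protein-free sphere independent of mesh density. The
bending sum is area-weighted for exactly this reason; the raw unweighted
sum is also returned (`W_b_raw`) for comparison.

*Moves and constraints.* One sweep makes `V` vertex-move attempts
(uniform cube displacements, half-width `δ = 0.1 l_min`, giving ~40–60%
acceptance at the default parameters), `E` bond-flip attempts, and one hop
attempt per protein, interleaved in random order. Hard constraints reject
outright: bond lengths must stay strictly inside `(l_min, l_max)`,
non-bonded vertices at least `l_min` apart (checked against a spatial hash
grid; explicit triangle–triangle intersection tests are omitted, which is
standard at this move scale), plate walls when confinement is on, and
flips that would create a duplicate edge or a vertex of degree < 3.
Everything else is Metropolis with `min[1, exp(−ΔE/kT)]`. The protein hop
(an occupancy swap with a random bonded neighbour) is not among the moves
the source scheme lists, but freely diffusing proteins need label
mobility; it carries a Hastings factor `deg(i)/deg(j)` because the
neighbour-pick proposal is asymmetric at mixed valence. Protein count is
conserved exactly by construction.

The energy breakdown is maintained incrementally (each accepted move adds
its locally recomputed difference) and can be recomputed from scratch at
any time; after hundreds of sweeps the two agree to better than 1e-6
relative, and `run_sweeps(debug = TRUE)` re-verifies topology, bond
window, self-avoidance, walls, and drift.

*Confinement.* Hard walls at `z = ±d/2`. The gap is reduced gradually
from the vesicle's current extent to the target over several
thermalization stages (rescaling z slightly ahead of each stage so the
current shape fits), because teleporting walls into a configuration would
reject every move.

*Observables and ensembles.* Tension is `σ = ⟨W_A/A⟩`; shape is
summarized by the gyration-tensor eigenvalues `λ1 ≥ λ2 ≥ λ3` and the
asphericity `A = [(λ1−λ2)² + (λ2−λ3)² + (λ3−λ1)²] / [2(λ1+λ2+λ3)²]`,
which is exactly 0/¼/1 for sphere/disk/rod. `sample_ensemble` draws
independent replicates (fresh protein assignment and seed each), with 200
states reproducing the full ensemble convention and smaller counts serving
as desk-scale presets. The test suite runs V between 162 and 642 with a
few hundred sweeps per replicate, and the confinement scan uses V = 600
with gaps 7 → 2 `l_min`; these sizes were chosen as the smallest at which
the physics checks (8πκ, quasi-sphere relaxation, monotone flattening
toward asphericity ¼) are unambiguous.

## Mesh construction

Meshes with an exact vertex count are built from the nearest icosahedral
subdivision level: a few longest-edge splits upward when the shortfall is
small (≤ 25% of the base), otherwise shortest-edge collapses downward
(collapsing a fine lattice scars it less than splitting a coarse one).
The result is relaxed on the sphere by alternating spherical-Delaunay
(convex-hull) edge flips with degree-normalized springs toward `l_0`,
stiffened near the hard window, with the sphere radius adapting to hold
the mean bond at `l_0`. Defect configurations that deterministic
relaxation cannot untangle fall back to simulated annealing: the Monte
Carlo engine in a soft-bond mode (harmonic bonds plus a radial spring
pinning vertices to the sphere, hard self-avoidance retained, and flips
forbidden from converting an under-length bond into a non-bonded pair),
cooled through five temperature stages, then lightly tidied. Construction
errors out with a diagnostic if the window cannot be satisfied — in
particular when a requested radius implies a mean bond length outside the
realizable band. The reference 3,127-vertex mesh (6,250 faces) builds in
well under a second; awkward counts that trigger annealing take seconds.

## Known limitations

- The polarity round trip carries a small positive bias at high targets
  (~0.04 at a target of 0.8): the propagated footprint clips a thin dim
  rim of the cell, shrinking `L` slightly. The bias is well inside the
  ±0.05 round-trip tolerance and vanishes at low polarity.
- Edge velocity inherits raster limits: isolated boundary points can read
  up to ~15% off on a one-pixel-per-frame front; smoothing in the
  downstream detectors absorbs this.
- The simulator has no volume constraint, no explicit contractility, and
  no hydrodynamics; tension is a purely elastic observable.
- Greedy linking is not globally optimal and does not close gaps; it is
  faithful to the measurement contract but not a general-purpose tracker.
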