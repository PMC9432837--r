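---
title: "Models and methods behind podomech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind podomech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

podomech analyses contractile sarcomere-like structures (SLSs) in cultured
kidney podocytes: periodic actomyosin assemblies with alternating myosin IIA
and synaptopodin/α-actinin 4 bands that appear in injured podocytes and
respond to substrate stiffness and actomyosin inhibition. The package covers
the four computational stages of such a study — synthetic ground-truth data,
sarcomeric spacing quantification, strain mapping from embedded microbeads,
and a finite-element model of an eigenstrain-contracting cell process — and
this vignette records the models, defaults and numerical choices behind each
stage.

Because no raw microscopy is distributed with studies of this kind, every
stage is validated by *parameter recovery* on synthetic data whose ground
truth is known exactly. That framing matters for interpreting the tests:
a passing recovery test shows the estimator is correct for data matching the
generator's assumptions, not that those assumptions capture every pathology
of real images.

## Synthetic striation images

`generate_striation_image()` renders a single striated fiber on a pixel
grid. The intensity model is separable around the fiber polyline:

* bands are Gaussian bumps along the fiber axis, centered at
  `s_k = (phase + k) * spacing`, with sd `band_width / 2.355` — i.e.
  `band_width` is a FWHM, mimicking a PSF-limited band rather than a square
  pulse and giving a well-defined, differentiable maximum for sub-pixel
  localization;
* the transverse falloff is Gaussian with sd `fiber_sigma` (default
  0.25 µm, the apparent half-width of a stress fiber at this magnification);
* each channel carries a phase offset as a fraction of the period; offset
  0.5 places one channel's bands midway between the other's, the alternating
  synaptopodin/myosin geometry;
* an isotropic Gaussian PSF (default sd 0.1 µm at 0.1 µm pixels) is applied
  by `EBImage::gblur`, then additive Gaussian noise of sd `noise_sd`.

Intensities are floats on a nominal [0, 1] scale internally and 16-bit on
TIFF export. Coordinates put the origin at the top-left corner, x rightward,
y downward, in µm. Spacing must exceed twice the pixel size (Nyquist), and
the polyline must stay inside the image.

The study conditions encoded in the defaults: sarcomeric spacings of 0.8 to
1.4 µm across substrate stiffnesses, 0.1 µm pixels (60x/100x confocal
imaging), fibers ≥ 6 µm. No noise statistics are reported for the original
images, so `noise_sd = 0.05` on a unit amplitude is a nominal choice held
fixed throughout the tests; it is high enough that naive argmax peak
picking would fail without the prominence rule below.

What the generator does *not* emulate: fiber crossings and curvature of real
SLS mats, photobleaching gradients, shot-noise scaling with intensity, and
3D defocus. Recovery results therefore certify the quantification pipeline,
not segmentation of crowded scenes (automated fiber tracing is deliberately
out of scope — lines are drawn by the analyst, as in the original workflow).

## Sarcomeric spacing quantification

`extract_profile()` samples channels by bilinear interpolation along the
polyline (default step: half a pixel) and averages across a perpendicular
width, reproducing the line-profile operation of interactive image analysis.
`detect_peaks()` then applies three rules:

1. *local maxima*: strictly greater than the left neighbor, at least equal
   to the right (so two-sample plateaus, which arise when the sampling grid
   aligns with pixel centers, yield one peak). End samples are not eligible
   peaks; a band centered exactly on the line's endpoint is rejected by the
   prominence rule, which is the conservative choice for spacing work since
   a truncated band has no measurable second flank.
2. *prominence* ≥ `min_prominence` (default 0.2) times the channel's
   intensity range. Topographic prominence — height above the higher of the
   two saddle minima toward higher terrain — makes detection invariant to
   adding a constant and to uniform rescaling of intensities.
3. *separation*: peaks closer than `min_separation` (default 0.4 µm) are
   pruned keeping the higher one. 0.4 µm sits safely below the smallest
   spacing regime of interest (0.8 µm) while suppressing noise doublets.

Each surviving peak is refined by a three-point parabolic fit, giving the
sub-pixel precision needed to resolve 0.2 µm spacing differences at 0.1 µm
pixels. The original analysis was interactive with no stated thresholds;
the defaults above are this package's choices and are exposed in every
signature.

`compute_spacings()` takes successive differences and applies the
eligibility rule for per-fiber averages: a fiber contributes a per-fiber
mean only if it is at least 6 µm long and has at least two peaks. Both
statistical conventions are kept side by side in `spacing_statistics()`
because both appear in practice: pooled spacings (n = number of spacings,
the histogram convention) and per-fiber means (n = number of fibers, the
convention for group comparisons). `alternation_index()` reports the
fraction of consecutive reference-channel intervals containing exactly one
peak of the other channel — 1.0 for a perfect sarcomeric register.

Recovery performance under the default conditions (30 fibers per group,
noise 0.05): group means within 5% of truth for 0.8 / 1.0 / 1.4 µm spacings
and correct ordering, as exercised by the test suite and the acceptance
script.

## Strain mapping from microbead displacements

Microbeads embedded in the hydrogel move as the cell's contraction is
released (actin depolymerization or lysis). `generate_bead_field()` scatters
beads uniformly and maps them through an analytic deformation (translation,
rotation, stretch, simple shear, radial contraction, or any composed or
imported field), storing the exact deformation gradient per bead.
Localization noise is modeled as isotropic Gaussian jitter on positions,
not on images — bead centroiding is treated as upstream plumbing.

The mapping algorithm is a *windowed weighted affine fit*: at each point of
a reference-frame grid (default 2 µm spacing), beads within
`window_radius` (default 5 µm) enter a weighted least-squares fit
`x_def ≈ F x_ref + t` with Gaussian weights of sd `window_radius / 2`.
This estimator was chosen for transparency: it is exact on affine fields
regardless of bead layout, its failure modes are explicit (fewer than
`min_neighbors = 4` beads, or a neighborhood whose weighted design is
rank-deficient — collinear beads — flags the point undefined rather than
extrapolating), and its bias under localization noise is measurable by
Monte Carlo (e1 bias below 0.005 on a 5% stretch with ~40 beads per
window and 0.05 µm noise).

From `F`, the Green-Lagrange tensor `E = (FᵀF − I)/2` and its first
principal value `e1` are reported. `E` is objective — superposing a rigid
motion on the deformed state leaves it unchanged — which the tests verify to
1e-10. The analysis is 2D ("in the adhesion plane"); out-of-plane bead
motion is ignored, a stated limitation. Fields are Lagrangian (sampled on
the reference grid). The sign convention fixes the pre-treatment
(contracted) frame as reference, so relaxation appears as positive strain.

`match_beads()` pairs frames by mutual nearest neighbors within `max_disp`,
never assigning a bead twice and reporting unmatched beads. This is valid
only when displacements stay below the typical inter-bead distance; for a
full release whose displacements exceed that, trajectories must be tracked
through intermediate frames (the bead-table format therefore stores matched
pairs, and the analysis script uses matching only on small increments).

## Eigenstrain finite-element model

The contracting cell process is modeled as half of a cylinder capped by a
quarter sphere, both of radius 4 µm, bonded to a 100 × 100 × 10 µm elastic
slab. Both bodies are isotropic linear elastic (cell: 1.0 kPa, Poisson 0.3;
substrate: 0.2–6.0 kPa or rigid, Poisson 0.3). Contractility is a
stress-free eigenstrain prescribed in the cell volume,
`level · (−10%, −8%, −2%)` along (x, y, z) with x the fiber direction;
the anisotropy follows the dominant contractility axis, which is why a
thermal-analogy isotropic contraction was rejected. The substrate base is
fixed, all other outer surfaces traction free, and the cell-substrate
interface is perfectly bonded (shared nodes; no cohesive or slip law).

Geometric and material linearity is a deliberate choice despite the 10%
contraction: it matches a linear-elastic treatment of prescribed
reference-configuration contraction, and it buys exact testable structure —
zero contraction gives the zero solution to machine precision, and every
output scales exactly with the contraction level, which stands in for
myosin inhibition (blebbistatin at 50% / 20% of full contractility).

Numerics:

* *Mesh.* A graded tensor-product hexahedral grid (spacing
  `radius / mesh_resolution` near the cell, geometric coarsening with ratio
  1.6 toward the slab edges) is split into five tetrahedra per hexahedron
  with alternating chirality, which keeps face diagonals of neighboring
  cells coincident (conforming) and — because the y grid is symmetric with
  an even cell count — makes the mesh exactly mirror symmetric in y.
  Elements are promoted to 10-node quadratic tetrahedra via shared edge
  midpoints. The cell volume is voxel-captured (hexahedra above z = 0 whose
  centroid falls inside the half-cylinder/quarter-sphere), trading a
  staircase lateral boundary for an exactly conforming interface at z = 0.
* *Element kernels.* Straight-sided quadratic tetrahedra with constant
  barycentric gradients and a 4-point degree-2 Gauss rule (exact for the
  stiffness integrand), assembled in compiled code; the eigenstrain load is
  `∫ Bᵀ C ε* dV` over cell elements.
* *Solver.* Sparse supernodal Cholesky (CHOLMOD via the Matrix package) on
  the free DOFs. Equilibrium is checked two ways: the relative residual on
  free DOFs (< 1e-10) and the net reaction on the fixed base, which must
  vanish because an eigenstrain is self-equilibrated.
* *Stress recovery.* Cauchy stress `C : (ε − ε*)` per element centroid;
  interface profiles average centroid values of interface-face cell
  elements to the interface nodes of the nearest grid column — standard
  nodal-averaged recovery.

Default `mesh_resolution = 4` (four quadratic elements across the radius,
roughly 17k elements) solves in seconds; convergence checks use
resolutions 3 vs 6, where the peak interfacial shear changes by under 1%.
This desk-scale meshing is deliberate: the qualitative predictions under
test (stress monotonicity in substrate modulus, peripheral shear
concentration, narrowing on soft substrates, linear scaling) are
convergence-trend-based rather than element-count-based.

Two geometric parameters are not published and are fixed here as
assumptions: the cell length (20 µm footprint — several radii, matching
the micropattern length scale) and the y-line position for the shear
profile (mid-length of the cylindrical portion, since only a picture
locates it). Both are exposed in the model configuration.

One symmetry clarification: along the y line, the shear component σ_zx is
*even* in y for this mirror-symmetric geometry (its extrema sit near the
two footprint edges with equal sign), while σ_zy is the component that is
odd in y. Both are returned by `interface_shear_profile()` and both
symmetries are asserted in the tests.

The rigid (glass) substrate is modeled by fixing the interface
displacements; emulating it with a 10⁴ kPa substrate reproduces the peak
interfacial shear to better than 1%, which bounds the modeling error of
the idealization.

## Scoring and statistics

Phenotype scoring uses the four frozen categories (SLSs central +
peripheral, peripheral only, loose striated pattern, no SLSs);
classification itself is manual or synthetic input — image-based automated
classification is out of scope. The synthetic population generator is a
seeded multinomial draw; its default probabilities put ~75% of cells in
SLS-containing classes, the regime reported for freshly reseeded primary
podocytes.

Cell length from a traced polyline is the path length; from a mask it is a
maximum-Feret-style diameter computed over pixel centers plus one pixel, a
convention chosen so a single pixel measures one pixel size and an
axis-aligned w × h rectangle measures ≈ √(w² + h²). Detachment series
enforce non-increasing attached counts and report detached fractions
`1 − attached/initial`.

Statistical comparisons are thin wrappers with no bespoke statistics:
one-way ANOVA with Tukey's multiple comparisons (sarcomeric spacing
between conditions) via `stats::aov` + `stats::TukeyHSD`, and two-way
ANOVA with Šídák-adjusted pairwise contrasts of the primary factor within
time points (detachment assays) via `stats::aov` + emmeans.

## Problem sizes used in the shipped analyses

The analysis scripts and acceptance checks run at: 30 fibers per condition
(two channels, 60 × 160 px at 0.1 µm), 1000 beads over a 50 × 50 µm domain
on a 2 µm grid, FEM sweeps at `mesh_resolution = 3` with the convergence
pair 3 vs 6, and phenotype populations of 10⁴ cells. These sizes make every
stage's recovery measurable while keeping a full run in minutes on a
laptop-class machine.

## Known limitations

* The spacing pipeline measures along analyst-supplied lines; it does not
  find fibers.
* Strain mapping is planar and Lagrangian; out-of-plane motion and stored
  strain energy are not computed.
* The FEM is geometrically and materially linear; finite-strain effects at
  10% contraction, viscoelasticity, stress-fiber remodeling dynamics and
  substrate curvature are outside the model.
* Mutual-nearest-neighbor matching degrades sharply once displacements
  approach the inter-bead spacing; use tracked pairs or incremental frames
  in that regime.
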