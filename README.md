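# podomech

Quantitative toolkit for the mechanobiology of **sarcomere-like structures
(SLSs)** in kidney podocytes — the periodic actomyosin assemblies, with
alternating myosin IIA and synaptopodin/α-actinin 4 bands, that appear in
injured podocytes and respond to substrate stiffness and actomyosin
inhibition. It is written for cell-mechanics labs that quantify striated
stress fibers from fluorescence images, measure substrate strain from
embedded microbeads, and model cell contractility on compliant substrates.

The package implements four connected analyses, each validated by parameter
recovery on seeded synthetic data (no raw microscopy is required):

1. **Synthetic data generators** — striated two-channel fiber images with
   known band centers, microbead clouds displaced by analytic deformation
   fields with known deformation gradients, and multinomial phenotype
   populations.
2. **Sarcomeric spacing quantification** — intensity profiles along traced
   fibers, prominence-based peak detection with parabolic sub-pixel
   refinement, spacing statistics in both conventions (pooled spacings and
   per-fiber means, the latter gated at a 6 µm minimum fiber length), and a
   two-channel alternation index.
3. **Strain mapping** — mutual-nearest-neighbor bead matching, windowed
   weighted affine fits of the deformation gradient *F* on a reference
   grid, and the Green–Lagrange tensor
   *E* = (*F*ᵀ*F* − *I*)/2 with its first principal value *e₁*
   (rotation-invariant; positive for extension measured from the contracted
   reference state).
4. **Eigenstrain finite-element model** — a cell process (half-cylinder
   capped by a quarter-sphere, radius 4 µm, cell modulus 1 kPa) bonded to an
   elastic slab (100 × 100 × 10 µm, modulus 0.2–6 kPa or rigid), contracting
   by a stress-free eigenstrain `level · (−10%, −8%, −2%)` along (x, y, z).
   Quadratic tetrahedra, sparse Cholesky, with interfacial shear profiles
   σ_zx(y), maximum principal Cauchy stress and cell-width change across
   stiffness/contractility sweeps.

Phenotype scoring (four frozen SLS categories), Feret-style cell length,
detachment-assay fractions, and ANOVA/Tukey/Šídák comparison wrappers round
out the workflow.

## Worked example

```r
library(podomech)

# 1. synthesize a striated fiber (1.0 um sarcomeric spacing, two channels)
fiber <- rbind(c(2, 3), c(14, 3))
spec <- striation_spec(spacing = 1.0, fiber_polyline = fiber,
                       noise_sd = 0.05, seed = 7)
img <- generate_striation_image(spec)
img
#> striation_image: 64 x 160 px (0.10 um/px), channels: synpo, myosin

# 2. recover the spacing from the synaptopodin channel
ss <- measure_fiber_spacing(img, fiber, channel = "synpo", step = 0.05)
round(ss$per_fiber_mean, 4)
#> [1] 0.9934

# 3. myosin bands alternate perfectly with synaptopodin bands
prof <- extract_profile(img, fiber, step = 0.05)
alternation_index(detect_peaks(prof, "synpo"), detect_peaks(prof, "myosin"))
#> [1] 1

# 4. strain map of a 5% radial contraction (1000 beads)
bf <- generate_bead_field(
  deformation_spec("radial_contraction", list(alpha = 0.05), c(0, 50, 0, 50)),
  density = 0.4, seed = 7)
pip <- strain_pipeline(bf, grid = 2, window_radius = 5)
round(pip$summary$mean_e1, 5)
#> [1] -0.04875

# 5. coarse FEM: soft vs stiff substrate at full contraction
sw <- stiffness_sweep(c(0.2, 6.0), levels = 1.0,
                      model = contraction_model(mesh_resolution = 3))
sw
#>   substrate_modulus_kPa contraction_level max_abs_sigma_zx_kPa
#> 1                   0.2                 1          0.004055049
#> 2                   6.0                 1          0.008433114
#>   max_principal_cauchy_kPa width_change_um
#> 1                0.1002953     -0.43361712
#> 2                0.1996426     -0.06163689
```

Reading the numbers: the recovered spacing (0.9934 µm) sits within 1% of
the 1.0 µm ground truth despite noise; the mean first principal
Green–Lagrange strain (−0.04875) equals the analytic value
((1 − 0.05)² − 1)/2 for a 5% radial contraction; and the sweep reproduces
the qualitative mechanics — interfacial shear and peak stress increase
with substrate stiffness while lateral narrowing (negative width change) is
strongest on the soft substrate.

## Analysis workflow

The `analysis/` directory holds numbered drivers that reproduce the study's
computational narrative, writing tables under `results/`:

| script | what it does |
| --- | --- |
| `01_simulate_images.R` | striated fiber sets for four substrate conditions |
| `02_spacing_quantification.R` | spacing statistics + ANOVA/Tukey between conditions |
| `03_strain_mapping.R` | contraction-release strain map + incremental bead matching |
| `04_fem_sweep.R` | stiffness/contractility sweeps, shear profiles, convergence |
| `05_scoring_stats.R` | phenotype scoring + detachment two-way ANOVA/Šídák |

Run them in order with `Rscript analysis/01_simulate_images.R` etc.

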