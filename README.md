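# poretex

Quantifying how endothelial cells arrange on porous culture membranes,
from fluorescence micrographs, without hand segmentation.

Transwell-style migration assays grow endothelial monolayers on a porous
membrane (track-etched polycarbonate with ~8 µm pores, or directly drilled
membranes with 25 µm pores on a regular lattice). Whether and how the pore
pattern perturbs the monolayer shows up not in cell counts alone but in the
*texture* of the actin cytoskeleton: its dominant orientations, the
coherence of local alignment, and where the strongest image gradients sit
relative to the pores. `poretex` implements that quantification pipeline
for R, together with a ground-truthed synthetic scene generator so every
stage is testable without any microscope data.

## What it computes

**Structure tensor with a Riesz-filter gradient.** For a grey-level image
*I*, the per-pixel tensor J = W ∗ (∇I ∇Iᵀ) (Gaussian window W, Riesz
transfer −i·(u,v)/‖(u,v)‖ in the frequency domain) yields three maps:

- orientation θ = ½·atan2(2 J₁₂, J₁₁ − J₂₂) + 90° folded to [−90°, 90°) —
  the local filament axis;
- energy E = tr J ≥ 0 — the magnitude of local gradient activity;
- coherency C = √((J₁₁ − J₂₂)² + 4 J₁₂²) / tr J ∈ [0, 1] — 1 for strongly
  elongated structure, 0 for local isotropy (flagged undefined where
  E ≈ 0).

Plus a hue–saturation–brightness composite (hue = orientation,
saturation = coherency, brightness = source image).

**Monogenic signal.** The 3-vector (I_bp, Re RI, Im RI) of an isotropically
band-passed image and its Riesz pair gives local amplitude (contrast
invariant to the carrier phase), local orientation, and local phase, which
classifies contours: phase ≈ 0 bright lines, ≈ ±π edges/dark lines, ±π/2
edges.

**GLCM texture + PCA.** 23 co-occurrence descriptors per matrix at
θ ∈ {0°, 45°, 90°} and d ∈ {0, 2}, z-scored (mean 0, variance 1) and
projected on principal components, with box-plot summaries.

**Nuclei statistics.** A classical segmenter (background opening, Otsu,
distance-transform watershed, calibrated per-object contour) reports
N_obj, per-nucleus areas (µm²) and percentage coverage over fixed-size
ROIs sampled to avoid pores.

**Polar anisotropy statistic.** Orientations of the top-5 % *energy*
pixels ("white features" of the energy map), binned into π-periodic polar
histograms with axial circular summaries (doubled-angle mean, resultant
length), ROI restriction, display scaling (e.g. ×10 for a low-signal ROI
curve), and a seeded permutation test for equality of two orientation
distributions.

**Pattern design calculators.** Pore-lattice coordinates and fractional
porosity π(d/2)²/(p_x·p_y); proton fluence → ion areal density
(pC/mm² / elementary charge).

**Synthetic scenes.** Actin-like fiber fields with axial von Mises
orientation statistics (µ, κ), optional multi-domain partitions, nuclei
blob fields with known counts/areas/clustering, and pore patterns
(regular lattices or random track-etch style) with depletion halos — all
with exact ground truth.

## Worked example

```r
library(poretex)

# a synthetic actin field aligned at 30 degrees
cfg   <- scene_config(256, 256, pixel_size_um = 0.5, seed = 42)
spec  <- filament_texture_spec(mu_deg = 30, kappa = 50,
                               spatial_period_um = 10,
                               n_filaments = 120, length_factor = 40)
scene <- make_filament_texture(cfg, spec)

tf <- tensor_analysis(scene$image, window_sigma_px = 2)
tf
#> <tensor_field> 256 x 256 px, window sigma 2 px
#>   energy max 31.53, median coherency 0.997 (defined pixels)

im <- interior_mask(tf)
circular_summary(tf$orientation_deg[im], tf$energy[im])
#> <circular_summary> mean 31.18 deg, resultant length 0.962, variance 0.038 (n = 61504)
```

The energy-weighted circular mean recovers the generating orientation
(31.2° vs the nominal 30°; κ = 50 puts an ~8° spread on individual
fibers), and the resultant length 0.96 says the field is strongly aligned.
The high-energy polar statistic agrees:

```r
mask <- high_energy_mask(tf, quantile = 0.95)   # top-5% energy "white features"
h <- orientation_polar(tf, mask = mask, weighting = "none")
histogram_mode_deg(h, smooth_bins = 2)
#> [1] 31.25

porosity(pore_lattice(25, 100))        # 25 um pores, 100 um pitch
#> [1] 0.0491
fluence_to_ion_density(122293)         # pC/mm^2 -> ions/mm^2
#> [1] 7.633e+11
```

## Analysis workflow

The `analysis/` scripts run the full comparative study on synthetic
substrates (uniform coverslip-like field, random-pore track-etched
membrane, 25 µm drilled lattice), writing tables and maps under
`results/`:

```sh
Rscript analysis/01_design_membrane.R    # lattice porosity, dose conversions
Rscript analysis/02_simulate_scenes.R    # the three ground-truthed substrates
Rscript analysis/03_orientation_maps.R   # orientation/energy/coherency + HSB
Rscript analysis/04_monogenic.R          # amplitude/phase/orientation maps
Rscript analysis/05_nuclei_stats.R       # N_obj, coverage, area histograms
Rscript analysis/06_texture_pca.R        # 23 GLCM descriptors, box plots, PCA
Rscript analysis/07_polar_anisotropy.R   # polar statistic, ROI contrast, tests
```

`run_pipeline()` performs the same orchestration programmatically on any
named list of scenes.

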