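---
title: "Methods: quantifying cell arrangement on porous membranes"
author: "poretex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying cell arrangement on porous membranes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poretex)
```

# The problem

Endothelial monolayers grown on porous membranes reorganize their actin
cytoskeleton in response to the substrate: on rigid continuous supports
the fibers align over long ranges, while porous, flexible membranes break
that order into local domains and concentrate remodeling near pores.
These effects are visible in phalloidin-stained fluorescence images but
resist classical segmentation — individual fibers cannot be delineated
reliably. `poretex` therefore quantifies the *field* properties of the
image: local orientation and its dispersion, local anisotropy, texture
statistics, and the spatial relationship between high-gradient features
and the pore pattern.

All angles in the package are *orientations* (axial data): theta and
theta + 180 degrees are the same physical structure. Circular statistics
are computed on doubled angles and folded back, and every orientation is
reported in degrees in [-90, 90), counterclockwise-positive with 0 at the
image horizontal.

# Structure-tensor orientation analysis

The gradient is computed with the Riesz filter pair, applied in the
frequency domain with transfer functions -i u/||(u,v)|| and
-i v/||(u,v)|| and zero DC response. Unlike finite differences, the Riesz
operator is an all-pass quadrature filter: translation-, rotation- and
scale-invariant, and it does not amplify high frequencies, which matters
on noisy fluorescence data. A finite-difference path is retained behind
`method = "finite_diff"` purely as a cross-check.

Per pixel, the tensor components jxx, jxy, jyy are the gradient products
smoothed with a normalized Gaussian window (default
`window_sigma_px = 2`, an OrientationJ-like local scale; the window is a
free parameter of the method and is always recorded with the result).
From them:

* **energy** E = jxx + jyy (trace of the tensor), the local gradient
  activity;
* **coherency** C = sqrt((jxx - jyy)^2 + 4 jxy^2) / E in [0, 1], 1 for a
  single dominant orientation, 0 for isotropy;
* **orientation**: the tensor's *major* eigenvector is the gradient
  (normal) axis; the structure axis along the filaments is perpendicular
  to it, so the package reports
  1/2 atan2(2 jxy, jxx - jyy) + 90 degrees, folded to [-90, 90). On a
  grating generated at 30 degrees the median interior orientation is
  30 +/- 0.01 degrees, which pins the convention.

Numerical choices: coherency is flagged `NA` where
E <= 1e-12 x max(E) (constant regions have no orientation); tensor
smoothing uses symmetric (mirror) boundary padding; the Riesz transform
itself is evaluated on a mirror-padded frame (pad up to 64 px) because
the operator has global support and the wrap-around discontinuity of a
periodic FFT otherwise biases orientations near -- and, through the 1/r^2
kernel tail, away from -- the border. Nyquist rows/columns of the odd
transfer are zeroed so the inverse transform is exactly real and
90-degree rotation covariance holds to machine precision. Summary
statistics exclude a boundary margin (2 sigma by default via
`interior_mask()`; recovery experiments use a wider 16 px margin because
the mirror extension reflects a fiber at mu into one at -mu, which
contaminates a band on the order of the texture period, not of the
window).

# Monogenic signal

At a single scale the monogenic signal is (I_bp, Re RI, Im RI): an
isotropic band-pass of the input and its Riesz transform pair. The
band-pass is a log-Gabor filter with two-octave bandwidth
(sigma_on_f = 0.55) centred at `scale_px` (default 8 px); a single
declared band-pass keeps the local phase model well defined, and the
scale is a required, logged parameter. Derived maps:

* amplitude = sqrt(I_bp^2 + Re^2 + Im^2), invariant to the carrier phase
  of the structure (verified to 0.03 % on quarter-period-shifted
  gratings);
* orientation = atan2(Im, Re) + 90 degrees folded — again the structure
  axis, consistent with the tensor convention;
* phase = atan2(sqrt(Re^2 + Im^2), I_bp), signed by the dominant Riesz
  direction: 0 marks bright lines (ridges), +/-pi dark lines, +/-pi/2
  edges.

A discrete step edge lies *between* two pixel columns; the phase sampled
half a pixel off the locus differs from pi/2 by about 2 pi x 0.5/scale.
Validation fixtures therefore centre the edge on a pixel (a half-intensity
column), where the measured phase is pi/2 to 5e-6 rad. The raw amplitude
map is typically very low contrast; `enhance_modulus()` provides the
percentile-clipped (0.5-99.5 %) gamma display copy (gamma = 0.5), an
order-preserving transform used for display only.

# GLCM texture and PCA

Images are quantized into 32 equal-width grey levels by default (the
level count is a logged parameter). Co-occurrence matrices are computed
at theta in {0, 45, 90} degrees and distances d in {0, 2} pixels
(offsets (0,+d), (-d,+d), (-d,0) in row/column convention), symmetrized
and normalized. d = 0 is the degenerate self-pairing matrix (diagonal,
trace = pixel count); it is implemented literally and its descriptors
reduce to grey-histogram functionals — retained because texture protocols
sometimes list it alongside positive distances.

Twenty-three descriptors are emitted per matrix in a frozen order
(`glcm_descriptor_names()`): Haralick's fourteen (angular second moment,
contrast, correlation, variance, inverse difference moment, sum average,
sum variance, sum entropy, entropy, difference variance, difference
entropy, two information measures of correlation, maximal correlation
coefficient) plus nine later extensions (autocorrelation, dissimilarity,
cluster shade, cluster prominence, maximum probability, inverse
difference, its two normalized variants, and the intensity second
moment). The exact membership of a 23-descriptor panel varies across the
literature; the count, the order and the definitions used here are the
package's contract, each verified against an independent brute-force
implementation to 1e-10. Conventions: natural logarithms with
0 log 0 = 0; sum variance is taken about the sum average; zero marginal
variance yields correlation 0.

Standardization is the z-score with the *population* variance convention
(denominator n), so a two-row column {1, 3} maps to {-1, +1}; constant
columns map to 0 with a warning. PCA is the eigen-decomposition of the
covariance of the standardized table (via `prcomp`), reporting scores,
loadings and percentage variance. Box-plot summaries use type-7
(linearly interpolated) quantiles and the 1.5 IQR outlier rule, stated
explicitly because whisker semantics depend on them.

# Nuclei statistics

A classical pipeline replaces learned detectors while honouring the same
output contract (label mask, N_obj, per-object areas in um^2, coverage
percentage): morphological opening with a disc of 5x the expected
nucleus radius subtracts background; Gaussian smoothing
(0.25x expected radius) suppresses noise; Otsu's threshold on the
smoothed foreground detects blobs; a distance-transform watershed splits
touching nuclei; objects outside [20, 500] um^2 are discarded (set the
filter to the expected size range of the preparation — validation scenes
with 2.5 um nuclei use a 10 um^2 floor). Otsu's cut systematically
dilates soft-edged blobs, so each object is finally cut at
`contour_fraction` (default 0.6) of its own smoothed peak; the value is
calibrated on the generator's blob profile so that the segmented
footprint matches the nominal-radius disc, and being relative per object
it leaves coverage invariant under intensity rescaling. On 50 seeded
scenes with 10-200 non-overlapping nuclei at SNR 5 the count accuracy is
100 % and coverage deviates from ground truth by < 0.1 percentage point.

ROIs for coverage statistics are axis-aligned squares sampled with a
seeded rejection loop that avoids an exclusion mask (the pore mask), the
practice of placing statistics windows over pore-free regions.

# The polar anisotropy statistic

The pipeline's distinctive summary asks not "how are image pixels
oriented?" but "how are the strongest anisotropy *features* oriented?".
`high_energy_mask()` selects the white features of the energy map —
by default the top-5 % energy quantile (Otsu available). "White" is not a
quantified notion in visual practice; the quantile is the single most
consequential free parameter of the statistic, so the method and
threshold value are always stored with the mask. `orientation_polar()`
then bins orientations over the selected pixels into 72 bins of
2.5 degrees (matching smooth polar curves), optionally energy-weighted
(the default for whole-image distributions; feature distributions are
unweighted by default — both weightings are available because published
polar plots rarely state which was used), with wrap-aware binning and a
duplicated [90, 270) display view for closed polar rendering.
`scale_for_display()` multiplies a low-signal ROI curve (e.g. x10) for
visual comparability without touching the normalized view or the
circular summary.

Two numerical points deserve note. First, the 2.5-degree bins are finer
than the orientation spread of realistic textures (kappa = 50 on doubled
angles is ~8 degrees of spread), so the raw argmax bin jitters between
near-equal neighbours; `histogram_mode_deg(h, smooth_bins)` reads the
peak off a circular moving average instead, the way one reads the peak of
a smooth polar curve. Second, round orientations (0, 45, 90 degrees) fall
exactly on bin *edges*, so the admissible mode bins around such a mu
extend to 1.5 bin widths (3.75 degrees) from it; validation asserts mode
recovery at that geometric limit.

`compare_histograms()` reports the axial circular-mean difference and a
permutation p-value for equality of two orientation distributions. The
permutation operates on doubled-angle unit vectors of the retained
per-pixel samples (each histogram keeps up to 20,000 deterministically
subsampled angles for exactly this purpose), shuffling group labels with
a seeded generator. Under the null the p-values are approximately
uniform; adjacent-pixel correlation within one image makes the test
anti-conservative for pixel-level inputs, so cross-scene comparisons are
the intended use.

# Pattern design calculators

For cylindrical through-pores the fractional volume equals the
fractional area, so lattice porosity is pi (d/2)^2 / (pitch_x pitch_y)
(4.909 % for 25 um pores at 100 um pitch). `porosity_raster()` provides
the independent numerical cross-check: stratified Monte-Carlo pixel
counting over one unit cell at 0.25 um sampling, averaged over 16 seeded
sub-pixel grid offsets. The jitter ensemble is part of the estimator's
definition: a single deterministic grid at that pitch carries a
lattice-point counting error of the same order as the 0.1 % agreement
the cross-check targets, while the jittered average is unbiased with
standard error well below it. Fluence converts to ion areal density
through the elementary charge (singly charged protons):
122,293 pC/mm^2 -> 7.63e11 ions/mm^2.

# The synthetic scene generator

Every stage is validated against scenes with exact ground truth, because
no reference micrographs ship with the package.

**Fiber fields.** Filaments are anti-aliased line segments with a
Gaussian cross profile (sigma = period/5), rendered at orientations drawn
from an axial von Mises distribution (Best-Fisher sampler on doubled
angles; kappa = 0 is isotropic, kappa -> infinity degenerate at mu).
Default segment length is 3 spatial periods; `length_factor` raises it.
Ground truth records the per-pixel orientation of the locally dominant
filament and the exact sampled angles. An optional `saturate` flag
applies 1 - exp(-I), the soft analogue of camera clipping in bright
confluent layers. Domain partitions assign each rectangle its own
(mu, kappa); rendering is clipped to the domain so partitions stay exact.

Three generator behaviours shape what validation can claim:

* *Short segments carry isotropic end caps.* With 3-period stubs, a large
  fraction of pixels lie near segment ends whose local structure is
  genuinely isotropic-to-perpendicular; the texture's true energy-weighted
  mean orientation is then not mu, by construction of the image, not by
  analysis error. Orientation-recovery experiments therefore use
  frame-spanning fibers (`length_factor` 30-40) — the realistic analogue
  of long stress fibers — for which mu is the exact ground truth; the
  recovery is then within ~1 degree with median coherency > 0.99.
* *Dense mats lose measurable anisotropy.* Above roughly 2-3x cumulative
  coverage, crossing fibers merge into an interference texture whose
  local orientations decorrelate from the generating distribution — a
  real phenomenon in confluent layers, and the reason recovery scenes use
  moderate fiber counts.
* *Saturation protects geometric statistics.* In pore scenes, rare bright
  fiber-overlap clusters can otherwise out-compete the pore-rim edges for
  the top-5 % energy mask, making the rim statistic hostage to texture
  luck; with `saturate = TRUE` the rim enrichment is a stable 5-50x.

**Nuclei fields.** Soft-edged discs (logistic edge, width 0.12 r) placed
by bounded dart throwing with a minimum separation; `clustering` in
[0, 1] interpolates towards aggregation around earlier nuclei. The label
mask paints exact nominal-radius discs.

**Pore scenes.** Lattice pores come from the design calculator's
coordinates; random track-etch pores follow a Boolean (Poisson disc)
model whose intensity is -log(1 - p)/(pi r^2), with centers sampled in a
frame extended by one radius, so the expected covered fraction equals
the requested porosity exactly (a naive density p/(pi r^2) undershoots
through overlap and edge clipping). The fiber texture is multiplied to
1 % inside pores and ramps linearly across an optional depletion halo.

What passing these tests does *not* show: the generator has no optics
(no point-spread function, no depth effects), fibers are straight
segments rather than curved bundles, nuclei are convex blobs without
texture, and noise is pixel-independent. Results on real micrographs
will additionally depend on illumination flatness, focus, and staining
variability; the pipeline's parameters that absorb those effects (tensor
window, monogenic scale, quantization levels, energy quantile, area
filter) are exactly the ones logged with every result.

# Problem sizes and determinism

Validation uses frames of 128-600 px (64-300 um at 0.5 um/px): large
enough that every scene holds hundreds of fibers or up to 200 nuclei and
a 3 x 3 pore lattice, while a full test run stays in minutes on one
core. Scene generation is bit-reproducible from (seed, spec); the
generators snapshot and restore the caller's RNG state. The acceptance
script derives every stage seed from its single `--seed` argument, and
`run_pipeline()` writes its JSON report without timestamps so identical
configurations produce byte-identical reports.

# Known limitations

* The structure-tensor window and monogenic scale are single-scale; no
  pyramid is provided.
* The permutation test treats pixels as exchangeable units; for
  within-image comparisons the effective sample size is far smaller than
  the pixel count.
* d = 0 co-occurrence is degenerate (kept for protocol compatibility);
  its descriptors carry no spatial information.
* The maximal correlation coefficient is numerically delicate on sparse
  matrices; levels with zero marginal probability are dropped before the
  eigen-problem, and the descriptor is 0 when fewer than two levels
  remain.
* Float TIFF maps are stored min-max rescaled with a `.range` sidecar
  (the TIFF writer clamps samples to [0, 1]); integer TIFFs round-trip
  exactly.
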