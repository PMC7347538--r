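---
title: "Quantifying cluster ion channel density from fluorescence images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cluster ion channel density from fluorescence images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Voltage-gated potassium (Kv) channels are recruited into membrane clusters
by scaffold proteins such as PSD-95, through an intrinsically disordered
C-terminal "chain" ending in a PDZ-binding motif. How densely channels
pack inside a cluster — the *cluster ion channel density* — is the
quantity of interest: it shapes the local ionic current and is a candidate
point of physiological regulation. In a confocal image of a fixed cell's
basal membrane, channel density within a cluster is proxied by *cluster
signal intensity*: the background-corrected integrated fluorescence of the
cluster (IFSc) divided by the cluster area (IFSc/µm²).

`kvclust` implements the full quantification chain on single-channel 2D
images with a physical pixel size:

1. **Cell delineation** (`segmentCell`): the largest 8-connected component
   above an automatic global threshold, morphologically closed and
   hole-filled. The threshold maximizes Otsu's between-class variance on
   the log-intensity histogram (512 bins; the first maximum is taken, so
   the split is deterministic). Total in-mask fluorescence is the cell's
   IFS.
2. **Spot detection** (`detectSpots`): the image is scanned with a square
   box at stride 1; the box maximum is accepted when it is the maximum of
   the box centred on it and exceeds the mean of the four box-corner
   pixels by more than a noise tolerance. Equal-valued plateaus are
   represented by their top-left pixel, accepted maxima within half a box
   (Chebyshev) of a stronger one are suppressed, and — when a cell mask is
   supplied — the centre and all four corner samples must lie inside the
   cell.
3. **Cluster segmentation** (`segmentClusters`): each accepted spot grows
   into the 8-connected region of pixels above `threshold_fraction` of the
   peak's prominence (default: half-maximum), restricted to the seed's
   nearest-seed (Voronoi) cell, which splits merged regions along seed
   bisectors. IFSc is the region's raw integrated signal minus the global
   background estimate times the pixel count, clipped at zero.
4. **Metrics** (`cellMetrics`, `summarizeVariant`): per cell, the four
   clustering attributes — normalized expression (IFS/area), clusters per
   area, fraction of signal in clusters (ΣIFSc/IFS), and the per-cluster
   intensities; per variant, means with standard errors, with cluster
   intensity pooled over the cluster population (the sampling unit for
   density statistics is the cluster, with hundreds to thousands per
   cohort, not the cell).
5. **Statistics** (`anovaOneway`, `gammaGlmLogLink`,
   `affinityDensityRegression`, `bellCurveArgmax`): one-way ANOVA across
   variants; a gamma GLM with log link on the strictly positive,
   right-skewed cluster densities, tested with a Wald χ² over the group
   contrasts (covariance scaled by the Pearson χ²/df dispersion from the
   final IRLS step); ordinary least squares of mean cluster intensity on
   PSD-95 binding energy over long-chain variants; and the chain length at
   the density maximum.

The packaged table `kvPresets()` carries the ten Shaker channel
chain-length variants (9–144 amino acids, including a reversed-sequence
144 control) with their measured clustering attributes and binding
energies; it drives both the synthetic generator and the deterministic
statistical recomputations.

## The synthetic scene generator

No raw images ship with the study this methodology reproduces, so the
package carries a first-class scene generator (`generateCell`,
`generateCohort`) whose output has complete ground truth. A scene is:

- a cell footprint: a low-order Fourier perturbation of a circle
  (harmonics 2–4, relative amplitude ≤ 0.1), area drawn uniformly from
  500–1,500 µm²;
- a diffuse in-cell signal with a mild linear illumination tilt (±2% by
  default — the residual flat-field error of a corrected instrument;
  larger tilts would be corrected upstream in any quantitative workflow);
- Gaussian clusters truncated at 2σ, placed with a minimum
  centre-to-centre separation of 1.1× the summed half-maximum radii and a
  full margin to the cell border;
- a Gaussian point-spread function of 150 nm full width at half maximum
  (Nyquist-sampled at 0.05 µm/pixel), then Poisson shot noise on the
  expected counts plus additive Gaussian read noise (0.2% of the 16-bit
  dynamic range — photon-counting confocal detection is shot-noise
  limited), written on a per-cell gain that puts the brightest expected
  pixel at 80% of the dynamic range (saturation never occurs by
  construction; the gain is recorded so analyses can report on the photon
  scale).

### Calibration in the operational convention

The measured quantities of this methodology are *operational*: a cluster's
"signal" is what half-maximum segmentation reports — the
background-corrected flux inside the half-maximum footprint of the
*blurred* profile — and its "intensity" is that signal over the footprint
area. The generator is calibrated in exactly this convention, because the
preset values it must reproduce are themselves products of that
convention. For a Gaussian cluster of intrinsic width σ, blurred width
σ′ = √(σ² + σ_psf²), the half-maximum footprint has area
*a* = 2π ln2 σ′² and contains half the total flux, so planting intensity
*I* requires peak amplitude 2 ln2 · *I* · σ′²/σ². Ground truth records
both this operational signal (used by the fraction-in-clusters
bookkeeping) and the total rendered flux (used by the exact conservation
identity diffuse + Σflux = total in-mask expected signal).

### One consistency relation instead of four free dials

A cell's summed in-cluster signal equals both `fraction × IFS` and
`n_clusters × intensity × mean_area`, so the four published attributes of
a variant jointly imply its mean operational cluster area:

  mean area = fraction × expression / (clusters_per_area × intensity).

Across the ten presets this gives 0.15–0.49 µm² (blurred Gaussian widths
σ′ of 0.17–0.34 µm — comfortably above the diffraction limit and
consistent with the sub-micron puncta visible in such data). The generator
derives cluster size from this relation; the diffuse level then follows
from the fraction, and the normalized expression level is matched *in
expectation* with no further freedom. Per-cluster areas get a log-normal
CV of 0.2, per-cluster intensities a gamma distribution (shape 8, giving
the right-skewed, approximately gamma density distributions the
statistical model assumes), and each cell carries independent log-normal
factors (CV 0.2) on cluster count and on intensity. The count and
intensity factors are independent rather than shared: the pooled
(cluster-weighted) mean intensity of a cohort is then unbiased, whereas a
shared factor would inflate it by E[L²]/E[L] ≈ 4%.

## Detection and segmentation defaults

All defaults live in `defaultConfig()` and are plain numbers a user can
override; the rationale for each:

| parameter | default | why |
|---|---|---|
| `pixel_size` | 0.05 µm/px | Nyquist sampling for ~150 nm lateral resolution |
| `box_size` (pipeline) | 13 px | the box must span the whole spot: preset-implied cluster FWHM is 8–16 px; a smaller box leaves the cluster shoulder outside, where secondary noise maxima split off spurious low-intensity fragments (`detectSpots`' own default stays 5 px for minimal, diffraction-limited spots) |
| `tolerance_k` (pipeline) | 7 | tolerance = k × robust noise σ (MAD of horizontal first differences / √2). The expected maximum of a 169-pixel box is ≈ 2.9σ above the mean by selection alone, so k = 5 leaves a ~2σ guard band and admits noise peaks; k = 7 restores a > 4σ margin |
| `threshold_fraction` | 0.5 | half-maximum borders make cluster area first-order insensitive to peak height |
| local border background | annulus median, 0.5–1.5 µm | the border is drawn at half the peak's *local* prominence; under a global level, any residual illumination tilt lets weak seeds on the bright side of the cell flood their surroundings. The *photometric* IFSc correction still uses the global background (median of in-mask pixels outside the 1-px-dilated clusters, re-estimated after segmentation to avoid self-subtraction) |
| `min_area_um2` | 0.0177 µm² | the half-maximum footprint of the PSF itself; nothing physical can be smaller |
| `max_area_um2` | 20 µm² | orders of magnitude above any plausible cluster; catches background floods |
| edge exclusion | half-box + 3 px | the detection box, corners included, must sample interior signal; inside the PSF roll-off at the cell border the corner gate passes spuriously |

Each of these was set by the error analysis above, run against the
generator's ground truth (false-positive mechanisms, per-cluster
signal-ratio distributions) — not by adjusting anything toward the
published summary values, which enter only as generator inputs and test
expectations.

## Numerical and degenerate-case conventions

- Plateau maxima: the top-left (row-major first) pixel represents an
  equal-valued plateau; constant images therefore contain no spots.
- Suppression and nearest-seed ties are fully ordered (peak, then row,
  then column; distance, then stronger peak, then lower seed index), so
  every stage is deterministic and order-independent.
- IFSc is clipped at zero: noise can push the correction negative and a
  negative density is meaningless; because regions are disjoint subsets of
  the mask and the correction is non-negative, ΣIFSc ≤ IFS and the
  fraction in clusters always lands in [0, 1]. A violation is raised as an
  error, never clamped.
- Half-open histogram bins [k·w, (k+1)·w) from zero; a value on an edge
  belongs to the upper bin.
- Cells smaller than 50 µm² of foreground are reported as "no cell found"
  rather than analyzed; zero-IFS cells with clusters are inconsistent and
  raise errors.
- `generateCell` refuses presets whose fraction demands more cluster
  signal than the expression level supplies, and reports a density limit
  when cluster placement cannot satisfy the separation constraint.

## Reproducibility and problem sizes

Every stochastic step flows from one master seed through deterministic
per-cell seed derivation; the same configuration and seed reproduce
byte-identical images and tables. Cohort studies in the test-suite and the
acceptance script use the study design the package emulates — ten variant
presets × 30 cells, repeated over five master seeds (1,500 synthetic
cells, ~10⁵ clusters) — for the headline checks, and smaller cohorts
(10–20 cells, compact 150–400 µm² geometries) for module-level
properties, keeping a desk-scale run in the minutes range.

## What the synthetic validation does and does not show

Passing recovery tests show that the implemented chain is *internally
consistent*: scenes with known operational truth are measured back within
±10% across a 12-fold density range, the bell-shaped density–chain-length
dependence and its chain-61 apex survive the full pipeline, and the
detector and split rules equal their brute-force references exactly. They
do not certify performance on real microscopy: real clusters are not
Gaussian, cell footprints are not smooth star-shaped domains, background
has structure beyond a linear tilt, and the Airyscan detector's noise is
only approximated by Poisson + read noise. The generator's dispersion
parameters (log-normal CVs, gamma shape) are field-plausible stand-ins,
stated here precisely so they can be challenged; no published source fixes
them.

Known limitations: clusters closer than ~half a detection box to the cell
border are not detectable (by design of the edge exclusion); the
segmentation macro originally used for this methodology is not public in
its exact threshold rules, so the half-maximum convention here is a
declared stand-in and absolute areas/IFSc are convention-dependent even
though the per-variant *comparisons* are not; and the per-variant
summaries inherit any error in the packaged binding energies, which are
taken as given inputs.
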