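# kvclust

Quantitative clustering metrics for scaffold-protein-mediated ion channel
clustering in fluorescence microscopy.

## What it is for

Voltage-gated potassium (Kv) channels are gathered into membrane clusters
by the scaffold protein PSD-95, via an intrinsically disordered C-terminal
"chain" tipped with a PDZ-binding motif. The density of channels *inside*
a cluster — and how it depends on chain length and binding affinity — is
the scientific quantity this package measures. It is written for
microscopists and quantitative biologists who image single-channel
fluorescence of cell basal membranes and want reproducible, scriptable
cluster statistics instead of an interactive macro.

From a calibrated 2D image (TIFF, µm/pixel known) the pipeline computes,
per cell:

* **normalized expression level** — integrated cell fluorescence over cell
  area, IFS/µm²;
* **clusters per area** — spot count over cell area, 1/µm²;
* **fraction of signal in clusters** — Σ IFSc / IFS;
* **cluster signal intensity** — per cluster, background-corrected
  integrated fluorescence over cluster area, IFSc/µm², the proxy for
  channel density within the cluster.

Clusters are found by the classic box-scan rule — a local maximum is
accepted when it exceeds the mean of the four corners of a box centred on
it by more than a noise tolerance — and grown to half-maximum borders with
nearest-seed splitting. Variants are compared with one-way ANOVA, a gamma
GLM (log link, Wald χ² test) for the right-skewed density distributions,
and ordinary least squares of mean cluster density on PSD-95 binding
energy ΔG:

IFSc/area ~ β₀ + β₁ · ΔG   (chain length ≥ 61 aa)

A seeded synthetic-scene generator (`generateCell`, `generateCohort`)
produces cells with complete ground truth — diffuse membrane signal plus
Gaussian clusters at controlled density, fraction-in-clusters and
intensity, blurred to 150 nm resolution and corrupted with shot and read
noise — so every stage of the pipeline is testable without raw microscopy
data. The packaged table `kvPresets()` holds the ten Shaker chain-length
variants (9–144 amino acids) with their measured clustering attributes and
binding energies, and parameterizes the generator.

See the methods vignette (`vignettes/kvclust-methods.Rmd`) for the model,
the calibration conventions, and every default with its rationale.

## Worked example

Generate a small cohort of the chain-61 variant, run the analysis, and
compare variants from the packaged table:

```r
library(kvclust)
presets <- kvPresets()
pre <- presets[presets$chain_length == 61, ]

cohort <- generateCohort(pre, n_cells = 5, seed = 1,
                         geometry = list(cell_area = c(250, 400)))
res <- analyzeCohort(cohort)
s <- summarizeVariant(res$cells, pre)
round(data.frame(n_cells = s$n_cells, n_clusters = s$n_clusters,
                 intensity_mean_1e5 = s$intensity_mean / 1e5,
                 fraction_1e3 = s$fraction_mean * 1e3,
                 clusters_per_um2 = s$clusters_per_area_mean), 3)
#>   n_cells n_clusters intensity_mean_1e5 fraction_1e3 clusters_per_um2
#> 1       5       1007             40.016       85.813            0.582
```

Five cells already land near the preset's nominal values (44.8 ×10⁵
IFSc/µm², 95.8 ×10⁻³, 0.642/µm²); cell-to-cell dispersion dominates the
remaining gap at this n, and 30-cell cohorts recover all presets within
±10% (this is asserted by the test suite).

```r
tab <- presets
tab$intensity_mean <- tab$cluster_intensity
affinityDensityRegression(tab)
#> StatsResult: affinity_density_ols
#>   estimates: slope = -2.96728e+06, intercept = -2.72609e+07,
#>              r.squared = 0.968809, n = 6
bellCurveArgmax(tab)
#> [1] 61
```

The negative slope says: the more negative the binding free energy (the
tighter the chain binds PSD-95), the denser the clusters — for chains of
61 amino acids and longer, where recruitment thermodynamics rather than
steric hindrance governs packing. The argmax is the apex of the
bell-shaped density-versus-chain-length curve.

A full multi-variant run (simulate → detect → segment → metrics → stats,
with CSV outputs and a JSON manifest):

```r
man <- runPipeline(seed = 1, outdir = "kvclust_run")   # ~3 min
man$argmax_chain      # chain length at the density maximum
man$regression_r2     # long-chain affinity-density R²
```

or, from a shell, `Rscript inst/scripts/run_pipeline.R --seed 1 --outdir
kvclust_run [--config run.yaml] [--quick]`.

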