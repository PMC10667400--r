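# radrepro

Test–retest reproducibility of radiomics features across pre-processing
settings.

## What this is for

Radiomics features — first-order intensity statistics, texture-matrix
summaries (GLCM, GLDM, GLRLM, GLSZM, NGTDM), and 3D shape measures — are
only useful as imaging biomarkers if they are stable when the same lesion
is scanned twice. For arbitrary-unit modalities such as T2-weighted
prostate MRI, stability depends heavily on pre-processing. `radrepro`
quantifies that dependence: it applies a 48-setting grid crossing

* gray-level discretization: fixed bin number (FBN 16/32/64/128) vs fixed
  bin size (FBS 5/10/20/40),
* dual-reference signal-intensity normalization (AR) vs none (NAR),
* intensity outlier filtering: none (NoF), clipping to μ ± 3σ (IN), or
  re-segmentation removing voxels outside μ ± 3σ (OUT),

extracts 107 features per lesion per scan per setting, scores each
(feature, setting) cell with the two-way random, single-measurement
intra-class correlation

ICC(2,1) = (MSR − MSE) / (MSR + (k−1)·MSE + (k/n)·(MSC − MSE)),  k = 2,

flags features with ICC > 0.75 as reproducible, selects the setting with
the most reproducible features (ties → lowest binning), and compares
reproducibility and baseline feature values across clinical categories
(PSAD ≤/> 0.15 ng/mL², prostate volume </≥ 40 mL, PI-RADS 3/4/5, ISUP
<1/1/>1) with Mann–Whitney U / Kruskal–Wallis tests under
Benjamini–Hochberg correction.

Patient data of this kind are not publicly distributable, so the package
includes a paired-cohort simulator with a known true reliability
(`var_shared / (var_shared + var_independent)`), inter-scan gain/offset
drift, and per-scan delineation jitter, which the test suite uses to
validate every stage end to end.

## Worked example

```r
library(radrepro)

# a reduced simulated cohort: 10 patients, 20 lesions, small ROIs
cfg <- sim_config(n_patients = 10L, total_lesions = 20L,
                  grid_shape = c(26L, 26L, 10L),
                  lesion_radius_range = c(2.5, 4.2), seed = 42)
cohort <- generate_cohort(cfg)

feats  <- extract_cohort(cohort)        # 20 x 2 x 48 x 107 values, long format
grid   <- build_grid(feats)             # 107 x 48 ICC(2,1) matrix
counts <- count_good(grid)              # good features (ICC > 0.75) per setting
sel    <- select_setting(counts)
setting_label(sel)
#> [1] "FBN128/AR/OUT"                   # 21 good features on this cohort
head(consistently_good(grid))
#> [1] "Shape_Elongation"              "Shape_Flatness"
#> [3] "Shape_LeastAxisLength"         "Shape_Maximum2DDiameterColumn"
#> [5] "Shape_Maximum2DDiameterRow"    "Shape_Maximum2DDiameterSlice"
```

The 11 consistently reproducible features on this synthetic cohort are
dominated by shape, as expected: shape ignores intensities entirely, so
only delineation jitter perturbs it. The mean ICC over all 5136 cells here
is 0.34 ± 0.29 — the simulator's default true reliability is 0.5, and
discretization/drift push individual features above or below it.

The estimator itself on the classic worked example:

```r
icc_2_1(matrix(c(1, 2, 3, 4, 5, 6, 7, 8), 4, 2, byrow = TRUE))
#> ICC(2,1) = 0.9302 (n = 4, k = 2)     # exactly 40/43
```

A full run (features, grid, selection, clinical comparisons, manifest) on
a cohort directory or in-memory cohort:

```r
res <- run_pipeline(cohort, "results/")   # writes features.csv, grid.csv,
                                          # selected_setting.json,
                                          # comparisons.csv, run_manifest.json
```

There is also a small CLI (`inst/cli/radrepro`):
`radrepro simulate|extract|icc|select|compare|run`.

## Notes

* Feature definitions follow the conventions of the standard extraction
  tooling (13 distance-1 directions, per-direction averaging, present-level
  indexing); see `vignettes/methods.Rmd` for the full conventions,
  degenerate-case constants, and the mesh algorithm discussion.
* Runtime scales with ROI size; the reduced cohort above completes in
  about two minutes on one CPU, a full-size 74-lesion cohort at default
  lesion sizes in roughly an hour.
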