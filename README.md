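# tagrsom

Quantitative image analysis for transrectal-absorber-guide (TAG)
raster-scanning optoacoustic mesoscopy (RSOM) of murine colitis.

RSOM resolves hemoglobin-bearing microvasculature at ~40 µm lateral / ~10 µm
axial resolution through several millimetres of tissue, but transabdominal
images of the mouse colon give no intrinsic landmark separating colon-wall
vessels from the peritoneal and skin vasculature above them. A rigid 3 mm
absorber guide in the rectum provides that landmark: with ink in its lumen
it is a bright fiducial whose traced surface anchors every measurement; with
water it is transparent, giving an artifact-free copy of the same scene.
`tagrsom` turns such co-acquired ink/water volume pairs into three
biomarkers of colitis severity:

* **colon-wall thickness** (µm) — axial distance from the guide's lumen
  interface to the top of the colon-wall vessel signal, minus the guide's
  transparent polymer wall; averaged over seven maximum-intensity-projection
  segments along the scan axis;
* **total signal intensity** (a.u.) — exact sum of the 8-bit masked colon
  volume;
* **blood volume** (µL) — voxels above the iterative-intermeans (IsoData
  "Default") threshold of the in-mask 8-bit histogram, ignoring zeros, times
  the voxel volume.

The pipeline: central crop → fiducial trace → tilt removal by triangulation
and quintic B-spline resampling → rigid ink/water co-registration →
per-frame bend straightening → TAG-anchored 5480 × 1600 × 520 µm analysis
volume → ±18° angular-sector segmentation with automatic (or manual)
overlay separation → biomarkers. A synthetic phantom generator reproduces
the acquisition geometry (four strata: skin, peritoneum, colon band on the
guide, guide lumen; anisotropic PSF; bend, tilt, inter-acquisition shift,
noise) with voxel-level ground truth, so every stage is validated without
animal data. A statistics module mirrors the study design: Shapiro-Wilk-
gated test selection (t-test/ANOVA vs Mann-Whitney/Kruskal-Wallis/Friedman,
Holm-adjusted pairwise comparisons) and Spearman correlation.

## Worked example

```r
library(tagrsom)

spec <- cohort_phantom_spec(wall_thickness_true = 100, seed = 3)
ph   <- generate_phantom(spec)               # ink + water + ground truth
q    <- quantify_pair(ph$ink, ph$water, cohort_run_config(),
                      measure_water = TRUE)

q$ink_set$thickness_um      # 96.9  -- true wall is 100 µm
q$ink_set$blood_volume_ul   # 0.0157 µL at threshold q$ink_set$threshold_8bit
q$ink_set$intensity_au      # 1.3e6 a.u. (8-bit sum over the colon mask)
q$water_set$thickness_um    # 96.9  -- ink-derived mask on the water volume
```

The thickness lands within two axial voxels (8 µm) of truth; ink- and
water-derived read-outs agree within a few percent, reflecting that the
guide's contrast state does not perturb the tissue measurement.

The `analysis/` directory holds the synthetic colitis study as numbered
drivers — `01_simulate.R` (design table + example volumes on disk),
`02_preprocess.R` (alignment, serialized transform records),
`03_quantify.R` (biomarker table), `04_stats.R` (group comparisons and
truth correlation) — each writing its tables under `results/`. On the
default design (10 healthy vs 10 inflamed phantoms) the run prints
thickness 56.6 ± 22 vs 131 ± 51 µm (truth 61 vs 136 µm), all three
biomarkers significantly different (p < 0.002), and Spearman r_s = 1.00
between measured and true thickness.

## Layout

```
R/                  package code: phantom, io, preprocess, segmentation,
                    biomarkers, stats, study orchestration
src/                compiled kernels (separable convolution, tube
                    rasterization, recursive spline prefilter, NCC search)
analysis/           the synthetic colitis study, numbered drivers
scripts/acceptance.R   geometry reproduction (above)
tests/testthat/     unit, property and end-to-end recovery tests
vignettes/          methods vignette: model, assumptions, parameter
                    defaults, limitations
```
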