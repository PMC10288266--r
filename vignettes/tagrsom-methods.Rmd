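---
title: "Quantifying colon-wall biomarkers from TAG-guided optoacoustic mesoscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying colon-wall biomarkers from TAG-guided optoacoustic mesoscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Raster-scanning optoacoustic mesoscopy (RSOM) resolves hemoglobin-bearing
microvasculature at roughly 40 µm lateral and 10 µm axial resolution down to
about 3 mm of depth. Imaged transabdominally in the mouse, the colonic wall
vasculature is sandwiched between skin and peritoneal vessel layers and has
no intrinsic landmark separating it from them. A transrectal absorber guide
(TAG) solves the localization problem: a rigid 3 mm cylinder in the rectum
whose lumen can be switched between ink (a strong, featureless absorber that
renders the guide's interface brightly) and water (acoustically equivalent
but transparent, for artifact-free measurement). The colon drapes over the
guide, so the guide's traced surface anchors every downstream measurement.

`tagrsom` implements the quantification chain from reconstructed volume
pairs to three biomarkers of colitis severity — colon-wall thickness, total
optoacoustic signal intensity, and blood volume — together with a synthetic
phantom generator that provides voxel-level ground truth, so the whole chain
is testable without any animal data.

## Volume convention

A volume is a non-negative scalar grid indexed `(X, Y, Z)`: X along the
guide/scan axis, Y lateral, Z depth increasing downward from the skin-facing
surface. The reconstruction voxel size is 20 × 20 × 4 µm. On disk, volumes
are Z-paged 16-bit TIFF stacks with `(Y, X)` pages plus a JSON sidecar
(`voxel_spacing_um`, `contrast_state`, `axes`, `intensity_scale`); the
16-bit quantization is exact for integer data and reversible to 1/65535 of
the per-volume intensity scale recorded in the sidecar.

## The preprocessing chain

1. **Central crop** to 6 × 3 × 2 mm (the largest window containing colon
   data across acquisitions). Odd margins leave the extra voxel on the
   high-index side.
2. **Fiducial trace.** Per X frame, voxels above half the volume maximum are
   labelled; the largest connected component is the ink lumen (a minimum
   area of 120 voxels rejects vessel cross-sections). Its minimum-Z voxel is
   the lumen-interface apex; sub-voxel position comes from the Y centroid of
   the component's top rows and linear interpolation of the threshold
   crossing in Z. The outer-cylinder apex is the lumen apex minus the
   polymer wall (150 µm by default; the guide's wall is transparent and
   never directly visible, and its thickness is configurable because it is
   a property of the physical guide, not of the data).
3. **Tilt removal.** The tilt is triangulated from the two extreme valid
   frames, `atan(dz/dx)` in physical units, then removed by resampling in
   the physical XZ plane with a quintic B-spline interpolant (recursive
   prefilter, 6 × 6 kernel, zero fill). Tilts below 0.2° — the chain's own
   residual-alignment tolerance — are left alone rather than resampled.
4. **Co-registration.** The water scan is mapped into the ink frame by the
   integer (Y, Z) translation maximizing overlap-normalized correlation of
   the X-maximum-intensity projections, with the guide and its blurred halo
   masked out (the lumen differs between contrast states by design).
   Projections use the maximum, not the mean: vessels are sparse along X
   and a mean projection buries them under the guide's halo. The search is
   exhaustive over ±10 voxels — co-acquired scans share the animal
   position, so the true offset is small. A peak correlation below 0.2
   returns the identity with a warning.
5. **Bend straightening.** The uplifted colon bends the guide slightly; each
   YZ frame is translated so the traced lumen apex lies on a line parallel
   to X. The traced reference is smoothed (locally weighted regression,
   span 0.15) before offsets are derived, because the physical deformation
   is smooth along the scan axis while the raw trace carries voxel-level
   jitter; deviations below 0.25 voxel skip the correction entirely.
   Fractional translations use the same quintic B-spline machinery.
6. **Analysis trim.** The canonical analysis volume is 5480 × 1600 × 520 µm
   = (274, 80, 130) voxels: X centered, Y centered on the traced guide
   axis, Z anchored one voxel below the traced outer-cylinder apex and
   extending toward the skin. Anchoring the window to the guide (rather
   than to the image) is an assumption — the protocol states one fixed
   analysis dimension but not its anchor — and is the natural choice here
   because every measurement is referenced to the guide surface.

All transforms are estimated on the ink volume and transferred unchanged to
the co-registered water volume; the serialized alignment record (rotation,
shift, per-frame offsets, windows, configuration echo) reproduces the
analysis volumes deterministically.

## Segmentation

Structures outside ±18° azimuth about the guide axis (measured from the
vertical toward the skin) are acoustic artifacts of the guide and are
discarded; voxels radially inside the outer cylinder are excluded. Within
the sector, the colon wall is separated from overlying peritoneal and skin
tissue. The study protocol did this manually, and a manual mask remains a
first-class input (intersected with the sector and guide exclusion). The
automated default scans each (X, Y) column upward from the guide surface and
cuts at the first vessel-free gap of at least 120 µm of sub-threshold
signal — the colon wall rests directly on the guide while the peritoneum is
separated by a gap. The threshold is a single iterative-intermeans threshold
of the in-sector volume rather than a per-column one: columns are only a few
hundred voxels and their histograms are too sparse to threshold stably. The
gap heuristic is an explicit stand-in for expert manual separation, not a
claim about how experts do it.

## Biomarkers

* **Thickness.** The analysis volume is split into seven X segments (sizes
  differ by at most one voxel, remainder from the low-X end) and each is
  projected to a YZ maximum-intensity projection of the masked volume. Per
  segment, thickness = (lumen-apex Z − top-of-vessel Z) × 4 µm − polymer
  wall, where the vessel boundary is read per column in a ±5-column band
  around the guide centerline (off-center columns would measure oblique
  chords) as the minimum Z above the segment's intermeans threshold, then
  the median over columns. Negative values clamp to zero with a warning;
  the mean is over unflagged segments.
* **Intensity.** The masked volume is rescaled to 8 bits against the
  analysis volume's global maximum (the ImageJ conversion convention;
  recorded in the output since it affects cross-subject comparability,
  but the protocol specifies no absolute calibration), rounded half-up,
  out-of-mask voxels zeroed, and summed exactly.
* **Blood volume.** The "Default" iterative-intermeans variant on the
  in-mask 8-bit histogram, disregarding zeros: iterate
  `t ← round((µ≤t + µ>t)/2)` from 127 to its fixed point, resolving ties
  (adjacent thresholds satisfying the fixed-point equation simultaneously)
  toward the smallest. Voxels strictly above the threshold are counted and
  converted by the voxel volume (1600 µm³ = 1.6 × 10⁻⁶ µL). The threshold
  is computed per subject; a config switch could share it per study, but
  per-subject matches the described workflow.

## The phantom generator

The generator rasterizes the four strata of the acquisition — skin vessels,
peritoneal vessels, the colon-wall vascular band draped on the guide, and
the guide itself — onto the reconstruction grid, then applies an
anisotropic Gaussian point-spread function (40/40/10 µm FWHM) and additive
Gaussian noise clipped at zero. Ground truth (wall thickness, colon vessel
voxel count and volume, applied tilt, shift and bend) is recorded on the
pre-blur binary rasterization, because blur admits no unambiguous truth
volume.

Vessel networks are random-walk tubes grown until the summed centerline
length reaches `density × layer volume`. Defaults: colon band density
1 × 10⁻⁴ µm/µm³ with radii 15–30 µm (capped at half the band thickness),
giving a vascular volume fraction near 15–20 % — a plausible figure for a
densely vascularized inflamed gut wall imaged at 532 nm; skin and
peritoneal layers at 6–8 × 10⁻⁵. In addition to the random network, a
superficial plexus of fine vessels (50 µm lateral spacing) runs along the
top of the band for the whole scan length: the outer boundary of a real
colon wall is a continuous vascularized surface, and without it the band's
upper edge — the very quantity the thickness biomarker measures — would be
defined only stochastically. The ink and water volumes differ only in the
lumen intensity (1.0 vs 0.02 a.u. against vessels at 0.5) and a small rigid
(Y, Z) offset between the two acquisitions; noise is drawn independently
per volume. `(spec, seed)` reproduces a pair bit-exactly.

What the phantom does not emulate: acoustic wave propagation and
reconstruction artifacts, depth-dependent fluence, breathing motion
(corrected upstream by vendor software in practice), intestinal content,
and the irregular, interrupted vessel topology of severe ulceration.
Passing recovery tests on phantoms therefore validates the geometry and
arithmetic of the chain, not its robustness to reconstruction artifacts.

## Problem sizes and numerical choices

Three phantom geometries are used, all at the 20 × 20 × 4 µm voxel size:
the full 6 × 3 × 2 mm grid (for the canonical analysis-volume geometry),
a mid-size 1.6 × 1.0 × 0.8 mm grid (volumetry validation, where the
sampled wedge must contain enough vessel voxels for a stable count), and a
compact 1.0 × 0.6 × 0.72 mm grid with a proportionally scaled analysis
window (cohort studies, where hundreds of phantoms are generated). The
synthetic colitis study uses the compact geometry: n = 10 per arm, true
wall thickness N(60, 20.7) µm healthy vs N(130, 53.7) µm inflamed
(truncated to 24–220 µm so the band fits the compact grid), inflamed
vessel density doubled — the magnitudes of the longitudinal severe-colitis
contrast.

Numerical details worth knowing: the quintic prefilter uses the exact pole
pair of the quintic B-spline's z-transform with mirror end conditions;
interpolation ringing can produce small negative intensities, which are
clamped to zero; rotation happens in physical coordinates (the grid is
5× anisotropic); frame translations decompose into an integer fast path
and a prefiltered 6-tap fractional path; bend round-trips are evaluated on
the grid interior since content translated across the boundary is
irrecoverably zero-filled; and the intermeans iteration resolves fixed-point
ties downward so it agrees with an exhaustive smallest-fixed-point scan.

## Statistics

The decision tree mirrors longitudinal colitis studies: Shapiro-Wilk on
every sample gates a parametric branch (unpaired t-test / one-way ANOVA /
paired t-test) against a rank branch (Mann-Whitney / Kruskal-Wallis /
Friedman); all p-values two-tailed at α = 0.05. Holm correction accompanies
the multi-group branches — the protocol names no specific multiple-
comparison method, so a conservative, assumption-free default was chosen
and is configurable. Repeated designs with more than two timepoints use
Friedman on both branches: a full mixed-effects model is deliberately out
of scope, being an off-the-shelf fit rather than part of the imaging
method. Spearman correlation (average ranks on ties) validates measured
thickness against ground truth, standing in for the histology correlation
of a real study.

## Known limitations

* The automatic overlay separation fails when the colon band and the
  peritoneal layer approach within the gap parameter (120 µm); severe
  wall thickening can close that gap, in which case a manual mask is the
  correct input.
* Thickness is biased low by roughly one axial voxel pair (the intermeans
  threshold sits above the half-maximum edge of the topmost vessel), well
  inside the two-voxel tolerance but systematic.
* The 8-bit normalization is per-volume; absolute intensities are not
  comparable across subjects unless acquisitions are calibrated.
* Blood volume compares against pre-blur truth only to ~10–15 %: blur
  moves intensity across the threshold surface, and thin vessels
  (diameter ≲ the lateral PSF) contribute disproportionate skirt.
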