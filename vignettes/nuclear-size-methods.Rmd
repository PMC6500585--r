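---
title: "Measuring nuclear size in 3D: methods, models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring nuclear size in 3D: methods, models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucsize)
```

## Scope and model

`nucsize` estimates the size of DAPI-stained nuclei in spatially calibrated
confocal z-stacks of thick plant-root sections, and turns the resulting size
distributions into ploidy-structure summaries. The measurement problem has
three hard features: voxels are strongly anisotropic (laterally ~0.37 µm,
axially 1.5 µm in the reference acquisition of a 375 × 375 × 45 µm field),
fluorescence falls off with depth, and the plant nuclei of interest share
the image with much smaller fungal nuclei and faint elongated wall staining.
All public APIs speak physical micrometres; the `(z, y, x)` array layout and
0-based half-open crop boxes are internal conventions chosen so that region
boxes partition a stack without overlap. No resampling is ever performed
implicitly: the volume formulas consume the raw calibration.

Three estimators are implemented because they fail differently:

1. **Slice-track.** Nuclei are detected per optical section as
   Laplacian-of-Gaussian maxima at the scale of a nominal 10 µm blob, then
   linked along z when lateral centroids coincide. The equatorial
   cross-section is $\pi (d_{max}/2)^2$ and the volume is the Cavalieri sum
   $\sum_i \pi (d_i/2)^2 \, \Delta z$. The three-section rule (volumes only
   for tracks spanning ≥ 3 sections) removes nuclei truncated by the stack
   ends — and, with a 1.5 µm step, also removes genuinely small nuclei whose
   axial extent is under ~4.5 µm. This selection bias is inherent to the
   method and is reproduced, not patched.
2. **Round surface detector.** Projection-based area measurement. Substacks
   of 6 slices (9 µm, about one nuclear diameter) keep axially distinct
   nuclei from overlapping in the projection while one nucleus rarely spans
   two substacks; nuclei that do straddle a boundary are deduplicated
   afterwards by keeping the larger-area record within a 3 µm merge radius
   in adjacent substacks (greedy by area, hence idempotent).
3. **Volumetric object counting.** One global threshold, 3D
   connected-component labeling, voxel-sum volumes. This is the most precise
   method on well-separated nuclei and the one that inherits the depth
   problem in full: a single threshold chosen for shallow nuclei
   under-covers deep ones. The per-substack thresholding available in the
   projection pipeline is deliberately *not* applied here by default.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `estimated_diameter` | 10 | µm | upper end of plant nuclear diameters; sets the LoG scale |
| `max_link_distance` | 5 | µm | "same x-y centroid" tolerance: half the nominal diameter |
| `max_gap` | 0 | slices | tracks are continuous traces; gaps off by default |
| `min_slices` | 3 | sections | truncation guard for slab-sum volumes |
| `thickness` | 6 | slices | substack depth ≈ one nuclear diameter (9 µm) |
| `rolling_ball_radius` | 20 | µm | background structuring element, > largest nuclear radius |
| `circularity` | 0.7–1 | — | rejects elongated wall staining |
| `size` | 15–150 | µm² | rejects fungal nuclei (below) and aggregates (above) |
| `min_volume`, `max_volume` | 15, 250 | µm³ | volumetric analogue of the area gate |
| `connectivity` | 26 | — | face+edge+corner adjacency in 3D |
| `lobedness_threshold` | 0.08 | — | see below |
| `width`, `anchor` | 25, 20 | µm³ | volume class grid (class I = 20–45 µm³) |

Numerical and procedural choices that were genuinely open:

* **Quality gate.** The slice-track quality threshold defaults to an Otsu
  split of the stack's detection-quality distribution, since no absolute
  scale exists across acquisitions; any numeric override is accepted.
* **Projection threshold.** Otsu is computed over candidate-foreground
  pixels (above 2% of the maximum of the background-subtracted projection).
  A plain whole-histogram Otsu is dominated by the empty background class
  and lands near 0.3 of the nuclear peak, inflating every area by ~15%; the
  restricted split lands near the half-maximum, where the rendered boundary
  of a bright, sharp-edged nucleus actually lies.
* **Perimeter and circularity.** Circularity is $4\pi A/P^2$, clamped to 1,
  with the perimeter from corner-corrected chain-code weights
  (0.980 per axial step, 1.406 per diagonal, −0.091 per corner). The raw
  pixel-edge perimeter overestimates $P$ by ~27% on discs and would wrongly
  reject small round nuclei at the 0.7 gate.
* **Lobedness.** Touching nuclei merge into one 3D component; the score
  $1 - \text{voxels}/\text{convex fill}$ flags them. The convex fill is
  computed per z-slice (2D convex hull of each slice's pixels, rasterised
  and summed): no 3D hull dependency is needed, convex single nuclei score
  < 0.03, and two equal tangent spheres score ≈ 0.12–0.14. The flag
  threshold is 0.08 — even a true 3D hull puts tangent equal spheres at only
  ≈ 0.20, so a threshold as high as 0.25 would miss the canonical
  touching-pair geometry. Purely axial stacking is invisible to the
  slice-wise hull; the cortex-cropping and substack workflows are the
  mitigation for that geometry.
* **Per-detection diameter.** Each detection's diameter is the
  circle-equivalent diameter of the half-maximum support of the
  background-subtracted window around the LoG peak. This is the FWHM
  convention: it recovers the geometric diameter for sharp-edged objects
  and 2.355σ for Gaussian blobs, and unlike a second-moment estimate it
  does not depend on the radial profile shape.
* **Linking determinism.** Candidate links are assigned greedily by
  increasing centroid distance, ties broken by lower track id then detection
  order, so identical inputs always produce identical tracks.
* **Classing boundaries.** Volume classes are half-open on the upper side
  (a 45 µm³ nucleus is class II), values below the 20 µm³ anchor fold into
  class I, and a value exactly at the top of the covering range joins the
  last class — so a 20–220 µm³ population yields exactly eight 25 µm³
  classes. The anchor and width defaults come from the published class
  limits (20–45, 70–95, ..., 195–220 µm³); the Sturges formula
  $R/(1 + 3.322\log_{10} N)$ is exposed as `sturges_width()` and gives
  ~10–18.5 µm³ for the published ranges and counts — the adopted 25 µm³
  width does not follow from the formula, so the two are kept separate and
  the width is always an explicit parameter.
* **Degenerate inputs.** Constant stacks make Otsu undefined (error asking
  for a manual value); constant projections yield an empty mask with a
  warning; constant samples have undefined skewness/kurtosis (`NA`);
  a degenerate median split returns p = 1 with a warning.

## Statistics

Size distributions are right-skewed; lognormal and gamma are the two
candidate families, fitted by maximum likelihood and ranked by both the
Anderson-Darling statistic and AIC (`fit_size_distribution`). Group
comparisons of central tendency use Mood's median test (exact hypergeometric
branch up to a pooled n of 200, chi-square with continuity correction
beyond) and Kruskal-Wallis with Dunn's rank-based post-hoc, Bonferroni
multiplied by the number of pairs.

To compare distribution *shape* across methods and treatments on equal
footing, `bootstrap_moments` homogenises sample sizes: 1000 iterations, each
resampling 500 values with replacement, refitting a lognormal (closed-form
MLE), regenerating 500 points from the fitted density, and recording mean,
sd, CV, skewness and excess kurtosis of the regenerated sample. The
regeneration step is applied per iteration (the alternative — one
regeneration per starting sample — would produce a single sample rather than
a distribution of moment statistics, defeating the purpose of the
bootstrap). Skewness and kurtosis use the bias-corrected (type 2)
estimators, and kurtosis is reported as excess; both conventions are
choices, stated here because results are not comparable across conventions.
Moment statistics are then compared across groups with a Gaussian linear
model and Tukey-adjusted pairwise contrasts, after a Shapiro-Wilk screen
that triggers a square-root transform when any group fails at α = 0.05 (the
transform is skipped with a warning if values can be negative, as excess
kurtosis can be).

Putative ploidy is a *label on volume classes* (class k ↦ $2^k$C), not a
calibrated DNA measurement; cell-category annotations (arbusculated,
neighbouring, far; split vs undivided) are consumed from input tables and
never inferred from images.

## What the phantom emulates — and what it does not

`generate_phantom` renders each object with the radial profile
$I = \text{peak} \cdot 2^{-m^4}$, where $m$ is the normalised ellipsoidal
radius: the half-maximum isosurface is exactly the true ellipsoid, and the
edge is steep, as in chromatin-dense DAPI-bright nuclei. Plant-nucleus
volumes come from a lognormal mixture centred near 30/55/80/105 µm³
(mimicking a population with recursive ploidy doubling, weights 0.45 / 0.27 /
0.17 / 0.11, log-sd 0.12); the equatorial radius is floored so equatorial
areas stay above ~15.5 µm², keeping plant nuclei above the fungal size gate
by construction. Fungal nuclei are ~1 µm-radius ellipsoids; wall artifacts
are dim 0.6 µm-thick bars 12–24 µm long (circularity far below 0.7). Depth
attenuation multiplies intensity by $e^{-z/L}$ with $L = 45$ µm by default
(noticeable loss across the 45 µm stack, matching the depth instability that
motivates cortex cropping); noise is Poisson shot noise plus Gaussian read
noise (sd 20 counts at a 3000-count plant peak). Objects are placed by
rejection sampling at a 12 µm minimum separation; a single seeded generator
makes every phantom bit-reproducible.

The phantom does **not** emulate: PSF blur beyond the smooth blob edge,
anisotropic optical distortion, chromatic or spherical aberration, real
root anatomy (beyond an optional "cortex band" placement for crop tests),
overlapping/clustered nuclei (separation is enforced — lobedness is tested
on constructed touching spheres instead), or spatially varying background
staining beyond the smooth ramp used in mask tests. Passing tests on
phantoms therefore demonstrate estimator correctness on bright, separated,
sharp-edged ellipsoids — they do not certify performance on real tissue,
where detection efficiency is known to drop well below manual counts.

Test and validation problem sizes were chosen to keep the full suite fast
while leaving no estimator untested at realistic geometry: phantoms of 8–50
nuclei on 256²–512² × 30 grids, labeling-oracle stacks of 12³–16³, 400–1000
replicate simulations for the type-I-error and bootstrap checks.

## Known limitations

* The slab-sum volume inherits every per-section diameter error and the
  three-section exclusion; with 1.5 µm steps it is unreliable for nuclei
  under ~35 µm³, exactly as observed when tracking-based measurement was
  applied to this problem.
* A single global threshold under-covers deep nuclei in attenuated stacks;
  the package reproduces this failure (it is asserted in the tests as a
  monotone coverage decline with depth) rather than silently correcting it.
* The slice-wise convex fill misses purely axial lobing.
* Dunn's test uses the normal approximation; for very small groups the
  Bonferroni-corrected p-values are conservative.
* The compact-letter-display assignment is greedy insert-absorb; with many
  groups it can emit more letters than the minimal covering.
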