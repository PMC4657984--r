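---
title: "Methods: object-based species discrimination across a phenology time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: object-based species discrimination across a phenology time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crownpheno)
```

## The model of the problem

A mixed broadleaved forest is surveyed repeatedly across one growing season
with two consumer cameras per date (RGB, and a modified color-infrared one),
delivering co-registered 3-band orthomosaics at 20 cm/pixel. Individual tree
crowns are delineated manually and labelled with one of five species
groups. The analysis treats the *crown* as the statistical object: each
crown contributes one feature vector per survey per camera, and a
supervised classifier measures how separable the species are with a given
set of surveys.

The scientific lever is phenological: species differ in the timing of leaf
flush, coloring and leaf fall. Spectral separability between species peaks
when the *within*-species variance is low (all crowns of a species in the
same phenological state) while the *between*-species differences are still
expressed. Field experience puts that optimum at the end of leaf flush in
late spring; the package's machinery exists to find such an optimum from
data, by exhaustively ranking date combinations.

## Crown metrics

Per crown × survey × camera the pipeline computes 37 metrics:

* **Geometry and masking.** The crown polygon is first narrowed by an
  inward buffer (default 0.50 m) to discard the border zone where crown and
  background mix. Pixels belong to a crown if their *center* lies inside
  the narrowed polygon (0-based row/col, top-left origin). Both choices are
  conventions the package fixes because delineation practice does not:
  center-in is exactly testable, and a metric-space buffer is
  resolution-independent.
* **Shadow filtering.** Pixel intensity is the sum of the three bands;
  relative intensity rescales it to 0–100 by the min–max over the mosaic's
  valid pixels. Crown pixels with relative intensity strictly below 20 are
  treated as cast shadow and discarded; a pixel at exactly the threshold is
  kept. A degenerate constant-intensity mosaic maps to 100 everywhere
  (nothing classed as shadow). The min–max normalisation is the simplest
  reading of "normalized 0–100"; normalising by the theoretical maximum
  (3 × 255) would compress the scale and silently shift the threshold's
  meaning, so it was not adopted.
* **Spectral statistics.** Band means, population SDs (n divisor — the
  crown is the full population of its pixels), the three unordered
  band-mean ratios (ordered pairs would only add reciprocals), normalized
  bands (band mean over the 3-band sum, summing to 1), and three
  normalized-difference indices per camera computed **on the crown-mean
  band values**: RGB (B, G, R) gives NGRVI, NGBI, NRBI; CIR (NIR, R, G)
  gives NDVI, GNDVI, NGRVI. Computing ND indices on means rather than
  averaging per-pixel indices is stabler under 8-bit quantisation; the
  difference is second order. Zero denominators yield 0 by convention and
  are logged.
* **Texture.** Seven gray-level co-occurrence metrics per band (variance,
  homogeneity, contrast, dissimilarity, entropy, second moment,
  correlation). The co-occurrence matrix is built *once per crown object*
  over its sunlit pixels: values quantised into 32 equal-width bins over
  the fixed [0, 255] scale, pairs counted only where both pixels are in
  the mask, symmetrised, pooled over the four offsets (0,1), (1,0), (1,1),
  (1,−1), then normalised. The object-level design has no window-size free
  parameter, unlike moving-window texture rasters averaged over the crown;
  anyone comparing numbers against a moving-window implementation should
  expect differences. Correlation is defined as 0 when the marginal
  variance vanishes. Crowns with fewer than 10 sunlit pixels on any layer
  are dropped entirely (with a logged reason): below that, SDs and
  co-occurrence distributions are noise.

## Classification protocol

Species classification uses random forests (the `randomForest` package)
under a balanced repeated design: per repetition, exactly `n_per_class`
crowns (default 50) are drawn per species without replacement, a forest of
`n_trees` (default 500) is fitted with the default feature-subset size
`floor(sqrt(p))` per split, and the out-of-bag predictions are scored. The
default 20 repetitions are averaged; the pooled confusion matrix and
per-class errors are reported alongside. Out-of-bag votes are tallied with
a deterministic tie-break (first species in sorted order) so a report is a
pure function of (table, settings, seed). Rows with any missing metric
among the selected columns are excluded *before* balancing — imputation
would leak the class structure the protocol is trying to measure.

Balance matters because the inventory is skewed (tens of crowns for some
species, nearly two hundred for others); an unbalanced OOB error would
reward majority-class guessing.

## Date-combination search

`enumerate_scenarios()` forms all C(n, k) subsets of surveys for k = 1, 2,
3; each scenario uses the union of both cameras' columns for its surveys
(a "survey" means the RGB + CIR flight pair; per-camera search remains
available via the `cameras` argument). Every scenario gets its own seed,
derived as a stable hash of (master seed, survey ids, cameras), so results
are reproducible, independent of evaluation order, and unchanged when more
scenarios are added. Each scenario draws its own balanced samples rather
than re-using one draw across scenarios: sharing a draw would correlate the
scenario errors and understate the ranking's sampling variability.
Rankings sort ascending by overall OOB error with ties broken by earliest
survey date, then lexicographic id.

## The synthetic world generator

The generator exists so that every stage is testable without aerial data.
It renders, per date, one RGB and one CIR layer (8-bit digital numbers,
shared grid, 0.20 m/pixel) from a per-species per-date 4-band mean
spectrum plus three variance components:

* **between-tree SD** — a crown-level spectral offset, the asynchrony of
  individuals within a species;
* **within-crown SD** — per-pixel noise (default 5 DN);
* **shadow** — a contiguous blob covering `shadow_fraction` (default 0.15)
  of each crown, attenuated ×0.1. Only its detectability by the
  relative-intensity rule matters downstream, so a fixed attenuation is
  enough.

Crowns are convex polygons (jittered radial outlines, convex hull) placed
without overlap by bounded rejection sampling; the background is a distinct
low-intensity texture; an optional multiplicative luminosity ramp along the
column axis emulates within-mosaic illumination drift. The CIR camera is
rendered directly from the NIR/R/G components; setting `cir_mixing = TRUE`
mixes the three CIR bands toward their common mean (85%), emulating the
near-collinear band sensitivities of a hot-mirror-removed consumer camera.

Four presets fix the study conditions:

* `null_world` — identical spectra and variances everywhere: the classifier
  must sit at the 80% chance error of five balanced classes.
* `separable_world` — species means at least 10 between-tree SDs apart at
  every date: errors must be ≈ 0.
* `planted_optimum` — one date `t_star` (drawn from the seed, so replicate
  worlds plant it at different calendar positions) has between-species
  spacing 40 DN at between-tree SD 3, all others spacing 6 DN at SD 15.
  The generative separation ratio (minimum pairwise distance between
  species means over maximum between-tree SD) is therefore ~13 at `t_star`
  and 0.4 elsewhere — the ranking search must recover `t_star`.
* `paper_like` — five species with staggered flush/senescence day-of-year
  parameters over the ten-survey spring-to-autumn calendar, and a U-shaped
  between-tree SD profile (16 DN at the first survey, minimum 4 DN at the
  third, 15 DN at the last), encoding the mechanism that makes the end of
  leaf flush optimal.

The magnitudes of these variance profiles are free parameters — no field
calibration of per-date within-species variance exists to pin them — so
all quantitative expectations on synthetic worlds are *rankings and
bounds*, never absolute errors to be matched.

What the generator does **not** emulate: radiative transfer, 3D canopy
structure and view-angle effects, photogrammetric artifacts
(blur, misregistration, mosaicking seams), non-convex or interlocking
crowns, and understory vegetation. Passing tests on these worlds therefore
validate the *machinery* (metrics, protocol, search) and the *mechanism*
(variance-driven date optimality), not absolute accuracy on real forests.

## Numerical choices and degenerate inputs

* Radiometry is 8-bit (0–255) with rounding at render time, matching
  consumer cameras.
* The inward buffer is computed exactly for convex polygons as the
  intersection of inward-offset edge half-planes; non-convex input raises
  an error rather than silently over- or under-shrinking (a correct inward
  offset of a reflex polygon requires a straight-skeleton construction
  that no installed dependency provides). An empty buffer result is a
  valid outcome: the crown is dropped with a logged reason.
* Co-registration is a contract, not a computation: layers must share one
  grid exactly, and mismatches raise a distinct error. No resampling is
  performed.
* Rasters are written as plain 8-bit TIFFs with ESRI world-file sidecars —
  a plain-text georeferencing convention that round-trips bit-exactly.
* All randomness flows from explicit integer seeds; repetition r of a
  scenario uses `seed + r`, and scenario seeds are hashes below 2^31.

## Problem sizes used by the tests

The shipped validation uses deliberately small worlds: the chance and
separability controls run 55 crowns per species on a single date with the
full protocol (20 × 500 trees, 50 crowns/class); the optimal-window
recovery runs ten replicate `planted_optimum` worlds of 12 crowns per
species across all ten dates with a reduced protocol (5 repetitions,
200 trees, 10 crowns/class) — the planted effect is large enough that the
reduced protocol recovers it comfortably, and the full k = 1, 2, 3
enumeration (175 scenarios per world) stays cheap.

## Known limitations

* Object-level GLCM numbers are not comparable to moving-window texture
  packages (deliberate; documented above).
* The inward buffer requires convex crowns; real delineations with deep
  concavities would need pre-processing.
* Radiometric equalisation between dates is out of scope: metrics are
  computed per mosaic, and the shadow filter's min–max normalisation is
  per mosaic too, which absorbs global but not within-mosaic illumination
  differences (the luminosity-ramp option exists to study exactly that
  sensitivity).
* The search stops at three-date combinations; beyond that the
  combinatorics grow while the marginal gain demonstrably shrinks.
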