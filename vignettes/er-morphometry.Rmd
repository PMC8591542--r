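---
title: "Quantifying ER morphology in yeast: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ER morphology in yeast: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ermorph)
```

# Overview

`ermorph` quantifies the morphology of the endoplasmic reticulum (ER) in
fluorescence micrographs of budding yeast and scores genome-scale
ER-expansion screens. The biological setting is a diploid strain carrying a
cytosolic BFP (cell body), a general ER marker tagging all ER membrane
(Sec63-mNeon-like) and a curvature-sensing reticulon marker
(Rtn1-mCherry-like) that labels tubules and sheet edges but is depleted
from sheet interiors. Cells are imaged either in optical *mid sections*,
where the peripheral ER appears as a band of profiles along the cell
border, or in *cortical sections*, a tangential view of the peripheral
tubule/sheet network.

The package has three analysis stages and one synthetic-data stage:

1. **Mid-section pipeline** — segment cells from the BFP channel, refine
   each cell border with a minimum-volume enclosing ellipse fitted to its
   segmented ER, and compute three ER-size metrics.
2. **Cortical classifier** — segment each marker channel with ring-kernel
   contrast tests and classify the ER into tubules, sheets and tubular
   clusters via a trimming-factor morphological opening.
3. **Screen scoring** — normalize per-field measurements across plates,
   correct smooth covariate trends by local regression, compute Z scores
   against per-plate background populations, aggregate per sample and call
   hits with a 2-of-3-metric rule.
4. **Synthetic microscopy generator** — seeded renderings of all channels
   with exact ground-truth masks, used by every test in the package.

# The three mid-section metrics

For a cell with fitted border ellipse $E$, the periphery band $B$ is the
set of pixels inside $E$ whose distance to the border, measured along the
ray from the ellipse center, is at most $w$ (default $w = 5$ px). With
segmented ER mask $M$:

* **peripheral ER size** $= |M \cap B| \, / \, |B|$ — the fraction of the
  periphery occupied by ER;
* **ER profile size** $=$ mean area of the 8-connected components of
  $M \cap B$, divided by $|B|$;
* **ER gaps per µm** $=$ number of 8-connected components of
  $B \setminus M$ per micrometre of periphery, where the periphery length
  is the Ramanujan perimeter of the band's centerline ellipse (semi-axes
  reduced by $w/2$) times the pixel size (default 0.108 µm/px, a 60×
  objective on an sCMOS-class camera).

Two refinements keep the gap count meaningful on real (noisy) masks: a gap
component must contain at least `min_gap_area` pixels (default $w$), and it
must span at least 60% of the band radially. Without the radial-span rule,
a fitted ellipse that sits half a pixel outside the true border converts
the outermost ring of the band into a long, one-pixel-thin "gap" sliver.
Both rules leave the closed-form cases untouched: a fully covered band
yields exactly $(1, 1, 0)$ and an empty ER mask yields one gap spanning
the whole band.

## Mid-section processing chain

The chain mirrors widefield screening practice:

* best focal slice = the slice with maximal intensity standard deviation
  (BFP for the field, curvature channel for the per-cell refinement), ties
  to the lowest index;
* FFT bandpass (annular mask retaining feature wavelengths of 2–40 px,
  a deliberately wide default since border ridges are 2–5 px) to enhance
  border contrast;
* Frangi vesselness (scales 1, 1.5, 2 px) + Otsu threshold for the border
  mask; a 3×3 opening removes speckle and a minimum-size filter removes
  vacuole-scale rings; a disk closing (radius 2) seals small breaks so
  interiors stay enclosed;
* enclosed interiors become cell objects; objects dimmer than
  median − 2·MAD of the object mean BFP are discarded (MAD scaled by
  1.4826, the robust-SD convention); touching cells are split by a
  distance-transform watershed; labels are then grown 3 px (never past the
  Voronoi midline to a neighbour) to recover the border-ridge thickness;
* per cell, the ER is segmented in both marker channels as
  (tubeness > 0.6·Otsu of the tubeness response) ∧
  (intensity > 0.8·Otsu of the channel). The intensity gate matters: a
  multi-scale ridge detector interpolates across genuine gaps in the band,
  while raw intensity inside a gap stays near background. The two
  multipliers are fixed package defaults calibrated on the synthetic
  generator — the source method tuned its thresholds on the original
  images, which are not available;
* the minimum-volume enclosing ellipse (Khachiyan's algorithm, tolerance
  10⁻³ by default; the final shape matrix is scaled minimally so all
  points are enclosed despite finite iteration) of the combined ER mask
  defines the refined border; ER collection is confined to the cell's
  Voronoi region, dilated at most 8 px from its label.

Cells whose ER mask is empty are dropped with a message. A final
population filter keeps cells whose every measurement (area, roundness,
both marker intensities, three metrics) lies within 2.5 SD of the
population mean, applied in a single pass; iterating the filter would
progressively shrink the population with no clear stopping rule, and on
unimodal populations one pass removes the segmentation failures it is
meant to catch.

# Cortical classification

Each channel is rolling-ball background-subtracted (ball radius 50 px,
computed on a downsampled image for large radii, as ImageJ does) and
stretched to [0, 1] between its 0.1 and 99.9 percentiles. Segmentation
applies two passes of a ring-kernel contrast test: a pixel is kept when
its 3×3-median-filtered intensity exceeds the mean over a surrounding
annulus of radius $r$ (inner radius $r$, outer $r+1$) by more than a
`strength` margin, and also exceeds the channel's Otsu threshold scaled by
a background multiplier. The small pass ($r = 2$, strength 0.02) targets
tubules, the large pass ($r = 6$, strength 0.01) targets sheets; their
union is the channel's total ER mask. Because a feature much wider than
the ring radius matches its own ring mean, the large pass detects big
sheets only near their rim; enclosed holes are therefore filled — for the
general channel only, since the curvature marker legitimately draws
closed rings (rims) whose interiors must stay empty.

Classification separates the general-marker total mask with a disk opening
of radius `trimming_factor` (default 3): surviving features are
provisional sheets, the remainder tubules. Plain opening is used rather
than opening followed by morphological reconstruction: binary
reconstruction floods an entire connected component from any surviving
seed, so the moment a tubule network touches one sheet patch the whole
network would be designated sheet. Plain opening preserves the
granulometry property exactly (provisional-sheet area is non-increasing
in the trimming factor), at the cost of slightly rounded sheet outlines.

Tubular clusters — dense tubule regions that look sheet-like in the
general marker — are identified per provisional-sheet component: the
component is a cluster when its 2-px-eroded core is at least 50%
curvature-marker-positive. A genuine sheet carries the curvature marker
only on a 1–2 px rim, so its core is dark in that channel. (An opened
version of the curvature mask was tried first and failed in both
directions: rim-plus-tubule ribbons along sheet edges survive a radius-3
opening and erode the sheet class, while true clusters are partly hollow
in the ring-segmented curvature mask and get missed.) Clusters are
subtracted from the sheets and added to the tubules, so
tubules ∪ sheets = total mask exactly and the two classes are disjoint on
every field.

ER masks are computed on whole images and assigned to cells afterwards;
any integer label mask is accepted (an external segmenter's output, the
generator's truth labels, or the built-in fallback
`segment_cortical_cells()`, which runs the bright-field chain: Gaussian
blur σ = 2 → 2× downscale → tubeness σ = 1 → upscale → Otsu → watershed).
Population summaries are medians across all cells.

All thresholds are Otsu-relative and the strength margins act on
[0, 1]-normalized intensities, so multiplying both channels by any
constant changes per-cell fractions by well under one percentage point.

# Screen scoring

One row per (plate, well, field of view); two fields per well and
duplicate untreated controls per plate reflect the acquisition design.
Fields with fewer than 25 analyzed cells are dropped. The scoring order
follows the source procedure literally:

1. marker intensity: per-plate mean centering, then local-regression
   correction against mean cell area and against cell count (bigger cells
   are brighter; crowded fields have higher overall fluorescence);
2. the **background population** (BP) of a plate = rows whose corrected
   intensity lies within 1.5 SD of the plate mean — most deletions do not
   affect ER expansion, so the bulk of a plate serves as its own
   reference;
3. per metric, Z = (value − BP mean) / BP SD with the row's plate BP;
   then per-plate local-regression correction of Z against well order
   (imaging a plate takes tens of minutes) and against cell count;
4. per sample and metric, the field-level Z of maximal absolute value is
   retained **with its sign**. A plain maximum would mask underexpansion
   hits, which are negative by construction; the signed max-magnitude
   reading keeps one aberrant field sufficient to flag a sample in either
   direction;
5. hits: peripheral ER size and ER profile size flag at Z < −2, ER gaps
   at Z > +2 (strict inequalities); a sample is a hit when at least two of
   the three metrics flag.

Local regression is `stats::loess` with tricube weights, span 0.3,
degree 2 and two redescending robustness iterations. Degree 2 rather than
a local-linear fit: at span 0.3 a degree-1 fit leaves a correlated
residual (≈ 0.14 correlation with a sinusoidal trend at n = 1000) because
straight segments underfit curvature at trend extrema; the quadratic local
fit removes it completely and is `loess`'s own default.

Because the BP statistics are computed before the well-order and
cell-count corrections, the corrected null Z has standard deviation
$\sigma_{resid} / \sqrt{\sigma_{resid}^2 + \sigma_{trend}^2}$ < 1. The
procedure is therefore well calibrated only when systematic trends are
subdominant to residual scatter — which is also the regime in which
Z-scoring against an uncorrected reference population is sensible at all.
The synthetic screen's default trend amplitudes (0.015 metric units,
30% of the 0.05 residual SD) respect that regime; with them the null
per-field Z has mean ≈ 0 and SD ≈ 0.95, the per-metric tail exceedance
after 2-field aggregation is ≈ 3.5% (the signed max-magnitude of two unit
normals has SD $\sqrt{1 + 2/\pi} \approx 1.28$, so tails inflate above
the nominal 2.3%), and the 2-of-3 hit rate stays below 1%.

# The synthetic generator

The generator stands in for the study's raw images, which were not
deposited. It renders, per field, bright-field, cytosolic BFP, general ER
and curvature ER channels with ground truth recorded before blur and
noise:

* **cells**: non-overlapping ellipses (aspect ratio ≤ 1.5, semi-major
  axis 15–25 px ≈ 1.6–2.7 µm — diploid-sized), placed by bounded
  rejection sampling;
* **mid sections**: the ER band runs along the cell border with thickness
  equal to the 5-px periphery definition, so the spec'd band coverage *is*
  the ground-truth peripheral ER size; gaps are `n_gaps` disjoint angular
  arcs totalling (1 − coverage) of the circumference, evenly spaced with
  jitter (each arc must rasterize to ≥ 2 px or the spec is rejected as
  infeasible); a five-slice z-stack (1 µm spacing) blurs away from the
  designated focus slice;
* **cortical sections**: sheets are smoothed elliptical patches placed to
  a target cortex fraction (±0.05 placement tolerance, error if
  unreachable); tubules are persistent random walks dilated to a 3-px
  width, added until their target fraction is met; optional dense
  tubular-cluster patches are curvature-positive throughout, whereas
  sheets receive only a 1–2 px curvature rim (interiors eroded by 2 px
  stay < 1% positive before noise);
* **optics and noise**: Gaussian PSF (σ = 1 px in focus, growing 1.5 px
  per µm of defocus with mild attenuation), optional Poisson shot noise,
  Gaussian read noise (default 5% of amplitude), channel-wise
  normalization to [0, 1];
* **determinism**: every random quantity derives from the spec's single
  seed through fixed Lehmer sub-streams (one per cell), so an identical
  spec reproduces byte-identical output.

The screen simulator draws each metric as global mean + plate offset +
smooth sinusoidal trends in cell size, cell count and well order +
planted effect (in residual-SD units) + Gaussian residual, with
marker intensity carrying the plate/size/count structure that the
normalization stage is supposed to remove.

What the generator does **not** emulate: photorealistic optics (no 3D
PSF, no chromatic aberration), nuclear envelope, vacuole autofluorescence,
cell-cycle morphology (no buds), uneven illumination, or focus failures.
Passing the recovery tests therefore shows that the computation is
faithful to its definitions and robust to blur, Poisson/Gaussian noise and
packing geometry — not that the fixed default thresholds would transfer
to real micrographs without the per-image tuning the original procedure
allowed.

# Numerical choices and edge cases

* Constant (degenerate) images yield empty masks with a warning, never an
  exception; cells with empty ER masks are dropped with a logged reason.
* Otsu thresholds are computed on [0, 1]-clamped images (EBImage's
  `otsu`); the 3×3 median filter quantizes to 16 bits (error ≤ 2⁻¹⁶).
* Profiles and gaps use 8-connectivity; EBImage's 4-connected labelling
  is augmented by a union–find merge over diagonal adjacencies.
* Khachiyan iterations stop when the relative enclosure defect drops
  below the tolerance; the returned ellipse is scaled by the residual
  defect so enclosure is exact. Collinear inputs raise an error.
* The rolling-ball background of a constant image is that constant
  (output exactly zero); output is clamped non-negative.
* Watershed ties and label order follow EBImage; best-slice ties take the
  lowest index; the population filter treats zero-variance measurements
  as always-pass.

# Problem sizes used in the test-suite

The bundled tests run the full pipelines at reduced but non-trivial
scale: mid fields of 256² px with 8 cells across seven coverage/gap
conditions; 20 cortical fields of 256² px spanning sheet fractions 0–0.8;
100 cortical fields of 128² px for the exact partition property; a
16-plate × 300-mutant × 2-field screen (9,664 rows) for null calibration
and a 50-mutant planted-hit recovery; 100 random 5-point sets against a
penalized Nelder–Mead oracle for the minimum-volume ellipse. These sizes
give stable statistics (binomial SE of the hit rate < 0.15 pp) while a
full run stays inside a few minutes.

# Known limitations

* Default segmentation parameters are calibrated on the generator, not on
  real data; on real images the per-image tuning that the semi-automated
  original workflow supported is exposed via the params objects and YAML
  overrides.
* The mid-section border fit degrades when ER covers ≲ 30% of the
  periphery concentrated on one side: a minimum-volume ellipse of a short
  arc is underdetermined. The population filter catches most such cells
  in screen use.
* Merged sheet+cluster components are classified whole; partial
  (sub-component) cluster attribution is not attempted.
* No bud/mother assignment, no 3D segmentation, no time-lapse.
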