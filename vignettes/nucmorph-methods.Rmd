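---
title: "Nuclear morphometric analysis with nucmorph: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nuclear morphometric analysis with nucmorph: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucmorph)
```

## The problem

Several cellular processes leave a signature in nuclear morphology:
senescence enlarges the nucleus while keeping it regular, apoptosis condenses
it into a small near-spherical body, and mitotic catastrophe or other
nuclear-damaging events produce lobed, irregular outlines. Scoring these
phenotypes from DAPI- or Hoechst-stained micrographs is usually done by eye,
which is slow and subjective. `nucmorph` quantifies them: it segments nuclei,
measures five shape descriptors per nucleus, collapses four of them into a
single irregularity score, calibrates what "normal" looks like for the cell
type at hand, and assigns each nucleus to one of seven phenotype classes in
the area-versus-irregularity plane.

## The five measurements and the NII

For a segmented nucleus with pixel set $P$, sub-pixel boundary contour $C$
(the 0.5 iso-level of its binary mask) and spatial calibration $c$
(length units per pixel):

* **Area** $= |P| \cdot c^2$ — pixel count, the particle-analysis convention.
* **Aspect** (Asp) — ratio of major to minor axis of the ellipse with the
  same second central moments as $P$; 1 for a circle, invariant under
  rotation.
* **Area box** (Arbx) $= |P| / (h \cdot w)$ with $(h, w)$ the axis-aligned
  bounding box of $P$; 1 for an axis-aligned rectangle, $\pi/4$ for a
  circle. Deliberately *not* rotation-invariant (the box is axis-aligned): a
  45°-rotated square has Arbx $\approx 0.5$.
* **Radius ratio** (Rr) — maximum over minimum distance from the centroid of
  $P$ to $C$, the minimum taken point-to-segment; 1 for a circle, $a/b$ for
  an ellipse, large for lobed shapes.
* **Roundness** (Rou) $= \mathrm{perimeter}^2 / (4\pi \cdot \mathrm{area})$
  — the isoperimetric quotient, exactly 1 for an ideal circle and larger for
  anything else.

The **Nuclear Irregularity Index** combines the four dimensionless
descriptors:

$$\mathrm{NII} = \mathrm{Asp} - \mathrm{Arbx} + \mathrm{Rr} + \mathrm{Rou}.$$

Area box enters negatively: compact, box-filling shapes score lower. Under
these definitions an ideal circle has
$\mathrm{NII} = 1 - \pi/4 + 1 + 1 \approx 2.215$; elongation raises Asp and
Rr, lobing raises Rr and Rou, so every departure from a regular disk raises
the index.

```{r nii}
computeNII(1, 0.785, 1, 1)
computeNII(2.0, 0.5, 3.0, 1.8)
```

## Perimeter estimation

Raw traced iso-contours carry a half-pixel staircase that overestimates a
circle's perimeter by more than 5% and would push its roundness to ~1.11.
`measurePerimeter()` therefore simplifies the contour with a Douglas–Peucker
tolerance of 0.6 px — about the discretization noise — before summing chord
lengths. Unlike moving-average smoothing, simplification collapses the
staircase into long chords while keeping genuine corners *exactly*, so a
rasterized disk of radius 50 px measures within 2% of $2\pi R$ while a
10×10 px square still measures ~38 (the traced contour of a pixelated
square is an octagon with clipped corners; its analytic length is 38.8, not
40). The result is independent of where the contour tracer started, which
makes the measurement exactly invariant under 90° image rotations. We
evaluated a 3-point moving average first: at a strength sufficient to
suppress the staircase on circles it erodes polygonal fixtures visibly
below their analytic perimeters, so it was rejected.

## Segmentation

The paper-and-pencil workflow this package replaces outlines nuclei
semi-manually; `segmentNuclei()` automates the standard recipe: Gaussian
smoothing (σ = 1 px), automatic Otsu (or fixed) thresholding, hole filling,
connected-component labeling, optional distance-transform watershed to split
touching nuclei, area filtering (default minimum 50 px², excluding debris)
and exclusion of border-touching regions (partial nuclei bias area
downward). Labeling runs on the pixel-adjacency graph, so 4- and
8-connectivity are handled uniformly; labels are deterministic
(raster-scan order). Coordinates are 1-based (row, col) with pixel centers
at integer positions, R's native matrix convention; boundary vertices are
sub-pixel. A flat or empty image yields an all-zero mask with a warning
rather than an error, so batch runs survive blank fields. Watershed
splitting is off by default: it separates touching round nuclei cleanly but
would fragment strongly lobed ones, and the recommended acquisition avoids
confluent fields anyway.

## Reference calibration and the seven classes

Users curate a set of normal nuclei from a control condition (excluding
mitoses and clear abnormalities — the package deliberately does no automatic
curation). `fitReference()` estimates the mean and sample standard deviation
(n−1 denominator, the spreadsheet convention) of area and NII, and stores
three SD multipliers with defaults $k_{\mathrm{area}} = 2$,
$k_{\mathrm{NII}} = 2$, $k_{\mathrm{NII,SI}} = 4$:

| threshold | definition |
|---|---|
| areaLow  | mean area − $k_{\mathrm{area}}$ · SD |
| areaHigh | mean area + $k_{\mathrm{area}}$ · SD |
| niiIrr   | mean NII + $k_{\mathrm{NII}}$ · SD |
| niiSi    | mean NII + $k_{\mathrm{NII,SI}}$ · SD |

The original workflow lets the analyst pick the number of SDs by eye; making
the thresholds deterministic functions of (mean, SD, k) — with k overridable
— trades that freedom for reproducibility. The upper NII bound of the small
class is an independent multiplier (not tied to the irregular cut) because
mitotic figures sit between the normal and strongly-irregular NII ranges;
its default of 4 SD places the small/small-irregular boundary well above the
mitotic band. The small-regular class shares its upper NII bound with the
N/I cut, since apoptotically condensed nuclei are as regular as normal ones.

Classification is a rectangular partition of the (area, NII) plane —
exhaustive, mutually exclusive, with ties resolved toward the
less-pathological class (inclusive ≤ on the normal/regular side):

| class | size | NII | reading |
|---|---|---|---|
| N  | normal | ≤ niiIrr | interphase, undisturbed |
| I  | normal | > niiIrr | mitotic catastrophe / nuclear damage |
| LR | large  | ≤ niiIrr | senescence |
| LI | large  | > niiIrr | damage in large / multinucleated cells |
| SR | small  | ≤ niiIrr | apoptotic condensation |
| S  | small  | (niiIrr, niiSi] | mitosis |
| SI | small  | > niiSi | damaged mitosis / fragments |

The "normal ellipse" drawn by `ellipseOutline()` (center at the reference
means, semi-axes $k \cdot$ SD per axis) is a *visualization* of the
reference cloud; the class boundaries themselves are the rectangles above,
matching the figure convention of rectangular category boxes with an
ellipse overlaying the normal cloud. A single NII cut is used for all sizes:
the data behind the method show large nuclei separating into two groups
around the same irregularity boundary as normal-sized ones, and one cut
keeps the partition interpretable.

`summarizePopulations()` reports per-class counts, percentages (displayed to
one decimal, stored at full precision) and mean area/NII — the numbers
conventionally printed in the boxes of an NMA plot.

## The synthetic generator

`generatePopulation()` renders micrographs with known ground truth so the
entire pipeline can be validated without real images. Each nucleus is a
star-shaped radial-Fourier body,

$$r(\theta) = R\,\Big(1 + \sum_m a_m \cos(m\theta + \varphi_m)\Big),$$

anisotropically scaled by $(\sqrt{e}, 1/\sqrt{e})$ — which makes $e$
exactly the axis ratio of the result — and randomly rotated. The total
perturbation amplitude is split evenly over the requested harmonics, so an
amplitude below 0.5 keeps $r > 0$ and the boundary simple by construction.
$R$ is set analytically from the drawn target area,
$A = \pi R^2 (1 + \sum_m a_m^2/2)$ (the scaling has unit determinant), so
measured pixel areas land within 2% of target for radii ≥ 20 px.
Rasterization is an exact polar inclusion test in the canonical frame, and
standalone shapes are placed at half-integer centers: an integer-centered
disk of radius $R$ spans $2R+1$ pixel rows instead of the generic $2R$, a
degenerate alignment that real nuclei never exhibit.

Scenes place nuclei by rejection sampling of non-overlapping bounding
circles (the acquisition guidance this emulates avoids confluent fields, so
overlap is forbidden rather than modeled), then render with per-nucleus
intensity jitter (±15%), a 1 px Gaussian blur and additive Gaussian read
noise at a configurable SNR (default 20). Everything is reproducible
bit-for-bit from one seed.

The four presets mirror the canonical phenotypes, relative to a normal mean
area $A$ = 2000 px² (a ~25 px-radius nucleus, typical of cultured cells at
moderate magnification):

| preset | area | elongation | amplitude (harmonics) |
|---|---|---|---|
| normal    | $A$, SD 10%  | 1.2  | 0.03 (3–5) |
| senescent | $3A$, SD 10% of $3A$ | 1.2 | 0.03 (3–5) |
| apoptotic | $0.4A$, SD 10% of $0.4A$ | 1.05 | 0.02 (3–5) |
| irregular | $2A$, SD 0.35$A$ (spanning ~1–3$A$) | 1.3 | 0.25 (2–6) |

What the generator does **not** emulate: chromatin texture,
senescence-associated heterochromatin foci, intensity gradients, uneven
illumination, overlapping or out-of-focus nuclei, and mitotic-plate shapes.
Passing the synthetic recovery tests therefore demonstrates that the
measurement-calibration-classification chain is correct, not that
segmentation is robust to every real-world acquisition artifact.

## End-to-end validation

`runPipeline()` chains simulate → segment → measure → calibrate → classify →
summarize from one config (seeded; defaults: 2048² frame, 50 nuclei per
phenotype, SNR 20). The reference is fit on the measured nuclei whose ground
truth is the normal phenotype, mirroring curated-control calibration. With
the default conditions the classifier recovers the generating phenotype for
≥ 95% of nuclei (irregular-phenotype nuclei legitimately land in I *or* LI,
since their generated areas span normal to large), the 25/25/25/25 mixing
proportions are recovered within a few points, and the S (mitotic) class
stays below 1% — no mitotic-like shapes are generated, mirroring the
near-absence of mitoses in senescent cultures.

```{r pipeline, eval = FALSE}
res <- runPipeline(readRunConfig())
res$summary
plotNMA(res$table, res$model, "nma_plot.png")
```

## Numerical choices and degenerate inputs

* Boundaries are traced at the 0.5 iso-level of each region's padded crop;
  the largest contour is kept (holes are filled before labeling) and
  oriented counter-clockwise (positive shoelace area in (row, col)).
* Sample SD uses the n−1 denominator everywhere.
* A reference fit needs n ≥ 3 and non-zero SDs (identical records are
  rejected as degenerate); below 50 nuclei a warning recommends the
  conventional ≥ 100 per condition. A non-positive areaLow is clamped to
  zero with a warning.
* One-pixel-wide regions have a degenerate moment ellipse (minor axis
  < 1 px) and are rejected as debris rather than clamped; failed nuclei are
  reported by warnings, never silently dropped.
* A centroid falling outside a strongly non-convex boundary still yields a
  radius ratio, with a `centroid_outside` flag on the record.
* Roundness can dip a few hundredths below 1 for small rasterized disks;
  values below 0.95 trigger a warning.
* Class boundaries are inclusive toward the less-pathological class, so a
  nucleus exactly on a threshold is called conservatively.

## Problem sizes used in the shipped tests

The shipped validation uses a 2048×2048 frame with 200 nuclei (50 per
phenotype) for end-to-end recovery, 30 nuclei per amplitude level for the
NII monotonicity check, 20 random ellipses for the aspect-recovery
property, and 10,000 random points for the partition sweep — sizes at which
every estimate is stable to well under its test tolerance while the whole
suite runs in well under a minute.

## Known limitations

* Intensity-based features (DNA content, SAHF, texture) are out of scope;
  so are multi-channel stains and 3D stacks.
* Time-lapse data are handled frame by frame; there is no tracking, and
  post-anaphase mitoses count as two nuclei — mitotic proportions are
  indicative, not exact.
* Classification quality is bounded by the curation of the reference set;
  the package will faithfully calibrate on a badly curated one (it warns
  only about sample size and degenerate spreads).
* The ImageJ-dialect CSV reader maps `AR` to Aspect but cannot reconstruct
  the NMA roundness from ImageJ's built-in `Round` (a different quantity);
  it fails loudly rather than miscomputing NII.
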