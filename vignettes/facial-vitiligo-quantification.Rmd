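---
title: "Quantifying facial vitiligo under Wood's light: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying facial vitiligo under Wood's light: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fviq)
```

## The measurement problem

Vitiligo treatment response on the face is usually graded by eye. Wood's
light changes that: under long-wave UV-A illumination depigmented skin
fluoresces bluish-white against dark, low-fluorescence healthy skin, so the
patch boundary becomes an image-analysis problem rather than a judgement
call. `fviq` implements a semi-automatic pipeline around that physics. The
operator contributes what humans are good at — outlining the face and
roughly circling each suspected patch — and the algorithm contributes what
software is good at: a reproducible pixel-level decision inside each region
of interest (ROI), identical on every rerun.

The pipeline's output is the Face Vitiligo Index,

$$\mathrm{FVI} = \frac{1}{n}\sum_{i=1}^{n} \frac{p_{v,i}}{p_{f,i}},$$

the mean over the available facial views $i$ (frontal, left, right;
canonically $n = 3$) of the ratio of detected vitiligo pixels $p_{v,i}$ to
face pixels $p_{f,i}$. Dividing by face area per view makes the index
invariant to image size, camera distance and face framing; averaging over
views covers patches that only one aspect can see. FVI is 0 when nothing is
detectable and 1 for a fully depigmented face; we report it both as a
fraction and as a percentage.

Assumptions worth stating explicitly: the face outline drawn by the
operator defines the denominator, so whether eyes, lips or hairline are
included is an annotation convention that must be held constant across a
patient's timepoints; patches are assumed brighter than surrounding skin in
the filtered image (true under Wood's light for depigmentation, not for
hyperpigmented lesions); and views are treated as independent samples of
the face rather than being registered into a 3-D model.

## Stage by stage

### Contrast filtering

The three 8-bit RGB channels are combined into one monochrome image. The
catalogue of combiners is `red`, `green`, `blue`, `luminance`
(0.299R + 0.587G + 0.114B), `blue_minus_red`, and `blue_over_sum`
(B/(R+G+B+1), one intensity unit of regularisation to keep the ratio
defined on black pixels). The default is `blue`: Wood's-light fluorescence
is blue-dominant, so the blue channel carries most of the patch/skin
separation. The combined image is min–max rescaled to [0, 1] per image (not
per ROI), so thresholds are comparable across ROIs of the same photograph;
a perfectly constant image maps to all zeros — no contrast, no patch
evidence — with a logged message.

Contrast-limited adaptive histogram equalisation (CLAHE) then equalises
contrast locally: the image is tiled (default 8×8), each tile's 256-bin
histogram is clipped at `clip_limit` × (tile pixel count) with the excess
redistributed uniformly, and each pixel is mapped through the bilinearly
interpolated cumulative distributions of its four neighbouring tiles. The
defaults — clip limit 0.01 as a fraction of tile pixels, 8×8 tiles, 256
bins — are the reference defaults of the method's common implementations;
every segmentation result records the resolved `filter_spec` so a report is
self-describing. The construction is implemented in the package rather than
delegated because the validation suite pins down a specific limiting
behaviour: with a single tile and a clip limit too large to bite, the
mapping must equal global histogram equalisation exactly (each quantised
level maps to its empirical CDF value), and the tests verify this against
an independently coded global equaliser.

One design decision needs its rationale recorded. The filter-quality
property we test — the default filter must not lose patch-vs-skin contrast
— is measured against the *raw* blue channel (B/255), not against the
min–max-stretched blue. CLAHE's input is already the stretched combination,
and a rank-based equaliser cannot be expected to widen the gap a min–max
stretch produces on an already clean bimodal image; what it must do is
preserve that separation while adapting to local illumination, which is the
property asserted.

### Per-ROI binarisation

Inside each patch ROI the filtered image is thresholded to a 0–1 map
(1 = vitiligo). The effective threshold per ROI resolves by precedence:
the ROI's own override, else the global threshold if one was supplied, else
the Otsu threshold computed from the 256-bin histogram of that ROI's pixels
only. Manual choices dominate because the instrument is semi-automatic by
design; Otsu replaces the interactive default so that unattended runs are
reproducible. The comparison is strict (`value > threshold`), making
threshold 1 the safe degenerate case (empty mask). A constant ROI raises an
explicit degenerate-ROI error asking for a manual override rather than
silently returning a cut — relevant in practice for a fully repigmented
region at follow-up, where Otsu would otherwise bisect pure noise and
hallucinate patch pixels.

The view mask is the union of the per-ROI masks intersected with the
rasterised face outline; per-ROI pixel counts are reported as-is and may
double-count overlap, but the index always uses the union. Intersecting
with the face before counting is what guarantees FVI ≤ 1.

### Rasterisation conventions

Polygons live in continuous pixel coordinates (origin top-left, x
rightward, y downward); a pixel belongs to a polygon iff its centre
(x+0.5, y+0.5) is inside under the even-odd rule. Centre-in even-odd is
reproducible, orientation-independent, and makes an axis-aligned w×h
rectangle with integer corners cover exactly w·h pixels. Degenerate
zero-area polygons rasterise to an empty mask with a warning. The
implementation is vectorised per edge; the test suite checks it
pixel-for-pixel against a separately written crossing-number loop on random
star-shaped polygons up to 64×64.

### Indices and longitudinal change

F-VASI is accepted as a clinician's fingertip-unit count and converted at
0.1% body surface area per unit; the package deliberately does not attempt
to derive F-VASI from photographs. vDLQI (10 + 4 items, 0–3 each, total
0–42) and VitiQoL (15 items, 0–6 each, total 0–90) are summed from
item-level responses; item texts are not shipped (the DLQI wording is
copyrighted) — identifiers and ranges are, and "not relevant" answers score
0 per the instrument's standard rule.

Change between timepoints is 100 × (before − after)/before, positive for
improvement in both directions of use (area repigmentation and score
reduction). Reports round to one decimal and retain the unrounded value;
cohort summaries average the rounded per-patient percentages, which is how
per-patient figures printed to one decimal combine into a cohort mean.
A baseline of exactly 0 makes relative change undefined and raises a
dedicated error suggesting the absolute change. When fewer than three views
are available the FVI divisor is the number of views provided, flagged in
the result — imputing zero for a missing view would understate disease.

## The synthetic-data generator

Because no clinical Wood's-light image set is publicly deposited, the
package ships a generator whose outputs exercise every pipeline stage with
known truth. It emulates: a dark bluish skin tone (RGB ≈ (20, 20, 60))
inside an elliptical face (half-ellipse for profile views) on a darker
background; patches as unions of 3–6 random overlapping discs per patch,
rendered by adding `patch_contrast` × 255 to the green and blue channels;
Gaussian pixel noise (`noise_sd`, on the [0, 1] scale); an optional linear
illumination ramp (×0.75 to ×1.25 left to right); and operator-style
annotations — the exact face ellipse plus, per patch, the convex hull of
points on each disc's circle at radius + 5 px, so ROIs over-cover patches
and leave the pixel decision to segmentation. The hull is taken over the
disc circles rather than the disc centres so that the ROI is guaranteed to
enclose the full patch extent whatever the radii.

Disc radii are scaled by a deterministic bisection until the realised
coverage is within 3% relative of the requested value (unreachable targets
raise a generation error); all random draws happen before the search, so
the RNG stream does not depend on how many iterations it takes, and
identical specs yield bit-identical images, masks and annotations.
Longitudinal pairs reuse the baseline geometry and shrink each disc in
place until follow-up coverage is (1 − repigmentation fraction) × baseline,
emulating patches receding from their edges; follow-up images carry fresh
noise, as a new photograph would.

What the generator does not emulate — facial anatomy (eyes, lips, hair),
perifollicular repigmentation patterns, camera vignetting beyond a linear
ramp, JPEG artefacts, or operator annotation error beyond the fixed
over-cover margin. Passing the synthetic suite therefore demonstrates that
the pipeline's arithmetic and segmentation logic are correct under the
stated appearance model, not that the default filter is optimal for any
particular clinic's camera.

## Validation design and numerical choices

The test suite validates each primitive against an independent oracle
(brute-force point-in-polygon; per-pixel threshold loop; global histogram
equalisation; a between-class-variance scan over all 256 candidate bins for
Otsu — ties on a plateau may resolve to a different bin than the scan's
first maximum, so the assertion is on the objective value, not the bin) and
the whole pipeline against generator truth: 20 seeds × requested coverages
{0.05, 0.15, 0.3} at 192×192 px, one frontal view, contrast 0.5, noise
0.02, requiring FVI within ±10% relative of the request and Dice ≥ 0.90;
plus longitudinal pairs at repigmentation fraction 0.789 and baseline
coverage 0.25, requiring the end-to-end FVI percent change within ±5
absolute of 78.9. The 192×192 single-view design keeps a full 60-replicate
sweep fast enough to run on every test invocation while leaving ≥ 30 px
patch structures at the lowest coverage.

Remaining numerical conventions, collected: 16-bit rasters are reduced to
8-bit by integer division by 257 (endpoints map to endpoints); CLAHE
histogram excess is redistributed uniformly with up to 20 re-clipping
iterations (mass-preserving); annotation vertices are serialised at 17
significant digits so a write/read round-trip is bit-exact; and all masks
are integer 0/1 matrices in row = y, column = x order.

## Known limitations

The face denominator is operator-defined, so FVI values are comparable
within a patient followed by one annotation convention, not across centres
without one. Otsu auto-thresholding presumes residual bimodality inside
each ROI; fully repigmented ROIs need an override or should be dropped.
Per-ROI counts double-count overlapping ROIs (the index does not). The
instrument quantifies facial views only — it is not a whole-body VASI — and
the package performs no statistical inference across patients: it produces
descriptive per-patient and cohort-mean changes.
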