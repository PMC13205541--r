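# fviq — quantifying facial vitiligo from Wood's-light photographs

`fviq` measures how much of a patient's face is affected by vitiligo, and how
that changes under treatment, from photographs taken under Wood's light
(long-wave UV-A, 340–365 nm). Depigmented skin fluoresces bluish-white under
this illumination while healthy skin stays dark, which makes patches
segmentable; the package turns that contrast into a reproducible area index.
It is aimed at dermatology research teams who follow vitiligo patients
longitudinally — for example patients who develop vitiligo as an immune-
checkpoint-inhibitor adverse event and are treated with topical JAK
inhibitors — and who need a number, not an impression, for "how much did the
face repigment".

## The method

The detection pipeline is semi-automatic. An operator supplies, per view, a
face-outline polygon and one rough polygon (ROI) around each suspected patch;
the algorithm refines these to pixel level in four steps:

1. **Filtering** — the RGB channels are combined into a monochrome image that
   enhances patch/skin contrast (default: the blue channel, since the
   fluorescence is blue-dominant), then contrast-limited adaptive histogram
   equalisation (CLAHE) is applied.
2. **Binarisation** — the filtered image is thresholded inside each ROI to a
   0–1 map (1 = vitiligo). Each ROI may use its own threshold: an explicit
   per-ROI override, a global value, or an automatic Otsu threshold computed
   from that ROI's intensities.
3. **Area normalisation** — vitiligo pixels are counted and divided by the
   face area of the view, making the result independent of image size,
   resolution and face framing: the ratio *p*<sub>v,i</sub>/*p*<sub>f,i</sub>
   for view *i*.
4. **Face Vitiligo Index** — the per-view ratios are averaged over the
   available views (frontal, left, right):

   FVI = (1/n) Σᵢ *p*<sub>v,i</sub>/*p*<sub>f,i</sub> ∈ [0, 1],

   0 when patches are barely detectable, 1 when the face is fully
   depigmented. Reported both as a fraction and as a percentage.

Around the imaging core the package also provides: F-VASI estimation from
clinician fingertip-unit counts (each unit = 0.1% body surface area), scoring
of the vDLQI (10 DLQI items + 4 vitiligo items, 0–42) and VitiQoL (15 items,
0–90) quality-of-life instruments, longitudinal percent-change reports
(100 × (before − after)/before, positive = improvement), and a synthetic
Wood's-light face generator with ground-truth masks so the whole pipeline can
be validated without clinical images.

## Worked example

Generate a synthetic patient with 20% facial coverage, segment it with the
default filter and automatic thresholds, and compare against ground truth:

```r
library(fviq)
spec <- synthetic_patient_spec(seed = 9, views = "frontal",
                               image_size = c(128L, 128L),
                               coverage_per_view = 0.2)
pat <- generate_patient(spec)
seg <- segment_view(pat$images$frontal, pat$annotations$frontal)
seg
#> <segmentation_result> view 'frontal': 1671 vitiligo px / 8136 face px (3 ROI)
#>   thresholds: 0.6113, 0.5918, 0.5938
face_vitiligo_index(view_index(seg))
#> <fvi_result> FVI = 0.2054 (20.54%) over 1 view(s)
#>   note: fewer than three views; mean taken over available views
dice_coefficient(seg$mask, pat$truth_masks$frontal)
#> [1] 1
```

The three Otsu thresholds (one per ROI) land between the skin and patch
intensity modes, every ground-truth pixel is recovered (Dice 1), and the
measured FVI of 0.2054 equals the generator's realised coverage.

Longitudinal change on the bundled three-patient case series (baseline and
follow-up FVI, F-VASI and questionnaire totals):

```r
reports <- case_series_reports()
reports$P2
#> <change_report> patient 'P2': baseline -> followup
#>   fvi_percent     55.95 -> 11.83     change +78.9%
#>   fvasi             5.1 -> 1.3       change +74.5%
#>   vdlqi              17 -> 14        change +17.6%
#>   vitiqol            73 -> 46        change +37.0%
cohort_summary(reports)
#> fvi_percent       fvasi       vdlqi     vitiqol
#>        91.3        85.9        57.6        68.4
```

So patient 2's face repigmented by 78.9% (FVI 55.95% → 11.83%), and across
the cohort the vDLQI burden fell by a mean 57.6% and VitiQoL by 68.4%.

A thin command-line wrapper over the same functions lives at
`inst/cli/fviq.R` (subcommands `simulate`, `segment`, `index`, `compare`,
`score`, `summary`).

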