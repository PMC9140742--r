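# pupilmetry

Pupil diameter estimation from RGB smartphone eye images.

Pupillometry — measuring pupil size and its dynamics, such as constriction
under light — is of diagnostic value, but it is usually done with infrared
cameras. On ordinary RGB images of dark-irised eyes, the pupil and iris are
nearly the same gray level, so grayscale segmentation fails. `pupilmetry`
implements two color-based pipelines that estimate a per-frame pupil
diameter time series from 80-frame sequences of 333 × 250 eye images, one
per lighting regime, plus the standard Canny/Hough comparison baseline and
a seeded synthetic eye-image generator with ground-truth diameters.

## The two estimators

**CCLPF** (outdoor sunlight). The red channel's 3×3 window means form a
(H−2)×(W−2) *mean matrix* (82,088 entries at the working resolution).
A 5000-entry *dark interval* is read forward from its global minimum,
clamped with a running-minimum filter applied backward (the suffix minimum
s<sub>i</sub> = min<sub>j≥i</sub> x<sub>j</sub>), and scanned upward: the
first consecutive jump above 5 fixes the upper component limit *U*, the
global minimum is the lower limit *L*, and the extraction threshold is
mean(L, U, (L+U)/2) = (L+U)/2. Pixels whose window mean falls below the
threshold form the pupil mask.

**PRSSM** (indoor artificial light with flash). The image is converted to
HSV (hue ∈ [0,180], saturation/value ∈ [0,255]); the saturation cut *t*
sweeps down from 255 in steps of 5, and at each stage the pixel growth
ratio

&nbsp;&nbsp;&nbsp;&nbsp;G<sub>n</sub> = (P<sub>n</sub> − P<sub>n−1</sub>) / S

(P<sub>n</sub> = pixels with saturation ≥ t<sub>n</sub>, S = total pixels)
is evaluated. The sweep stops at the first decline G<sub>n</sub> <
G<sub>n−1</sub> — just after the flash-lit pupil's tight saturation cluster
has been swallowed — and that stage's cut defines the mask.

Both pipelines then share the same back half: morphological opening with a
10×10 element (removing the specular highlight), 8-connected outer
contours, diameter = the largest contour's bounding-box extent, and a
rule-of-thumb temporal correction (tolerance 10 px outdoors, 5 px indoors)
that carries the previous accepted diameter through outlier frames.

## Worked example

```r
library(pupilmetry)

# 80-frame indoor-flash sequence, true diameter decaying 90 -> 45 px
seqd   <- generate_eye_sequence(n = 80, scene = eye_scene(mode = "indoor"), seed = 7)
series <- run_prssm(seqd$frames)
head(tibble::as_tibble(series), 5)
#>   frame_index raw_px corrected_px flagged substituted
#> 1           0     86           86 FALSE   FALSE
#> 2           1     83           83 FALSE   FALSE
#> 3           2     82           82 FALSE   FALSE
#> 4           3     82           82 FALSE   FALSE
#> 5           4     79           79 FALSE   FALSE

glance(evaluate_diameters(series, seqd$truth))
#>   n_frames max_error_px mean_error_px
#> 1       80         9.01          5.03
```

The first frame's true diameter is 90 px; the estimate 86 px reflects the
small negative bias of bounding-box measurement on blurred boundaries.
Over the whole constriction the corrected series stays within 9 px of
truth (mean 5 px). `autoplot(series)` draws the raw and corrected series;
`autoplot(evaluate_diameters(...))` draws the per-frame error curve.

A thin command-line interface wraps the same functions:

```sh
Rscript inst/cli/pupilmetry.R synth   --dir frames --mode indoor --frames 80 --seed 7
Rscript inst/cli/pupilmetry.R analyze --dir frames --out pred.csv --algorithm prssm
Rscript inst/cli/pupilmetry.R eval    --pred pred.csv --truth frames/truth.csv
```

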