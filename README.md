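# alrls — adaptive localizing region-based level sets with CNN speed compensation

Region-based active contours segment dark, air-filled cavities bounded by
bright bone — the maxillary sinus on CT is the motivating case — by
expanding a level-set contour from a seed inside the cavity until local
intensity statistics balance at the wall.  When the cavity contains bright
lesions (mucosal thickening, polyps), the contour stalls on the first
lesion edge it meets: a local minimum that can exclude half of the true
cavity.  `alrls` implements the fixed-parameter localizing level set (FLS)
together with an adaptive escape mechanism: contour points whose motion has
ceased are classified from their local 10×10 image patch by a small
convolutional network (cavity wall, probability `p1`, vs. lesion, `p2`);
ambiguous calls (`|p1 − p2| ≤ 0.2`) are dropped, wall points keep their
status to the end of the run, and lesion points receive a sustained outward
speed compensation

    exp(|λ1 + λ2|^(1/2)) · ((1 + p2)/(1 + p1) − 1/2) ≥ 0

added to the local data integrand, which carries the contour through the
lesion to the true wall.

The localized energies are the uniform-modelling (Chan–Vese) residual
`λ1 (I − u_x)² − λ2 (I − v_x)²` and the mean-separation variant with
area-normalized residuals, where `u_x`, `v_x` are the interior/exterior
means inside a disk around each contour point.  Since the clinical data the
method targets are not redistributable, the package includes a synthetic
sinus-phantom generator (dark irregular cavity, bright wall, wall-attached
heterogeneous lesions, bias field, noise) with exact ground truth, plus the
CLAHE patch-preprocessing pipeline, elastic/affine patch augmentation, a
pure-R/Rcpp trainable CNN (batch norm, leaky ReLU, SGD with moving-average
weights), and a Dice/CI evaluation harness.

## Worked example

```r
library(alrls)

## a phantom with two large wall-attached lesions (the stalling regime)
ph   <- generateCohort(1, "stalling", seed = 11)[[1]]
seed <- seedPoint(ph)

## fixed-parameter localizing level set: stalls on the lesion edges
fls <- runSegmentation(phantomImage(ph), seed$center, 5, runConfig())
diceCoefficient(segMask(fls), cavityMask(ph))
#> [1] 0.579

## train the patch classifier on a phantom cohort, then compensate
coh     <- generateCohort(16, "stalling", seed = 301)
patches <- augmentPatchSet(harvestPatches(coh, 1500, seed = 302), 2, seed = 77)
cnn     <- trainCNN(buildCNN(cnnSpec(), seed = 5),
                    patches, trainingConfig(max_steps = 1200))
tail(cnn$log$val_accuracy, 1)
#> [1] 0.882

alr <- runSegmentation(phantomImage(ph), seed$center, 5,
                       runConfig(compensation_enabled = TRUE), cnn$model)
diceCoefficient(segMask(alr), cavityMask(ph))
#> [1] 0.871
table(stalledLog(alr)$decision)
#>          ambiguous        compensated confirmed_boundary
#>                  6                 35                119
```

The first Dice (0.58) is the stalled baseline: the contour stopped on the
lesion edges and the missing lesion-occluded area counts against it (the
ground truth is the full cavity).  After compensation the contour has
passed through the lesions and settled on the bone wall (0.87; at the
full 3000-step training scale the cohort mean reaches ~0.91).  The
stalled-point log records every classifier decision (iteration, location,
`p1`, `p2`, verdict).

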