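# muscleseg

Automated thigh-muscle segmentation and fat-fraction quantification for
fat–water decomposition (Dixon) MRI.

## What it does

Intramuscular fat infiltration — in neuromuscular disease, metabolic
disorders and sarcopenia — can be quantified noninvasively from Dixon MRI,
which reconstructs separate water (W) and fat (F) magnitude images so that
the per-voxel fat fraction is simply

    FF = F / (W + F)

The bottleneck is segmentation: manually outlining whole-volume muscle
groups takes hours per scan. `muscleseg` implements a fully automated
pipeline for the four functional thigh muscle groups — quadriceps femoris
(ROI1), sartorius (ROI2), gracilis (ROI3), hamstrings (ROI4):

1. **Split** bilateral volumes into left/right thigh volumes.
2. **Preprocess** the water image: K-means intensity clustering removes
   subcutaneous fat, an order-statistic filter strips the skin rim, holes
   are filled and the mask dilated.
3. **Segment** with a two-channel (water + fat) slice-wise U-net,
   channels min–max normalized to [0, 1]; per-ROI probability maps are
   binarized at 0.5 with an argmax tie-break. The network (conv/pool/
   upsample forward and backward passes, Adam) is implemented in
   RcppArmadillo and trains on an ordinary CPU.
4. **Postprocess**: per ROI, keep only the largest 3D connected
   component.
5. **Quantify**: FF maps on original intensities; per-ROI meanFF (%) and
   volume (mm³).
6. **Evaluate**: volumetric Dice, percent volume difference, meanFF
   difference, ICC(2,1) scan–rescan reproducibility with 95% CI, and a
   one-tailed Welch t-test for normal-vs-infiltrated group comparison.

Because real labelled Dixon scans cannot ship with a package, `muscleseg`
includes a synthetic bilateral-thigh phantom generator with exact known
ground truth (skin ring, subcutaneous fat ring, four muscle-ROI sectors
with configurable fat fractions, bone, Gaussian noise, scan–rescan
repositioning), used by the test-suite and the acceptance analysis to
exercise the pipeline end to end. See the methods vignette
(`vignettes/muscleseg-methods.Rmd`) for the model, parameter rationale and
limitations.

## Worked example

```r
library(muscleseg)

# a noise-free bilateral phantom with known fat fractions
spec <- phantomSpec(roiFatFraction = c(0.05, 0.10, 0.20, 0.30),
                    noiseSigma = 0)
ph <- generatePhantom(spec)
ph$volume
#> FatWaterVolume 64 x 128 x 12 voxels @ 1 x 1 x 6 mm [bilateral]
#>   water range [0, 100], fat range [0, 90]

# split, preprocess one thigh
halves <- splitThighs(ph$volume)
mask <- muscleMaskFromWater(waterImage(halves$left))
mask
#> MuscleRegionMask: 16176 of 49152 voxels retained
#>   - kmeans (k=2): kept cluster 2/2, 14208 voxels
#>   - order-statistic filter (5x5, rank 7): 12096 voxels
#>   - slice-wise hole filling: 13440 voxels
#>   - disc dilation (radius 2): 16176 voxels

# quantify with ground-truth masks: meanFF recovers the specification
quantifyVolume(ph$volume, ph$labels)
#>   roi n_voxels n_undefined volume_mm3 mean_ff_percent
#> 1   1    10320           0      61920               5
#> 2   2     1440           0       8640              10
#> 3   3     1488           0       8928              20
#> 4   4     8496           0      50976              30
```

`volume_mm3` is voxel count × voxel volume (here 1 × 1 × 6 mm³);
`mean_ff_percent` equals the prescribed per-ROI fat fractions exactly
because the phantom's signal model is W = I(1−FF), F = I·FF.

Training and applying the segmenter end to end (phantom cohort →
preprocessing → U-net → postprocessing → report):

```r
res <- runPipeline(pipelineConfig(
  seed = 1,
  phantom = list(nTrainSubjects = 20, nTestSubjects = 5),
  unet = list(depth = 3, baseFilters = 16, epochs = 25,
              learningRate = 1e-3)))
res$report$summary$mean_dice
#> [1] 0.9702747   # average 3D Dice over 4 ROIs x 10 held-out thigh volumes
```

A thin CLI wraps the same functions:
`exec/muscleseg <phantom|preprocess|train|segment|postprocess|quantify|icc|compare-groups|run>`.

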