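# tomoQC — quality assessment for cellular cryo-electron tomography

Cellular cryo-ET projects routinely reconstruct hundreds of tomograms whose
usefulness for annotation varies enormously; screening them is usually done
by eye. **tomoQC** scores every 2-D z-slice of a tomogram with a residual
convolutional regressor trained on category-labeled slices — the label being
the width in pixels of the smallest reliably discernible biological feature
(no-feature, 6+, 4–5, 3, 2, 1 px, mapped to targets 0.0–1.0 in steps of
0.2) — and condenses the per-slice profile into two numbers:

* **estimated thickness** `T = #{ i : s_i > 0.2 }` — the count of slices
  whose score exceeds the feature-presence threshold (0.2 is the score of
  the coarsest feature-bearing category), convertible to nm via the voxel
  size;
* **TomoScore** `= mean(s_i : s_i > 0.2)` — the average quality of the
  feature-bearing slices, 0 for a tomogram revealing no cellular structure,
  1 for a hypothetically perfect one.

Around this core the package provides everything needed to exercise the
method end to end without any deposited data: MRC2014 volume/movie-stack
I/O, a synthetic generator of labeled slices, depth-graded tomograms and
multi-frame tilt movies, even/odd frame-split dose fractionation with
Fourier ring correlation, label smoothing / augmentation / balanced
sampling / tomogram-level partitioning, RANSAC thickness regression, and
log2 dose–response analysis.

## A worked example

```r
library(tomoQC)

cfg    <- synthConfig(seed = 42)                       # 128-px study conditions
corpus <- synthTrainingSet(100, cfg, seed = 42)        # 600 labeled slices
model  <- trainModel(buildNetwork(miniNetConfig(seed = 7)), corpus)

tomo   <- makeTomogram(40, 24, "1px", cfg, seed = 1234)  # held-out tomogram
report <- tomoReport(tomo$volume, model, tomogramId = "demo")
report
#> TomoReport 'demo': TomoScore 0.621, thickness 24 slices (31.8 nm), threshold 0.20
```

The generator placed a 24-slice cell band in a 40-slice volume; the trained
model recovers all 24 feature-bearing slices, and the TomoScore of ~0.6
reflects a band whose quality degrades from 1-px features at the center to
6+-px at the cell boundary. Profiles correlate strongly with the
generator's smoothed targets:

```r
prof <- predictVolume(model, tomo$volume)
pearsonProfile(prof, smoothProfile(categoryToScore(categories(tomo$truth))))
#> $r
#> [1] 0.978  (status "ok", p = 1.2e-27)
```

Even/odd half-dose renders of the same tomogram (200 e⁻/Å² each, the two
halves of a 400 e⁻/Å² acquisition) score consistently — every per-slice
difference stays below 1/6, the step size of the human categorization:

```r
ev <- renderVolumeAtDose(tomo$volume, 200, seed = 555)
od <- renderVolumeAtDose(tomo$volume, 200, seed = 556)
evenOddConsistency(predictVolume(model, ev), predictVolume(model, od))
#> $maxDiff     0.075
#> $withinHumanStep TRUE
```

A shell front end over the same functions lives at
`inst/scripts/tomoscore-cli.R` (`simulate`, `train`, `score`, `split-dose`,
`frc`, `validate`).

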