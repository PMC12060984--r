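# Shared fixtures. The trained mini model is expensive (~1 min) and is
# cached for the whole test session; everything downstream (profiles,
# reports, consistency checks) reuses it.

.fixtures <- new.env(parent = emptyenv())

# Study conditions: 128-px slices, default category blur/noise ladders.
studyConfig <- function() synthConfig(seed = 42L)

# Mini quality model trained on the balanced synthetic corpus
# (100 slices per category, 10 epochs, batch 8).
trainedMini <- function() {
  if (is.null(.fixtures$model)) {
    cfg <- studyConfig()
    corpus <- synthTrainingSet(100L, cfg, seed = 42L)
    .fixtures$model <- trainModel(buildNetwork(miniNetConfig(seed = 7L)),
                                  corpus)
  }
  .fixtures$model
}

# Held-out synthetic tomogram (never used in training): 40 slices with a
# centered 24-slice cell band peaking at the finest category.
heldoutTomogram <- function() {
  if (is.null(.fixtures$heldout))
    .fixtures$heldout <- makeTomogram(40L, 24L, "1px", studyConfig(),
                                      seed = 1234L)
  .fixtures$heldout
}

# Lightweight labeled slice for bookkeeping tests (sampling, augmentation,
# partitioning) where pixel content is irrelevant.
fakeLabeledSlice <- function(category, id = "t1", z = 0L,
                             px = matrix(as.numeric(1:16), 4, 4)) {
  new("LabeledSlice",
      slice = new("SliceImage", pixels = px, apix = 1),
      tomogramId = id, zIndex = as.integer(z), category = category,
      target = categoryToScore(category))
}

# Full width at half maximum of a 1-D profile, linear interpolation at the
# half-maximum crossings: the oracle for "smallest discernible feature
# width" on noiseless renders.
profileFWHM <- function(p) {
  i <- which.max(p)
  half <- p[i] / 2
  right <- i
  while (right < length(p) && p[right + 1] > half) right <- right + 1
  left <- i
  while (left > 1 && p[left - 1] > half) left <- left - 1
  rfrac <- if (right < length(p)) (p[right] - half) / (p[right] - p[right + 1]) else 0
  lfrac <- if (left > 1) (p[left] - half) / (p[left] - p[left - 1]) else 0
  (right + rfrac) - (left - lfrac)
}
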