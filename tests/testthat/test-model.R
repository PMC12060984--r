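test_that("network outputs are sigmoid-bounded and seed-deterministic", {
  cfg <- miniNetConfig(seed = 3L, inputSize = 32L)
  m1 <- buildNetwork(cfg)
  m2 <- buildNetwork(cfg)
  expect_identical(m1@params, m2@params)
  set.seed(1)
  s <- matrix(rnorm(32 * 32), 32, 32)
  p <- predictSlice(m1, s)
  expect_gt(p, 0)
  expect_lt(p, 1)
  expect_identical(predictSlice(m1, s), predictSlice(m1, s))
  expect_error(predictSlice(m1, matrix(0, 16, 16)), "input size")
})

test_that("batched and single-slice predictions agree exactly", {
  m <- buildNetwork(miniNetConfig(seed = 3L, inputSize = 32L))
  cfg <- synthConfig(sliceSize = 32L, seed = 5L)
  mats <- lapply(1:5, function(i)
    pixels(normalizeSlice(makeSlice("3px", cfg, seed = i)@slice)))
  batch <- tomoQC:::.predictMatrixBatch(m, mats)
  singles <- vapply(mats, function(x) predictSlice(m, x), numeric(1))
  expect_equal(batch, singles, tolerance = 1e-12)
})

test_that("analytic gradients match finite differences", {
  # tiny net, tiny input: the full backward pass against central differences
  m <- buildNetwork(miniNetConfig(seed = 21L, inputSize = 32L))
  set.seed(22)
  x <- array(rnorm(32 * 32 * 1 * 2), c(32, 32, 1, 2))
  y <- c(0.2, 0.9)
  # give the zero-init head non-trivial weights so gradients flow everywhere
  m@params[[length(m@params)]]$w[] <- rnorm(32, sd = 0.3)
  loss <- function(params) {
    s <- plogis(tomoQC:::.forwardNet(m@layers, params, x)$logits)
    mean((s - y)^2)
  }
  fw <- tomoQC:::.forwardNet(m@layers, m@params, x, keepCache = TRUE)
  s <- plogis(fw$logits)
  dlogit <- matrix(2 * (s - y) * s * (1 - s) / 2, 1L)
  gr <- tomoQC:::.backwardNet(m@layers, m@params, fw$caches, dlogit)
  eps <- 1e-5
  for (li in c(1L, 2L, 3L, length(m@params))) {    # conv, res, down, fc
    if (is.null(gr[[li]])) next
    nm <- names(gr[[li]])[1]
    for (k in c(1L, length(m@params[[li]][[nm]]))) {
      pp <- m@params
      pp[[li]][[nm]][k] <- pp[[li]][[nm]][k] + eps
      up <- loss(pp)
      pp[[li]][[nm]][k] <- pp[[li]][[nm]][k] - 2 * eps
      dn <- loss(pp)
      expect_equal(gr[[li]][[nm]][k], (up - dn) / (2 * eps),
                   tolerance = 1e-4)
    }
  }
})

test_that("training drives MSE down and is reproducible from the seed", {
  cfg32 <- synthConfig(sliceSize = 32L, seed = 11L)
  train <- synthTrainingSet(6L, cfg32, seed = 11L)
  nc <- miniNetConfig(seed = 2L, inputSize = 32L, epochs = 4L)
  mA <- trainModel(buildNetwork(nc), train)
  mB <- trainModel(buildNetwork(nc), train)
  expect_identical(mA@lossHistory, mB@lossHistory)
  expect_lte(mA@lossHistory[4], mA@lossHistory[1])
  expect_error(trainModel(buildNetwork(nc), list()), "non-empty")
})

test_that("a constant-target dataset is fitted to near-zero MSE", {
  cfg32 <- synthConfig(sliceSize = 32L, seed = 13L)
  slices <- lapply(1:24, function(i) {
    ls <- makeSlice(qualityCategories()[(i %% 6) + 1], cfg32, seed = 100 + i)
    initialize(ls, target = 0.5)
  })
  m <- trainModel(buildNetwork(miniNetConfig(seed = 4L, inputSize = 32L,
                                             epochs = 5L)), slices)
  expect_lt(m@lossHistory[5], 0.01)
})

test_that("a mini net separates featureless from finest-category slices", {
  cfg32 <- synthConfig(sliceSize = 32L, seed = 17L)
  mk <- function(cat, seeds) lapply(seeds, function(s)
    makeSlice(cat, cfg32, seed = s))
  train <- c(mk("no-feature", 1:20), mk("1px", 21:40))
  m <- trainModel(buildNetwork(miniNetConfig(seed = 5L, inputSize = 32L,
                                             epochs = 10L)), train)
  heldNo <- predictSlices(m, lapply(mk("no-feature", 101:110),
                                    function(x) pixels(normalizeSlice(x@slice))))
  held1 <- predictSlices(m, lapply(mk("1px", 111:120),
                                   function(x) pixels(normalizeSlice(x@slice))))
  ranking <- mean(outer(held1, heldNo, ">"))   # pairwise ranking accuracy
  expect_gt(ranking, 0.9)
})

test_that("volume prediction yields one in-range score per z-slice", {
  m <- buildNetwork(miniNetConfig(seed = 3L, inputSize = 32L))
  cfg <- synthConfig(sliceSize = 32L, seed = 19L)
  tg <- makeTomogram(20L, 10L, "2px", cfg, seed = 6L)
  prof <- predictVolume(m, tg$volume, tomogramId = "x")
  expect_s4_class(prof, "QualityProfile")
  expect_length(scores(prof), 20L)
  expect_true(all(scores(prof) > 0 & scores(prof) < 1))
  expect_equal(apix(prof), cfg@apix)
  # oversized slices are center-cropped with the training preprocessing
  big <- new("TomoVolume", voxels = array(rnorm(2 * 48 * 48), c(2, 48, 48)),
             apix = 1)
  expect_length(scores(predictVolume(m, big)), 2L)
  small <- new("TomoVolume", voxels = array(0, c(2, 16, 16)), apix = 1)
  expect_error(predictVolume(m, small), "smaller|input size")
})

test_that("the 101-layer bottleneck backbone constructs at 960-px input", {
  m <- buildNetwork(netConfig("101-layer", inputSize = 960L, seed = 1L))
  expect_s4_class(m, "QualityModel")
  # bottleneck stages 3 + 4 + 23 + 3 plus stem, pool, feature norm and head
  expect_length(m@layers, 37L)
  expect_identical(m@layers[[2]]$type, "bneck")
  rm(m)
  gc(verbose = FALSE)
})

test_that("checkpoints round-trip through disk", {
  m <- buildNetwork(miniNetConfig(seed = 3L, inputSize = 32L))
  p <- withr::local_tempfile(fileext = ".rds")
  saveModel(m, p)
  m2 <- loadModel(p)
  expect_identical(m2@params, m@params)
  expect_identical(m2@config, m@config)
})
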