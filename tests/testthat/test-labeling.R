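test_that("the category-to-score ladder is the fixed 0.2-step mapping", {
  expect_identical(categoryToScore("3px"), 0.6)
  expect_identical(categoryToScore("1px"), 1.0)
  expect_identical(categoryToScore("no-feature"), 0.0)
  expect_equal(categoryToScore(qualityCategories()), seq(0, 1, by = 0.2))
  # strictly increasing in feature fineness
  expect_true(all(diff(categoryToScore(qualityCategories())) > 0))
  expect_error(categoryToScore("7px"), "unknown category")
})

test_that("profile smoothing convolves with a normalized Gaussian kernel", {
  # constants are preserved exactly (kernel sums to 1, reflective edges)
  expect_equal(smoothProfile(rep(0.4, 25), sigma = 3), rep(0.4, 25))
  # unit impulse: center output equals g(0) / sum g over the +-3 sigma window
  n <- 41L
  imp <- numeric(n)
  imp[21] <- 1
  g <- dnorm(-9:9, sd = 3)
  expect_equal(smoothProfile(imp, sigma = 3)[21], g[10] / sum(g),
               tolerance = 1e-12)
  # monotone step stays monotone (positive kernel, no overshoot)
  step <- c(rep(0, 20), rep(1, 20))
  sm <- smoothProfile(step, sigma = 3)
  expect_true(all(diff(sm) >= -1e-12))
  expect_true(all(sm >= 0 & sm <= 1))
  expect_length(sm, 40L)
  # length preserved on short inputs too
  expect_length(smoothProfile(c(0.2, 0.8), sigma = 3), 2L)
  expect_error(smoothProfile(numeric(0)), "non-empty")
  expect_error(smoothProfile(1:3, sigma = 0), "sigma")
})

test_that("rotation augmentation expands only the two scarce categories", {
  pool <- c(lapply(1:730, function(i) fakeLabeledSlice("6+px", z = i)),
            lapply(1:3, function(i) fakeLabeledSlice("4-5px", z = i)),
            lapply(1:5, function(i) fakeLabeledSlice("1px", z = i)))
  aug <- augmentSlices(pool)
  cats <- vapply(aug, function(s) s@category, character(1))
  expect_identical(sum(cats == "6+px"), 2920L)   # 730 x 4
  expect_identical(sum(cats == "4-5px"), 9L)     # 3 x 3
  expect_identical(sum(cats == "1px"), 5L)       # unchanged
  # labels, ids and targets survive rotation
  expect_true(all(vapply(aug, function(s) s@target, numeric(1)) ==
                    categoryToScore(cats)))
  # a rotated copy is a true 90-degree rotation of its predecessor
  first64 <- which(cats == "6+px")[1:2]
  p0 <- pixels(aug[[first64[1]]]@slice)
  p1 <- pixels(aug[[first64[2]]]@slice)
  expect_false(identical(p0, p1))
  expect_identical(sort(as.vector(p0)), sort(as.vector(p1)))
  expect_identical(augmentSlices(list()), list())
})

test_that("tomogram partitions are disjoint, covering and seeded", {
  ids <- sprintf("tomo%03d", 1:114)
  p <- partitionTomograms(ids, 98L, 1L, seed = 3L)
  expect_length(p@trainIds, 98L)
  expect_length(p@valIds, 1L)
  expect_length(p@testIds, 15L)
  expect_setequal(c(p@trainIds, p@valIds, p@testIds), ids)
  expect_identical(partitionTomograms(ids, 98L, 1L, seed = 3L)@testIds,
                   p@testIds)
  # boundary: everything in train
  pa <- partitionTomograms(ids, 114L, 0L, seed = 1L)
  expect_length(pa@testIds, 0L)
  expect_error(partitionTomograms(ids, 114L, 1L, seed = 1L), "exceed")
  # partition property across seeds and sizes
  for (s in 1:5) {
    pp <- partitionTomograms(ids, 50L, 10L, seed = s)
    expect_setequal(c(pp@trainIds, pp@valIds, pp@testIds), ids)
    expect_identical(anyDuplicated(c(pp@trainIds, pp@valIds, pp@testIds)), 0L)
  }
})

test_that("balanced sampling draws exactly perCategory slices per class", {
  pool <- unlist(lapply(qualityCategories(), function(cat)
    lapply(1:8, function(i) fakeLabeledSlice(cat, z = i))), recursive = FALSE)
  out <- balancedSample(pool, 5L, seed = 2L)
  cats <- vapply(out, function(s) s@category, character(1))
  expect_length(out, 30L)
  expect_true(all(table(cats) == 5L))
  # minimal draw
  one <- balancedSample(pool, 1L, seed = 2L)
  expect_length(one, 6L)
  expect_setequal(vapply(one, function(s) s@category, character(1)),
                  qualityCategories())
  # undersized category errors by name unless upsampling is requested
  expect_error(balancedSample(pool, 9L, seed = 1L), "'no-feature' has only 8")
  expect_length(balancedSample(pool, 9L, seed = 1L, replace = TRUE), 54L)
  # reproducible
  expect_identical(labeledSliceTable(balancedSample(pool, 5L, seed = 2L)),
                   labeledSliceTable(out))
})
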