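test_that("generated slices are deterministic in (category, config, seed)", {
  cfg <- synthConfig(sliceSize = 32L, seed = 5L)
  a <- makeSlice("3px", cfg, seed = 9L)
  b <- makeSlice("3px", cfg, seed = 9L)
  expect_identical(pixels(a@slice), pixels(b@slice))
  expect_identical(a@category, "3px")
  expect_equal(a@target, 0.6)
  c <- makeSlice("3px", cfg, seed = 10L)
  expect_false(identical(pixels(a@slice), pixels(c@slice)))
  expect_error(makeSlice("5px", cfg), "unknown category")
})

test_that("'no-feature' slices contain zero inserted features", {
  cfg <- synthConfig(sliceSize = 32L, seed = 5L)
  r <- makeSlice("no-feature", cfg, seed = 3L, withTruth = TRUE)
  expect_identical(r$nFeatures, 0L)
  rf <- makeSlice("2px", cfg, seed = 3L, withTruth = TRUE)
  expect_gte(rf$nFeatures, 1L)
})

test_that("category blur widths match their nominal feature widths (FWHM)", {
  cfg <- synthConfig()
  widths <- c("6+px" = 6, "4-5px" = 4.5, "3px" = 3, "2px" = 2, "1px" = 1)
  measured <- vapply(names(widths), function(cat) {
    img <- matrix(0, 33, 33)
    img[17, ] <- 1                                  # noiseless 1-px line
    profileFWHM(tomoQC:::.blurImage(img, cfg@blurSigma[[cat]])[, 17])
  }, numeric(1))
  expect_true(all(abs(measured - widths) / widths < 0.2))
  # monotone quality ladder: finer category => narrower smallest feature
  expect_true(all(diff(measured) < 0))
  expect_true(all(diff(cfg@noiseSd[-1]) < 0))       # and less noise
})

test_that("synthetic tomograms have a centered unimodal category band", {
  cfg <- synthConfig(sliceSize = 32L, seed = 5L)
  tg <- makeTomogram(21L, 11L, "1px", cfg, seed = 2L)
  cats <- categories(tg$truth)
  expect_identical(cats[1:5], rep("no-feature", 5))
  expect_identical(cats[17:21], rep("no-feature", 5))
  expect_identical(cats[11], "1px")                 # slice 10 (0-based)
  ord <- match(cats, qualityCategories()) - 1L
  expect_true(all(diff(ord[6:11]) >= 0))            # rising to center
  expect_true(all(diff(ord[11:16]) <= 0))           # falling after
  expect_identical(thicknessTrue(tg$truth), 11L)
  expect_equal(thicknessTrue(tg$truth), sum(cats != "no-feature"))
  expect_equal(nSlices(tg$volume), 21L)
  # empty cell
  tg0 <- makeTomogram(20L, 0L, "1px", cfg, seed = 2L)
  expect_true(all(categories(tg0$truth) == "no-feature"))
  expect_error(makeTomogram(10L, 11L, "1px", cfg), "exceed")
})

test_that("label tables expose 0-based indices and mapped targets", {
  cfg <- synthConfig(sliceSize = 32L, seed = 5L)
  tg <- makeTomogram(7L, 3L, "2px", cfg, seed = 4L)
  tab <- labelTable(tg$truth, "t42")
  expect_equal(nrow(tab), 7L)
  expect_equal(tab$slice_index, 0:6)
  expect_equal(tab$target_score, categoryToScore(tab$category))
})

test_that("tilt movies respect dose accounting and share per-tilt signal", {
  cfg <- synthConfig(sliceSize = 16L, seed = 5L)
  mv <- makeTiltMovie(51L, 152L, 400, cfg, seed = 6L)
  # 400 / (51 * 152) = 0.0516 e-/A^2/frame, cf. 0.052 at 152 frames/tilt
  expect_equal(dosePerFrame(mv$series@stacks[[1]]), 400 / (51 * 152),
               tolerance = 1e-12)
  expect_equal(totalDose(mv$series), 400, tolerance = 1e-9)
  expect_equal(mv$truth@dose, 400)
  # two frames of one tilt: identical signal, independent noise
  st <- mv$series@stacks[[1]]
  n1 <- frames(st)[, , 1] - mv$signals[[1]]
  n2 <- frames(st)[, , 2] - mv$signals[[1]]
  expect_lt(abs(cor(as.vector(n1), as.vector(n2))), 0.05)
  # frame average converges to the noiseless signal as frames accumulate
  cfgBig <- synthConfig(sliceSize = 16L, seed = 5L)
  mvb <- makeTiltMovie(1L, 400L, 400, cfgBig, seed = 8L)
  avg <- pixels(averageFrames(mvb$series@stacks[[1]]))
  sdFrame <- cfgBig@doseNoiseSd1 / sqrt(dosePerFrame(mvb$series@stacks[[1]]))
  expect_lt(max(abs(avg - mvb$signals[[1]])), 5 * sdFrame / sqrt(400))
  expect_error(makeTiltMovie(0L, 10L, 100, cfg), ">= 1")
})

test_that("dose rendering is deterministic with 1/dose noise variance", {
  cfg <- synthConfig(sliceSize = 32L, seed = 5L)
  truth <- makeTomogram(6L, 4L, "2px", cfg, seed = 3L)$volume
  r1 <- renderVolumeAtDose(truth, 100, seed = 11L)
  r2 <- renderVolumeAtDose(truth, 100, seed = 11L)
  expect_identical(voxels(r1), voxels(r2))
  v100 <- var(as.vector(voxels(r1) - voxels(truth)))
  v200 <- var(as.vector(voxels(renderVolumeAtDose(truth, 200, seed = 12L)) -
                        voxels(truth)))
  expect_equal(v100 / v200, 2, tolerance = 0.1)
  # high-dose limit approaches the truth
  hi <- renderVolumeAtDose(truth, 1e9, seed = 13L)
  expect_lt(max(abs(voxels(hi) - voxels(truth))), 1e-3)
  expect_error(renderVolumeAtDose(truth, 0, seed = 1L), "dose")
})
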