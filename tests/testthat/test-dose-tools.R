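mkStack <- function(vals, dpf = 1, size = 2L) {
  new("FrameStack",
      frames = array(rep(vals, each = size * size), c(size, size, length(vals))),
      dosePerFrame = dpf, tiltAngle = 0, apix = 1)
}
mkSeries <- function(nFrames, dpf = 1, nStacks = 2L)
  new("TiltMovieSeries",
      stacks = lapply(1:nStacks, function(i) mkStack(seq_len(nFrames), dpf)))

test_that("even/odd splitting partitions frames by 0-based parity", {
  sr <- mkSeries(4L)
  halves <- splitEvenOdd(sr)
  expect_equal(frames(halves$even@stacks[[1]])[1, 1, ], c(1, 3))  # f0, f2
  expect_equal(frames(halves$odd@stacks[[1]])[1, 1, ], c(2, 4))   # f1, f3
  # 5-frame convention: even half is larger by one
  h5 <- splitEvenOdd(mkSeries(5L))
  expect_equal(frames(h5$even@stacks[[1]])[1, 1, ], c(1, 3, 5))
  expect_equal(frames(h5$odd@stacks[[1]])[1, 1, ], c(2, 4))
  expect_error(splitEvenOdd(mkSeries(1L)), "stack 1")
})

test_that("a 400 e/A2 series of 152-frame stacks splits into two exact 200s", {
  dpf <- 400 / (2 * 152)             # 2 stacks
  sr <- mkSeries(152L, dpf)
  expect_equal(totalDose(sr), 400)
  halves <- splitEvenOdd(sr)
  expect_equal(totalDose(halves$even), 200, tolerance = 1e-12)
  expect_equal(totalDose(halves$odd), 200, tolerance = 1e-12)
  expect_equal(dim(frames(halves$even@stacks[[1]]))[3], 76L)
  # frame conservation: multiset of frames is partitioned, nothing lost
  orig <- sort(frames(sr@stacks[[1]])[1, 1, ])
  back <- sort(c(frames(halves$even@stacks[[1]])[1, 1, ],
                 frames(halves$odd@stacks[[1]])[1, 1, ]))
  expect_identical(back, orig)
})

test_that("recursive splitting halves dose down the ladder", {
  dpf <- 400 / (2 * 152)
  sr <- mkSeries(152L, dpf)
  lad2 <- recursiveSplit(sr, 2L, keep = "even")
  expect_length(lad2, 2L)
  expect_equal(vapply(lad2, totalDose, numeric(1)), c(200, 100),
               tolerance = 1e-12)
  # frame-count oracle: even-keep retains ceil(n/2) each round
  lad4 <- recursiveSplit(sr, 4L, keep = "even")
  counts <- vapply(lad4, function(s) dim(frames(s@stacks[[1]]))[3],
                   integer(1))
  oracle <- Reduce(function(n, .) as.integer(ceiling(n / 2)), 1:4,
                   accumulate = TRUE, init = 152L)[-1]
  expect_identical(counts, oracle)                 # 76, 38, 19, 10
  expect_equal(vapply(lad4, totalDose, numeric(1)), 400 * counts / 152,
               tolerance = 1e-9)
  expect_identical(recursiveSplit(sr, 0L), list())
  expect_error(recursiveSplit(mkSeries(4L), 3L), "round 3")
})

test_that("fraction extraction keeps evenly spaced frames and reduces dose", {
  dpf <- 400 / (2 * 152)
  sr <- mkSeries(152L, dpf)
  expect_equal(frames(extractFraction(sr, 1)@stacks[[1]]),
               frames(sr@stacks[[1]]))
  half <- extractFraction(sr, 0.5)
  expect_equal(dim(frames(half@stacks[[1]]))[3], 76L)
  expect_equal(totalDose(half), 200, tolerance = 1e-12)
  # the 16% extraction of a 400 e series lands near the 64 e dose point
  frac16 <- extractFraction(sr, 0.16)
  expect_lt(abs(totalDose(frac16) - 64), 2)
  expect_gt(totalDose(sr) - totalDose(extractFraction(sr, 0.9)), 0)
  expect_error(extractFraction(sr, 0), "fraction")
  expect_error(extractFraction(mkSeries(3L), 0.1), "no frames")
})

test_that("frame averaging is the pixel-wise mean", {
  st <- mkStack(c(2, 2, 2))
  expect_true(all(pixels(averageFrames(st)) == 2))
  one <- mkStack(5)
  expect_true(all(pixels(averageFrames(one)) == 5))
  # linearity: mean of half-averages equals full average for even counts
  set.seed(1)
  stR <- new("FrameStack", frames = array(rnorm(4 * 4 * 6), c(4, 4, 6)),
             dosePerFrame = 1, tiltAngle = 0, apix = 1)
  sr <- new("TiltMovieSeries", stacks = list(stR))
  halves <- splitEvenOdd(sr)
  combined <- (pixels(averageFrames(halves$even@stacks[[1]])) +
               pixels(averageFrames(halves$odd@stacks[[1]]))) / 2
  expect_equal(combined, pixels(averageFrames(stR)), tolerance = 1e-12)
})

test_that("FRC satisfies self-, sign- and independence properties", {
  set.seed(3)
  x <- matrix(rnorm(64 * 64), 64, 64)
  self <- frc(x, x)
  expect_true(all(abs(self@correlations - 1) < 1e-9))
  flip <- frc(x, -x)
  expect_true(all(abs(flip@correlations + 1) < 1e-9))
  expect_true(all(self@ringRadii <= 0.5 + 1e-12))
  expect_true(!is.unsorted(self@ringRadii, strictly = TRUE))
  # independent noise decorrelates ring-wise (Monte Carlo over seeds)
  ms <- vapply(1:5, function(s) {
    set.seed(100 + s)
    a <- matrix(rnorm(256 * 256), 256, 256)
    b <- matrix(rnorm(256 * 256), 256, 256)
    mean(frc(a, b)@correlations)
  }, numeric(1))
  expect_true(all(abs(ms) < 0.05))
  # symmetry
  y <- matrix(rnorm(64 * 64), 64, 64)
  expect_equal(frc(x, y)@correlations, frc(y, x)@correlations,
               tolerance = 1e-12)
  expect_error(frc(x, matrix(0, 32, 32)), "shapes differ")
})

test_that("half-set FRC is high at low and decaying at high frequency", {
  cfg <- synthConfig(sliceSize = 64L, seed = 23L)
  tg <- makeTomogram(5L, 5L, "2px", cfg, seed = 31L)
  a <- array(voxels(renderVolumeAtDose(tg$volume, 200, seed = 1L))[3, , ],
             c(64, 64))
  b <- array(voxels(renderVolumeAtDose(tg$volume, 200, seed = 2L))[3, , ],
             c(64, 64))
  curve <- frc(a, b)
  k <- length(curve@correlations)
  expect_gt(mean(curve@correlations[1:3]), 0.6)
  expect_lt(mean(curve@correlations[(k - 4):k]),
            mean(curve@correlations[1:3]))
})
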