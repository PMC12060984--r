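## Synthetic tomogram, labeled-slice and tilt-movie generator.
##
## The generator emulates what quality categories measure: the smallest
## reliably discernible feature width in a slice.  Features (membrane-like
## closed curves, filament segments, small disks) are drawn as 1-px strokes,
## Gaussian-blurred with a per-category sigma chosen so the blurred stroke's
## full width at half maximum matches the category width, rescaled to unit
## contrast, and overlaid with a smooth background ramp plus additive
## Gaussian noise on a monotone per-category ladder (finer categories =>
## less blur and less noise).  "no-feature" slices carry background and
## noise only.  Everything is a pure function of (arguments, seed).

## FWHM of a blurred 1-px stroke ~ sqrt(1 + (2.355 sigma)^2); sigmas below
## target widths {6, 4.5, 3, 2, 1} px for the five feature categories.
.DEFAULT_BLUR <- c("no-feature" = 0, "6+px" = 2.6, "4-5px" = 1.9,
                   "3px" = 1.2, "2px" = 0.75, "1px" = 0.25)
.DEFAULT_NOISE <- c("no-feature" = 0.30, "6+px" = 0.30, "4-5px" = 0.26,
                    "3px" = 0.22, "2px" = 0.18, "1px" = 0.14)

#' Configuration of the synthetic data generator
#'
#' Defaults are the package's study conditions: 128-px test slices (960 px
#' remains available to mirror full-scale acquisition), per-category blur
#' sigmas targeting feature widths of 6, 4.5, 3, 2 and 1 px, a monotone
#' per-category noise ladder, dose-rendering noise sd `2/sqrt(dose)` (10%
#' of feature contrast at the 400 e-/A^2 full dose), and the 13.26 A/px
#' pixel size of the high-dose platelet acquisitions.
#'
#' @param sliceSize slice edge length in pixels.
#' @param featuresPerSlice (min, max) features drawn per slice.
#' @param noiseSd named per-category noise sd table (6 entries).
#' @param blurSigma named per-category blur sigma table (6 entries).
#' @param doseNoiseSd1 dose-render noise sd at unit dose.
#' @param apix pixel size stamped on generated data, Angstrom/pixel.
#' @param seed integer base seed.
#' @return A [SynthConfig-class].
#' @export
#' @examples
#' cfg <- synthConfig(seed = 7)
#' ls1 <- makeSlice("1px", cfg)
#' ls1
synthConfig <- function(sliceSize = 128L, featuresPerSlice = c(6L, 12L),
                        noiseSd = .DEFAULT_NOISE, blurSigma = .DEFAULT_BLUR,
                        doseNoiseSd1 = 2.0, apix = 13.26, seed = 1L) {
  new("SynthConfig", sliceSize = as.integer(sliceSize),
      featuresPerSlice = as.integer(featuresPerSlice),
      noiseSd = noiseSd, blurSigma = blurSigma,
      doseNoiseSd1 = doseNoiseSd1, apix = apix, seed = as.integer(seed))
}

## Gaussian blur by separable banded convolution.  Kernel rows are
## renormalized after truncation at +-3 sigma, so constants are preserved
## at the image edges.
.gaussBandMat <- function(n, sigma) {
  h <- ceiling(3 * sigma)
  M <- stats::dnorm(abs(outer(seq_len(n), seq_len(n), "-")), sd = sigma)
  M[abs(outer(seq_len(n), seq_len(n), "-")) > h] <- 0
  M / rowSums(M)
}

.blurImage <- function(img, sigma) {
  if (sigma <= 0) return(img)
  Mr <- .gaussBandMat(nrow(img), sigma)
  Mc <- if (ncol(img) == nrow(img)) Mr else .gaussBandMat(ncol(img), sigma)
  Mr %*% img %*% t(Mc)
}

.setCurve <- function(img, ys, xs, value) {
  n <- nrow(img); m <- ncol(img)
  r <- round(ys); c <- round(xs)
  keep <- r >= 1 & r <= n & c >= 1 & c <= m
  img[cbind(r[keep], c[keep])] <- value
  img
}

## Draw nFeatures 1-px-stroke features; consumes the current RNG stream.
.drawFeatures <- function(size, nFeatures) {
  img <- matrix(0, size, size)
  if (nFeatures == 0L) return(img)
  types <- sample(c("membrane", "filament", "disk"), nFeatures, replace = TRUE)
  for (ty in types) {
    if (ty == "membrane") {
      cx <- stats::runif(1, 0.2, 0.8) * size
      cy <- stats::runif(1, 0.2, 0.8) * size
      rx <- stats::runif(1, 0.08, 0.25) * size
      ry <- stats::runif(1, 0.08, 0.25) * size
      phi <- stats::runif(1, 0, 2 * pi)
      t <- seq(0, 2 * pi, length.out = ceiling(8 * pi * max(rx, ry)))
      pert <- 1 + 0.15 * sin(3 * t + phi)
      img <- .setCurve(img, cy + ry * pert * sin(t), cx + rx * pert * cos(t), 1)
    } else if (ty == "filament") {
      x0 <- stats::runif(1, 0.1, 0.9) * size
      y0 <- stats::runif(1, 0.1, 0.9) * size
      ang <- stats::runif(1, 0, pi)
      len <- stats::runif(1, 0.2, 0.5) * size
      t <- seq(0, len, by = 0.25)
      img <- .setCurve(img, y0 + t * sin(ang), x0 + t * cos(ang), 1)
    } else {
      cx <- stats::runif(1, 0.15, 0.85) * size
      cy <- stats::runif(1, 0.15, 0.85) * size
      rad <- stats::runif(1, 2, 6)
      w <- ceiling(rad)
      ys <- pmax(1, round(cy) - w):pmin(size, round(cy) + w)
      xs <- pmax(1, round(cx) - w):pmin(size, round(cx) + w)
      d2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
      img[ys, xs][d2 <= rad^2] <- 0.9
    }
  }
  img
}

## Smooth low-order background ramp; consumes the RNG stream.
.drawBackground <- function(size) {
  gx <- stats::runif(1, -0.1, 0.1)
  gy <- stats::runif(1, -0.1, 0.1)
  u <- seq(-0.5, 0.5, length.out = size)
  outer(u * gy, u * gx, "+") + stats::runif(1, -0.05, 0.05)
}

## Noiseless category render; consumes the RNG stream.
.renderCategory <- function(category, config) {
  size <- config@sliceSize
  if (category == "no-feature") {
    return(list(image = .drawBackground(size), nFeatures = 0L))
  }
  nf <- sample(config@featuresPerSlice[1]:config@featuresPerSlice[2], 1L)
  feat <- .drawFeatures(size, nf)
  feat <- .blurImage(feat, config@blurSigma[[category]])
  mx <- max(feat)
  if (mx > 0) feat <- feat / mx
  list(image = feat + .drawBackground(size), nFeatures = nf)
}

#' Generate one labeled synthetic slice
#'
#' @param category one of [qualityCategories()].
#' @param config a [SynthConfig-class].
#' @param seed integer seed (defaults to `config@seed`); the same
#'   (category, config, seed) always yields a bitwise-identical slice.
#' @param withTruth if `TRUE`, return `list(slice, nFeatures)`.
#' @return A [LabeledSlice-class] whose target is
#'   `categoryToScore(category)`, or a list when `withTruth = TRUE`.
#' @export
makeSlice <- function(category, config, seed = config@seed,
                      withTruth = FALSE) {
  if (!category %in% .CATEGORIES)
    stop(sprintf("unknown category '%s'", category))
  out <- withSeed(seed, {
    r <- .renderCategory(category, config)
    r$image <- r$image +
      matrix(stats::rnorm(config@sliceSize^2, sd = config@noiseSd[[category]]),
             config@sliceSize, config@sliceSize)
    r
  })
  sl <- new("LabeledSlice",
            slice = new("SliceImage", pixels = out$image, apix = config@apix),
            tomogramId = "synthetic", zIndex = NA_integer_,
            category = category, target = categoryToScore(category))
  if (withTruth) list(slice = sl, nFeatures = out$nFeatures) else sl
}

#' Generate a synthetic tomogram with a depth-dependent quality profile
#'
#' Real tomograms are sharpest near the midplane of the cell and degrade
#' toward the top and bottom boundaries. The generated category profile is
#' unimodal: `peakCategory` at the central slices, degrading linearly (in
#' category ordinal) to "6+px" at the edges of a centered band of
#' `thicknessTrue` slices, and "no-feature" outside the band.
#'
#' @param nSlices number of z slices.
#' @param thicknessTrue number of slices carrying cell signal,
#'   `<= nSlices`.
#' @param peakCategory category of the central slices (not "no-feature").
#' @param config a [SynthConfig-class].
#' @param seed integer seed (defaults to `config@seed`).
#' @return `list(volume = TomoVolume, truth = GroundTruth)`.
#' @export
makeTomogram <- function(nSlices, thicknessTrue, peakCategory, config,
                         seed = config@seed) {
  if (thicknessTrue > nSlices)
    stop("thicknessTrue must not exceed nSlices")
  if (peakCategory == "no-feature" && thicknessTrue > 0L)
    stop("peakCategory must not be 'no-feature'")
  peakOrd <- match(peakCategory, .CATEGORIES) - 1L
  cats <- rep("no-feature", nSlices)
  if (thicknessTrue > 0L) {
    start <- (nSlices - thicknessTrue) %/% 2L          # 0-based band start
    band <- start + seq_len(thicknessTrue) - 1L        # 0-based indices
    center <- start + (thicknessTrue - 1) / 2
    half <- max((thicknessTrue - 1) / 2, 1e-9)
    ord <- round(1 + (peakOrd - 1) * (1 - abs(band - center) / half))
    cats[band + 1L] <- .CATEGORIES[pmin(pmax(ord, 1L), 5L) + 1L]
  }
  seeds <- childSeeds(seed, nSlices)
  vox <- array(0, dim = c(nSlices, config@sliceSize, config@sliceSize))
  for (i in seq_len(nSlices))
    vox[i, , ] <- pixels(makeSlice(cats[i], config, seeds[i])@slice)
  list(volume = new("TomoVolume", voxels = vox, apix = config@apix),
       truth = new("GroundTruth", categoryPerSlice = cats,
                   thicknessTrue = as.integer(sum(cats != "no-feature")),
                   dose = NA_real_))
}

#' Generate a synthetic multi-frame tilt-movie series
#'
#' Each tilt has one shared noiseless projection image; every frame is that
#' signal plus independent Gaussian noise whose variance scales as
#' 1/(dose per frame), so averaging frames behaves exactly like acquiring
#' at the accumulated dose, and even/odd frame subsets give two half-dose
#' realizations of the same signal. Dose per frame is
#' `totalDose / (nTilts * framesPerTilt)`, e.g. 400 e-/A^2 over 51 tilts of
#' 152 frames gives 0.0516 e-/A^2/frame.
#'
#' @param nTilts number of tilt angles (spread over -50..+50 degrees).
#' @param framesPerTilt frames recorded per tilt.
#' @param totalDose accumulated dose of the whole series, e-/A^2.
#' @param config a [SynthConfig-class].
#' @param seed integer seed (defaults to `config@seed`).
#' @return `list(series = TiltMovieSeries, truth = GroundTruth,
#'   signals = list)` where `signals` holds the per-tilt noiseless images.
#' @export
makeTiltMovie <- function(nTilts, framesPerTilt, totalDose, config,
                          seed = config@seed) {
  if (nTilts < 1L || framesPerTilt < 1L || totalDose <= 0)
    stop("nTilts, framesPerTilt must be >= 1 and totalDose > 0")
  dpf <- totalDose / (nTilts * framesPerTilt)
  frameSd <- config@doseNoiseSd1 / sqrt(dpf)
  angles <- if (nTilts == 1L) 0 else seq(-50, 50, length.out = nTilts)
  seeds <- childSeeds(seed, nTilts)
  size <- config@sliceSize
  stacks <- vector("list", nTilts)
  signals <- vector("list", nTilts)
  for (t in seq_len(nTilts)) {
    res <- withSeed(seeds[t], {
      sig <- .renderCategory("3px", config)$image
      fr <- array(stats::rnorm(size * size * framesPerTilt, sd = frameSd),
                  dim = c(size, size, framesPerTilt))
      list(signal = sig, frames = fr + as.vector(sig))
    })
    signals[[t]] <- res$signal
    stacks[[t]] <- new("FrameStack", frames = res$frames, dosePerFrame = dpf,
                       tiltAngle = angles[t], apix = config@apix)
  }
  list(series = new("TiltMovieSeries", stacks = stacks),
       truth = new("GroundTruth", categoryPerSlice = character(0),
                   thicknessTrue = 0L, dose = totalDose),
       signals = signals)
}

#' Render a ground-truth volume at a given accumulated dose
#'
#' Adds independent Gaussian noise with variance proportional to 1/dose
#' (sd = `noiseSd1 / sqrt(dose)`). Two calls with different seeds at dose d
#' emulate the even-frame and odd-frame half-reconstructions of a
#' 2d-dose acquisition.
#'
#' @param truthVolume a [TomoVolume-class] holding the noise-free-at-dose
#'   reference (e.g. from [makeTomogram()]).
#' @param dose accumulated dose in e-/A^2, > 0.
#' @param seed integer seed.
#' @param noiseSd1 noise sd at unit dose (default matches [synthConfig()]).
#' @return A [TomoVolume-class].
#' @export
renderVolumeAtDose <- function(truthVolume, dose, seed, noiseSd1 = 2.0) {
  if (dose <= 0) stop("dose must be > 0")
  stopifnot(is(truthVolume, "TomoVolume"))
  vox <- withSeed(seed, truthVolume@voxels +
    array(stats::rnorm(length(truthVolume@voxels), sd = noiseSd1 / sqrt(dose)),
          dim = dim(truthVolume@voxels)))
  new("TomoVolume", voxels = vox, apix = truthVolume@apix)
}

#' Per-slice label table of a synthetic tomogram
#'
#' @param truth a [GroundTruth-class] from [makeTomogram()].
#' @param tomogramId id to record in the table.
#' @return `data.frame(tomogram_id, slice_index, category, target_score)`
#'   with 0-based slice indices.
#' @export
labelTable <- function(truth, tomogramId = "synthetic") {
  cats <- truth@categoryPerSlice
  data.frame(tomogram_id = tomogramId,
             slice_index = seq_along(cats) - 1L,
             category = cats,
             target_score = categoryToScore(cats),
             stringsAsFactors = FALSE)
}

#' Generate a balanced labeled-slice corpus
#'
#' Convenience wrapper producing `nPerCategory` independent labeled slices
#' of each of the six categories, the desk-scale analog of the balanced
#' 2500-per-category training set.
#'
#' @param nPerCategory slices per category.
#' @param config a [SynthConfig-class].
#' @param seed integer seed (defaults to `config@seed`).
#' @return List of [LabeledSlice-class], category-blocked in
#'   [qualityCategories()] order.
#' @export
synthTrainingSet <- function(nPerCategory, config, seed = config@seed) {
  seeds <- childSeeds(seed, 6L * nPerCategory)
  out <- vector("list", 6L * nPerCategory)
  k <- 0L
  for (cat in .CATEGORIES) {
    for (i in seq_len(nPerCategory)) {
      k <- k + 1L
      out[[k]] <- makeSlice(cat, config, seeds[k])
    }
  }
  out
}
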