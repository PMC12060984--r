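#' @useDynLib tomoQC, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

## Canonical quality categories, ordered coarse -> fine.  Ordinal 0 is the
## "no discernible feature" class; ordinals 1..5 are the smallest reliably
## discernible feature width in pixels (6+, 4-5, 3, 2, 1).
.CATEGORIES <- c("no-feature", "6+px", "4-5px", "3px", "2px", "1px")

#' Quality category names
#'
#' The six slice-quality categories used throughout the package, ordered from
#' coarsest ("no-feature", no discernible biological feature) to finest
#' ("1px", smallest discernible feature one pixel wide).
#'
#' @return Character vector of length 6.
#' @export
#' @examples
#' qualityCategories()
qualityCategories <- function() .CATEGORIES

#' SliceImage: one 2-D tomogram slice
#'
#' A single z-slice of a tomogram: a rectangular pixel grid plus the pixel
#' size in Angstrom per pixel. `sourceZ` optionally records the 0-based
#' z index the slice was extracted from.
#'
#' @slot pixels numeric matrix of pixel values.
#' @slot apix pixel size in Angstrom/pixel, > 0.
#' @slot sourceZ integer 0-based source slice index, or `NA_integer_`.
#' @export
setClass("SliceImage",
  representation(pixels = "matrix", apix = "numeric", sourceZ = "integer"),
  prototype(apix = 1, sourceZ = NA_integer_),
  validity = function(object) {
    if (length(object@pixels) == 0L) return("pixel grid must be non-empty")
    if (!is.numeric(object@pixels)) return("pixels must be numeric")
    if (length(object@apix) != 1L || !is.finite(object@apix) || object@apix <= 0)
      return("apix must be a single positive number")
    TRUE
  })

#' TomoVolume: a 3-D tomogram
#'
#' A reconstructed tomogram stored as a 3-D array indexed (z, y, x), with z
#' the slowest axis (the beam axis); slices perpendicular to z are the unit
#' of quality scoring.
#'
#' @slot voxels 3-D numeric array, dim (nz, ny, nx).
#' @slot apix voxel size in Angstrom/voxel, > 0.
#' @export
setClass("TomoVolume",
  representation(voxels = "array", apix = "numeric"),
  prototype(apix = 1),
  validity = function(object) {
    d <- dim(object@voxels)
    if (length(d) != 3L) return("voxels must be a 3-D array (z, y, x)")
    if (any(d < 1L)) return("all three dimensions must be >= 1")
    if (length(object@apix) != 1L || !is.finite(object@apix) || object@apix <= 0)
      return("apix must be a single positive number")
    TRUE
  })

#' FrameStack: the movie frames of one tilt angle
#'
#' Short-exposure movie frames recorded at a single stage tilt, with a
#' uniform electron dose per frame. Frames are stored as a 3-D array
#' (rows, cols, frame) in acquisition order.
#'
#' @slot frames 3-D numeric array (nrow, ncol, nframes).
#' @slot dosePerFrame dose per frame in e-/A^2, > 0.
#' @slot tiltAngle stage tilt in degrees.
#' @slot apix pixel size in Angstrom/pixel.
#' @export
setClass("FrameStack",
  representation(frames = "array", dosePerFrame = "numeric",
                 tiltAngle = "numeric", apix = "numeric"),
  prototype(tiltAngle = 0, apix = 1),
  validity = function(object) {
    d <- dim(object@frames)
    if (length(d) != 3L || any(d < 1L))
      return("frames must be a non-empty 3-D array (rows, cols, frame)")
    if (length(object@dosePerFrame) != 1L || object@dosePerFrame <= 0)
      return("dosePerFrame must be a single positive number")
    TRUE
  })

#' TiltMovieSeries: the frame stacks of one tilt series
#'
#' An ordered list of [FrameStack-class] objects, one per tilt angle. The
#' series' total dose is the sum over stacks of frames x dose/frame.
#'
#' @slot stacks list of `FrameStack` objects.
#' @export
setClass("TiltMovieSeries",
  representation(stacks = "list"),
  validity = function(object) {
    if (length(object@stacks) == 0L) return("series must contain >= 1 stack")
    ok <- vapply(object@stacks, is, logical(1), class2 = "FrameStack")
    if (!all(ok)) return("all stacks must be FrameStack objects")
    TRUE
  })

#' LabeledSlice: a slice with a categorical label and training target
#'
#' @slot slice a [SliceImage-class].
#' @slot tomogramId character id of the source tomogram.
#' @slot zIndex integer 0-based slice index.
#' @slot category one of [qualityCategories()].
#' @slot target continuous quality target in [0, 1].
#' @export
setClass("LabeledSlice",
  representation(slice = "SliceImage", tomogramId = "character",
                 zIndex = "integer", category = "character",
                 target = "numeric"),
  validity = function(object) {
    if (!object@category %in% .CATEGORIES)
      return(sprintf("unknown category '%s'", object@category))
    if (object@target < 0 || object@target > 1)
      return("target must lie in [0, 1]")
    TRUE
  })

#' GroundTruth: generator-side truth for a synthetic tomogram or series
#'
#' @slot categoryPerSlice character vector of per-slice categories.
#' @slot thicknessTrue integer count of slices carrying cell signal
#'   (category other than "no-feature").
#' @slot dose total dose in e-/A^2 for movie renders, or `NA`.
#' @export
setClass("GroundTruth",
  representation(categoryPerSlice = "character", thicknessTrue = "integer",
                 dose = "numeric"),
  prototype(dose = NA_real_),
  validity = function(object) {
    if (length(object@categoryPerSlice) > 0L &&
        object@thicknessTrue != sum(object@categoryPerSlice != "no-feature"))
      return("thicknessTrue must equal the number of non-'no-feature' slices")
    TRUE
  })

#' SynthConfig: parameters of the synthetic slice generator
#'
#' Per-category blur and noise tables are named by [qualityCategories()] and
#' must have exactly six entries. The same `seed` plus the same arguments
#' always reproduce identical output.
#'
#' @slot sliceSize slice edge length in pixels.
#' @slot featuresPerSlice integer range (min, max) of features per slice.
#' @slot noiseSd per-category additive Gaussian noise sd (6 entries).
#' @slot blurSigma per-category Gaussian blur sigma in pixels (6 entries).
#' @slot doseNoiseSd1 sd of dose-rendering noise at unit dose (1 e-/A^2).
#' @slot apix pixel size in Angstrom/pixel stamped on generated slices.
#' @slot seed integer base seed.
#' @export
setClass("SynthConfig",
  representation(sliceSize = "integer", featuresPerSlice = "integer",
                 noiseSd = "numeric", blurSigma = "numeric",
                 doseNoiseSd1 = "numeric", apix = "numeric", seed = "integer"),
  validity = function(object) {
    if (length(object@noiseSd) != 6L || length(object@blurSigma) != 6L)
      return("noiseSd and blurSigma must each have exactly 6 entries")
    if (object@sliceSize < 16L) return("sliceSize must be >= 16")
    if (length(object@featuresPerSlice) != 2L ||
        any(object@featuresPerSlice < 1L))
      return("featuresPerSlice must be a positive (min, max) pair")
    TRUE
  })

#' TomoPartition: a tomogram-level train/validation/test split
#'
#' Slices of one tomogram never cross split boundaries: membership is decided
#' per tomogram id, so no test slice has near-duplicate neighbours in
#' training.
#'
#' @slot trainIds,valIds,testIds character id vectors, pairwise disjoint.
#' @export
setClass("TomoPartition",
  representation(trainIds = "character", valIds = "character",
                 testIds = "character"),
  validity = function(object) {
    all3 <- c(object@trainIds, object@valIds, object@testIds)
    if (anyDuplicated(all3)) return("partition sets must be pairwise disjoint")
    TRUE
  })

#' QualityProfile: per-slice predicted quality scores for one tomogram
#'
#' @slot scores numeric vector of per-slice scores in [0, 1], z-ordered.
#' @slot tomogramId character id.
#' @slot apix Angstrom/voxel of the source volume.
#' @export
setClass("QualityProfile",
  representation(scores = "numeric", tomogramId = "character",
                 apix = "numeric"),
  prototype(tomogramId = "", apix = 1),
  validity = function(object) {
    if (length(object@scores) == 0L) return("profile must be non-empty")
    if (any(object@scores < 0 | object@scores > 1))
      return("all scores must lie in [0, 1]")
    TRUE
  })

#' TomoReport: thickness and TomoScore summary for one tomogram
#'
#' @slot profile the underlying [QualityProfile-class].
#' @slot thicknessEst integer count of slices scoring above the threshold.
#' @slot thicknessNm estimated thickness in nm (slices x voxel spacing).
#' @slot tomoscore mean quality of above-threshold slices, in [0, 1].
#' @slot threshold the feature-presence cutoff used (default 0.2).
#' @export
setClass("TomoReport",
  representation(profile = "QualityProfile", thicknessEst = "integer",
                 thicknessNm = "numeric", tomoscore = "numeric",
                 threshold = "numeric"),
  validity = function(object) {
    n <- length(object@profile@scores)
    if (object@thicknessEst < 0L || object@thicknessEst > n)
      return("thicknessEst must lie in [0, n slices]")
    if (object@tomoscore < 0 || object@tomoscore > 1)
      return("tomoscore must lie in [0, 1]")
    if ((object@thicknessEst == 0L) != (object@tomoscore == 0))
      return("tomoscore must be 0 exactly when thicknessEst is 0")
    TRUE
  })

#' QualityModel: the residual slice-quality regressor
#'
#' A compact residual convolutional network ending in a single sigmoid unit,
#' so every prediction lies strictly in (0, 1). Weights are stored as plain
#' arrays; `lossHistory` records the per-epoch training MSE.
#'
#' @slot config list of network/training settings (see [netConfig()]).
#' @slot layers list describing the layer stack.
#' @slot params list of per-layer weight arrays.
#' @slot lossHistory numeric per-epoch training MSE (empty if untrained).
#' @export
setClass("QualityModel",
  representation(config = "list", layers = "list", params = "list",
                 lossHistory = "numeric"))

#' FRCCurve: a Fourier ring correlation curve
#'
#' @slot ringRadii ring-centre spatial frequencies in cycles/pixel,
#'   strictly increasing, at most Nyquist (0.5).
#' @slot correlations per-ring correlation in [-1, 1].
#' @slot ringWidth ring width in Fourier pixels.
#' @export
setClass("FRCCurve",
  representation(ringRadii = "numeric", correlations = "numeric",
                 ringWidth = "numeric"),
  validity = function(object) {
    if (length(object@ringRadii) != length(object@correlations))
      return("ringRadii and correlations must be matched in length")
    if (is.unsorted(object@ringRadii, strictly = TRUE))
      return("ringRadii must be strictly increasing")
    if (any(object@ringRadii > 0.5 + 1e-12))
      return("ring radii must not exceed Nyquist (0.5 cycles/pixel)")
    if (any(abs(object@correlations) > 1 + 1e-9))
      return("correlations must lie in [-1, 1]")
    TRUE
  })

#' DoseResponse: TomoScore as a function of accumulated dose
#'
#' @slot doses accumulated doses in e-/A^2, sorted increasing.
#' @slot tomoscores matched TomoScore values.
#' @slot percentOfMax TomoScore as percent of the maximum-dose entry
#'   (100 at the maximum dose).
#' @export
setClass("DoseResponse",
  representation(doses = "numeric", tomoscores = "numeric",
                 percentOfMax = "numeric"),
  validity = function(object) {
    if (length(object@doses) != length(object@tomoscores) ||
        length(object@doses) != length(object@percentOfMax))
      return("doses, tomoscores and percentOfMax must be matched in length")
    if (is.unsorted(object@doses)) return("doses must be sorted increasing")
    if (abs(object@percentOfMax[length(object@percentOfMax)] - 100) > 1e-9)
      return("percentOfMax must be 100 at the maximum dose")
    TRUE
  })

#' FitResult: a (robust) linear fit summary
#'
#' @slot slope,intercept fitted line parameters.
#' @slot rSquared coefficient of determination in [0, 1].
#' @slot pValue two-sided p-value for the slope.
#' @slot inlierMask logical consensus mask (RANSAC fits; empty otherwise).
#' @export
setClass("FitResult",
  representation(slope = "numeric", intercept = "numeric",
                 rSquared = "numeric", pValue = "numeric",
                 inlierMask = "logical"),
  prototype(inlierMask = logical(0)),
  validity = function(object) {
    if (!is.na(object@rSquared) &&
        (object@rSquared < -1e-9 || object@rSquared > 1 + 1e-9))
      return("rSquared must lie in [0, 1]")
    TRUE
  })
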