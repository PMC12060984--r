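#' @name accessors
#' @title Accessors for tomoQC classes
#' @description Slot accessors: `pixels()`, `apix()`, `voxels()`,
#'   `nSlices()`, `getSlice()`, `frames()`, `dosePerFrame()`, `totalDose()`,
#'   `scores()`, `categories()`, `thicknessTrue()`.
#' @param object,x a tomoQC object.
#' @param z 0-based slice index (for `getSlice`).
#' @return The slot value, or for `getSlice()` a [SliceImage-class].
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setGeneric("apix", function(object) standardGeneric("apix"))
#' @rdname accessors
#' @export
setGeneric("voxels", function(object) standardGeneric("voxels"))
#' @rdname accessors
#' @export
setGeneric("nSlices", function(object) standardGeneric("nSlices"))
#' @rdname accessors
#' @export
setGeneric("getSlice", function(object, z) standardGeneric("getSlice"))
#' @rdname accessors
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))
#' @rdname accessors
#' @export
setGeneric("dosePerFrame", function(object) standardGeneric("dosePerFrame"))
#' @rdname accessors
#' @export
setGeneric("totalDose", function(object) standardGeneric("totalDose"))
#' @rdname accessors
#' @export
setGeneric("scores", function(object) standardGeneric("scores"))
#' @rdname accessors
#' @export
setGeneric("categories", function(object) standardGeneric("categories"))
#' @rdname accessors
#' @export
setGeneric("thicknessTrue", function(object) standardGeneric("thicknessTrue"))

setMethod("pixels", "SliceImage", function(object) object@pixels)
setMethod("apix", "SliceImage", function(object) object@apix)
setMethod("apix", "TomoVolume", function(object) object@apix)
setMethod("apix", "QualityProfile", function(object) object@apix)
setMethod("voxels", "TomoVolume", function(object) object@voxels)
setMethod("nSlices", "TomoVolume", function(object) dim(object@voxels)[1L])
setMethod("nSlices", "QualityProfile", function(object) length(object@scores))

setMethod("getSlice", "TomoVolume", function(object, z) {
  nz <- dim(object@voxels)[1L]
  if (z < 0L || z >= nz)
    stop(sprintf("slice index %d out of range [0, %d]", z, nz - 1L))
  new("SliceImage",
      pixels = array(object@voxels[z + 1L, , ], dim = dim(object@voxels)[2:3]),
      apix = object@apix, sourceZ = as.integer(z))
})

setMethod("frames", "FrameStack", function(object) object@frames)
setMethod("dosePerFrame", "FrameStack", function(object) object@dosePerFrame)
setMethod("totalDose", "FrameStack",
          function(object) dim(object@frames)[3L] * object@dosePerFrame)
setMethod("totalDose", "TiltMovieSeries", function(object)
  sum(vapply(object@stacks, totalDose, numeric(1))))

setMethod("scores", "QualityProfile", function(object) object@scores)
setMethod("scores", "TomoReport", function(object) object@profile@scores)
setMethod("categories", "GroundTruth", function(object) object@categoryPerSlice)
setMethod("thicknessTrue", "GroundTruth", function(object) object@thicknessTrue)

setMethod("show", "SliceImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("SliceImage %dx%d px, apix %.4g A/px%s\n", d[1], d[2], object@apix,
              if (is.na(object@sourceZ)) "" else sprintf(", z=%d", object@sourceZ)))
})
setMethod("show", "TomoVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("TomoVolume %d slices of %dx%d px, apix %.4g A/voxel\n",
              d[1], d[2], d[3], object@apix))
})
setMethod("show", "FrameStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf("FrameStack %d frames of %dx%d px, %.4g e-/A^2/frame, tilt %g deg\n",
              d[3], d[1], d[2], object@dosePerFrame, object@tiltAngle))
})
setMethod("show", "TiltMovieSeries", function(object) {
  cat(sprintf("TiltMovieSeries of %d tilts, total dose %.4g e-/A^2\n",
              length(object@stacks), totalDose(object)))
})
setMethod("show", "QualityProfile", function(object) {
  cat(sprintf("QualityProfile '%s': %d slices, scores %.3f-%.3f (median %.3f)\n",
              object@tomogramId, length(object@scores),
              min(object@scores), max(object@scores), stats::median(object@scores)))
})
setMethod("show", "TomoReport", function(object) {
  cat(sprintf(paste0("TomoReport '%s': TomoScore %.3f, thickness %d slices",
                     " (%.1f nm), threshold %.2f\n"),
              object@profile@tomogramId, object@tomoscore, object@thicknessEst,
              object@thicknessNm, object@threshold))
})
setMethod("show", "LabeledSlice", function(object) {
  d <- dim(object@slice@pixels)
  cat(sprintf("LabeledSlice '%s' z=%s: %dx%d px, category %s, target %.1f\n",
              object@tomogramId,
              if (is.na(object@zIndex)) "?" else object@zIndex,
              d[1], d[2], object@category, object@target))
})
setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d slices, thickness %d, dose %s e-/A^2\n",
              length(object@categoryPerSlice), object@thicknessTrue,
              format(object@dose)))
})
setMethod("show", "TomoPartition", function(object) {
  cat(sprintf("TomoPartition: %d train / %d validation / %d test tomograms\n",
              length(object@trainIds), length(object@valIds),
              length(object@testIds)))
})
setMethod("show", "QualityModel", function(object) {
  cat(sprintf("QualityModel (%s backbone, %dpx input): %s\n",
              object@config$backboneDepth, object@config$inputSize,
              if (length(object@lossHistory))
                sprintf("trained %d epochs, final MSE %.4g",
                        length(object@lossHistory),
                        object@lossHistory[length(object@lossHistory)])
              else "untrained"))
})
setMethod("show", "FRCCurve", function(object) {
  cat(sprintf("FRCCurve: %d rings to %.3f cycles/px, FRC %.3f at lowest ring\n",
              length(object@ringRadii), max(object@ringRadii),
              object@correlations[1]))
})
setMethod("show", "DoseResponse", function(object) {
  cat(sprintf("DoseResponse over %d doses (%g-%g e-/A^2), %%-of-max %.1f-%.1f\n",
              length(object@doses), min(object@doses), max(object@doses),
              min(object@percentOfMax), max(object@percentOfMax)))
})
setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult: slope %.4g, intercept %.4g, R^2 %.3f, p %.3g%s\n",
              object@slope, object@intercept, object@rSquared, object@pValue,
              if (length(object@inlierMask))
                sprintf(", %d/%d inliers", sum(object@inlierMask),
                        length(object@inlierMask)) else ""))
})

## internal: evaluate expr under a temporary RNG state seeded with `seed`,
## restoring the caller's RNG afterwards.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## internal: derive k reproducible child seeds below 2^31 from one seed
childSeeds <- function(seed, k) withSeed(seed, sample.int(2147483646L, k))
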