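## Per-tomogram summary metrics derived from a quality profile: the
## slice-count thickness estimate  #(score > threshold)  and TomoScore,
## the mean quality of the slices above the feature-presence threshold.
## The threshold defaults to 0.2, the score of the coarsest feature-bearing
## category, so "above threshold" means "contains biological features".

.profileScores <- function(profile) {
  if (is(profile, "QualityProfile")) profile@scores
  else if (is.numeric(profile)) profile
  else stop("profile must be a QualityProfile or a numeric vector")
}

.checkThreshold <- function(threshold) {
  if (length(threshold) != 1L || threshold < 0 || threshold > 1)
    stop("threshold must be a single value in [0, 1]")
  threshold
}

#' Estimate specimen thickness in slices
#'
#' Counts the slices whose predicted quality score exceeds the
#' feature-presence threshold (strictly: a score of exactly `threshold`
#' does not count). With `contiguous = TRUE` the longest contiguous run of
#' above-threshold slices is returned instead of the plain count.
#'
#' @param profile a [QualityProfile-class] or numeric score vector.
#' @param threshold feature-presence cutoff in [0, 1] (default 0.2).
#' @param contiguous use the longest-run variant (default `FALSE`).
#' @return Integer slice count.
#' @export
#' @examples
#' estimateThickness(c(0.1, 0.25, 0.5, 0.25, 0.1))  # 3
estimateThickness <- function(profile, threshold = 0.2, contiguous = FALSE) {
  .checkThreshold(threshold)
  above <- .profileScores(profile) > threshold
  if (!contiguous) return(sum(above))
  best <- run <- 0L
  for (a in above) {
    run <- if (a) run + 1L else 0L
    best <- max(best, run)
  }
  best
}

#' TomoScore: mean quality of feature-bearing slices
#'
#' The average predicted quality score over the slices scoring above the
#' feature-presence threshold. 0 means no slice reveals cellular structure
#' (no slice above threshold; returned by convention since the mean is then
#' undefined); 1 would be a theoretically perfect tomogram.
#'
#' @inheritParams estimateThickness
#' @return A value in [0, 1].
#' @export
#' @examples
#' tomoScore(c(0.1, 0.3, 0.5, 0.3, 0.1))  # (0.3 + 0.5 + 0.3) / 3
tomoScore <- function(profile, threshold = 0.2) {
  .checkThreshold(threshold)
  sc <- .profileScores(profile)
  above <- sc > threshold
  if (!any(above)) return(0)
  mean(sc[above])
}

#' Score a tomogram and summarize it as a report
#'
#' Runs [predictVolume()] and derives the thickness estimate (in slices and
#' in nm) and TomoScore. The nm conversion uses the volume's voxel size
#' times `binning`, since binning history is not recoverable from a volume
#' alone (e.g. a bin2-of-bin2 reconstruction needs `binning = 4` relative
#' to the acquisition pixel size recorded in the header — or `binning = 1`
#' if the header already reflects the binned voxel size).
#'
#' @param volume a [TomoVolume-class].
#' @param model a trained [QualityModel-class].
#' @param threshold feature-presence cutoff (default 0.2).
#' @param binning net binning factor applied to `apix` for the nm estimate.
#' @param tomogramId id recorded on the report.
#' @return A [TomoReport-class].
#' @export
tomoReport <- function(volume, model, threshold = 0.2, binning = 1,
                       tomogramId = "") {
  profile <- predictVolume(model, volume, tomogramId = tomogramId)
  profileReport(profile, threshold = threshold, binning = binning)
}

#' @rdname tomoReport
#' @param profile a precomputed [QualityProfile-class].
#' @export
profileReport <- function(profile, threshold = 0.2, binning = 1) {
  th <- estimateThickness(profile, threshold)
  new("TomoReport", profile = profile, thicknessEst = as.integer(th),
      thicknessNm = th * profile@apix * binning / 10,
      tomoscore = tomoScore(profile, threshold), threshold = threshold)
}

#' Tabulate and rank tomogram reports
#'
#' @param reports list of [TomoReport-class].
#' @return `data.frame(tomogram_id, n_slices, thickness_est, thickness_nm,
#'   tomoscore)` sorted by descending TomoScore — the screening order for
#'   further analysis.
#' @export
rankReports <- function(reports) {
  df <- do.call(rbind, lapply(reports, as.data.frame))
  df[order(-df$tomoscore), , drop = FALSE]
}

#' @describeIn rankReports one-row summary of a single report.
#' @param x a [TomoReport-class].
#' @param row.names,optional,... ignored (S3 compatibility).
#' @export
as.data.frame.TomoReport <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
  data.frame(tomogram_id = x@profile@tomogramId,
             n_slices = length(x@profile@scores),
             thickness_est = x@thicknessEst,
             thickness_nm = x@thicknessNm,
             tomoscore = x@tomoscore,
             stringsAsFactors = FALSE)
}

#' Serialize a report as JSON
#'
#' @param report a [TomoReport-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeReport <- function(report, path) {
  jsonlite::write_json(
    list(tomogram_id = report@profile@tomogramId,
         n_slices = length(report@profile@scores),
         thickness_est = report@thicknessEst,
         thickness_nm = report@thicknessNm,
         tomoscore = report@tomoscore,
         threshold = report@threshold,
         scores = report@profile@scores),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
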