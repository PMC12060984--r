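## Evaluation statistics: per-tomogram Pearson correlation of predicted vs
## labeled profiles, even/odd consistency bounds, RANSAC thickness
## regression, and the log2 dose-response fit.

#' Pearson correlation between predicted and labeled profiles
#'
#' Standard Pearson r with a two-sided t-distribution p-value. A constant
#' sequence (e.g. an all-zero label profile of a featureless tomogram) has
#' no defined correlation and yields status `"undefined"` rather than an
#' error.
#'
#' @param predicted a [QualityProfile-class] or numeric vector.
#' @param labeled numeric score sequence of the same length (>= 3).
#' @return `list(r, p, status)` with status `"ok"` or `"undefined"`.
#' @export
pearsonProfile <- function(predicted, labeled) {
  x <- .profileScores(predicted)
  y <- as.numeric(labeled)
  if (length(x) != length(y))
    stop(sprintf("length mismatch: %d predicted vs %d labeled",
                 length(x), length(y)))
  if (length(x) < 3L) stop("need at least 3 slices")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, status = "undefined"))
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, status = "ok")
}

#' Even/odd half-set consistency of quality profiles
#'
#' Summarizes the per-slice score differences between profiles of two
#' half-dose reconstructions of the same specimen. The reference bound is
#' 1/6 (16.7%), the step size of the discrete human categorization: a
#' consistent model keeps every per-slice difference below one human
#' category step.
#'
#' @param profileA,profileB [QualityProfile-class] or numeric vectors of
#'   equal length.
#' @param threshold feature-presence cutoff used for the TomoScore
#'   difference.
#' @return `list(maxDiff, meanDiff, withinHumanStep, tomoScoreDiff)` where
#'   `withinHumanStep` is `maxDiff < 1/6`.
#' @export
evenOddConsistency <- function(profileA, profileB, threshold = 0.2) {
  a <- .profileScores(profileA)
  b <- .profileScores(profileB)
  if (length(a) != length(b))
    stop(sprintf("length mismatch: %d vs %d slices", length(a), length(b)))
  d <- abs(a - b)
  list(maxDiff = max(d), meanDiff = mean(d),
       withinHumanStep = max(d) < 1 / 6,
       tomoScoreDiff = abs(tomoScore(a, threshold) - tomoScore(b, threshold)))
}

.fitFromLm <- function(fit, inlierMask = logical(0)) {
  sm <- suppressWarnings(summary(fit))  # degenerate perfect fits are valid here
  co <- stats::coef(sm)
  p <- if (nrow(co) >= 2L) co[2L, 4L] else NA_real_
  r2 <- sm$r.squared
  new("FitResult",
      slope = unname(stats::coef(fit)[2L]),
      intercept = unname(stats::coef(fit)[1L]),
      rSquared = if (is.nan(r2)) NA_real_ else r2,
      pValue = if (is.nan(p)) NA_real_ else p,
      inlierMask = inlierMask)
}

#' Robust line fit by random sample consensus (RANSAC)
#'
#' Repeatedly fits a line through a random minimal sample (2 points), counts
#' points within the inlier residual threshold, and refits by ordinary least
#' squares on the largest consensus set. Used to regress estimated against
#' measured thickness in the presence of outlier tomograms (missing-wedge
#' smearing, tilted samples).
#'
#' @param x,y numeric vectors, length >= 3.
#' @param nIter sampling iterations (default 1000).
#' @param inlierThreshold absolute residual bound for inliers; default
#'   1.5 x MAD of the residuals of a preliminary least-squares fit.
#' @param minInliers minimum consensus size (default `max(3, floor(n/2))`).
#' @param seed integer seed.
#' @return A [FitResult-class] with the consensus `inlierMask`.
#' @export
ransacFit <- function(x, y, nIter = 1000L, inlierThreshold = NULL,
                      minInliers = NULL, seed = 1L) {
  n <- length(x)
  if (length(y) != n) stop("x and y must be matched in length")
  if (n < 3L) stop("need at least 3 points")
  if (is.null(inlierThreshold)) {
    pre <- stats::lm(y ~ x)
    inlierThreshold <- 1.5 * stats::mad(stats::residuals(pre))
  }
  if (is.null(minInliers)) minInliers <- max(3L, floor(n / 2))
  eps <- 1e-9 * (1 + max(abs(y)))
  best <- NULL
  bestCount <- -1L
  bestRss <- Inf
  withSeed(seed, {
    for (it in seq_len(nIter)) {
      s <- sample.int(n, 2L)
      dx <- x[s[2L]] - x[s[1L]]
      if (dx == 0) next
      sl <- (y[s[2L]] - y[s[1L]]) / dx
      ic <- y[s[1L]] - sl * x[s[1L]]
      res <- abs(y - (ic + sl * x))
      inl <- res <= inlierThreshold + eps
      cnt <- sum(inl)
      rss <- sum(res[inl]^2)
      if (cnt > bestCount || (cnt == bestCount && rss < bestRss)) {
        bestCount <- cnt
        bestRss <- rss
        best <- inl
      }
    }
  })
  if (is.null(best) || bestCount < minInliers)
    stop(sprintf("no consensus set of >= %d inliers found", minInliers))
  fit <- stats::lm(y[best] ~ x[best])
  mask <- best
  .fitFromLm(fit, inlierMask = mask)
}

#' TomoScore dose response as percent of the full-dose score
#'
#' Expresses each dose point's TomoScore as a percentage of the
#' maximum-dose (reference) TomoScore, the representation used to locate
#' the optimum accumulated-dose range.
#'
#' @param doses accumulated doses in e-/A^2 (>= 2 values including the
#'   reference maximum).
#' @param tomoscores matched TomoScore values; the score at the maximum
#'   dose must be > 0.
#' @return A [DoseResponse-class] sorted by dose.
#' @export
doseResponse <- function(doses, tomoscores) {
  if (length(doses) != length(tomoscores))
    stop("doses and tomoscores must be matched in length")
  if (length(doses) < 2L) stop("need at least 2 dose points")
  o <- order(doses)
  doses <- doses[o]
  tomoscores <- tomoscores[o]
  ref <- tomoscores[length(tomoscores)]
  if (ref <= 0) stop("TomoScore at the reference (maximum) dose must be > 0")
  new("DoseResponse", doses = doses, tomoscores = tomoscores,
      percentOfMax = tomoscores / ref * 100)
}

#' Linear fit of percent-of-max TomoScore against log2 dose
#'
#' Ordinary least squares of the percent-of-max response on `log2(dose)`,
#' quantifying the (approximately linear in log2 dose) quality-vs-dose
#' trend.
#'
#' @param response a [DoseResponse-class] with >= 3 dose points, all > 0.
#' @return A [FitResult-class].
#' @export
log2DoseFit <- function(response) {
  stopifnot(is(response, "DoseResponse"))
  if (any(response@doses <= 0)) stop("all doses must be > 0")
  if (length(response@doses) < 3L) stop("need at least 3 dose points")
  l2 <- log2(response@doses)
  .fitFromLm(stats::lm(response@percentOfMax ~ l2))
}
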