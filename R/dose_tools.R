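## Dose fractionation tools: even/odd frame splitting, recursive dose
## series, evenly spaced frame extraction, frame averaging, and Fourier
## ring correlation between half-set images.
##
## Frame indices are 0-based: "even" frames are positions 0, 2, 4, ...  For
## an odd frame count the even half is one frame larger, so dose is
## conserved exactly and halved exactly whenever counts are even.

.stackSubset <- function(stack, idx) {
  initialize(stack, frames = stack@frames[, , idx, drop = FALSE])
}

#' Split a tilt-movie series into even-frame and odd-frame halves
#'
#' Every stack is partitioned by 0-based frame parity, preserving order.
#' The two halves carry identical signal with independent noise; their
#' doses sum to the input dose, and are exactly equal for even frame
#' counts (e.g. a 400 e-/A^2 series of 152-frame stacks splits into two
#' 200 e-/A^2 series of 76 frames).
#'
#' @param series a [TiltMovieSeries-class]; every stack needs >= 2 frames.
#' @return `list(even = , odd = )` of [TiltMovieSeries-class].
#' @export
splitEvenOdd <- function(series) {
  stopifnot(is(series, "TiltMovieSeries"))
  ev <- od <- vector("list", length(series@stacks))
  for (i in seq_along(series@stacks)) {
    st <- series@stacks[[i]]
    n <- dim(st@frames)[3L]
    if (n < 2L)
      stop(sprintf("stack %d has %d frame(s); need >= 2 to split", i, n))
    ev[[i]] <- .stackSubset(st, seq(1L, n, by = 2L))
    od[[i]] <- .stackSubset(st, seq(2L, n, by = 2L))
  }
  list(even = new("TiltMovieSeries", stacks = ev),
       odd = new("TiltMovieSeries", stacks = od))
}

#' Recursive even/odd dose series
#'
#' Iteratively splits the series and keeps one parity, producing series at
#' roughly halving doses (total/2, total/4, ...); halving is exact while
#' frame counts remain even. This reproduces the accumulated-dose ladder
#' 200, 100, 50, ... e-/A^2 from a 400 e-/A^2 / 152-frame acquisition, the
#' low-dose tail differing only by integer-frame rounding.
#'
#' @param series a [TiltMovieSeries-class].
#' @param rounds number of halvings; `rounds = 0` returns an empty list.
#' @param keep which parity to retain at each round.
#' @return List of `rounds` [TiltMovieSeries-class] at decreasing doses.
#' @export
recursiveSplit <- function(series, rounds, keep = c("even", "odd")) {
  keep <- match.arg(keep)
  out <- vector("list", rounds)
  cur <- series
  for (r in seq_len(rounds)) {
    counts <- vapply(cur@stacks, function(s) dim(s@frames)[3L], integer(1))
    if (any(counts < 2L))
      stop(sprintf("round %d: stack %d is depleted (%d frame(s) left)",
                   r, which(counts < 2L)[1], min(counts)))
    cur <- splitEvenOdd(cur)[[keep]]
    out[[r]] <- cur
  }
  out
}

#' Extract evenly spaced frames
#'
#' Keeps `k = round(fraction * n)` evenly spaced frames per stack (0-based
#' indices `floor(j * n / k)`), the scheme behind intermediate dose points
#' such as 256/128/64/32/16 e-/A^2 from a 400 e-/A^2 series.
#'
#' @param series a [TiltMovieSeries-class].
#' @param fraction fraction of frames to keep, in (0, 1].
#' @return A [TiltMovieSeries-class] at `~fraction` of the input dose.
#' @export
extractFraction <- function(series, fraction) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  stacks <- lapply(seq_along(series@stacks), function(i) {
    st <- series@stacks[[i]]
    n <- dim(st@frames)[3L]
    k <- round(fraction * n)
    if (k < 1L)
      stop(sprintf("fraction %g keeps no frames of stack %d (n = %d)",
                   fraction, i, n))
    .stackSubset(st, floor((seq_len(k) - 1L) * n / k) + 1L)
  })
  new("TiltMovieSeries", stacks = stacks)
}

#' Average the frames of one stack
#'
#' Pixel-wise mean over frames — the motion-free analog of merging aligned
#' movie frames into one tilt projection.
#'
#' @param stack a [FrameStack-class] with >= 1 frame.
#' @return A [SliceImage-class].
#' @export
averageFrames <- function(stack) {
  stopifnot(is(stack, "FrameStack"))
  d <- dim(stack@frames)
  if (d[3L] < 1L) stop("stack has no frames")
  m <- matrix(rowMeans(matrix(stack@frames, d[1L] * d[2L], d[3L])),
              d[1L], d[2L])
  new("SliceImage", pixels = m, apix = stack@apix)
}

#' Fourier ring correlation between two images
#'
#' Standard half-set similarity measure: per spatial-frequency ring, the
#' real part of the cross-spectrum normalized by the geometric mean of the
#' ring energies,
#' `Re(sum F_A conj(F_B)) / sqrt(sum |F_A|^2 * sum |F_B|^2)`.
#' Rings are `ringWidth` Fourier pixels wide; the DC term is excluded and
#' rings run to the Nyquist frequency (0.5 cycles/pixel).
#'
#' @param imageA,imageB [SliceImage-class] or numeric matrices of equal
#'   shape.
#' @param ringWidth ring width in Fourier pixels (> 0).
#' @return An [FRCCurve-class].
#' @export
frc <- function(imageA, imageB, ringWidth = 1) {
  a <- if (is(imageA, "SliceImage")) pixels(imageA) else imageA
  b <- if (is(imageB, "SliceImage")) pixels(imageB) else imageB
  if (!all(dim(a) == dim(b)))
    stop(sprintf("image shapes differ: %dx%d vs %dx%d",
                 nrow(a), ncol(a), nrow(b), ncol(b)))
  if (ringWidth <= 0) stop("ringWidth must be > 0")
  fa <- stats::fft(a)
  fb <- stats::fft(b)
  nr <- nrow(a); nc <- ncol(a)
  fr <- (seq_len(nr) - 1L); fr[fr > nr / 2] <- fr[fr > nr / 2] - nr
  fc <- (seq_len(nc) - 1L); fc[fc > nc / 2] <- fc[fc > nc / 2] - nc
  rcyc <- sqrt(outer((fr / nr)^2, (fc / nc)^2, "+"))   # cycles/pixel
  nmin <- min(nr, nc)
  wc <- ringWidth / nmin                               # ring width, cycles/px
  bin <- floor(rcyc / wc)
  keep <- rcyc > 0                                      # exclude DC
  cross <- Re(fa * Conj(fb))
  ea <- Mod(fa)^2
  eb <- Mod(fb)^2
  radii <- correls <- numeric(0)
  for (m in sort(unique(bin[keep]))) {
    ctr <- (m + 0.5) * wc
    if (ctr > 0.5) break
    sel <- keep & bin == m
    denom <- sqrt(sum(ea[sel]) * sum(eb[sel]))
    if (denom == 0) next
    radii <- c(radii, ctr)
    correls <- c(correls, sum(cross[sel]) / denom)
  }
  new("FRCCurve", ringRadii = radii,
      correlations = pmin(pmax(correls, -1), 1), ringWidth = ringWidth)
}

#' @describeIn frc FRC curve as a data frame (radius, correlation).
#' @param x an [FRCCurve-class].
#' @param row.names,optional,... ignored (S3 compatibility).
#' @export
as.data.frame.FRCCurve <- function(x, row.names = NULL, optional = FALSE,
                                   ...) {
  data.frame(radius = x@ringRadii, correlation = x@correlations)
}
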