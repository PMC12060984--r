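## Category scheme, continuous targets, label-profile smoothing,
## rotation augmentation, tomogram-level partitioning and balanced sampling.

#' Map quality categories to continuous training targets
#'
#' The fixed ladder used for network targets: no-feature -> 0.0,
#' 6+px -> 0.2, 4-5px -> 0.4, 3px -> 0.6, 2px -> 0.8, 1px -> 1.0.
#' A score of 0.2 therefore marks the threshold for the presence of
#' biological features.
#'
#' @param category character vector of categories (see
#'   [qualityCategories()]).
#' @return Numeric vector of targets in `[0, 1]`.
#' @export
#' @examples
#' categoryToScore(c("3px", "1px", "no-feature"))  # 0.6 1.0 0.0
categoryToScore <- function(category) {
  ord <- match(category, .CATEGORIES)
  if (anyNA(ord))
    stop(sprintf("unknown category: %s",
                 paste(unique(category[is.na(ord)]), collapse = ", ")))
  c(0.0, 0.2, 0.4, 0.6, 0.8, 1.0)[ord]
}

.reflectIndex <- function(p, n) {
  ## symmetric boundary reflection of 1-based index p into 1..n
  while (p < 1L || p > n) {
    if (p < 1L) p <- 1L - p
    if (p > n) p <- 2L * n + 1L - p
  }
  p
}

#' Gaussian smoothing of a per-tomogram score profile
#'
#' Convolves a z-ordered score sequence with a normalized discrete Gaussian
#' kernel (truncated at +-3 sigma, renormalized to unit sum), turning
#' discrete per-slice category targets into a smooth depth profile.
#' Boundaries are handled by symmetric reflection, so constant sequences
#' are preserved exactly and output values stay within the input range.
#'
#' @param scoreProfile numeric score sequence, length >= 1.
#' @param sigma kernel width in slices, > 0 (default 3).
#' @return Smoothed numeric vector, same length as the input.
#' @export
smoothProfile <- function(scoreProfile, sigma = 3) {
  n <- length(scoreProfile)
  if (n == 0L) stop("score profile must be non-empty")
  if (sigma <= 0) stop("sigma must be > 0")
  h <- ceiling(3 * sigma)
  g <- stats::dnorm(-h:h, sd = sigma)
  g <- g / sum(g)
  vapply(seq_len(n), function(i) {
    idx <- vapply(i + (-h:h), .reflectIndex, integer(1), n = n)
    sum(g * scoreProfile[idx])
  }, numeric(1))
}

.rot90 <- function(m) t(m)[rev(seq_len(ncol(m))), , drop = FALSE]

#' Rotation augmentation of the rare coarse categories
#'
#' Slices of the two scarce categories are augmented by 90-degree rotations:
#' each "6+px" slice yields itself plus rotations by 90, 180 and 270 degrees
#' (x4 in total), each "4-5px" slice yields itself plus rotations by 90 and
#' 180 degrees (x3). All other categories pass through unchanged. Rotated
#' copies keep the original's label, tomogram id and z index.
#'
#' @param dataset list of [LabeledSlice-class].
#' @return Augmented list of [LabeledSlice-class].
#' @export
augmentSlices <- function(dataset) {
  out <- vector("list", 0L)
  for (ls in dataset) {
    nrot <- switch(ls@category, "6+px" = 3L, "4-5px" = 2L, 0L)
    out[[length(out) + 1L]] <- ls
    if (nrot > 0L) {
      p <- pixels(ls@slice)
      for (r in seq_len(nrot)) {
        p <- .rot90(p)
        out[[length(out) + 1L]] <-
          initialize(ls, slice = initialize(ls@slice, pixels = p))
      }
    }
  }
  out
}

#' Tomogram-level train/validation/test partition
#'
#' Splits tomogram ids (not slices) uniformly at random without replacement,
#' so no slice of a held-out tomogram ever appears in training (neighbouring
#' slices of one tomogram are nearly identical). The reference corpus split
#' is 98 train / 1 validation / 15 test out of 114 tomograms.
#'
#' @param ids character (or coercible) tomogram ids.
#' @param nTrain,nVal training and validation set sizes;
#'   `nTrain + nVal <= length(ids)`; the remainder becomes the test set.
#' @param seed integer seed.
#' @return A [TomoPartition-class].
#' @export
#' @examples
#' partitionTomograms(sprintf("tomo%03d", 1:114), 98, 1, seed = 1)
partitionTomograms <- function(ids, nTrain, nVal, seed = 1L) {
  ids <- as.character(ids)
  if (nTrain + nVal > length(ids))
    stop("nTrain + nVal must not exceed the number of tomogram ids")
  perm <- withSeed(seed, sample(ids))
  new("TomoPartition",
      trainIds = perm[seq_len(nTrain)],
      valIds = if (nVal > 0) perm[nTrain + seq_len(nVal)] else character(0),
      testIds = if (length(ids) > nTrain + nVal)
        perm[(nTrain + nVal + 1L):length(ids)] else character(0))
}

#' Balanced per-category sampling of labeled slices
#'
#' Draws exactly `perCategory` slices of each of the six categories,
#' uniformly without replacement (the reference corpus uses 2500 per
#' category, 15,000 slices in total). A category with too few slices is an
#' error unless `replace = TRUE` opts in to upsampling.
#'
#' @param pool list of [LabeledSlice-class] (typically after
#'   [augmentSlices()]).
#' @param perCategory slices to draw per category.
#' @param seed integer seed.
#' @param replace sample with replacement (default `FALSE`).
#' @return List of `6 * perCategory` [LabeledSlice-class] objects.
#' @export
balancedSample <- function(pool, perCategory, seed = 1L, replace = FALSE) {
  cats <- vapply(pool, function(s) s@category, character(1))
  idx <- withSeed(seed, {
    picked <- integer(0)
    for (cat in .CATEGORIES) {
      have <- which(cats == cat)
      if (!replace && length(have) < perCategory)
        stop(sprintf("category '%s' has only %d slices, need %d",
                     cat, length(have), perCategory))
      picked <- c(picked,
                  have[sample.int(length(have), perCategory, replace = replace)])
    }
    picked
  })
  pool[idx]
}

#' Tabulate labeled slices
#'
#' @param slices list of [LabeledSlice-class].
#' @param split optional split name recorded per row.
#' @return `data.frame(tomogram_id, z_index, category, target, split)`.
#' @export
labeledSliceTable <- function(slices, split = NA_character_) {
  data.frame(
    tomogram_id = vapply(slices, function(s) s@tomogramId, character(1)),
    z_index = vapply(slices, function(s) s@zIndex, integer(1)),
    category = vapply(slices, function(s) s@category, character(1)),
    target = vapply(slices, function(s) s@target, numeric(1)),
    split = split, stringsAsFactors = FALSE)
}

#' Write a partition manifest as JSON
#'
#' @param partition a [TomoPartition-class].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writePartition <- function(partition, path) {
  jsonlite::write_json(
    list(train = partition@trainIds, val = partition@valIds,
         test = partition@testIds),
    path, auto_unbox = FALSE)
  invisible(path)
}
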