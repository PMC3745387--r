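## Objective histogram-split thresholding and masked intensity measurement.

#' @include AllClasses.R
NULL

## Core numeric routine: split-variance scan over the gray levels present.
## Background class = values <= t, foreground = values > t; candidates are
## every present gray level except the maximum (the split must leave both
## sides nonempty). Ties go to the lower level.
splitVarianceScan <- function(values, method) {
  lev <- sort(unique(as.numeric(values)))
  if (length(lev) < 2L)
    stop("no split exists: image has fewer than 2 distinct gray levels")
  cnt <- tabulate(match(as.numeric(values), lev), nbins = length(lev))
  csN <- cumsum(cnt)
  csS <- cumsum(cnt * lev)
  csQ <- cumsum(cnt * lev^2)
  N <- csN[length(lev)]
  idx <- seq_len(length(lev) - 1L)
  n1 <- csN[idx]; n2 <- N - n1
  m1 <- csS[idx] / n1
  m2 <- (csS[length(lev)] - csS[idx]) / n2
  ## population variances per class; clamp tiny negatives from rounding
  v1 <- pmax(csQ[idx] / n1 - m1^2, 0)
  v2 <- pmax((csQ[length(lev)] - csQ[idx]) / n2 - m2^2, 0)
  obj <- if (method == "weighted") (n1 * v1 + n2 * v2) / N else v1 + v2
  k <- which.min(obj)  # first minimum = lowest level on ties
  list(level = lev[k], objective = obj[k])
}

#' @rdname computeThreshold
#' @export
setMethod("computeThreshold", "IntensityImage", function(object, method = c("weighted", "unweighted")) {
  method <- match.arg(method)
  res <- splitVarianceScan(object@pixels, method)
  new("ThresholdResult", level = as.integer(res$level),
      objective = res$objective, method = method)
})

#' @rdname computeThreshold
#' @export
setMethod("computeThreshold", "matrix", function(object, method = c("weighted", "unweighted")) {
  method <- match.arg(method)
  res <- splitVarianceScan(object, method)
  new("ThresholdResult", level = as.integer(res$level),
      objective = res$objective, method = method)
})

.binarizeCore <- function(image, level, template) {
  maxv <- 2^image@bitDepth - 1
  if (level < 0 || level > maxv)
    stop(sprintf("threshold level %d outside the image gray range [0, %d]",
                 level, maxv))
  bits <- image@pixels > level
  if (!is.null(template)) {
    if (!is(template, "BinaryMask"))
      stop("template must be a BinaryMask")
    if (!identical(dim(template@bits), dim(bits)))
      stop("template dimensions do not match the image")
    bits <- bits & template@bits
  }
  BinaryMask(bits)
}

#' @rdname binarize
#' @export
setMethod("binarize", signature("IntensityImage", "ThresholdResult"),
  function(object, threshold, template = NULL)
    .binarizeCore(object, threshold@level, template))

#' @rdname binarize
#' @export
setMethod("binarize", signature("IntensityImage", "numeric"),
  function(object, threshold, template = NULL) {
    stopifnot(length(threshold) == 1L, is.finite(threshold))
    .binarizeCore(object, as.integer(threshold), template)
  })

#' Mean masked fluorescence intensity across a z-stack
#'
#' For the mitochondrial immunofluorescence assay: the fluorescence
#' emission through a region of interest is summarized as the mean of the
#' per-slice mean intensities over the masked pixels, in arbitrary
#' fluorescence units.
#'
#' @param zstack a list of \linkS4class{IntensityImage} slices (or one
#'   image), all sharing dimensions with `mask`.
#' @param mask a \linkS4class{BinaryMask} with at least one positive pixel.
#' @return a single numeric value.
#' @examples
#' sl <- IntensityImage(matrix(100L, 4, 4))
#' m <- BinaryMask(matrix(TRUE, 4, 4))
#' meanMaskedIntensity(list(sl), m)
#' @export
meanMaskedIntensity <- function(zstack, mask) {
  if (is(zstack, "IntensityImage")) zstack <- list(zstack)
  stopifnot(length(zstack) >= 1L, is(mask, "BinaryMask"))
  if (mask@nPositive == 0L) stop("empty ROI")
  sliceMeans <- vapply(zstack, function(sl) {
    stopifnot(is(sl, "IntensityImage"))
    if (!identical(dim(sl@pixels), dim(mask@bits)))
      stop("slice dimensions do not match the mask")
    mean(sl@pixels[mask@bits])
  }, numeric(1))
  mean(sliceMeans)
}
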