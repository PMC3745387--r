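#' Compute an objective split-variance threshold for one channel
#'
#' Scans every gray level present in the image and returns the split point
#' that minimizes the configured split-variance objective over the image
#' histogram (one bin per integer gray level, no smoothing).
#'
#' @param object an \linkS4class{IntensityImage} (or a numeric/integer
#'   matrix of gray levels).
#' @param method `"weighted"` (default) minimizes the within-class variance
#'   weighted by class pixel counts (the Otsu criterion); `"unweighted"`
#'   minimizes the plain sum of the two class variances.
#' @return a \linkS4class{ThresholdResult}.
#' @details Candidate splits place pixels with gray level `<= t` in the
#'   background class and `> t` in the foreground class. Ties in the
#'   objective are broken toward the lower level. A constant image admits
#'   no split and is an error.
#' @examples
#' img <- IntensityImage(matrix(c(10, 10, 200, 200), 2, 2))
#' computeThreshold(img)
#' @export
setGeneric("computeThreshold", function(object, method = c("weighted", "unweighted"))
  standardGeneric("computeThreshold"))

#' Binarize a channel at a threshold
#'
#' Pixels strictly greater than the threshold level are positive.
#'
#' @param object an \linkS4class{IntensityImage}.
#' @param threshold a \linkS4class{ThresholdResult} or a single gray level.
#' @param template optional \linkS4class{BinaryMask}; when supplied, the
#'   result is restricted to template-positive pixels (dimensions must
#'   match).
#' @return a \linkS4class{BinaryMask}.
#' @export
setGeneric("binarize", function(object, threshold, template = NULL)
  standardGeneric("binarize"))

#' Directional non-colocalization (appositional) score
#'
#' The fraction of pattern A positive pixels that lie outside pattern B:
#' `|A \ B| / |A|`. A score of 0 indicates complete overlap of A with B and
#' a score of 1 indicates no overlap.
#'
#' @param maskA,maskB \linkS4class{BinaryMask} objects of equal dimensions;
#'   `maskA` (the numerator pattern) must have at least one positive pixel.
#' @return a single numeric value in `[0, 1]`.
#' @examples
#' a <- BinaryMask(matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2))
#' b <- BinaryMask(matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2))
#' appositionScore(a, b)  # 0.5
#' @export
setGeneric("appositionScore", function(maskA, maskB)
  standardGeneric("appositionScore"))

#' @rdname IntensityImage-class
#' @param object an object.
#' @export
setGeneric("pixelData", function(object) standardGeneric("pixelData"))

#' @rdname IntensityImage-class
#' @export
setGeneric("bitDepth", function(object) standardGeneric("bitDepth"))

#' @rdname IntensityImage-class
#' @export
setGeneric("pixelSizeUm", function(object) standardGeneric("pixelSizeUm"))

#' @rdname IntensityImage-class
#' @export
setGeneric("channelLabel", function(object) standardGeneric("channelLabel"))

#' @rdname BinaryMask-class
#' @param object an object.
#' @export
setGeneric("maskBits", function(object) standardGeneric("maskBits"))

#' @rdname BinaryMask-class
#' @export
setGeneric("nPositive", function(object) standardGeneric("nPositive"))

#' @rdname ThresholdResult-class
#' @param object an object.
#' @export
setGeneric("thresholdLevel", function(object) standardGeneric("thresholdLevel"))
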