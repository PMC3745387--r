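## Central S4 data objects for the NMJ-disruption pipeline.

#' @include AllGenerics.R
NULL

CHANNEL_LABELS <- c("AChR", "AChE", "LAMB2", "SV2", "MITO")
DIAGNOSES <- c("CP", "IS")
COMBOS <- c("LAMB2-triple", "SV2-triple")

## Directional comparison codes: first letter = numerator stain, last letter
## = reference stain; R = AChR, E = AChE, L = laminin beta-2, V = SV2.
LAMB2_CODES <- c("ROE", "EOR", "LOE", "EOL", "LOR", "ROL")
SV2_CODES <- c("ROE", "EOR", "VOE", "EOV", "VOR", "ROV")
ALL_CODES <- c("ROE", "EOR", "LOE", "EOL", "LOR", "ROL", "VOE", "EOV", "VOR", "ROV")
CODE_LETTER <- c(AChR = "R", AChE = "E", LAMB2 = "L", SV2 = "V")

#' IntensityImage: one stain channel of one NMJ field
#'
#' A single-channel grayscale micrograph: an integer pixel grid with its
#' acquisition bit depth, physical pixel size, and stain label. The
#' reference acquisition setup is a monochrome 12-bit camera, so gray
#' levels run 0..4095 by default; 8- and 16-bit data are also supported.
#'
#' @slot pixels integer matrix of gray levels, all in `[0, 2^bitDepth - 1]`,
#'   both dimensions at least 2.
#' @slot bitDepth integer scalar, one of 8, 12 or 16 typically.
#' @slot pixelSizeUm positive numeric, micrometres per pixel.
#' @slot channel one of `"AChR"`, `"AChE"`, `"LAMB2"`, `"SV2"`, `"MITO"`.
#'
#' @param pixels numeric or integer matrix of gray levels.
#' @param bitDepth integer bit depth (default 12).
#' @param pixelSizeUm micrometres per pixel (default 0.1).
#' @param channel stain label (default `"AChR"`).
#' @return `IntensityImage()` returns an IntensityImage object.
#' @examples
#' img <- IntensityImage(matrix(0:3, 2, 2), bitDepth = 12L)
#' bitDepth(img)
#' @aliases pixelData bitDepth pixelSizeUm channelLabel
#' @export IntensityImage
#' @exportClass IntensityImage
setClass("IntensityImage",
  representation(
    pixels = "matrix",
    bitDepth = "integer",
    pixelSizeUm = "numeric",
    channel = "character"
  )
)

setValidity("IntensityImage", function(object) {
  msg <- character()
  px <- object@pixels
  if (!is.numeric(px)) msg <- c(msg, "pixels must be a numeric matrix")
  if (any(dim(px) < 2L)) msg <- c(msg, "both image dimensions must be >= 2")
  if (length(object@bitDepth) != 1L || object@bitDepth < 1L)
    msg <- c(msg, "bitDepth must be a positive integer scalar")
  maxv <- 2^object@bitDepth - 1
  if (is.numeric(px) && length(px) &&
      (anyNA(px) || min(px) < 0 || max(px) > maxv))
    msg <- c(msg, sprintf("pixel values must lie in [0, %d]", maxv))
  if (is.numeric(px) && length(px) && any(px != round(px)))
    msg <- c(msg, "pixel values must be integers")
  if (length(object@pixelSizeUm) != 1L || !is.finite(object@pixelSizeUm) ||
      object@pixelSizeUm <= 0)
    msg <- c(msg, "pixelSizeUm must be a positive scalar")
  if (length(object@channel) != 1L || !object@channel %in% CHANNEL_LABELS)
    msg <- c(msg, paste("channel must be one of:", paste(CHANNEL_LABELS, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

IntensityImage <- function(pixels, bitDepth = 12L, pixelSizeUm = 0.1,
                           channel = "AChR") {
  storage.mode(pixels) <- "integer"
  new("IntensityImage", pixels = pixels, bitDepth = as.integer(bitDepth),
      pixelSizeUm = pixelSizeUm, channel = channel)
}

#' BinaryMask: positive-pixel mask of one channel
#'
#' The result of thresholding a channel: a logical grid in which `TRUE`
#' marks a positive (foreground) pixel, together with the positive count.
#'
#' @slot bits logical matrix.
#' @slot nPositive integer, the number of `TRUE` entries (kept consistent
#'   by the validity method).
#'
#' @param bits logical matrix.
#' @return `BinaryMask()` returns a BinaryMask object.
#' @aliases maskBits nPositive
#' @export BinaryMask
#' @exportClass BinaryMask
setClass("BinaryMask",
  representation(bits = "matrix", nPositive = "integer")
)

setValidity("BinaryMask", function(object) {
  msg <- character()
  if (!is.logical(object@bits)) msg <- c(msg, "bits must be a logical matrix")
  if (anyNA(object@bits)) msg <- c(msg, "bits must not contain NA")
  if (is.logical(object@bits) && object@nPositive != sum(object@bits))
    msg <- c(msg, "nPositive does not equal the count of TRUE entries")
  if (length(msg)) msg else TRUE
})

BinaryMask <- function(bits) {
  new("BinaryMask", bits = bits, nPositive = as.integer(sum(bits)))
}

#' ThresholdResult: an objective histogram split
#'
#' The gray level `t` at which the image histogram is split into background
#' (`<= t`) and foreground (`> t`), together with the value of the
#' split-variance objective at `t` and which objective was used.
#'
#' @slot level integer gray level.
#' @slot objective numeric value of the objective at `level`.
#' @slot method `"weighted"` (count-weighted within-class variance, the
#'   Otsu criterion) or `"unweighted"` (plain sum of class variances).
#' @aliases thresholdLevel
#' @export
#' @exportClass ThresholdResult
setClass("ThresholdResult",
  representation(level = "integer", objective = "numeric", method = "character")
)

setValidity("ThresholdResult", function(object) {
  msg <- character()
  if (!object@method %in% c("weighted", "unweighted"))
    msg <- c(msg, "method must be 'weighted' or 'unweighted'")
  if (length(object@objective) != 1L || !is.finite(object@objective) ||
      object@objective < 0)
    msg <- c(msg, "objective must be a non-negative finite scalar")
  if (length(msg)) msg else TRUE
})

#' NMJRecord: one triple-stained NMJ
#'
#' One NMJ of one patient, carrying the three stain channels of its
#' staining combination: `"LAMB2-triple"` has channels AChR, AChE and
#' LAMB2; `"SV2-triple"` has AChR, AChE and SV2. Channels may be raw
#' \linkS4class{IntensityImage}s (thresholded internally during scoring)
#' or ready-made \linkS4class{BinaryMask}s; all grids must share
#' dimensions.
#'
#' @slot patientId character patient identifier.
#' @slot diagnosis `"CP"` or `"IS"`.
#' @slot nmjId character NMJ identifier, unique within the patient.
#' @slot combo `"LAMB2-triple"` or `"SV2-triple"`.
#' @slot channels named list of IntensityImage or BinaryMask objects.
#'
#' @param patientId,diagnosis,nmjId,combo,channels see slots.
#' @return `NMJRecord()` returns an NMJRecord object.
#' @export NMJRecord
#' @exportClass NMJRecord
setClass("NMJRecord",
  representation(
    patientId = "character",
    diagnosis = "character",
    nmjId = "character",
    combo = "character",
    channels = "list"
  )
)

setValidity("NMJRecord", function(object) {
  msg <- character()
  if (!object@diagnosis %in% DIAGNOSES)
    msg <- c(msg, "diagnosis must be 'CP' or 'IS'")
  if (!object@combo %in% COMBOS)
    msg <- c(msg, "combo must be 'LAMB2-triple' or 'SV2-triple'")
  need <- if (identical(object@combo, "LAMB2-triple"))
    c("AChR", "AChE", "LAMB2") else c("AChR", "AChE", "SV2")
  if (!setequal(names(object@channels), need))
    msg <- c(msg, paste("channels must be exactly:", paste(need, collapse = ", ")))
  dims <- lapply(object@channels, function(ch) {
    if (is(ch, "IntensityImage")) dim(ch@pixels)
    else if (is(ch, "BinaryMask")) dim(ch@bits)
    else NULL
  })
  if (any(vapply(dims, is.null, logical(1))))
    msg <- c(msg, "channels must be IntensityImage or BinaryMask objects")
  else if (length(dims) > 1L &&
           !all(vapply(dims[-1], function(d) identical(d, dims[[1]]), logical(1))))
    msg <- c(msg, "all channel grids must share dimensions")
  if (length(msg)) msg else TRUE
})

NMJRecord <- function(patientId, diagnosis, nmjId, combo, channels) {
  new("NMJRecord", patientId = as.character(patientId),
      diagnosis = as.character(diagnosis), nmjId = as.character(nmjId),
      combo = as.character(combo), channels = channels)
}

#' MorphometryTrace: digitized geometry of one TEM contact region
#'
#' Polylines and polygons digitized from one nerve-muscle contact region of
#' a transmission electron micrograph, in micrometres: the synaptic cleft
#' line, the traced postsynaptic fold paths (each starting on the cleft),
#' the marked fold-opening points along the cleft, the mitochondrion
#' outlines, and the nerve-terminal outline.
#'
#' @slot nmjId character NMJ identifier.
#' @slot group `"CP"` or `"IS"`.
#' @slot contactRegionIndex integer in 1..5 (five distinct contact regions
#'   are analyzed per NMJ, each defined by a distinct synaptic gutter).
#' @slot pixelSizeUm positive numeric, micrometres per pixel of the source
#'   micrograph (coordinates are already converted to micrometres).
#' @slot cleft two-column matrix, ordered polyline along the synaptic cleft.
#' @slot folds list of two-column matrices, each a fold path with >= 2
#'   points.
#' @slot foldEdges two-column matrix of fold-opening points lying on the
#'   cleft polyline, ordered by arc length.
#' @slot mitochondria list of two-column matrices, simple closed polygons.
#' @slot terminal two-column matrix, simple closed polygon of the nerve
#'   terminal (convex outlines are clipped exactly; see
#'   [mitoAreaFraction()]).
#'
#' @param nmjId,group,contactRegionIndex,pixelSizeUm,cleft,folds,foldEdges,mitochondria,terminal
#'   see slots.
#' @return `MorphometryTrace()` returns a MorphometryTrace object.
#' @export MorphometryTrace
#' @exportClass MorphometryTrace
setClass("MorphometryTrace",
  representation(
    nmjId = "character",
    group = "character",
    contactRegionIndex = "integer",
    pixelSizeUm = "numeric",
    cleft = "matrix",
    folds = "list",
    foldEdges = "matrix",
    mitochondria = "list",
    terminal = "matrix"
  )
)

setValidity("MorphometryTrace", function(object) {
  msg <- character()
  if (!object@group %in% DIAGNOSES) msg <- c(msg, "group must be 'CP' or 'IS'")
  if (object@contactRegionIndex < 1L || object@contactRegionIndex > 5L)
    msg <- c(msg, "contactRegionIndex must be in 1..5")
  if (object@pixelSizeUm <= 0) msg <- c(msg, "pixelSizeUm must be positive")
  ok2col <- function(m) is.matrix(m) && ncol(m) == 2L && all(is.finite(m))
  if (!ok2col(object@cleft) || nrow(object@cleft) < 2L)
    msg <- c(msg, "cleft must be a finite two-column matrix with >= 2 points")
  if (length(object@folds) &&
      !all(vapply(object@folds, function(f) ok2col(f) && nrow(f) >= 2L, logical(1))))
    msg <- c(msg, "each fold path must be a finite two-column matrix with >= 2 points")
  if (nrow(object@foldEdges) > 0L && !ok2col(object@foldEdges))
    msg <- c(msg, "foldEdges must be a finite two-column matrix")
  if (length(object@mitochondria) &&
      !all(vapply(object@mitochondria,
                  function(p) ok2col(p) && nrow(p) >= 3L, logical(1))))
    msg <- c(msg, "each mitochondrion must be a finite polygon with >= 3 vertices")
  if (!ok2col(object@terminal) || nrow(object@terminal) < 3L)
    msg <- c(msg, "terminal must be a finite polygon with >= 3 vertices")
  if (length(msg)) msg else TRUE
})

MorphometryTrace <- function(nmjId, group, contactRegionIndex, pixelSizeUm,
                             cleft, folds, foldEdges, mitochondria, terminal) {
  as2col <- function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  }
  new("MorphometryTrace",
      nmjId = as.character(nmjId), group = as.character(group),
      contactRegionIndex = as.integer(contactRegionIndex),
      pixelSizeUm = pixelSizeUm,
      cleft = as2col(cleft), folds = lapply(folds, as2col),
      foldEdges = if (length(foldEdges)) as2col(foldEdges) else
        matrix(numeric(0), 0, 2),
      mitochondria = lapply(mitochondria, as2col),
      terminal = as2col(terminal))
}

#' SignificanceMatrix: patient-versus-pool comparison flags
#'
#' The patients-by-codes grid of Bonferroni-controlled patient-versus-pool
#' outcomes: `"higher"` / `"lower"` when the patient's NMJ scores differ
#' from the pooled control scores at the per-test threshold (family alpha
#' divided by the number of patients tested), direction by median
#' difference; `"ns"` otherwise.
#'
#' @slot entries character matrix, rows = CP patient ids, columns =
#'   comparison codes, entries in `{"higher","lower","ns"}`.
#' @slot familyAlpha family-wise alpha.
#' @slot alphaPerTest per-test threshold = familyAlpha / nrow(entries).
#' @export
#' @exportClass SignificanceMatrix
setClass("SignificanceMatrix",
  representation(entries = "matrix", familyAlpha = "numeric",
                 alphaPerTest = "numeric")
)

setValidity("SignificanceMatrix", function(object) {
  msg <- character()
  if (!is.character(object@entries))
    msg <- c(msg, "entries must be a character matrix")
  else if (!all(object@entries %in% c("higher", "lower", "ns")))
    msg <- c(msg, "entries must be 'higher', 'lower' or 'ns'")
  if (nrow(object@entries) > 0L &&
      abs(object@alphaPerTest - object@familyAlpha / nrow(object@entries)) > 1e-12)
    msg <- c(msg, "alphaPerTest must equal familyAlpha / number of patients")
  if (length(msg)) msg else TRUE
})

#' SimulationProfile: study-condition parameters for the generators
#'
#' Bundles the group-level parameters the synthetic-data generators draw
#' from: per-code target median outside-fractions with between-patient and
#' within-patient dispersion, image-rendering parameters, TEM morphometry
#' parameters, and qPCR plate parameters. Two built-in profiles,
#' `"is-default"` and `"cp-default"`, carry the published group values
#' (per-patient median score tables, TEM group means with sd back-computed
#' from printed SEM times sqrt(25), and per-subject telomere T/S ratios).
#'
#' @slot name profile name.
#' @slot group `"CP"` or `"IS"`.
#' @slot codeTargets data.frame with columns `code`, `median` (target
#'   median outside-fraction per comparison code).
#' @slot betweenSdLogit between-patient sd of the outside-fraction on the
#'   logit scale.
#' @slot withinSd within-patient NMJ-to-NMJ jitter sd on the fraction
#'   scale.
#' @slot imaging list: `imageSize`, `nDiscs`, `radiusRange`, `fgMean`,
#'   `fgSd`, `bgMean`, `bgSd`, `bitDepth`, `pixelSizeUm`.
#' @slot tem list: `spacingMeanUm`, `spacingSdUm`, `foldLenMeanUm`,
#'   `foldLenSdUm`, `mitoFracMean`, `mitoFracSd`, `foldsPerRegion`.
#' @slot qpcr list: `trueTS` (named per-sample true T/S ratios),
#'   `calibrator`, `cqNoiseSd`, `baseCqTelomere`, `baseCqScg`,
#'   `efficiency`.
#' @seealso [simulationProfile()]
#' @export
#' @exportClass SimulationProfile
setClass("SimulationProfile",
  representation(
    name = "character",
    group = "character",
    codeTargets = "data.frame",
    betweenSdLogit = "numeric",
    withinSd = "numeric",
    imaging = "list",
    tem = "list",
    qpcr = "list"
  )
)

setValidity("SimulationProfile", function(object) {
  msg <- character()
  ct <- object@codeTargets
  if (!all(c("code", "median") %in% names(ct)))
    msg <- c(msg, "codeTargets needs columns 'code' and 'median'")
  else if (any(ct$median < 0 | ct$median > 1))
    msg <- c(msg, "code target medians must lie in [0, 1]")
  if (object@betweenSdLogit < 0 || object@withinSd < 0)
    msg <- c(msg, "dispersions must be >= 0")
  if (!object@group %in% DIAGNOSES) msg <- c(msg, "group must be 'CP' or 'IS'")
  if (length(msg)) msg else TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "IntensityImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("IntensityImage: %s, %d x %d px, %d-bit, %.4g um/px, range [%d, %d]\n",
              object@channel, d[1], d[2], object@bitDepth, object@pixelSizeUm,
              min(object@pixels), max(object@pixels)))
})

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object@bits)
  cat(sprintf("BinaryMask: %d x %d px, %d positive (%.1f%%)\n",
              d[1], d[2], object@nPositive,
              100 * object@nPositive / length(object@bits)))
})

setMethod("show", "ThresholdResult", function(object) {
  cat(sprintf("ThresholdResult: level %d (%s objective = %.6g)\n",
              object@level, object@method, object@objective))
})

setMethod("show", "NMJRecord", function(object) {
  cat(sprintf("NMJRecord: patient %s (%s), NMJ %s, %s [%s]\n",
              object@patientId, object@diagnosis, object@nmjId, object@combo,
              paste(names(object@channels), collapse = ", ")))
})

setMethod("show", "MorphometryTrace", function(object) {
  cat(sprintf(
    "MorphometryTrace: NMJ %s (%s), region %d: %d folds, %d fold edges, %d mitochondria\n",
    object@nmjId, object@group, object@contactRegionIndex,
    length(object@folds), nrow(object@foldEdges), length(object@mitochondria)))
})

setMethod("show", "SignificanceMatrix", function(object) {
  cat(sprintf("SignificanceMatrix: %d patients x %d codes (family alpha %.3g, per-test %.3g)\n",
              nrow(object@entries), ncol(object@entries),
              object@familyAlpha, object@alphaPerTest))
  nf <- sum(apply(object@entries != "ns", 1L, any))
  cat(sprintf("  %d patient(s) with >= 1 significant comparison\n", nf))
})

setMethod("show", "SimulationProfile", function(object) {
  cat(sprintf("SimulationProfile '%s' (group %s): %d code targets\n",
              object@name, object@group, nrow(object@codeTargets)))
})

## ---- accessors ----------------------------------------------------------

#' @rdname IntensityImage-class
setMethod("pixelData", "IntensityImage", function(object) object@pixels)

#' @rdname IntensityImage-class
setMethod("bitDepth", "IntensityImage", function(object) object@bitDepth)

#' @rdname IntensityImage-class
setMethod("pixelSizeUm", "IntensityImage", function(object) object@pixelSizeUm)

#' @rdname MorphometryTrace-class
#' @param object a MorphometryTrace.
setMethod("pixelSizeUm", "MorphometryTrace", function(object) object@pixelSizeUm)

#' @rdname IntensityImage-class
setMethod("channelLabel", "IntensityImage", function(object) object@channel)

#' @rdname BinaryMask-class
setMethod("maskBits", "BinaryMask", function(object) object@bits)

#' @rdname BinaryMask-class
setMethod("nPositive", "BinaryMask", function(object) object@nPositive)

#' @rdname ThresholdResult-class
setMethod("thresholdLevel", "ThresholdResult", function(object) object@level)

#' Entries, alpha and dimensions of a SignificanceMatrix
#'
#' @param object a \linkS4class{SignificanceMatrix}.
#' @return `significanceEntries()` the character matrix of flags;
#'   `alphaPerTest()` the per-test threshold.
#' @export
significanceEntries <- function(object) {
  stopifnot(is(object, "SignificanceMatrix"))
  object@entries
}

#' @rdname significanceEntries
#' @export
alphaPerTest <- function(object) {
  stopifnot(is(object, "SignificanceMatrix"))
  object@alphaPerTest
}
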