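## Directional non-colocalization scoring of thresholded stain pairs and
## patient-level aggregation with the >= 15-NMJ eligibility rule.

#' @include AllClasses.R imaging.R
NULL

#' @rdname appositionScore
#' @export
setMethod("appositionScore", signature("BinaryMask", "BinaryMask"),
  function(maskA, maskB) {
    if (!identical(dim(maskA@bits), dim(maskB@bits)))
      stop("mask dimensions differ")
    nA <- maskA@nPositive
    if (nA == 0L)
      stop("undefined score (empty numerator pattern)")
    sum(maskA@bits & !maskB@bits) / nA
  })

## Codes for a staining combination, as ordered (numerator, reference)
## stain pairs. Both directions of each unordered pair are scored.
comboCodes <- function(combo) {
  third <- if (identical(combo, "LAMB2-triple")) "LAMB2" else "SV2"
  pairs <- rbind(
    c("AChR", "AChE"), c("AChE", "AChR"),
    c(third, "AChE"), c("AChE", third),
    c(third, "AChR"), c("AChR", third))
  data.frame(
    code = paste0(CODE_LETTER[pairs[, 1]], "O", CODE_LETTER[pairs[, 2]]),
    numerator = pairs[, 1], reference = pairs[, 2],
    stringsAsFactors = FALSE)
}

#' Score one NMJ: all six directional non-colocalization scores
#'
#' Thresholds each channel of the record (when channels are intensity
#' images) with the objective split-variance algorithm and computes the six
#' directional scores of the record's staining combination: both directions
#' for each of the three stain pairs. Channels supplied as ready-made
#' \linkS4class{BinaryMask}s are used as-is.
#'
#' @param record an \linkS4class{NMJRecord}.
#' @param method threshold objective passed to [computeThreshold()].
#' @return a data.frame with columns `code` and `value`. A code whose
#'   numerator mask is empty is omitted (with a message): the score is
#'   undefined for that pattern.
#' @export
scoreNMJ <- function(record, method = c("weighted", "unweighted")) {
  method <- match.arg(method)
  stopifnot(is(record, "NMJRecord"))
  validObject(record)
  masks <- lapply(record@channels, function(ch) {
    if (is(ch, "BinaryMask")) ch
    else binarize(ch, computeThreshold(ch, method))
  })
  codes <- comboCodes(record@combo)
  out <- lapply(seq_len(nrow(codes)), function(i) {
    a <- masks[[codes$numerator[i]]]
    b <- masks[[codes$reference[i]]]
    if (a@nPositive == 0L) {
      message(sprintf("NMJ %s/%s: empty %s mask, code %s omitted",
                      record@patientId, record@nmjId,
                      codes$numerator[i], codes$code[i]))
      return(NULL)
    }
    data.frame(code = codes$code[i], value = appositionScore(a, b),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Score a cohort of NMJ records into a long score table
#'
#' @param records a list of \linkS4class{NMJRecord}s.
#' @param method threshold objective passed to [computeThreshold()].
#' @return a long data.frame (the score table) with one row per
#'   (patient, NMJ, code): columns `patient_id`, `diagnosis`, `nmj_id`,
#'   `combo`, `code`, `value`.
#' @export
scoreCohort <- function(records, method = c("weighted", "unweighted")) {
  method <- match.arg(method)
  rows <- lapply(records, function(r) {
    sc <- scoreNMJ(r, method)
    if (is.null(sc) || nrow(sc) == 0L) return(NULL)
    data.frame(patient_id = r@patientId, diagnosis = r@diagnosis,
               nmj_id = r@nmjId, combo = r@combo,
               code = sc$code, value = sc$value, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(tab)) tab <- data.frame(
    patient_id = character(), diagnosis = character(), nmj_id = character(),
    combo = character(), code = character(), value = numeric())
  tab
}

#' Aggregate NMJ-level scores to patient-level medians
#'
#' Each patient receives, per comparison code, the median of the scores of
#' their NMJs. Patients are flagged eligible when at least `minNmjs`
#' distinct NMJs contributed to every code of their staining
#' combination(s); ineligible patients are retained but flagged (their
#' NMJ-level scores still enter pooled comparisons, only patient-level
#' comparisons exclude them).
#'
#' @param table a long score table from [scoreCohort()].
#' @param minNmjs minimum NMJ count per code for eligibility (default 15).
#' @return a data.frame with one row per (patient, code): `patient_id`,
#'   `diagnosis`, `code`, `median_score`, `n_nmjs`, `eligible`.
#' @export
aggregatePatients <- function(table, minNmjs = 15L) {
  stopifnot(is.data.frame(table), minNmjs >= 1L)
  if (nrow(table) == 0L)
    return(data.frame(patient_id = character(), diagnosis = character(),
                      code = character(), median_score = numeric(),
                      n_nmjs = integer(), eligible = logical()))
  sep <- "\x1f"  # unit separator: cannot occur in identifiers
  key <- paste(table$patient_id, table$code, sep = sep)
  med <- tapply(table$value, key, stats::median)
  n <- tapply(table$nmj_id, key, function(x) length(unique(x)))
  parts <- do.call(rbind, strsplit(names(med), sep, fixed = TRUE))
  out <- data.frame(patient_id = parts[, 1], code = parts[, 2],
                    median_score = as.numeric(med), n_nmjs = as.integer(n),
                    stringsAsFactors = FALSE)
  diag <- unique(table[, c("patient_id", "diagnosis")])
  out <- merge(out, diag, by = "patient_id", sort = FALSE)
  elig <- tapply(out$n_nmjs >= minNmjs, out$patient_id, all)
  out$eligible <- as.logical(elig[out$patient_id])
  out <- out[order(out$patient_id, out$code),
             c("patient_id", "diagnosis", "code", "median_score",
               "n_nmjs", "eligible")]
  rownames(out) <- NULL
  out
}
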