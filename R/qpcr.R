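## Efficiency-corrected relative quantification: telomere T/S ratios and
## expression fold differences versus a calibrator sample.

#' @include AllClasses.R
NULL

#' Efficiency-corrected relative quantification ratio
#'
#' The relative expression ratio
#' `E_target^dCq_target / E_ref^dCq_ref`, where each `dCq` is the
#' quantification-cycle difference `Cq(calibrator) - Cq(sample)` for that
#' amplicon and `E` is the amplification efficiency (2 = perfect
#' doubling).
#'
#' @param eTarget,eRef amplification efficiencies, in `(1, 2.2]`.
#' @param dcqTarget,dcqRef Cq differences, calibrator minus sample.
#' @return the relative quantity (positive numeric).
#' @examples
#' pfafflRatio(2, 3, 2, 0)  # 8
#' @export
pfafflRatio <- function(eTarget, dcqTarget, eRef, dcqRef) {
  if (any(c(eTarget, eRef) <= 1) || any(c(eTarget, eRef) > 2.2))
    stop("amplification efficiencies must lie in (1, 2.2]")
  eTarget^dcqTarget / eRef^dcqRef
}

.averageReplicates <- function(wells) {
  stopifnot(is.data.frame(wells),
            all(c("sample_id", "target", "cq") %in% names(wells)))
  if (any(!is.finite(wells$cq)) || any(wells$cq <= 0))
    stop("all Cq values must be finite and positive")
  if (is.null(wells$efficiency)) wells$efficiency <- NA_real_
  agg <- stats::aggregate(cq ~ sample_id + target, data = wells, FUN = mean)
  eff <- stats::aggregate(efficiency ~ sample_id + target, data = wells,
                          FUN = function(e) mean(e, na.rm = TRUE),
                          na.action = NULL)
  merge(agg, eff, by = c("sample_id", "target"))
}

#' Relative quantities versus a calibrator sample
#'
#' Computes, per sample, the efficiency-corrected ratio of a target
#' amplicon to a reference amplicon relative to a calibrator sample.
#' Replicate wells of a (sample, target) pair are averaged arithmetically
#' on the Cq scale before the ratio is formed. With the telomere amplicon
#' as target and a single-copy gene as reference this is the telomere T/S
#' ratio; with a gene of interest as target and a housekeeping gene (e.g.
#' GUSB) as reference it is an expression fold difference versus the
#' calibrator tissue.
#'
#' @param wells data.frame of wells: `sample_id`, `target`, `cq`, optional
#'   `efficiency` (default 2 when absent or NA).
#' @param calibratorId sample to which all ratios are relative; its own
#'   ratio is exactly 1.
#' @param target target amplicon name (default `"telomere"`).
#' @param reference reference amplicon name (default `"scg"`, the
#'   single-copy gene).
#' @return a data.frame with columns `sample_id`, `ratio`,
#'   `calibrator_id`, `method` (`"Pfaffl"`). Samples missing either
#'   amplicon are skipped with a message.
#' @export
tsRatio <- function(wells, calibratorId, target = "telomere",
                    reference = "scg") {
  avg <- .averageReplicates(wells)
  avg$efficiency[is.na(avg$efficiency)] <- 2
  get1 <- function(sid, tg) {
    r <- avg[avg$sample_id == sid & avg$target == tg, ]
    if (nrow(r) != 1L) NULL else r
  }
  calT <- get1(calibratorId, target)
  calR <- get1(calibratorId, reference)
  if (is.null(calT) || is.null(calR))
    stop(sprintf("calibrator '%s' must have both '%s' and '%s' measurements",
                 calibratorId, target, reference))
  samples <- setdiff(unique(avg$sample_id), character(0))
  out <- lapply(samples, function(sid) {
    st <- get1(sid, target)
    sr <- get1(sid, reference)
    if (is.null(st) || is.null(sr)) {
      message(sprintf("sample %s missing a target: skipped", sid))
      return(NULL)
    }
    ratio <- pfafflRatio(st$efficiency, calT$cq - st$cq,
                         sr$efficiency, calR$cq - sr$cq)
    data.frame(sample_id = sid, ratio = ratio, calibrator_id = calibratorId,
               method = "Pfaffl", stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res[order(res$sample_id), , drop = FALSE]
}

#' Group means of relative quantities
#'
#' Arithmetic mean ratio per group, reported at full precision and rounded
#' to 2 decimals (the precision at which group means are typically
#' tabulated).
#'
#' @param ratios data.frame from [tsRatio()].
#' @param labels named character vector mapping `sample_id` to group.
#' @return a data.frame with columns `group`, `mean`, `mean_2dp`, `n`.
#'   Groups with no labeled samples are omitted with a message.
#' @export
groupMeans <- function(ratios, labels) {
  stopifnot(is.data.frame(ratios), !is.null(names(labels)))
  miss <- setdiff(ratios$sample_id, names(labels))
  if (length(miss))
    stop(sprintf("unlabeled samples: %s", paste(miss, collapse = ", ")))
  grp <- labels[ratios$sample_id]
  out <- lapply(unique(grp), function(g) {
    v <- ratios$ratio[grp == g]
    if (length(v) == 0L) {
      message(sprintf("group %s empty: omitted", g))
      return(NULL)
    }
    data.frame(group = g, mean = mean(v), mean_2dp = round(mean(v), 2),
               n = length(v), stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
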