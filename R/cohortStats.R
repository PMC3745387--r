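## Nested cohort comparisons: pooled NMJs, per-patient medians, and
## patient-versus-pool with Bonferroni control; plus the logistic-regression
## diagnosis predictor, Spearman correlation and fiber-type frequencies.

#' @include AllClasses.R
NULL

#' Two-sided Mann-Whitney U test
#'
#' Wraps [stats::wilcox.test()] with a fixed policy: the exact two-sided
#' p value is used whenever `length(x) * length(y) <= 400` and the pooled
#' sample has no ties; otherwise the tie-corrected normal approximation
#' with continuity correction is used.
#'
#' @param x,y nonempty numeric vectors.
#' @return a list with elements `U` (the Mann-Whitney U statistic for `x`)
#'   and `p` (two-sided p value).
#' @examples
#' mannWhitney(c(1, 2), c(3, 4))  # U = 0, p = 1/3
#' @export
mannWhitney <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L)
    stop("both samples must be nonempty")
  pooled <- c(x, y)
  if (all(pooled == pooled[1]))  # fully tied: no evidence either way
    return(list(U = length(x) * length(y) / 2, p = 1))
  hasTies <- anyDuplicated(pooled) > 0L
  exact <- !hasTies && length(x) * length(y) <= 400
  res <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  list(U = unname(res$statistic), p = res$p.value)
}

.comparisonRow <- function(code, xIS, xCP, alpha) {
  mw <- mannWhitney(xIS, xCP)
  data.frame(code = code,
             median_IS = stats::median(xIS), min_IS = min(xIS), max_IS = max(xIS),
             n_IS = length(xIS),
             median_CP = stats::median(xCP), min_CP = min(xCP), max_CP = max(xCP),
             n_CP = length(xCP),
             U = mw$U, p = mw$p, significant = mw$p < alpha,
             stringsAsFactors = FALSE)
}

#' Comparison 1: pooled NMJ-level comparison by diagnosis
#'
#' All NMJ-level scores of each diagnosis group are pooled (disregarding
#' patient structure) and compared per comparison code by two-sided
#' Mann-Whitney test; group medians and ranges are reported.
#'
#' @param table a long score table from [scoreCohort()].
#' @param alpha significance level (default 0.05).
#' @return a data.frame, one row per code, with group medians, ranges,
#'   counts, `U`, `p` and `significant`. Codes absent from one group are
#'   skipped with a message.
#' @export
pooledComparison <- function(table, alpha = 0.05) {
  stopifnot(is.data.frame(table), nrow(table) > 0L)
  if (!all(DIAGNOSES %in% table$diagnosis))
    stop("both diagnoses must be present")
  out <- lapply(intersect(ALL_CODES, unique(table$code)), function(cd) {
    sub <- table[table$code == cd, ]
    xIS <- sub$value[sub$diagnosis == "IS"]
    xCP <- sub$value[sub$diagnosis == "CP"]
    if (length(xIS) == 0L || length(xCP) == 0L) {
      message(sprintf("code %s absent from one group: skipped", cd))
      return(NULL)
    }
    .comparisonRow(cd, xIS, xCP, alpha)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Comparison 2: per-patient median comparison by diagnosis
#'
#' Each eligible patient contributes one value per code (their median
#' score); the two diagnosis groups of patient medians are compared per
#' code by two-sided Mann-Whitney test.
#'
#' @param summaries patient summaries from [aggregatePatients()].
#' @param alpha significance level (default 0.05).
#' @return a data.frame as in [pooledComparison()], computed over eligible
#'   patients' medians.
#' @export
perPatientComparison <- function(summaries, alpha = 0.05) {
  stopifnot(is.data.frame(summaries))
  el <- summaries[summaries$eligible, ]
  out <- lapply(intersect(ALL_CODES, unique(el$code)), function(cd) {
    sub <- el[el$code == cd, ]
    xIS <- sub$median_score[sub$diagnosis == "IS"]
    xCP <- sub$median_score[sub$diagnosis == "CP"]
    if (length(xIS) < 2L || length(xCP) < 2L)
      stop(sprintf("fewer than 2 eligible patients in a group for code %s", cd))
    .comparisonRow(cd, xIS, xCP, alpha)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Comparison 3: each CP patient versus the pooled control group
#'
#' Every eligible CP patient's NMJ-level scores are compared, per code,
#' with the pooled NMJ-level scores of all eligible control (IS) patients
#' by two-sided Mann-Whitney test. Bonferroni control divides the family
#' alpha by the number of CP patients tested (e.g. 0.05 / 25 = 0.002). An
#' entry is `"higher"` or `"lower"` (by the sign of the median difference)
#' when `p <= alphaPerTest`, `"ns"` otherwise.
#'
#' @param table a long score table from [scoreCohort()].
#' @param familyAlpha family-wise alpha (default 0.05).
#' @param minNmjs eligibility threshold on NMJs per code (default 15).
#' @return a \linkS4class{SignificanceMatrix}.
#' @export
patientVsPool <- function(table, familyAlpha = 0.05, minNmjs = 15L) {
  stopifnot(is.data.frame(table), nrow(table) > 0L,
            familyAlpha > 0, familyAlpha < 1)
  summ <- aggregatePatients(table, minNmjs)
  eligibleIds <- unique(summ$patient_id[summ$eligible])
  cpIds <- sort(unique(table$patient_id[table$diagnosis == "CP" &
                                          table$patient_id %in% eligibleIds]))
  isIds <- unique(table$patient_id[table$diagnosis == "IS" &
                                     table$patient_id %in% eligibleIds])
  if (length(cpIds) == 0L)
    stop("no eligible CP patient")
  pool <- table[table$patient_id %in% isIds, ]
  if (nrow(pool) == 0L)
    stop("pooled control NMJ scores are empty")
  codes <- intersect(ALL_CODES, unique(table$code))
  aPer <- familyAlpha / length(cpIds)
  entries <- matrix("ns", length(cpIds), length(codes),
                    dimnames = list(cpIds, codes))
  for (pid in cpIds) {
    for (cd in codes) {
      xs <- table$value[table$patient_id == pid & table$code == cd]
      ctrl <- pool$value[pool$code == cd]
      if (length(xs) == 0L || length(ctrl) == 0L) {
        message(sprintf("patient %s lacks code %s: ns", pid, cd))
        next
      }
      mw <- mannWhitney(xs, ctrl)
      if (mw$p <= aPer) {
        d <- stats::median(xs) - stats::median(ctrl)
        if (d != 0)
          entries[pid, cd] <- if (d > 0) "higher" else "lower"
      }
    }
  }
  new("SignificanceMatrix", entries = entries, familyAlpha = familyAlpha,
      alphaPerTest = aPer)
}

#' Count patients with at least one significant comparison
#'
#' @param matrix a \linkS4class{SignificanceMatrix} (or a character matrix
#'   of `{"higher","lower","ns"}` entries).
#' @return a list with `nFlagged` (patients having >= 1 non-`"ns"` entry)
#'   and `fraction` (of all patients in the matrix).
#' @export
countFlagged <- function(matrix) {
  m <- if (is(matrix, "SignificanceMatrix")) matrix@entries else matrix
  stopifnot(is.matrix(m), nrow(m) > 0L)
  flagged <- apply(m != "ns", 1L, any)
  list(nFlagged = sum(flagged), fraction = mean(flagged))
}

#' Univariate logistic regression of diagnosis on patient medians
#'
#' For each comparison code, diagnosis (CP = 1, IS = 0) is regressed on the
#' eligible patients' median scores with a univariate logistic model; the
#' slope coefficient and its Wald p value are reported, with a flag for
#' codes predictive at `alpha`. Complete separation (or non-convergence) is
#' reported as such rather than as a silent estimate; a constant predictor
#' yields coefficient 0 and p = 1.
#'
#' @param summaries patient summaries from [aggregatePatients()].
#' @param alpha significance level for the `predictive` flag (default 0.05).
#' @return a data.frame with columns `code`, `coefficient`, `p`,
#'   `converged`, `predictive`.
#' @export
logisticPredictor <- function(summaries, alpha = 0.05) {
  stopifnot(is.data.frame(summaries))
  el <- summaries[summaries$eligible, ]
  if (!all(DIAGNOSES %in% el$diagnosis))
    stop("both diagnoses must be present among eligible patients")
  out <- lapply(intersect(ALL_CODES, unique(el$code)), function(cd) {
    sub <- el[el$code == cd, ]
    y <- as.integer(sub$diagnosis == "CP")
    x <- sub$median_score
    if (length(unique(y)) < 2L) stop("both diagnoses required per code")
    if (stats::var(x) == 0)
      return(data.frame(code = cd, coefficient = 0, p = 1,
                        converged = TRUE, predictive = FALSE))
    sepWarn <- FALSE
    fit <- withCallingHandlers(
      stats::glm(y ~ x, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
            grepl("did not converge", conditionMessage(w)))
          sepWarn <<- TRUE
        invokeRestart("muffleWarning")
      })
    ## complete separation drives the deviance to ~0 with a divergent MLE,
    ## sometimes without any IRLS warning
    conv <- fit$converged && !sepWarn && fit$deviance > 1e-6
    co <- summary(fit)$coefficients
    data.frame(code = cd,
               coefficient = if (conv) unname(co["x", "Estimate"]) else NA_real_,
               p = if (conv) unname(co["x", "Pr(>|z|)"]) else NA_real_,
               converged = conv,
               predictive = conv && co["x", "Pr(>|z|)"] < alpha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Tie-corrected Spearman rank correlation
#'
#' Pearson correlation of mid-ranks, as returned by
#' `stats::cor(method = "spearman")`.
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return Spearman's rho.
#' @export
spearmanRho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("rho undefined for a constant vector")
  stats::cor(x, y, method = "spearman")
}

#' Fiber-type frequency comparison between diagnosis groups
#'
#' Per patient, the type I fiber frequency `n_type1 / (n_type1 + n_type2)`
#' is computed (patients with zero counted fibers are excluded with a
#' message; patients under the 100-fiber counting floor are kept but
#' flagged) and the two diagnosis groups of frequencies are compared by
#' two-sided Mann-Whitney test.
#'
#' @param counts a data.frame with columns `patient_id`, `diagnosis`,
#'   `n_type1`, `n_type2`.
#' @param alpha significance level (default 0.05).
#' @return a list: `frequencies` (per-patient data.frame with
#'   `type1_frequency` and `under_sampled`), `U`, `p`, `significant`.
#' @export
fiberTypeTest <- function(counts, alpha = 0.05) {
  stopifnot(is.data.frame(counts),
            all(c("patient_id", "diagnosis", "n_type1", "n_type2") %in%
                  names(counts)))
  tot <- counts$n_type1 + counts$n_type2
  drop <- tot == 0L
  if (any(drop))
    message(sprintf("excluding %d patient(s) with zero counted fibers: %s",
                    sum(drop), paste(counts$patient_id[drop], collapse = ", ")))
  counts <- counts[!drop, ]
  tot <- tot[!drop]
  freq <- data.frame(patient_id = counts$patient_id,
                     diagnosis = counts$diagnosis,
                     type1_frequency = counts$n_type1 / tot,
                     under_sampled = tot < 100L,
                     stringsAsFactors = FALSE)
  xIS <- freq$type1_frequency[freq$diagnosis == "IS"]
  xCP <- freq$type1_frequency[freq$diagnosis == "CP"]
  if (length(xIS) < 2L || length(xCP) < 2L)
    stop("at least 2 patients per group are required")
  mw <- mannWhitney(xCP, xIS)
  list(frequencies = freq, U = mw$U, p = mw$p, significant = mw$p < alpha)
}
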