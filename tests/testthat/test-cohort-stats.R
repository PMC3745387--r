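test_that("Mann-Whitney matches exact enumeration and is symmetric", {
  res <- mannWhitney(c(1, 2), c(3, 4))
  expect_equal(res$U, 0)
  expect_equal(res$p, 1 / 3)   # 2 of the C(4,2) = 6 rank assignments

  # identical multisets -> p near 1
  x <- c(1, 2, 3, 4, 5)
  expect_gte(mannWhitney(x, x)$p, 0.9)

  # two-sided p unchanged under sample swap
  set.seed(3)
  for (i in 1:20) {
    a <- rnorm(sample(3:15, 1)); b <- rnorm(sample(3:15, 1))
    expect_equal(mannWhitney(a, b)$p, mannWhitney(b, a)$p)
  }
  expect_error(mannWhitney(numeric(0), 1:3), "nonempty")
})

test_that("Mann-Whitney holds its nominal type-I error under the null", {
  set.seed(1234)
  rej <- 0L
  for (i in 1:10000) {
    if (mannWhitney(rnorm(20), rnorm(20))$p < 0.05) rej <- rej + 1L
  }
  expect_gte(rej / 10000, 0.04)
  expect_lte(rej / 10000, 0.06)
})

test_that("pooled comparison reports per-code medians, ranges and flags", {
  # one NMJ per group per code: medians are the single values
  tab <- rbind(makeScoreTable(list(C1 = 0.4), list(C1 = "CP")),
               makeScoreTable(list(I1 = 0.1), list(I1 = "IS")))
  cmp <- pooledComparison(tab)
  expect_equal(cmp$median_CP, 0.4)
  expect_equal(cmp$median_IS, 0.1)

  # clear EOL shift flagged, null ROE not (large pooled samples)
  set.seed(8)
  mk <- function(code, shift) rbind(
    makeScoreTable(setNames(list(rnorm(300, 0.2 + shift, 0.05)), "C1"),
                   list(C1 = "CP"), code = code),
    makeScoreTable(setNames(list(rnorm(300, 0.2, 0.05)), "I1"),
                   list(I1 = "IS"), code = code))
  cmp2 <- pooledComparison(rbind(mk("EOL", 0.04), mk("ROE", 0)))
  expect_true(cmp2$significant[cmp2$code == "EOL"])
  expect_false(cmp2$significant[cmp2$code == "ROE"])
})

test_that("per-patient comparison works on eligible medians only", {
  vals <- c(rep(0.1, 10), rep(0.9, 10))
  ids <- sprintf("P%02d", 1:20)
  summaries <- data.frame(patient_id = ids,
                          diagnosis = rep(c("IS", "CP"), each = 10),
                          code = "EOL", median_score = vals,
                          n_nmjs = 20L, eligible = TRUE)
  cmp <- perPatientComparison(summaries)
  expect_lt(cmp$p, 0.001)

  same <- summaries
  same$median_score <- 0.5
  expect_gte(perPatientComparison(same)$p, 0.9)

  few <- summaries
  few$eligible[few$diagnosis == "CP"] <- FALSE
  expect_error(perPatientComparison(few), "fewer than 2 eligible")
})

test_that("patient-vs-pool applies the Bonferroni-by-patients threshold", {
  set.seed(99)
  cpv <- setNames(lapply(1:25, function(i) rnorm(20, 0.1, 0.03)),
                  sprintf("C%02d", 1:25))
  isv <- setNames(lapply(1:25, function(i) rnorm(20, 0.1, 0.03)),
                  sprintf("I%02d", 1:25))
  tab <- rbind(makeScoreTable(cpv, as.list(setNames(rep("CP", 25), names(cpv)))),
               makeScoreTable(isv, as.list(setNames(rep("IS", 25), names(isv)))))
  m <- patientVsPool(tab, familyAlpha = 0.05)
  # 25 patients tested at family alpha 0.05 -> per-test threshold 0.002
  expect_equal(alphaPerTest(m), 0.002)
  expect_equal(dim(significanceEntries(m)), c(25L, 1L))

  # every flagged entry must satisfy p <= threshold when recomputed
  ent <- significanceEntries(m)
  pool <- tab$value[tab$diagnosis == "IS"]
  for (pid in rownames(ent)) {
    p <- mannWhitney(tab$value[tab$patient_id == pid], pool)$p
    if (ent[pid, "EOL"] != "ns") expect_lte(p, 0.002)
    else expect_gt(p, 0.002)
  }

  # complete separation above the pool -> 'higher'
  sep <- tab
  sep$value[sep$patient_id == "C01"] <- rnorm(20, 5, 0.01)
  m2 <- patientVsPool(sep, 0.05)
  expect_equal(unname(significanceEntries(m2)["C01", "EOL"]), "higher")
})

test_that("patient-vs-pool keeps family-wise error controlled under the null", {
  fwe <- 0L
  nrep <- 500
  for (r in seq_len(nrep)) {
    set.seed(r + 10000)
    cpv <- setNames(lapply(1:25, function(i) rnorm(20, 0.1, 0.03)),
                    sprintf("C%02d", 1:25))
    isv <- setNames(lapply(1:25, function(i) rnorm(20, 0.1, 0.03)),
                    sprintf("I%02d", 1:25))
    tab <- rbind(makeScoreTable(cpv, as.list(setNames(rep("CP", 25), names(cpv)))),
                 makeScoreTable(isv, as.list(setNames(rep("IS", 25), names(isv)))))
    if (countFlagged(patientVsPool(tab, 0.05))$nFlagged > 0L) fwe <- fwe + 1L
  }
  expect_lte(fwe / nrep, 0.10)
})

test_that("flag counting reproduces the packaged reference matrix", {
  m <- loadFixture("table4_significance")
  res <- countFlagged(m)
  expect_identical(res$nFlagged, 21L)
  expect_equal(res$fraction, 0.84)

  allNs <- matrix("ns", 4, 3, dimnames = list(paste0("P", 1:4), NULL))
  expect_identical(countFlagged(allNs)$nFlagged, 0L)
  expect_equal(countFlagged(allNs)$fraction, 0)
  allHi <- matrix("higher", 4, 3, dimnames = list(paste0("P", 1:4), NULL))
  expect_equal(countFlagged(allHi)$fraction, 1)
})

test_that("logistic predictor matches a likelihood-maximization oracle", {
  # fixed 8-patient dataset
  med <- c(0.02, 0.05, 0.08, 0.10, 0.07, 0.12, 0.16, 0.20)
  dg <- c("IS", "IS", "IS", "IS", "CP", "CP", "CP", "CP")
  summaries <- data.frame(patient_id = sprintf("P%d", 1:8), diagnosis = dg,
                          code = "EOL", median_score = med,
                          n_nmjs = 20L, eligible = TRUE)
  fit <- logisticPredictor(summaries)
  # independent maximizer of the Bernoulli log-likelihood
  nll <- function(b) {
    eta <- b[1] + b[2] * med
    -sum(ifelse(dg == "CP", stats::plogis(eta, log.p = TRUE),
                stats::plogis(-eta, log.p = TRUE)))
  }
  grid <- expand.grid(b0 = seq(-20, 10, 0.5), b1 = seq(-50, 150, 2))
  best <- grid[which.min(apply(grid, 1, nll)), ]
  opt <- stats::optim(as.numeric(best), nll)$par
  expect_equal(fit$coefficient, opt[2], tolerance = 1e-3)

  # constant predictor: slope 0, p = 1
  const <- summaries
  const$median_score <- 0.1
  fitc <- logisticPredictor(const)
  expect_equal(fitc$coefficient, 0)
  expect_equal(fitc$p, 1)

  # complete separation is reported, not silently estimated
  sep <- summaries
  sep$median_score <- ifelse(dg == "CP", 0.9, 0.1)
  fits <- logisticPredictor(sep)
  expect_false(fits$converged)
  expect_false(fits$predictive)
})

test_that("a lone shifted code is the unique predictive one", {
  set.seed(21)
  n <- 12
  mkcode <- function(code, shiftCP) {
    data.frame(patient_id = sprintf("P%02d", 1:(2 * n)),
               diagnosis = rep(c("IS", "CP"), each = n),
               code = code,
               median_score = c(rnorm(n, 0.30, 0.04),
                                rnorm(n, 0.30 + shiftCP, 0.04)),
               n_nmjs = 20L, eligible = TRUE)
  }
  summaries <- rbind(mkcode("EOL", 0.10), mkcode("ROE", 0), mkcode("LOR", 0))
  fit <- logisticPredictor(summaries)
  expect_true(fit$predictive[fit$code == "EOL"])
  expect_false(any(fit$predictive[fit$code != "EOL"]))
})

test_that("Spearman correlation is Pearson on mid-ranks", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(spearmanRho(x, x^3), 1)
  expect_equal(spearmanRho(x, -x^3), -1)
  # ties: compare against an explicit mid-rank Pearson
  a <- c(1, 2, 2, 3, 5, 5, 5, 8)
  b <- c(2, 1, 4, 4, 6, 7, 7, 9)
  expect_equal(spearmanRho(a, b), stats::cor(rank(a), rank(b)))
  expect_error(spearmanRho(rep(1, 5), 1:5), "undefined")
})

test_that("fiber-type frequencies are compared by exact rank test", {
  counts <- data.frame(
    patient_id = sprintf("F%02d", 1:20),
    diagnosis = rep(c("CP", "IS"), each = 10),
    n_type1 = c(60L + 0:9, 41L + 0:9),
    n_type2 = c(40L - 0:9, 59L - 0:9))
  res <- fiberTypeTest(counts)
  expect_equal(res$frequencies$type1_frequency[1], 0.6)
  # all CP frequencies above all IS, no ties: exact two-sided p = 2 / C(20,10)
  expect_equal(res$p, 2 / choose(20, 10))

  same <- counts
  same$n_type1 <- 55L
  same$n_type2 <- 45L
  expect_gte(fiberTypeTest(same)$p, 0.9)

  withZero <- counts
  withZero$n_type1[1] <- 0L
  withZero$n_type2[1] <- 0L
  expect_message(res2 <- fiberTypeTest(withZero), "zero counted")
  expect_equal(nrow(res2$frequencies), 19L)
})
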