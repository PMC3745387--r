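maskFromIdx <- function(idx, n = 10L) {
  b <- matrix(FALSE, n, n)
  b[idx] <- TRUE
  BinaryMask(b)
}

test_that("apposition score identities hold exactly", {
  a <- maskFromIdx(1:10)
  expect_equal(appositionScore(a, a), 0)                   # complete overlap
  expect_equal(appositionScore(a, maskFromIdx(21:40)), 1)  # disjoint
  # |A| = 10, |A intersect B| = 7 -> 0.3
  expect_equal(appositionScore(a, maskFromIdx(4:40)), 0.3)
  expect_error(appositionScore(maskFromIdx(integer(0)), a),
               "empty numerator")
  expect_error(appositionScore(a, BinaryMask(matrix(FALSE, 3, 3))),
               "dimensions differ")
})

test_that("overlap fraction and score are exact complements", {
  set.seed(5)
  for (i in 1:50) {
    a <- maskFromIdx(sample(100, sample(5:60, 1)))
    b <- maskFromIdx(sample(100, sample(5:60, 1)))
    inside <- sum(maskBits(a) & maskBits(b)) / nPositive(a)
    expect_equal(inside + appositionScore(a, b), 1)
  }
})

test_that("scores are invariant under joint translation of both masks", {
  place <- function(dr, dc, rows, cols) {
    m <- matrix(FALSE, 20, 20)
    m[rows + dr, cols + dc] <- TRUE
    BinaryMask(m)
  }
  s0 <- appositionScore(place(0, 0, 5:9, 5:9), place(0, 0, 6:11, 4:8))
  s1 <- appositionScore(place(3, 2, 5:9, 5:9), place(3, 2, 6:11, 4:8))
  expect_equal(s1, s0)
  expect_gt(s0, 0)
})

test_that("scoreNMJ returns the six directional scores of the combo", {
  bits <- matrix(FALSE, 12, 12)
  bits[3:8, 3:8] <- TRUE
  same <- BinaryMask(bits)
  rec <- NMJRecord("P1", "CP", "n1", "LAMB2-triple",
                   list(AChR = same, AChE = same, LAMB2 = same))
  sc <- scoreNMJ(rec)
  expect_setequal(sc$code, c("ROE", "EOR", "LOE", "EOL", "LOR", "ROL"))
  expect_true(all(sc$value == 0))

  # AChE strictly contains AChR: |E| = 200, |R| = 150 -> ROE 0, EOR 0.25
  e <- matrix(FALSE, 20, 20); e[1:200] <- TRUE
  r <- matrix(FALSE, 20, 20); r[1:150] <- TRUE
  rec2 <- NMJRecord("P1", "CP", "n2", "SV2-triple",
                    list(AChR = BinaryMask(r), AChE = BinaryMask(e),
                         SV2 = BinaryMask(e)))
  sc2 <- scoreNMJ(rec2)
  expect_setequal(sc2$code, c("ROE", "EOR", "VOE", "EOV", "VOR", "ROV"))
  expect_equal(sc2$value[sc2$code == "ROE"], 0)
  expect_equal(sc2$value[sc2$code == "EOR"], 0.25)

  # empty numerator -> code omitted with a message
  rec3 <- NMJRecord("P1", "CP", "n3", "LAMB2-triple",
                    list(AChR = same, AChE = same,
                         LAMB2 = BinaryMask(matrix(FALSE, 12, 12))))
  expect_message(sc3 <- scoreNMJ(rec3), "empty")
  expect_false(any(c("LOE", "LOR") %in% sc3$code))
  expect_true(all(c("ROE", "EOR") %in% sc3$code))
})

test_that("pipeline scores match generator ground truth on rendered images", {
  prof <- simulationProfile("cp-default")
  co <- genNmjCohort(prof, 2, 4, seed = 31, render = TRUE)
  tab <- scoreCohort(co$records)
  codes6 <- c("ROE", "EOR", "LOE", "EOL", "LOR", "ROL")
  long <- do.call(rbind, lapply(codes6,
    function(cd) data.frame(nmj_id = co$manifest$nmj_id, code = cd,
                            truth = co$manifest[[paste0("true_", cd)]])))
  cmp <- merge(tab, long, by = c("nmj_id", "code"))
  expect_equal(nrow(cmp), nrow(tab))
  expect_lt(max(abs(cmp$value - cmp$truth)), 0.05)
})

test_that("patient aggregation reproduces brute-force medians and eligibility", {
  tab <- makeScoreTable(list(P1 = c(0.1, 0.2, 0.3)), list(P1 = "CP"))
  expect_equal(aggregatePatients(tab, minNmjs = 1)$median_score, 0.2)

  # even count -> midpoint of the two central values
  tab2 <- makeScoreTable(list(P1 = c(0.1, 0.2, 0.4, 0.8)), list(P1 = "CP"))
  expect_equal(aggregatePatients(tab2, minNmjs = 1)$median_score, 0.3)

  # 14 NMJs miss the 15-NMJ floor
  tab3 <- makeScoreTable(list(P1 = runif(14), P2 = runif(15)),
                         list(P1 = "CP", P2 = "IS"))
  ag <- aggregatePatients(tab3)
  expect_false(ag$eligible[ag$patient_id == "P1"])
  expect_true(ag$eligible[ag$patient_id == "P2"])

  # 25-patient cohort against independent sort-and-middle medians
  set.seed(41)
  vals <- setNames(lapply(1:25, function(i) runif(sample(10:30, 1))),
                   sprintf("P%02d", 1:25))
  diag <- setNames(rep(c("CP", "IS"), length.out = 25), names(vals))
  ag2 <- aggregatePatients(makeScoreTable(vals, as.list(diag)), minNmjs = 1)
  sortMiddle <- function(v) {
    s <- sort(v); n <- length(s)
    if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  }
  for (pid in names(vals))
    expect_equal(ag2$median_score[ag2$patient_id == pid],
                 sortMiddle(vals[[pid]]))
})
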