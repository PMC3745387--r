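straightTrace <- function(folds = list(rbind(c(0, 0), c(0, -1.5))),
                          edges = rbind(c(0, 0), c(1, 0), c(2, 0)),
                          mito = list(), terminal = rbind(c(0, 0.1), c(4, 0.1),
                                                          c(4, 1.6), c(0, 1.6)),
                          cleft = rbind(c(0, 0), c(4, 0))) {
  MorphometryTrace("T1", "CP", 1L, 0.005, cleft, folds, edges, mito, terminal)
}

test_that("fold lengths are polyline arc lengths", {
  tr <- straightTrace(folds = list(
    rbind(c(0, 0), c(0, -1.5)),                       # straight 1.5
    rbind(c(1, 0), c(1, -1.0), c(1.5, -1.0))))        # L-shaped 1.0 + 0.5
  expect_equal(foldLengths(tr), c(1.5, 1.5))
  expect_error(foldLengths(straightTrace(folds = list())), "no fold paths")
})

test_that("fold spacings are arc-length gaps along the cleft", {
  tr <- straightTrace()
  expect_equal(foldSpacings(tr), c(1, 1))

  # curved cleft: arc distance exceeds the straight-line separation
  th <- seq(0, pi / 2, length.out = 50)
  arc <- cbind(cos(th), sin(th))
  trc <- straightTrace(cleft = arc,
                       edges = rbind(arc[1, ], arc[50, ]),
                       terminal = rbind(c(-2, -2), c(2, -2), c(2, 2), c(-2, 2)))
  sp <- foldSpacings(trc)
  chord <- sqrt(sum((arc[50, ] - arc[1, ])^2))
  expect_gt(sp, chord)
  expect_equal(sp, pi / 2, tolerance = 1e-3)

  expect_message(sp0 <- foldSpacings(straightTrace(edges = rbind(c(0, 0)))),
                 "fewer than 2")
  expect_length(sp0, 0)
})

test_that("mitochondrial area fraction clips to the terminal", {
  sq <- function(x0, y0, s) rbind(c(x0, y0), c(x0 + s, y0),
                                  c(x0 + s, y0 + s), c(x0, y0 + s))
  # 1 um^2 mitochondrion inside a 10 um^2 terminal -> 0.1
  term <- rbind(c(0, 0), c(5, 0), c(5, 2), c(0, 2))
  tr <- straightTrace(mito = list(sq(1, 0.5, 1)), terminal = term)
  expect_equal(mitoAreaFraction(tr), 0.1)

  expect_equal(mitoAreaFraction(straightTrace(mito = list(), terminal = term)), 0)

  # half outside: square straddling the terminal edge counts its inside half
  half <- straightTrace(mito = list(sq(-0.5, 0.5, 1)), terminal = term)
  expect_equal(mitoAreaFraction(half), 0.05)

  # exact clip agrees with a rasterization estimate within 1%
  tilted <- rbind(c(4.5, 1.5), c(5.5, 0.8), c(6, 2), c(5, 2.4))
  trt <- straightTrace(mito = list(tilted), terminal = term)
  clipped <- mitoAreaFraction(trt) * 10
  rast <- nmjcoloc:::rasterIntersectionArea(tilted, term, cells = 600L)
  expect_equal(clipped, rast, tolerance = 0.01)

  degen <- straightTrace(terminal = rbind(c(0, 0), c(1, 0), c(2, 0)))
  expect_error(mitoAreaFraction(degen), "degenerate")
})

test_that("measures are invariant under rigid motion and scale correctly", {
  tr <- straightTrace(
    folds = list(rbind(c(0, 0), c(0.3, -1.2)), rbind(c(1, 0), c(1, -0.8))),
    mito = list(rbind(c(0.5, 0.5), c(1.5, 0.5), c(1.5, 1.2), c(0.5, 1.2))))
  rot <- function(m, a, dx, dy) {
    R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
    sweep(m %*% t(R), 2, c(-dx, -dy))
  }
  xform <- function(t, a, dx, dy) MorphometryTrace(
    t@nmjId, t@group, t@contactRegionIndex, t@pixelSizeUm,
    rot(t@cleft, a, dx, dy), lapply(t@folds, rot, a, dx, dy),
    rot(t@foldEdges, a, dx, dy), lapply(t@mitochondria, rot, a, dx, dy),
    rot(t@terminal, a, dx, dy))
  tr2 <- xform(tr, 0.7, 3.1, -2.2)
  expect_equal(foldLengths(tr2), foldLengths(tr))
  expect_equal(foldSpacings(tr2), foldSpacings(tr))
  expect_equal(mitoAreaFraction(tr2), mitoAreaFraction(tr))

  k <- 2.5
  scl <- function(m) m * k
  tr3 <- MorphometryTrace(tr@nmjId, tr@group, tr@contactRegionIndex,
                          tr@pixelSizeUm, scl(tr@cleft),
                          lapply(tr@folds, scl), scl(tr@foldEdges),
                          lapply(tr@mitochondria, scl), scl(tr@terminal))
  expect_equal(foldLengths(tr3), k * foldLengths(tr))
  expect_equal(foldSpacings(tr3), k * foldSpacings(tr))
  expect_equal(mitoAreaFraction(tr3), mitoAreaFraction(tr))
})

test_that("generated traces reproduce their manifest draws exactly", {
  prof <- simulationProfile("is-default")
  tc <- genTemCohort(prof, 3, seed = 11)
  mm <- measureTraces(tc$traces)
  cmp <- merge(mm, tc$manifest, by = c("nmj_id", "region"))
  expect_equal(cmp$mean_spacing_um, cmp$mean_spacing_drawn)
  expect_equal(cmp$mean_fold_length_um, cmp$mean_fold_length_drawn)
  expect_equal(cmp$mito_area_fraction, cmp$mito_fraction_drawn)

  # zero-dispersion profile: every value equals the profile mean
  prof0 <- prof
  prof0@tem$spacingSdUm <- 0
  prof0@tem$foldLenSdUm <- 0
  prof0@tem$mitoFracSd <- 0
  tc0 <- genTemCohort(prof0, 1, seed = 1)
  for (tr in tc0$traces) {
    expect_equal(unique(round(foldSpacings(tr), 12)), prof@tem$spacingMeanUm)
    expect_equal(unique(round(foldLengths(tr), 12)), prof@tem$foldLenMeanUm)
    expect_equal(mitoAreaFraction(tr), prof@tem$mitoFracMean)
  }
})

test_that("inter-rater reliability penalizes offsets only in the ICC", {
  x <- c(1.2, 2.4, 3.1, 4.8, 5.0, 6.3)
  idem <- interraterReliability(x, x)
  expect_equal(idem$icc, 1)
  expect_equal(idem$r, 1)

  off <- interraterReliability(x, x + 2)
  expect_equal(off$r, 1)
  expect_lt(off$icc, 1)

  # ANOVA-decomposition oracle on a fixed 6-value fixture
  y <- c(1.0, 2.9, 2.8, 5.2, 4.6, 6.9)
  res <- interraterReliability(x, y)
  long <- data.frame(value = c(x, y),
                     subject = factor(rep(1:6, 2)),
                     rater = factor(rep(1:2, each = 6)))
  ms <- summary(stats::aov(value ~ subject + rater, data = long))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  iccOracle <- (msr - mse) / (msr + mse + 2 * (msc - mse) / 6)
  expect_equal(res$icc, unname(iccOracle))

  expect_error(interraterReliability(rep(1, 5), 1:5), "constant")
})
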