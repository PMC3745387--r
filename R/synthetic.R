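## Ground-truthed synthetic data: multi-channel NMJ images with controlled
## directional outside-fractions, TEM traces with known morphometry, and
## qPCR plates with known T/S ratios; plus the packaged reference tables.

#' @include AllClasses.R colocalization.R
NULL

## Per-patient median score targets (group medians of the per-patient
## median non-colocalization scores) used by the built-in profiles.
.IS_CODE_MEDIANS <- c(ROE = 0.04, EOR = 0.30, LOE = 0.41, EOL = 0.06,
                      LOR = 0.53, ROL = 0.04, VOE = 0.07, EOV = 0.54,
                      VOR = 0.19, ROV = 0.44)
.CP_CODE_MEDIANS <- c(ROE = 0.04, EOR = 0.31, LOE = 0.38, EOL = 0.10,
                      LOR = 0.51, ROL = 0.05, VOE = 0.06, EOV = 0.58,
                      VOR = 0.21, ROV = 0.45)

## TEM group values: mean with sd back-computed from the printed SEM over
## n = 25 NMJs (sd = SEM * sqrt(25)).
.IS_TEM <- list(spacingMeanUm = 0.392, spacingSdUm = 0.0299 * 5,
                foldLenMeanUm = 1.012, foldLenSdUm = 0.0636 * 5,
                mitoFracMean = 0.238, mitoFracSd = 0.014 * 5,
                foldsPerRegion = 8L)
.CP_TEM <- list(spacingMeanUm = 0.655, spacingSdUm = 0.0368 * 5,
                foldLenMeanUm = 1.536, foldLenSdUm = 0.128 * 5,
                mitoFracMean = 0.078, mitoFracSd = 0.018 * 5,
                foldsPerRegion = 8L)

.IS_TS <- c(RA014 = 0.95, RA017 = 1.07, RA021 = 0.94, RA022 = 0.55,
            RA024 = 1.24, RA027 = 0.94, RA103 = 0.51, RA105 = 1.01,
            RA113 = 0.79, RA114 = 0.81)
.CP_TS <- c(RA003 = 0.74, RA016 = 0.98, RA019 = 0.75, RA026 = 0.89,
            RA030 = 1.00, RA041 = 0.91, RA042 = 0.83, RA100 = 0.70,
            RA104 = 0.67, RA111 = 0.57)

#' Built-in simulation profiles
#'
#' Returns a \linkS4class{SimulationProfile} carrying the study conditions
#' of one diagnosis group: `"is-default"` (idiopathic scoliosis controls)
#' or `"cp-default"` (cerebral palsy). Per-code target medians are the
#' published per-patient median scores; TEM means carry the published
#' group values with sd back-computed from the printed SEM times
#' sqrt(25); the qPCR block carries the published per-subject T/S ratios
#' of that group.
#'
#' @param name `"is-default"` or `"cp-default"`.
#' @return a \linkS4class{SimulationProfile}.
#' @examples
#' simulationProfile("cp-default")
#' @export
simulationProfile <- function(name = c("is-default", "cp-default")) {
  name <- match.arg(name)
  cp <- identical(name, "cp-default")
  med <- if (cp) .CP_CODE_MEDIANS else .IS_CODE_MEDIANS
  new("SimulationProfile",
      name = name,
      group = if (cp) "CP" else "IS",
      codeTargets = data.frame(code = names(med), median = unname(med),
                               stringsAsFactors = FALSE),
      betweenSdLogit = 0.35,
      withinSd = 0.05,
      imaging = list(imageSize = 96L, nDiscs = 4L, radiusRange = c(7, 12),
                     fgMean = 2500, fgSd = 300, bgMean = 300, bgSd = 80,
                     bitDepth = 12L, pixelSizeUm = 0.1),
      tem = if (cp) .CP_TEM else .IS_TEM,
      qpcr = list(trueTS = if (cp) .CP_TS else .IS_TS,
                  calibrator = "NORMAL_LEG", cqNoiseSd = 0.1,
                  baseCqTelomere = 15, baseCqScg = 23, efficiency = 2))
}

.patientSeed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 65011) * 33013 + i * 9973) %% 2147483646L + 1L
}

drawTruncNorm <- function(n, mean, sd, lower = 0, upper = Inf) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      v <- stats::rnorm(1, mean, sd)
      if (v > lower && v < upper) break
    }
    out[i] <- v
  }
  out
}

## Beta draw matched to (mean, sd) on [0,1]; mean-unbiased, unlike a
## 0-truncated normal. Falls back to a truncated normal when the requested
## variance is infeasible for a beta.
drawBeta <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  v <- sd^2
  if (v >= mean * (1 - mean)) return(drawTruncNorm(n, mean, sd, 0, 1))
  nu <- mean * (1 - mean) / v - 1
  stats::rbeta(n, mean * nu, (1 - mean) * nu)
}

## ---- NMJ image cohort ---------------------------------------------------

## Union-of-discs footprint roughly centered in the image.
.discFootprint <- function(size, nDiscs, radiusRange) {
  xs <- matrix(rep(seq_len(size), size), size, size)
  ys <- matrix(rep(seq_len(size), each = size), size, size)
  bits <- matrix(FALSE, size, size)
  lo <- size * 0.3; hi <- size * 0.7
  for (i in seq_len(nDiscs)) {
    cx <- stats::runif(1, lo, hi)
    cy <- stats::runif(1, lo, hi)
    r <- stats::runif(1, radiusRange[1], radiusRange[2])
    bits <- bits | ((xs - cx)^2 + (ys - cy)^2 <= r^2)
  }
  bits
}

.dilateOnce <- function(bits) {
  n <- nrow(bits); m <- ncol(bits)
  out <- bits
  out[-1, ] <- out[-1, ] | bits[-n, ]
  out[-n, ] <- out[-n, ] | bits[-1, ]
  out[, -1] <- out[, -1] | bits[, -m]
  out[, -m] <- out[, -m] | bits[, -1]
  out
}

## Build a mask against reference `ref` with exact positive-pixel
## arithmetic: `interCount` pixels inside ref (a directionally coherent
## subset) plus `outCount` pixels just outside ref (nearest dilation
## rings). Exactness of counts makes the two directional fractions exact
## by construction.
.constructMask <- function(ref, interCount, outCount) {
  n <- nrow(ref); m <- ncol(ref)
  xs <- matrix(rep(seq_len(n), m), n, m)
  ys <- matrix(rep(seq_len(m), each = n), n, m)
  theta <- stats::runif(1, 0, 2 * pi)
  score <- cos(theta) * xs + sin(theta) * ys
  refIdx <- which(ref)
  keep <- refIdx[order(score[refIdx])][seq_len(interCount)]
  outIdx <- integer(0)
  if (outCount > 0) {
    grown <- ref
    while (length(outIdx) < outCount) {
      nxt <- .dilateOnce(grown)
      ring <- which(nxt & !grown)
      if (length(ring) == 0L) break  # image exhausted
      ring <- ring[order(score[ring])]
      outIdx <- c(outIdx, ring)
      grown <- nxt
    }
    if (length(outIdx) < outCount)
      stop("requested outside-fraction unreachable for this footprint")
    outIdx <- outIdx[seq_len(outCount)]
  }
  bits <- matrix(FALSE, n, m)
  bits[c(keep, outIdx)] <- TRUE
  bits
}

## Counts for a mask X built against reference B of size nB so that
## (B outside X) = a and (X outside B) = b, using exact rounding.
.maskCounts <- function(nB, a, b) {
  inter <- max(1L, round(nB * (1 - a)))
  outc <- round(b / (1 - b) * inter)
  list(inter = as.integer(inter), outc = as.integer(outc))
}

.renderChannel <- function(bits, channel, img) {
  maxv <- 2^img$bitDepth - 1
  px <- stats::rnorm(length(bits), img$bgMean, img$bgSd)
  px[bits] <- stats::rnorm(sum(bits), img$fgMean, img$fgSd)
  px <- matrix(pmin(pmax(round(px), 0), maxv), nrow(bits), ncol(bits))
  IntensityImage(px, bitDepth = img$bitDepth,
                 pixelSizeUm = img$pixelSizeUm, channel = channel)
}

.outsideFraction <- function(a, b) sum(a & !b) / sum(a)

#' Generate a ground-truthed synthetic NMJ image cohort
#'
#' Simulates `nPatients` patients with `nmjsPerPatient` triple-stained NMJs
#' each. Per NMJ, an NMJ-shaped footprint (union of random overlapping
#' discs) serves as the AChR mask; the basal-lamina mask (laminin beta-2 or
#' SV2) is constructed against it by exact pixel reassignment to achieve
#' the drawn directional outside-fractions for the (AChR, third-stain)
#' pair, and the AChE mask is constructed against the third-stain mask
#' likewise for the (AChE, third-stain) pair. The remaining AChR-AChE
#' fractions are emergent. Patient-level fractions are drawn logit-normal
#' around the profile's code medians; NMJ-level jitter is normal on the
#' fraction scale. Channels are rendered as foreground/background Gaussian
#' intensities clipped to the camera bit depth, or returned as exact
#' binary masks with `render = FALSE`.
#'
#' @param profile a \linkS4class{SimulationProfile}.
#' @param nPatients number of patients (>= 1).
#' @param nmjsPerPatient NMJs per patient (>= 1).
#' @param seed integer seed; generation uses per-patient substreams derived
#'   from it, so a patient's data do not depend on how many other patients
#'   are generated before it.
#' @param combo `"LAMB2"` (default), `"SV2"`, or `"both"` (alternating
#'   NMJs).
#' @param render render intensity images (default) or return the exact
#'   \linkS4class{BinaryMask} channels.
#' @return a list with `records` (list of \linkS4class{NMJRecord}) and
#'   `manifest` (data.frame of the exact set-arithmetic outside-fraction of
#'   every code of every NMJ, plus the patient-level drawn fractions for
#'   the controlled codes).
#' @export
genNmjCohort <- function(profile, nPatients, nmjsPerPatient, seed,
                         combo = c("LAMB2", "SV2", "both"), render = TRUE) {
  stopifnot(is(profile, "SimulationProfile"),
            nPatients >= 1L, nmjsPerPatient >= 1L)
  combo <- match.arg(combo)
  img <- profile@imaging
  med <- stats::setNames(profile@codeTargets$median, profile@codeTargets$code)
  clampF <- function(f) pmin(pmax(f, 0), 0.95)
  records <- vector("list", nPatients * nmjsPerPatient)
  manifest <- vector("list", nPatients * nmjsPerPatient)
  k <- 0L
  for (p in seq_len(nPatients)) {
    set.seed(.patientSeed(seed, p))
    pid <- sprintf("%s%02d", substr(profile@group, 1, 1), p)
    ## patient-level controlled fractions, logit-normal around the medians
    ## degenerate targets (0 or 1) stay exact; others are logit-normal
    pf <- vapply(ALL_CODES, function(cd) {
      m <- med[[cd]]
      if (m <= 0 || m >= 1) m
      else clampF(stats::plogis(stats::rnorm(1, stats::qlogis(m),
                                             profile@betweenSdLogit)))
    }, numeric(1))
    names(pf) <- ALL_CODES
    for (q in seq_len(nmjsPerPatient)) {
      thisCombo <- switch(combo,
        LAMB2 = "LAMB2-triple", SV2 = "SV2-triple",
        both = if (q %% 2L == 1L) "LAMB2-triple" else "SV2-triple")
      third <- if (thisCombo == "LAMB2-triple") "LAMB2" else "SV2"
      tl <- CODE_LETTER[third]
      ## controlled codes: (R outside T, T outside R) and
      ## (T outside E ... ) -> chain R -> third -> E
      cRoT <- paste0("RO", tl); cToR <- paste0(tl, "OR")
      cEoT <- paste0("EO", tl); cToE <- paste0(tl, "OE")
      attempt <- 0L
      repeat {
        attempt <- attempt + 1L
        f <- clampF(pf[c(cRoT, cToR, cEoT, cToE)] +
                      stats::rnorm(4, 0, profile@withinSd))
        names(f) <- c(cRoT, cToR, cEoT, cToE)
        footprint <- .discFootprint(img$imageSize, img$nDiscs, img$radiusRange)
        nR <- sum(footprint)
        ctT <- .maskCounts(nR, f[cRoT], f[cToR])
        built <- tryCatch({
          thirdBits <- .constructMask(footprint, ctT$inter, ctT$outc)
          ctE <- .maskCounts(sum(thirdBits), f[cToE], f[cEoT])
          acheBits <- .constructMask(thirdBits, ctE$inter, ctE$outc)
          TRUE
        }, error = function(e) FALSE)
        if (built) break
        if (attempt >= 10L)
          stop("requested outside-fractions unreachable for this image size")
        message(sprintf("NMJ %s #%d: fraction unreachable, resampling", pid, q))
      }
      masks <- list(footprint, acheBits, thirdBits)
      names(masks) <- c("AChR", "AChE", third)
      codes <- comboCodes(thisCombo)
      achieved <- vapply(seq_len(nrow(codes)), function(i)
        .outsideFraction(masks[[codes$numerator[i]]],
                         masks[[codes$reference[i]]]), numeric(1))
      names(achieved) <- codes$code
      channels <- if (render)
        lapply(names(masks), function(ch) .renderChannel(masks[[ch]], ch, img))
      else lapply(masks, BinaryMask)
      names(channels) <- names(masks)
      nmjId <- sprintf("%s_nmj%03d", pid, q)
      k <- k + 1L
      records[[k]] <- NMJRecord(pid, profile@group, nmjId, thisCombo, channels)
      mrow <- data.frame(patient_id = pid, diagnosis = profile@group,
                         nmj_id = nmjId, combo = thisCombo,
                         stringsAsFactors = FALSE)
      for (cd in codes$code) mrow[[paste0("true_", cd)]] <- unname(achieved[cd])
      for (cd in names(f)) mrow[[paste0("drawn_", cd)]] <- unname(f[cd])
      for (cd in ALL_CODES) mrow[[paste0("patient_", cd)]] <- unname(pf[cd])
      manifest[[k]] <- mrow
    }
  }
  manifest <- do.call(rbind, c(manifest[seq_len(k)], list(make.row.names = FALSE)))
  list(records = records[seq_len(k)], manifest = manifest)
}

## ---- TEM trace cohort ---------------------------------------------------

#' Generate a ground-truthed synthetic TEM trace cohort
#'
#' Simulates `nNmjs` NMJs with five contact regions each. Per region, fold
#' edges are placed along a straight synaptic cleft with spacings drawn
#' truncated-normal (positive) around the profile's group mean; fold paths
#' are straight with truncated-normal lengths; mitochondrion polygons are
#' placed inside a rectangular nerve-terminal outline to realize a
#' mitochondrial area fraction drawn from a beta distribution matched to
#' the profile mean and sd (clamped to at most 0.8 of the terminal).
#' Measured values equal the manifest draws to float precision.
#'
#' @param profile a \linkS4class{SimulationProfile}.
#' @param nNmjs number of NMJs (>= 1).
#' @param seed integer seed (per-NMJ substreams).
#' @return a list with `traces` (list of \linkS4class{MorphometryTrace},
#'   5 per NMJ) and `manifest` (data.frame per region of the drawn mean
#'   spacing, mean fold length, and mitochondrial fraction).
#' @export
genTemCohort <- function(profile, nNmjs, seed) {
  stopifnot(is(profile, "SimulationProfile"), nNmjs >= 1L)
  tem <- profile@tem
  traces <- list()
  manifest <- list()
  for (i in seq_len(nNmjs)) {
    set.seed(.patientSeed(seed, i))
    nmjId <- sprintf("%sTEM%03d", substr(profile@group, 1, 1), i)
    for (r in 1:5) {
      nf <- tem$foldsPerRegion
      spac <- drawTruncNorm(nf - 1L, tem$spacingMeanUm, tem$spacingSdUm,
                            lower = 0.02)
      flen <- drawTruncNorm(nf, tem$foldLenMeanUm, tem$foldLenSdUm,
                            lower = 0.05)
      frac <- min(drawBeta(1L, tem$mitoFracMean, tem$mitoFracSd), 0.8)
      margin <- 0.3
      edgeX <- margin + cumsum(c(0, spac))
      W <- margin * 2 + sum(spac)
      cleft <- cbind(c(0, W), c(0, 0))
      folds <- lapply(seq_len(nf), function(j)
        cbind(c(edgeX[j], edgeX[j]), c(0, -flen[j])))
      edges <- cbind(edgeX, rep(0, nf))
      H <- 1.5
      terminal <- cbind(c(0, W, W, 0), c(0.05, 0.05, 0.05 + H, 0.05 + H))
      aTot <- W * H
      aMito <- frac * aTot
      s <- sqrt(aMito / 3)
      mito <- if (frac == 0) list()
      else if (3 * s * 1.2 < W && s < H - 0.2) {
        g <- (W - 3 * s) / 4
        lapply(0:2, function(j) {
          x0 <- g + j * (s + g)
          cbind(c(x0, x0 + s, x0 + s, x0), 0.15 + c(0, 0, s, s))
        })
      } else {
        h <- min(H - 0.2, max(0.2, aMito / (0.9 * W)))
        w <- aMito / h
        list(cbind(c(0.05, 0.05 + w, 0.05 + w, 0.05), 0.15 + c(0, 0, h, h)))
      }
      traces[[length(traces) + 1L]] <- MorphometryTrace(
        nmjId, profile@group, r, 0.005, cleft, folds, edges, mito, terminal)
      manifest[[length(manifest) + 1L]] <- data.frame(
        nmj_id = nmjId, group = profile@group, region = r,
        mean_spacing_drawn = mean(spac), mean_fold_length_drawn = mean(flen),
        mito_fraction_drawn = frac, stringsAsFactors = FALSE)
    }
  }
  list(traces = traces,
       manifest = do.call(rbind, c(manifest, list(make.row.names = FALSE))))
}

## ---- qPCR plate ---------------------------------------------------------

#' Generate a synthetic qPCR plate with known T/S ratios
#'
#' Builds triplicate telomere and single-copy-gene wells for every sample
#' in the profile (plus the calibrator, true ratio 1). The telomere Cq of a
#' sample is offset from the base cycle by `-log_E(true T/S)` so that the
#' efficiency-corrected ratio recovers the true value; Gaussian Cq noise of
#' the profile's sd is added per well.
#'
#' @param profile a \linkS4class{SimulationProfile}.
#' @param seed integer seed.
#' @return a list with `wells` (data.frame: `sample_id`, `target`, `cq`,
#'   `efficiency`, `replicate`) and `manifest` (data.frame of true ratios).
#' @export
genQpcrPlate <- function(profile, seed) {
  stopifnot(is(profile, "SimulationProfile"))
  set.seed(as.integer(seed %% 2147483646L) + 1L)
  q <- profile@qpcr
  ts <- c(q$trueTS, stats::setNames(1, q$calibrator))
  rows <- list()
  for (sid in names(ts)) {
    for (rep3 in 1:3) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid, target = "telomere",
        cq = q$baseCqTelomere - log(ts[[sid]]) / log(q$efficiency) +
          stats::rnorm(1, 0, q$cqNoiseSd),
        efficiency = q$efficiency, replicate = rep3, stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid, target = "scg",
        cq = q$baseCqScg + stats::rnorm(1, 0, q$cqNoiseSd),
        efficiency = q$efficiency, replicate = rep3, stringsAsFactors = FALSE)
    }
  }
  list(wells = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       manifest = data.frame(sample_id = names(ts), true_ts = unname(ts),
                             stringsAsFactors = FALSE))
}

## ---- packaged reference tables ------------------------------------------

#' Load a packaged reference table
#'
#' `"table4_significance"`: the published patient-versus-pool significance
#' matrix (25 CP patients by 10 comparison codes, entries `"higher"`,
#' `"lower"`, `"ns"`). `"table5_telomere"`: the published per-subject
#' telomere T/S ratios with the per-patient median EOL score where
#' printed.
#'
#' @param name fixture name.
#' @return for `"table4_significance"`, a character matrix; for
#'   `"table5_telomere"`, a data.frame with columns `subject`, `diagnosis`,
#'   `ts_ratio`, `median_eol`.
#' @export
loadFixture <- function(name = c("table4_significance", "table5_telomere")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"), package = "nmjcoloc",
                      mustWork = TRUE)
  if (name == "table4_significance") {
    df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
    m <- as.matrix(df[, -1])
    rownames(m) <- df[[1]]
    m[m == "+++"] <- "higher"
    m[m == "---"] <- "lower"
    m[m == ""] <- "ns"
    m
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
}

#' Write a significance matrix in the published serialization
#'
#' Entries are serialized as `"+++"` (higher), `"---"` (lower) and empty
#' (not significant), with patient ids in the first column.
#'
#' @param matrix a \linkS4class{SignificanceMatrix} or a character matrix
#'   with entries in `{"higher","lower","ns"}`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeSignificanceCsv <- function(matrix, path) {
  m <- if (is(matrix, "SignificanceMatrix")) matrix@entries else matrix
  out <- m
  out[m == "higher"] <- "+++"
  out[m == "lower"] <- "---"
  out[m == "ns"] <- ""
  df <- data.frame(patient_id = rownames(m), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
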