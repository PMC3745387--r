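## TEM morphometry from digitized traces: postsynaptic fold length,
## inter-fold spacing along the cleft, mitochondrial area fraction of the
## nerve terminal, and inter-rater reliability.

#' @include AllClasses.R
NULL

polylineLength <- function(pts) {
  if (nrow(pts) < 2L) stop("polyline needs >= 2 points")
  sum(sqrt(rowSums(diff(pts)^2)))
}

## Arc-length position along a polyline of the projection of point p onto
## the nearest polyline segment.
arcPosition <- function(pts, p) {
  segs <- nrow(pts) - 1L
  cum <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  best <- c(dist = Inf, pos = 0)
  for (i in seq_len(segs)) {
    a <- pts[i, ]; b <- pts[i + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- if (len2 == 0) 0 else max(0, min(1, sum((p - a) * ab) / len2))
    q <- a + t * ab
    d <- sqrt(sum((p - q)^2))
    if (d < best["dist"])
      best <- c(dist = d, pos = cum[i] + t * sqrt(len2))
  }
  unname(best["pos"])
}

shoelaceArea <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  j <- c(2:n, 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

isConvexPolygon <- function(poly, tol = 1e-9) {
  n <- nrow(poly)
  if (n < 3L) return(FALSE)
  j <- c(2:n, 1L)
  k <- c(3:n, 1L, 2L)
  cr <- (poly[j, 1] - poly[, 1]) * (poly[k, 2] - poly[j, 2]) -
        (poly[j, 2] - poly[, 2]) * (poly[k, 1] - poly[j, 1])
  all(cr >= -tol) || all(cr <= tol)
}

## Sutherland-Hodgman clipping of polygon `subject` against a convex
## polygon `clip`. Exact for convex clip regions.
clipPolygonConvex <- function(subject, clip) {
  if (shoelaceArea(clip) == 0) stop("degenerate clip polygon")
  ## orient clip counter-clockwise
  n <- nrow(clip)
  j <- c(2:n, 1L)
  if (sum(clip[, 1] * clip[j, 2] - clip[j, 1] * clip[, 2]) < 0)
    clip <- clip[rev(seq_len(n)), ]
  out <- subject
  nC <- nrow(clip)
  for (i in seq_len(nC)) {
    if (nrow(out) == 0L) break
    a <- clip[i, ]
    b <- clip[if (i == nC) 1L else i + 1L, ]
    inside <- function(p) (b[1] - a[1]) * (p[2] - a[2]) -
                          (b[2] - a[2]) * (p[1] - a[1]) >= 0
    res <- matrix(numeric(0), 0, 2)
    m <- nrow(out)
    for (s in seq_len(m)) {
      cur <- out[s, ]
      prv <- out[if (s == 1L) m else s - 1L, ]
      curIn <- inside(cur)
      prvIn <- inside(prv)
      if (curIn != prvIn) {
        d <- cur - prv
        denom <- (b[1] - a[1]) * d[2] - (b[2] - a[2]) * d[1]
        t <- ((b[1] - a[1]) * (a[2] - prv[2]) -
              (b[2] - a[2]) * (a[1] - prv[1])) / denom
        res <- rbind(res, prv + t * d)
      }
      if (curIn) res <- rbind(res, cur)
    }
    out <- res
  }
  out
}

## Even-odd point-in-polygon test, vectorized over points.
pointsInPolygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

## Rasterized area of (polyA intersect polyB) on a subcell grid.
rasterIntersectionArea <- function(polyA, polyB, cells = 400L) {
  xr <- range(polyA[, 1]); yr <- range(polyA[, 2])
  dx <- diff(xr) / cells
  dy <- diff(yr) / cells
  gx <- xr[1] + (seq_len(cells) - 0.5) * dx
  gy <- yr[1] + (seq_len(cells) - 0.5) * dy
  px <- rep(gx, times = cells)
  py <- rep(gy, each = cells)
  inA <- pointsInPolygon(px, py, polyA)
  inB <- pointsInPolygon(px[inA], py[inA], polyB)
  sum(inB) * dx * dy
}

#' Postsynaptic fold lengths of a contact region
#'
#' Each traced fold path is measured as its cumulative arc length from the
#' cleft-attached first point to its terminal point: the distance the
#' contiguous fold extends into the muscle, following the fold's own
#' course (not the straight-line penetration depth).
#'
#' @param trace a \linkS4class{MorphometryTrace} with >= 1 fold path.
#' @return numeric vector of fold lengths in micrometres.
#' @export
foldLengths <- function(trace) {
  stopifnot(is(trace, "MorphometryTrace"))
  if (length(trace@folds) == 0L) stop("trace has no fold paths")
  vapply(trace@folds, polylineLength, numeric(1))
}

#' Inter-fold spacings along the synaptic cleft
#'
#' Arc-length distances along the cleft polyline between the neighboring
#' edges of successive folds; `n` fold-edge points yield `n - 1` spacings.
#' With fewer than 2 edge points an empty vector is returned with a
#' message.
#'
#' @param trace a \linkS4class{MorphometryTrace}.
#' @return numeric vector of spacings in micrometres.
#' @export
foldSpacings <- function(trace) {
  stopifnot(is(trace, "MorphometryTrace"))
  ne <- nrow(trace@foldEdges)
  if (ne < 2L) {
    message(sprintf("NMJ %s region %d: fewer than 2 fold edges, no spacings",
                    trace@nmjId, trace@contactRegionIndex))
    return(numeric(0))
  }
  pos <- vapply(seq_len(ne),
                function(i) arcPosition(trace@cleft, trace@foldEdges[i, ]),
                numeric(1))
  diff(pos)
}

#' Mitochondrial cross-sectional area fraction of the nerve terminal
#'
#' The summed area of the mitochondrion polygons clipped to the nerve
#' terminal polygon, divided by the terminal area (cross-sectional area of
#' mitochondria per square micrometre of nerve terminal). Convex terminal
#' outlines are clipped exactly (Sutherland-Hodgman); non-convex outlines
#' fall back to a fine-grid rasterization estimate.
#'
#' @param trace a \linkS4class{MorphometryTrace} with a non-degenerate
#'   terminal polygon.
#' @return a numeric fraction in `[0, 1]`.
#' @export
mitoAreaFraction <- function(trace) {
  stopifnot(is(trace, "MorphometryTrace"))
  aT <- shoelaceArea(trace@terminal)
  if (aT <= 0) stop("degenerate terminal polygon")
  if (length(trace@mitochondria) == 0L) return(0)
  convex <- isConvexPolygon(trace@terminal)
  aM <- sum(vapply(trace@mitochondria, function(m) {
    if (convex) {
      cl <- clipPolygonConvex(m, trace@terminal)
      if (nrow(cl) < 3L) 0 else shoelaceArea(cl)
    } else {
      rasterIntersectionArea(m, trace@terminal)
    }
  }, numeric(1)))
  min(aM / aT, 1)
}

#' Morphometry measures for a set of traces
#'
#' Applies [foldLengths()], [foldSpacings()] and [mitoAreaFraction()] to
#' each contact-region trace and summarizes per region.
#'
#' @param traces list of \linkS4class{MorphometryTrace}s.
#' @return a data.frame with one row per contact region: `nmj_id`, `group`,
#'   `region`, `mean_fold_length_um`, `mean_spacing_um`,
#'   `mito_area_fraction`, plus fold and edge counts.
#' @export
measureTraces <- function(traces) {
  rows <- lapply(traces, function(tr) {
    fl <- foldLengths(tr)
    sp <- suppressMessages(foldSpacings(tr))
    data.frame(nmj_id = tr@nmjId, group = tr@group,
               region = tr@contactRegionIndex,
               n_folds = length(fl),
               mean_fold_length_um = mean(fl),
               n_spacings = length(sp),
               mean_spacing_um = if (length(sp)) mean(sp) else NA_real_,
               mito_area_fraction = mitoAreaFraction(tr),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Group summary of TEM morphometry (mean and SEM per group)
#'
#' Aggregates region-level measures to NMJ-level means, then reports per
#' group the mean and standard error over NMJs, mirroring how the three
#' measures are summarized per diagnosis group.
#'
#' @param measures output of [measureTraces()].
#' @return a data.frame with one row per (group, measure): `group`,
#'   `measure`, `mean`, `sem`, `n_nmjs`.
#' @export
summarizeTemGroups <- function(measures) {
  stopifnot(is.data.frame(measures))
  perNmj <- do.call(rbind, lapply(split(measures, measures$nmj_id), function(d)
    data.frame(nmj_id = d$nmj_id[1], group = d$group[1],
               fold_length_um = mean(d$mean_fold_length_um),
               spacing_um = mean(d$mean_spacing_um, na.rm = TRUE),
               mito_area_fraction = mean(d$mito_area_fraction),
               stringsAsFactors = FALSE)))
  out <- lapply(split(perNmj, perNmj$group), function(d) {
    vals <- d[, c("fold_length_um", "spacing_um", "mito_area_fraction")]
    data.frame(group = d$group[1], measure = names(vals),
               mean = vapply(vals, mean, numeric(1)),
               sem = vapply(vals, function(v) stats::sd(v) / sqrt(length(v)),
                            numeric(1)),
               n_nmjs = nrow(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  rownames(out) <- NULL
  out
}

#' Inter-rater reliability of repeated measurements
#'
#' Two-way single-measure absolute-agreement intraclass correlation
#' (ICC(A,1), from the two-way ANOVA decomposition) and the Pearson
#' correlation between two blinded raters' measurements of the same items.
#' Absolute agreement penalizes a systematic offset between raters, which
#' leaves the Pearson r at 1 but pulls the ICC below 1.
#'
#' @param rater1,rater2 numeric vectors of equal length >= 3, neither
#'   constant.
#' @return a list with elements `icc` and `r`.
#' @export
interraterReliability <- function(rater1, rater2) {
  n <- length(rater1)
  stopifnot(length(rater2) == n, n >= 3L)
  if (stats::sd(rater1) == 0 || stats::sd(rater2) == 0)
    stop("reliability undefined for constant measurements")
  k <- 2L
  dat <- cbind(rater1, rater2)
  grand <- mean(dat)
  rowM <- rowMeans(dat)
  colM <- colMeans(dat)
  ssr <- k * sum((rowM - grand)^2)            # subjects
  ssc <- n * sum((colM - grand)^2)            # raters
  sse <- sum((dat - outer(rowM, rep(1, k)) -
                outer(rep(1, n), colM) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  list(icc = icc, r = stats::cor(rater1, rater2))
}
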