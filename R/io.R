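## Readers and writers: grayscale TIFF channels, manifest/score/summary
## CSVs, trace JSON, and qPCR plate CSVs.

#' @include AllClasses.R
NULL

#' Read a single-channel grayscale TIFF
#'
#' Pixel values are read as stored integers. The acquisition bit depth is
#' taken from the caller (typically the manifest's `bit_depth` column) and
#' never guessed from pixel maxima: 12-bit data are routinely stored in
#' 16-bit containers.
#'
#' @param path TIFF file path.
#' @param bitDepth acquisition bit depth (default 12).
#' @param pixelSizeUm micrometres per pixel (default 0.1).
#' @param channel stain label.
#' @return an \linkS4class{IntensityImage}.
#' @export
readChannelTiff <- function(path, bitDepth = 12L, pixelSizeUm = 0.1,
                            channel = "AChR") {
  px <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  IntensityImage(px, bitDepth = bitDepth, pixelSizeUm = pixelSizeUm,
                 channel = channel)
}

#' Write a channel as a 16-bit grayscale TIFF
#'
#' @param image an \linkS4class{IntensityImage}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeChannelTiff <- function(image, path) {
  stopifnot(is(image, "IntensityImage"))
  tiff::writeTIFF(image@pixels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write a binary mask as an 8-bit TIFF (0/255)
#'
#' @param mask a \linkS4class{BinaryMask}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeMaskTiff <- function(mask, path) {
  stopifnot(is(mask, "BinaryMask"))
  tiff::writeTIFF(ifelse(mask@bits, 1, 0), path, bits.per.sample = 8L)
  invisible(path)
}

#' Read an image-cohort manifest CSV into NMJ records
#'
#' The manifest has one row per NMJ with columns `patient_id`,
#' `diagnosis`, `nmj_id`, `combo` (`LAMB2-triple` or `SV2-triple`),
#' per-channel TIFF paths (`achr_path`, `ache_path`, `third_path`),
#' `bit_depth` and `pixel_size_um`. Relative paths are resolved against
#' the manifest's directory.
#'
#' @param path manifest CSV path.
#' @return a list of \linkS4class{NMJRecord}s.
#' @export
readManifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "diagnosis", "nmj_id", "combo", "achr_path",
            "ache_path", "third_path", "bit_depth", "pixel_size_um")
  if (!all(need %in% names(df)))
    stop(sprintf("manifest misses columns: %s",
                 paste(setdiff(need, names(df)), collapse = ", ")))
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p,
                                file.path(base, p))
  lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    third <- if (r$combo == "LAMB2-triple") "LAMB2" else "SV2"
    chans <- list(
      AChR = readChannelTiff(resolve(r$achr_path), r$bit_depth,
                             r$pixel_size_um, "AChR"),
      AChE = readChannelTiff(resolve(r$ache_path), r$bit_depth,
                             r$pixel_size_um, "AChE"))
    chans[[third]] <- readChannelTiff(resolve(r$third_path), r$bit_depth,
                                      r$pixel_size_um, third)
    NMJRecord(r$patient_id, r$diagnosis, r$nmj_id, r$combo, chans)
  })
}

#' Write a simulated image cohort as TIFFs plus a manifest CSV
#'
#' @param cohort output of [genNmjCohort()] with `render = TRUE`.
#' @param dir output directory (created if needed).
#' @return the manifest CSV path, invisibly.
#' @export
writeCohortTiffs <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort$records, function(r) {
    third <- if (r@combo == "LAMB2-triple") "LAMB2" else "SV2"
    paths <- vapply(c("AChR", "AChE", third), function(ch) {
      p <- sprintf("%s_%s.tif", r@nmjId, ch)
      writeChannelTiff(r@channels[[ch]], file.path(dir, p))
      p
    }, character(1))
    img <- r@channels[["AChR"]]
    data.frame(patient_id = r@patientId, diagnosis = r@diagnosis,
               nmj_id = r@nmjId, combo = r@combo,
               achr_path = paths[[1]], ache_path = paths[[2]],
               third_path = paths[[3]],
               bit_depth = img@bitDepth, pixel_size_um = img@pixelSizeUm,
               stringsAsFactors = FALSE)
  })
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), mpath, row.names = FALSE)
  utils::write.csv(cohort$manifest, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(mpath)
}

#' Read and write long score tables and patient summaries
#'
#' Tidy CSVs: one observation per row, UTF-8, `.` decimal.
#'
#' @param table a data.frame ([scoreCohort()] / [aggregatePatients()]
#'   output).
#' @param path CSV path.
#' @return readers return a data.frame; writers return the path,
#'   invisibly.
#' @export
writeScoreTable <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeScoreTable
#' @export
readScoreTable <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read digitized TEM traces from JSON
#'
#' Schema: an array of objects `{nmj_id, group, contact_region_index,
#' pixel_size_um, cleft: [[x,y],...], folds: [[[x,y],...],...],
#' fold_edges: [[x,y],...], mitochondria: [[[x,y],...],...],
#' terminal: [[x,y],...]}`, coordinates in micrometres.
#'
#' @param path JSON file path.
#' @return a list of \linkS4class{MorphometryTrace}s.
#' @export
readTraceJson <- function(path) {
  js <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  toMat <- function(pts) {
    if (length(pts) == 0L) return(matrix(numeric(0), 0, 2))
    do.call(rbind, lapply(pts, function(q) as.numeric(unlist(q))))
  }
  lapply(js, function(tr) {
    MorphometryTrace(tr$nmj_id, tr$group, tr$contact_region_index,
                     tr$pixel_size_um, toMat(tr$cleft),
                     lapply(tr$folds, toMat), toMat(tr$fold_edges),
                     lapply(tr$mitochondria, toMat), toMat(tr$terminal))
  })
}

#' @rdname readTraceJson
#' @param traces a list of \linkS4class{MorphometryTrace}s.
#' @export
writeTraceJson <- function(traces, path) {
  js <- lapply(traces, function(tr) list(
    nmj_id = tr@nmjId, group = tr@group,
    contact_region_index = tr@contactRegionIndex,
    pixel_size_um = tr@pixelSizeUm,
    cleft = tr@cleft, folds = tr@folds, fold_edges = tr@foldEdges,
    mitochondria = tr@mitochondria, terminal = tr@terminal))
  jsonlite::write_json(js, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a qPCR plate CSV
#'
#' Columns: `sample_id`, `target`, `cq`, optional `efficiency`,
#' optional `replicate`, optional `group`.
#'
#' @param path CSV path.
#' @return a data.frame of wells.
#' @export
readQpcrPlate <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "target", "cq")
  if (!all(need %in% names(df)))
    stop(sprintf("plate misses columns: %s",
                 paste(setdiff(need, names(df)), collapse = ", ")))
  df
}
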