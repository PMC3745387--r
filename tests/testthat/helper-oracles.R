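# Independent oracles used by several test files.

# Exhaustive split-variance scan over every integer candidate split in the
# image's gray range; deliberately naive (plain loops, direct formulas).
bruteForceThreshold <- function(values, method) {
  v <- as.numeric(values)
  best <- NULL
  for (t in seq(min(v), max(v) - 1)) {
    lo <- v[v <= t]
    hi <- v[v > t]
    varp <- function(x) if (length(x) < 2) 0 else mean((x - mean(x))^2)
    obj <- if (method == "weighted")
      (length(lo) * varp(lo) + length(hi) * varp(hi)) / length(v)
    else varp(lo) + varp(hi)
    if (is.null(best) || obj < best$obj) best <- list(t = t, obj = obj)
  }
  best
}

randomTestImage <- function(size = 8L, nLevels = NULL, bitDepth = 12L) {
  maxv <- 2^bitDepth - 1
  k <- if (is.null(nLevels)) sample(3:20, 1) else nLevels
  lev <- sample(0:maxv, k)
  IntensityImage(matrix(sample(lev, size * size, replace = TRUE), size, size),
                 bitDepth = bitDepth)
}

# Tiny score-table builder for the statistics tests.
makeScoreTable <- function(patientValues, diagnosis, code = "EOL",
                           combo = "LAMB2-triple") {
  rows <- lapply(names(patientValues), function(pid) {
    v <- patientValues[[pid]]
    data.frame(patient_id = pid, diagnosis = diagnosis[[pid]],
               nmj_id = sprintf("%s_n%03d", pid, seq_along(v)),
               combo = combo, code = code, value = v,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
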