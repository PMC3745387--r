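## End-to-end orchestration: manifest -> scores -> nested comparisons ->
## predictor, with tidy CSV outputs and a JSON run report.

#' @include AllClasses.R colocalization.R cohortStats.R io.R
NULL

#' Assemble a run configuration
#'
#' Settings for [runFullAnalysis()]. A YAML configuration file may supply
#' defaults; arguments given here override the file (flags win).
#'
#' @param manifest path to the image-cohort manifest CSV.
#' @param outDir output directory.
#' @param scores optional path to a pre-computed score-table CSV (skips
#'   image scoring).
#' @param thresholdMethod `"weighted"` or `"unweighted"`.
#' @param minNmjs eligibility threshold (default 15).
#' @param familyAlpha family-wise alpha for the patient-versus-pool matrix
#'   (default 0.05).
#' @param seed integer seed recorded in the run report.
#' @param configFile optional YAML file with any of the above fields
#'   (snake_case keys).
#' @return a `RunConfig` list.
#' @export
runConfig <- function(manifest = NULL, outDir = NULL, scores = NULL,
                      thresholdMethod = NULL, minNmjs = NULL,
                      familyAlpha = NULL, seed = NULL, configFile = NULL) {
  cfg <- list(manifest = manifest, outDir = outDir, scores = scores,
              thresholdMethod = thresholdMethod, minNmjs = minNmjs,
              familyAlpha = familyAlpha, seed = seed)
  if (!is.null(configFile)) {
    yml <- yaml::read_yaml(configFile)
    map <- c(manifest = "manifest", out_dir = "outDir", scores = "scores",
             threshold_method = "thresholdMethod", min_nmjs = "minNmjs",
             family_alpha = "familyAlpha", seed = "seed")
    for (k in names(map))  # explicit arguments beat file values
      if (!is.null(yml[[k]]) && is.null(cfg[[map[[k]]]]))
        cfg[[map[[k]]]] <- yml[[k]]
  }
  defaults <- list(outDir = "nmjcoloc-out", thresholdMethod = "weighted",
                   minNmjs = 15L, familyAlpha = 0.05, seed = 1L)
  for (k in names(defaults))
    if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  stopifnot(cfg$minNmjs >= 1L, cfg$familyAlpha > 0, cfg$familyAlpha < 1)
  class(cfg) <- "RunConfig"
  cfg
}

#' Run the full NMJ-disruption analysis
#'
#' Scores the cohort (or loads a pre-computed score table), aggregates to
#' patient medians, runs the three nested comparisons and the logistic
#' predictor, and writes: `scores.csv`, `patient_summaries.csv`,
#' `comparison1_pooled.csv`, `comparison2_patient.csv`,
#' `comparison3_matrix.csv` (published serialization: `+++` / `---` /
#' empty), `predictor.csv`, and `report.json`. On failure, partial outputs
#' are removed.
#'
#' @param config a `RunConfig` from [runConfig()].
#' @return the report, invisibly (a list).
#' @export
runFullAnalysis <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(obj, name, writer = utils::write.csv) {
    p <- file.path(config$outDir, name)
    writer(obj, p)
    written <<- c(written, p)
    p
  }
  ok <- FALSE
  on.exit(if (!ok) unlink(written), add = TRUE)

  if (!is.null(config$scores)) {
    scores <- readScoreTable(config$scores)
  } else {
    if (is.null(config$manifest) || !file.exists(config$manifest))
      stop("manifest path not resolvable")
    records <- readManifest(config$manifest)
    scores <- scoreCohort(records, config$thresholdMethod)
  }
  emit(scores, "scores.csv", function(o, p) utils::write.csv(o, p, row.names = FALSE))
  summaries <- aggregatePatients(scores, config$minNmjs)
  emit(summaries, "patient_summaries.csv",
       function(o, p) utils::write.csv(o, p, row.names = FALSE))
  cmp1 <- pooledComparison(scores)
  emit(cmp1, "comparison1_pooled.csv",
       function(o, p) utils::write.csv(o, p, row.names = FALSE))
  cmp2 <- perPatientComparison(summaries)
  emit(cmp2, "comparison2_patient.csv",
       function(o, p) utils::write.csv(o, p, row.names = FALSE))
  mat <- patientVsPool(scores, config$familyAlpha, config$minNmjs)
  emit(mat, "comparison3_matrix.csv", writeSignificanceCsv)
  pred <- logisticPredictor(summaries)
  emit(pred, "predictor.csv",
       function(o, p) utils::write.csv(o, p, row.names = FALSE))

  flg <- countFlagged(mat)
  report <- list(
    package = "nmjcoloc",
    version = as.character(utils::packageVersion("nmjcoloc")),
    seed = config$seed,
    threshold_method = config$thresholdMethod,
    min_nmjs = config$minNmjs,
    family_alpha = config$familyAlpha,
    alpha_per_test = alphaPerTest(mat),
    n_nmjs = length(unique(paste(scores$patient_id, scores$nmj_id))),
    n_patients = length(unique(scores$patient_id)),
    n_eligible_patients = length(unique(summaries$patient_id[summaries$eligible])),
    n_flagged_patients = flg$nFlagged,
    fraction_flagged = flg$fraction)
  p <- file.path(config$outDir, "report.json")
  jsonlite::write_json(report, p, auto_unbox = TRUE, digits = NA)
  written <- c(written, p)
  ok <- TRUE
  invisible(report)
}
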