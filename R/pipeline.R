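# End-to-end orchestration on a synthetic cohort: simulate -> segment ->
# score -> CPA -> calibrate -> classify, with every table written to an
# output directory and a manifest capturing seeds and parameters so a rerun
# is byte-identical.

#' Pipeline run configuration
#'
#' Validates and bundles all stage parameters. Parameters are checked
#' against the stage preconditions up front so a bad configuration fails
#' before any stage runs.
#'
#' @param outDir Output directory (created if absent).
#' @param seed Master seed; every stage derives its own stream from it.
#' @param totalBins Synthetic genome size in bins (default 1500).
#' @param nControls Reference-panel controls (default 50).
#' @param nCalibrationControls Extra controls used to calibrate the CPA
#'   cutoff (default 100).
#' @param nCasesPerClass Cases per histology class (default 10).
#' @param tumorFraction Tumor-fraction range for cases.
#' @param penetrance Optional scalar fingerprint penetrance override.
#' @param alpha,nPerm Segmentation parameters.
#' @param fdr Abnormality FDR (default 0.01).
#' @param threshold Discretization threshold for training states.
#' @param nPerClassTraining Training-table samples per class (default 68).
#' @param family Classifier family (default "ridge").
#' @return A validated `runConfig` list.
#' @export
runConfig <- function(outDir, seed = 1L, totalBins = 1500, nControls = 50,
                      nCalibrationControls = 100, nCasesPerClass = 10,
                      tumorFraction = c(0.1, 0.5), penetrance = NULL,
                      alpha = 0.01, nPerm = 1000L, fdr = 0.01,
                      threshold = 0.1, nPerClassTraining = 68,
                      family = "ridge") {
  stopifnot(is.character(outDir), length(outDir) == 1)
  stopifnot(alpha > 0, alpha < 1, nPerm >= 100, fdr > 0, fdr < 1,
            nControls >= 2, nCalibrationControls >= 20,
            nCasesPerClass >= 1, totalBins >= 200,
            tumorFraction[1] >= 0, tumorFraction[2] <= 1)
  as.list(environment())
}

#' Run the full synthetic-cohort pipeline
#'
#' Stages, in the order the analysis prescribes: synthetic genome and
#' reference panel; case simulation per histology class; CBS segmentation;
#' segmental Z-scores and calls; CPA scores; control-based cutoff
#' calibration and abnormality flags; training-table simulation,
#' discretization and ridge classification of the cases. All tables are
#' written under `config$outDir` together with a `manifest.txt` of every
#' parameter and seed.
#'
#' @param config A [runConfig()].
#' @return Invisibly, a list with the in-memory stage results
#'   (`grid`, `panel`, `cases`, `segsets`, `cpa`, `calibration`, `model`,
#'   `predictions`).
#' @export
runPipeline <- function(config) {
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  cc <- cohortConfig(nControls = config$nControls,
                     nCasesPerClass = config$nCasesPerClass,
                     tumorFraction = config$tumorFraction,
                     seed = config$seed)
  grid0 <- syntheticGenome(totalBins = config$totalBins)
  panel <- simulatePanel(grid0, cc)
  grid <- applyPanelWeights(grid0, panel)
  panel <- referencePanel(ratios(panel), grid)
  writeGridFile(grid, file.path(config$outDir, "grid.tsv"))

  fps <- defaultFingerprints(config$penetrance)
  classes <- names(fps)
  sp <- segmentationParams(alpha = config$alpha, nPerm = config$nPerm,
                           seed = childSeed(config$seed, 100L))

  # cases
  cases <- list()
  for (cl in classes) {
    for (k in seq_len(config$nCasesPerClass)) {
      id <- sprintf("%s_%02d", cl, k)
      f <- withSeed(childSeed(config$seed, 200L + length(cases)),
                    drawTumorFraction(cc))
      cases[[id]] <- c(simulateCase(grid, fps[[cl]], f, cc, sampleId = id,
                                    seed = childSeed(config$seed, 300L + length(cases))),
                       list(class = cl, tumorFraction = f))
    }
  }

  # segmentation + scoring + CPA
  segsets <- list()
  for (id in names(cases)) {
    ss <- segmentProfile(cases[[id]]$profile, sp)
    ss <- scoreSegments(ss, cases[[id]]$profile, panel)
    segsets[[id]] <- ss
    writeSegments(ss, file.path(config$outDir, paste0("segments_", id, ".tsv")))
    writeBinRatios(cases[[id]]$profile,
                   file.path(config$outDir, paste0("ratios_", id, ".tsv")))
  }
  cpa <- cpaReport(segsets, modality = "LB")

  # calibration on held-out controls
  controlCpa <- vapply(seq_len(config$nCalibrationControls), function(k) {
    sim <- simulateCase(grid, NULL, 0, cc, sampleId = sprintf("ctrl_%03d", k),
                        seed = childSeed(config$seed, 1000L + k))
    cpaScore(scoreSegments(segmentProfile(sim$profile, sp), sim$profile,
                           panel))
  }, numeric(1))
  calibration <- calibrateCutoff(controlCpa, fdr = config$fdr,
                                 modality = "LB",
                                 seed = childSeed(config$seed, 2000L))
  cpa <- classifyAbnormal(cpa, calibration)
  writeCpaReport(cpa, file.path(config$outDir, "cpa_report.tsv"))

  # classification: train on array-style table, predict the cases
  tt <- simulateTrainingTable(grid, fps, nPerClass = config$nPerClassTraining,
                              config = cc)
  fmTrain <- discretizeFeatures(tt, grid, threshold = config$threshold)
  model <- trainModel(fmTrain, family = config$family,
                      seed = childSeed(config$seed, 3000L))
  fmCases <- discretizeFeatures(segsets, grid,
                                labels = vapply(cases, `[[`, "", "class"))
  predictions <- cbind(sampleId = names(cases),
                       predictClass(model, fmCases))
  writeFeatureMatrix(fmCases, file.path(config$outDir, "features_cases.tsv"))
  write.table(predictions, file.path(config$outDir, "predictions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  writeLines(c("plasmaCNA pipeline manifest",
               paste0("package_version=", as.character(utils::packageVersion("plasmaCNA"))),
               vapply(setdiff(names(config), "outDir"), function(nm)
                 paste0(nm, "=", paste(format(config[[nm]]), collapse = ",")),
                 character(1))),
             file.path(config$outDir, "manifest.txt"))

  invisible(list(grid = grid, panel = panel, cases = cases,
                 segsets = segsets, cpa = cpa, calibration = calibration,
                 model = model, predictions = predictions))
}
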