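## Pipeline orchestration: simulate -> fit -> split -> train -> predict
## -> evaluate, each stage persisted in the run directory and resumable
## from its outputs.

#' Run the full synthesis pipeline
#'
#' Executes the stages in order, writing each stage's outputs under
#' `outDir` and skipping stages whose outputs already exist (delete a
#' stage's outputs to re-run from there). A structured log with the
#' config hash and per-stage seeds is appended to `run.log`.
#'
#' Stages: `cohort` (phantom truths + echo series), `maps` (fitted
#' T1rho/T2 maps per subject), `split` (subject-wise partition),
#' `model` (trained U-Net), `predictions` (synthetic T1rho for the test
#' subjects), `report` (evaluation JSON + per-subject CSV).
#'
#' @param config A [runConfig()] list.
#' @param outDir Run directory.
#' @param shift Optional [DomainShiftSpec-class]; when given, a second
#'   `domain_shift` stratum is generated for the test subjects and
#'   evaluated alongside.
#' @param verbose Print stage progress.
#' @return Invisibly, the evaluation report list (per stratum).
#' @export
runPipeline <- function(config, outDir, shift = NULL, verbose = TRUE) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  saveRunConfig(config, file.path(outDir, "config.yaml"))
  logf <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
    cat(line, "\n", file = file.path(outDir, "run.log"), append = TRUE)
    if (verbose) message(line)
  }
  logf("run config hash %s seed %d", configHash(config), config$seed)

  ## stage: cohort ---------------------------------------------------
  cohortDir <- file.path(outDir, "cohort")
  if (!file.exists(file.path(cohortDir, "manifest.csv"))) {
    logf("stage cohort: generating %d phantom subjects",
         config$phantom@nSubjects)
    cohort <- makeCohort(config$phantom, config$acquisition, dir = cohortDir)
  } else {
    logf("stage cohort: resuming from %s", cohortDir)
    cohort <- makeCohort(config$phantom, config$acquisition)
  }
  ids <- cohort$manifest$subjectId

  ## stage: maps -----------------------------------------------------
  mapsDir <- file.path(outDir, "maps")
  dir.create(mapsDir, showWarnings = FALSE)
  fitted <- list()
  for (id in ids) {
    t1p <- file.path(mapsDir, paste0(id, "_t1rho_fit.nii"))
    t2p <- file.path(mapsDir, paste0(id, "_t2_fit.nii"))
    if (file.exists(t1p) && file.exists(t2p)) {
      fitted[[id]] <- list(T1rho = readMap(t1p, "T1rho"),
                           T2 = readMap(t2p, "T2"))
    } else {
      f1 <- fitMonoexponential(cohort$echoes[[id]]$T1rho)
      f2 <- fitMonoexponential(cohort$echoes[[id]]$T2)
      fitted[[id]] <- list(T1rho = f1@map, T2 = f2@map)
      writeMap(t1p, f1@map)
      writeMap(t2p, f2@map)
    }
  }
  logf("stage maps: %d subjects fitted", length(fitted))

  ## stage: split ----------------------------------------------------
  splitPath <- file.path(outDir, "split.json")
  if (file.exists(splitPath)) {
    split <- jsonlite::read_json(splitPath, simplifyVector = TRUE)
  } else {
    split <- splitDataset(ids, config$train@splitFractions,
                          seed = config$train@seed)
    jsonlite::write_json(split, splitPath)
  }
  assertSplitIntegrity(split, ids)
  logf("stage split: train %d / val %d / test %d subjects",
       length(split$train), length(split$val), length(split$test))

  ## stage: model ----------------------------------------------------
  modelPath <- file.path(outDir, "model.rds")
  pairsOf <- function(sids) unlist(lapply(sids, function(id)
    makeSlicePairs(fitted[[id]]$T2, fitted[[id]]$T1rho,
                   cohort$truths[[id]]@labels, id)), recursive = FALSE)
  if (file.exists(modelPath)) {
    model <- readRDS(modelPath)
    logf("stage model: resumed from checkpoint")
  } else {
    model <- buildModel(config$model, seed = deriveSeed(config$seed, "init"))
    model <- trainModel(model, pairsOf(split$train), pairsOf(split$val),
                        config$train)
    saveRDS(model, modelPath)
    utils::write.csv(trainingHistory(model),
                     file.path(outDir, "history.csv"), row.names = FALSE)
    logf("stage model: trained, best epoch %d val loss %.6f",
         attr(model, "bestEpoch"), attr(model, "bestValLoss"))
  }

  ## stage: predictions ----------------------------------------------
  predDir <- file.path(outDir, "predictions")
  dir.create(predDir, showWarnings = FALSE)
  preds <- list()
  for (id in split$test) {
    pp <- file.path(predDir, paste0(id, "_t1rho_pred.nii"))
    if (file.exists(pp)) {
      preds[[id]] <- readMap(pp, "T1rho")
    } else {
      preds[[id]] <- predictMap(model, fitted[[id]]$T2)
      writeMap(pp, preds[[id]])
    }
  }
  logf("stage predictions: %d test subjects", length(preds))

  ## stage: report ---------------------------------------------------
  truthsT1 <- lapply(cohort$truths[split$test], function(tr) tr@t1rho)
  labelsL <- lapply(cohort$truths[split$test], function(tr) tr@labels)
  strata <- stats::setNames(rep("in_distribution", length(split$test)),
                            split$test)
  predsAll <- preds
  truthsAll <- truthsT1
  labelsAll <- labelsL

  if (!is.null(shift)) {
    for (id in split$test) {
      sh1 <- applyDomainShift(cohort$echoes[[id]]$T1rho, shift,
                              cohort$truths[[id]])
      sh2 <- applyDomainShift(cohort$echoes[[id]]$T2, shift,
                              cohort$truths[[id]])
      fs1 <- fitMonoexponential(sh1)
      fs2 <- fitMonoexponential(sh2)
      sid <- paste0(id, "_shift")
      predsAll[[sid]] <- predictMap(model, fs2@map)
      truthsAll[[sid]] <- fs1@map
      labelsAll[[sid]] <- cohort$truths[[id]]@labels
      strata[sid] <- "domain_shift"
    }
    logf("stage report: domain-shift stratum added (%d subjects)",
         length(split$test))
  }

  report <- evaluateCohort(predsAll, truthsAll, labelsAll, strata)
  reportDir <- file.path(outDir, "report")
  dir.create(reportDir, showWarnings = FALSE)
  for (st in names(report)) {
    utils::write.csv(report[[st]]$perSubject,
                     file.path(reportDir, paste0(st, "_per_subject.csv")),
                     row.names = FALSE)
    jsonlite::write_json(list(
      aggregated = report[[st]]$aggregated,
      agreement = report[[st]]$agreement[c("bias", "loa", "sd")],
      pearson = report[[st]]$agreement$pearson,
      quantError = report[[st]]$agreement$quantError),
      file.path(reportDir, paste0(st, "_report.json")),
      auto_unbox = TRUE, digits = NA)
  }
  logf("stage report: written to %s", reportDir)
  invisible(report)
}

## Verify the subject-wise partition on every run.
assertSplitIntegrity <- function(split, ids) {
  all3 <- c(split$train, split$val, split$test)
  if (anyDuplicated(all3) || !setequal(all3, ids))
    stop("split integrity violation: partition is not disjoint/exhaustive")
  invisible(TRUE)
}

#' Bland-Altman plot of an agreement analysis
#'
#' Scatter of pair differences against pair means with the bias and the
#' 1.96-SD limits of agreement.
#'
#' @param ba Result of [blandAltman()].
#' @param file Optional PNG path; NULL plots to the active device.
#' @param main Plot title.
#' @return Invisibly, `ba`.
#' @export
blandAltmanPlot <- function(ba, file = NULL, main = "Bland-Altman") {
  if (!is.null(file)) {
    grDevices::png(file, width = 640, height = 480)
    on.exit(grDevices::dev.off())
  }
  with(ba$table, {
    graphics::plot(mean, difference, pch = 19, col = "#00000088",
                   xlab = "Mean of pair (ms)",
                   ylab = "Difference pred - truth (ms)", main = main,
                   ylim = range(c(difference, ba$loa)) * 1.1)
  })
  graphics::abline(h = ba$bias, col = "blue", lwd = 2)
  graphics::abline(h = ba$loa, col = "red", lty = 2)
  invisible(ba)
}
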