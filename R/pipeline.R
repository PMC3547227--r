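#' Run the full QC pipeline on a simulated dataset
#'
#' Orchestrates simulate -> merge -> refine error model -> apply
#' corrected sigmas -> sigma-based outlier rejection -> ice-window
#' detection and exclusion -> Wilson fit -> Laue-class comparison, and
#' assembles a [QCReport-class].  Working statistics (error model,
#' rejection) are computed under mmm, which is valid whatever the true
#' symmetry; the final merging statistics are reported under the Laue
#' class the comparison selects.  Every stage's tabular output is
#' written to \code{outDir} and one structured log line per stage
#' records the input/output/rejected counts.  The run is fully
#' deterministic given \code{seed}.
#'
#' @param cfg a [SimulationConfig-class].
#' @param seed integer seed overriding \code{cfg@seed}.
#' @param outDir directory for intermediate TSVs (created if needed);
#'   NULL to skip writing.
#' @param label dataset label for the report.
#' @param threshold sigma rejection threshold (default 4).
#' @param iceCenters candidate ice-ring centers for detection.
#' @param lowResCutoff optional low-resolution cutoff in Angstrom.
#' @param nShells resolution shells for the report statistics.
#' @param verbose emit per-stage log lines (default TRUE).
#' @return a [QCReport-class].
#' @examples
#' cfg <- simulationConfig(cell = unitCell(40, 40, 30), dMin = 2.8)
#' rep <- runPipeline(cfg, seed = 5L, outDir = NULL, verbose = FALSE)
#' @export
runPipeline <- function(cfg, seed, outDir = NULL, label = "synthetic",
                        threshold = 4, iceCenters = c(3.90, 3.67, 3.44),
                        lowResCutoff = NULL, nShells = 10L,
                        verbose = TRUE) {
  stopifnot(is(cfg, "SimulationConfig"))
  cfg@seed <- as.integer(seed)
  log <- function(stage, ...) {
    if (verbose) message(sprintf("[%s] %s", stage, sprintf(...)))
  }
  files <- character(0)
  emit <- function(name, writer) {
    if (!is.null(outDir)) {
      if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
      path <- file.path(outDir, name)
      writer(path)
      files[[name]] <<- path
    }
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  sim <- stage("simulate", simulateDataset(cfg))
  log("simulate", "%d observations of %d unique reflections (seed %d)",
      nrow(sim$observations), nrow(sim$truth), cfg@seed)
  emit("observations.tsv",
       function(p) writeReflectionTSV(sim$observations, p))
  emit("truth.tsv", function(p) fwrite(as.data.table(sim$truth), p, sep = "\t"))

  lcWork <- laueClass("mmm")
  merged <- stage("merge", mergeObservations(sim$observations, lcWork))
  log("merge", "%d groups under %s", nGroups(merged), laueName(lcWork))
  emit("merged_mmm.tsv", function(p) writeMergedTSV(merged, p))

  em <- stage("refine-errors", refineErrorModel(merged))
  log("refine-errors", "K = %.3f, g = %.4f, chi2 %.3f -> %.3f",
      em@K, em@g, em@chi2Before, em@chi2After)
  emit("error_model.tsv", function(p)
    fwrite(data.table(K = em@K, g = em@g, chi2_before = em@chi2Before,
                      chi2_after = em@chi2After, n_bins = em@nBins,
                      converged = em@converged), p, sep = "\t"))

  corrected <- stage("apply-errors", applyErrorModel(merged, em))
  rej <- stage("reject", rejectOutliers(corrected, threshold = threshold))
  log("reject", "%d observations flagged at %.1f sigma", rej$nRejected,
      threshold)
  emit("rejected.tsv", function(p)
    writeReflectionTSV(observationTable(rej$merged), p))

  uniqueRef <- generateUnique(cfg@cell, lcWork, cfg@dMin, cfg@dMax)
  windows <- stage("deice",
                   detectIceRings(rej$merged, candidateCenters = iceCenters))
  excl <- stage("deice",
                applyExclusions(observationTable(rej$merged), windows,
                                lowResCutoff = lowResCutoff,
                                uniqueRef = uniqueRef, lc = lcWork))
  log("deice", "%d window(s) flagged; completeness %.3f -> %.3f",
      nrow(windows), excl$completenessBefore, excl$completenessAfter)
  emit("ice_windows.tsv",
       function(p) fwrite(as.data.table(excl$windows), p, sep = "\t"))
  cleanObs <- excl$observations
  emit("observations_clean.tsv", function(p) writeReflectionTSV(cleanObs, p))

  laue <- stage("laue-check",
                laueCompare(cleanObs, cfg@cell, dMin = cfg@dMin,
                            dMax = cfg@dMax, nShells = nShells))
  log("laue-check", "delta R_meas = %.4f -> %s", laue@deltaRMeas,
      laue@chosen)

  lcFinal <- laueClass(laue@chosen)
  mergedFinal <- stage("merge-final", mergeObservations(cleanObs, lcFinal))
  wf <- stage("wilson", wilsonFit(mergedFinal))
  log("wilson", "B = %.2f +/- %.2f A^2", wf@B, wf@stderrB)
  emit("wilson_shells.tsv",
       function(p) fwrite(as.data.table(wf@shells), p, sep = "\t"))

  stats <- classStats(laue, laue@chosen)
  emit("merged_final.tsv", function(p) writeMergedTSV(mergedFinal, p))
  emit("stats.tsv", function(p) writeStatsTSV(stats, p))

  report <- new("QCReport",
                label = label, cell = cfg@cell,
                resolutionRange = c(cfg@dMax, cfg@dMin),
                stats = stats, errorModel = em, wilson = wf, laue = laue,
                nRejectedOutliers = as.integer(rej$nRejected),
                iceWindows = excl$windows,
                completenessBeforeExclusion = excl$completenessBefore,
                completenessAfterExclusion = excl$completenessAfter,
                files = files)
  emit("qc_report.txt", function(p) writeQCReport(report, p))
  report
}

formatQCReport <- function(object) {
  s <- object@stats
  os <- outerShell(s)
  fmt <- function(v, vo, digits = 3)
    sprintf("%.*f (%.*f)", digits, v, digits, vo)
  cp <- cellParameters(object@cell)
  lines <- c(
    sprintf("QC report: %s", object@label),
    sprintf("Unit cell              a = %.2f  b = %.2f  c = %.2f A",
            cp["a"], cp["b"], cp["c"]),
    sprintf("Observed reflections   %d", s@nObs),
    sprintf("Unique reflections     %d", s@nUnique),
    sprintf("Resolution (A)         %.2f-%.2f (%.2f-%.2f)",
            object@resolutionRange[1L], object@resolutionRange[2L],
            os$dMax, os$dMin),
    sprintf("Completeness (%%)       %s",
            fmt(100 * s@completeness, 100 * os$completeness, 1)),
    sprintf("R_merge                %s", fmt(s@rMerge, os$rMerge)),
    sprintf("R_meas                 %s", fmt(s@rMeas, os$rMeas)),
    sprintf("R_pim                  %s", fmt(s@rPim, os$rPim)),
    sprintf("Merged mean I/sigma    %s",
            fmt(s@meanIOverSigma, os$meanIOverSigma, 1)),
    sprintf("Redundancy             %s", fmt(s@redundancy, os$redundancy, 1)),
    sprintf("B_Wilson (A^2)         %.1f", object@wilson@B),
    sprintf("Error model            K = %.3f, g = %.4f, chi2 = %.3f",
            object@errorModel@K, object@errorModel@g,
            object@errorModel@chi2After),
    sprintf("Laue class             %s (delta R_meas = %.4f)",
            object@laue@chosen, object@laue@deltaRMeas),
    sprintf("Outlier rejections     %d", object@nRejectedOutliers),
    sprintf("Ice windows excluded   %d (completeness %.3f -> %.3f)",
            nrow(object@iceWindows),
            object@completenessBeforeExclusion,
            object@completenessAfterExclusion),
    "(outer resolution shell values in brackets)")
  lines
}

#' Write a QC report as aligned text
#'
#' @param report a [QCReport-class].
#' @param path file path.
#' @export
writeQCReport <- function(report, path) {
  stopifnot(is(report, "QCReport"))
  writeLines(formatQCReport(report), path)
  invisible(path)
}

setMethod("show", "QCReport", function(object) {
  cat(formatQCReport(object), sep = "\n")
})
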