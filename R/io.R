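## TSV input/output for reflection tables.
##
## Unmerged schema: h k l batch I sigma d flags, tab separated with a
## header line; flags is a comma-joined subset of
## {outlier, ice, lowres}, "-" when none.

#' Read and write unmerged reflection TSV files
#'
#' @param observations observation data.frame (see
#'   [mergeObservations()] for columns).
#' @param path file path.
#' @return \code{readReflectionTSV}: observation data.frame with flag
#'   columns expanded; \code{writeReflectionTSV}: the path, invisibly.
#' @export
writeReflectionTSV <- function(observations, path) {
  obs <- normalizeObservations(observations)
  flags <- character(nrow(obs))
  tok <- cbind(ifelse(obs$flagOutlier, "outlier", NA),
               ifelse(obs$flagIce, "ice", NA),
               ifelse(obs$flagLowres, "lowres", NA))
  flags <- apply(tok, 1L, function(x) {
    x <- x[!is.na(x)]
    if (length(x)) paste(x, collapse = ",") else "-"
  })
  out <- data.table(h = obs$h, k = obs$k, l = obs$l, batch = obs$batch,
                    I = obs$I, sigma = obs$sigma, d = obs$d,
                    flags = if (nrow(obs)) flags else character(0))
  fwrite(out, path, sep = "\t")
  invisible(path)
}

#' @rdname writeReflectionTSV
#' @export
readReflectionTSV <- function(path) {
  dt <- fread(path, sep = "\t")
  need <- c("h", "k", "l", "batch", "I", "sigma", "d")
  if (!all(need %in% names(dt)))
    stop("reflection TSV needs columns ", paste(need, collapse = ", "),
         ", flags")
  flags <- if ("flags" %in% names(dt)) dt$flags else rep("-", nrow(dt))
  dt[, `:=`(flagOutlier = grepl("outlier", flags),
            flagIce = grepl("ice", flags),
            flagLowres = grepl("lowres", flags))]
  if ("flags" %in% names(dt)) dt[, flags := NULL]
  as.data.frame(dt)
}

#' Write merged reflections as TSV
#'
#' Columns: h k l (asymmetric-unit index), I_mean, sigma_mean, n, d.
#'
#' @param merged a [MergedReflections-class].
#' @param path file path.
#' @export
writeMergedTSV <- function(merged, path) {
  stopifnot(is(merged, "MergedReflections"))
  g <- merged@groups
  fwrite(data.table(h = g$asuH, k = g$asuK, l = g$asuL,
                    I_mean = g$Imean, sigma_mean = g$sigmaMean,
                    n = g$n, d = g$d),
         path, sep = "\t")
  invisible(path)
}

#' Write merging statistics as TSV (overall row plus one per shell)
#'
#' @param stats a [MergeStats-class].
#' @param path file path.
#' @export
writeStatsTSV <- function(stats, path) {
  stopifnot(is(stats, "MergeStats"))
  overall <- data.frame(shell = 0L,
                        dMax = stats@perShell$dMax[1L],
                        dMin = outerShell(stats)$dMin,
                        nObs = stats@nObs, nUnique = stats@nUnique,
                        completeness = stats@completeness,
                        redundancy = stats@redundancy,
                        rMerge = stats@rMerge, rMeas = stats@rMeas,
                        rPim = stats@rPim,
                        meanIOverSigma = stats@meanIOverSigma)
  fwrite(rbind(overall, stats@perShell), path, sep = "\t")
  invisible(path)
}
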