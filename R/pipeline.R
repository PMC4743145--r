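## End-to-end runs: the three program modes (multiple series, single series,
## selectivity) plus series merging, producing all artifacts on disk.

.countStereoGroups <- function(analysis) {
  total <- 0L
  for (lab in analysis@partition@labels) {
    si <- subsetStereoIndices(analysis, lab)
    si <- si[!is.na(si)]
    if (length(si)) total <- total + length(unique(si))
  }
  total
}

.exportSeriesArtifacts <- function(analysis, outDir, graphKind, formats,
                                   target = NULL) {
  sid <- analysis@series@seriesId
  cs <- analysis@compounds
  files <- character(0)
  emit <- function(obj, stem) {
    for (fmt in formats) {
      f <- file.path(outDir, sprintf("%s.%s", stem,
                                     ifelse(fmt == "graphml", "graphml", fmt)))
      exportGraph(obj, fmt, f)
      files <<- c(files, f)
    }
  }
  n <- analysis@core@nSites
  wantComplete <- graphKind %in% c("complete", "both") && n >= 1L && n <= 12L
  complete <- if (n >= 1L && n <= 12L)
    buildCompleteGraph(analysis@partition, cs, target) else NULL
  if (wantComplete && !is.null(complete))
    emit(complete, sprintf("%s_complete", sid))
  if (graphKind %in% c("reduced", "both")) {
    reduced <- if (!is.null(complete)) reduceGraph(complete)
               else buildReducedGraphDirect(analysis@partition, cs, target)
    emit(reduced, sprintf("%s_reduced", sid))
  }
  for (lab in analysis@partition@labels) {
    tree <- buildRGroupTree(analysis, lab, target)
    f <- file.path(outDir, sprintf("%s_subset_%s_tree.json", sid,
                                   gsub("[^0-9.]", "_", lab)))
    exportGraph(tree, "json", f)
    files <- c(files, f)
  }
  rep <- file.path(outDir, sprintf("%s_subsets.tsv", sid))
  writeSubsetReport(analysis, rep)
  files <- c(files, rep)
  files
}

#' Run a complete analysis from an SD file to exported artifacts
#'
#' Modes mirror the three classic program applications: `multi` processes
#' every extracted series, `single` one selected series, `selectivity`
#' compares node statistics between two targets; `merge` additionally unites
#' two series via a recomputed MCS before analysis.
#'
#' @param input SD file path.
#' @param outDir output directory (created if missing).
#' @param potencyFields SD tags to read as potencies.
#' @param targetLabels target names (default: the field names).
#' @param mode one of "multi", "single", "selectivity", "merge".
#' @param seriesId series to process in single mode.
#' @param mergePair character vector of two series ids (merge mode).
#' @param selTargets character vector of two target labels (selectivity
#'   mode; default: the first two).
#' @param scaffoldLevel "framework" or "generic_skeleton".
#' @param minSeriesSize minimum series size (default 2).
#' @param graphKind "complete", "reduced" or "both".
#' @param formats export formats for graphs (default graphml + json).
#' @param verbose emit per-series summary lines (default TRUE).
#' @param ... passed to [computeMCS()] (e.g. `timeoutSec`).
#' @return invisibly, a list with `manifest` (data.frame of written files)
#'   and `analyses` (list of [SeriesAnalysis-class]).
#' @export
runAnalysis <- function(input, outDir, potencyFields,
                        targetLabels = potencyFields,
                        mode = c("multi", "single", "selectivity", "merge"),
                        seriesId = NULL, mergePair = NULL, selTargets = NULL,
                        scaffoldLevel = "framework", minSeriesSize = 2L,
                        graphKind = c("both", "complete", "reduced"),
                        formats = c("graphml", "json"), verbose = TRUE,
                        ...) {
  mode <- match.arg(mode)
  graphKind <- match.arg(graphKind)
  if (mode == "selectivity" && length(potencyFields) != 2L)
    stop("selectivity mode requires exactly 2 potency fields")
  cs <- readCompounds(input, potencyFields, targetLabels)
  allSeries <- groupIntoSeries(cs, scaffoldLevel, minSeriesSize)
  if (!length(allSeries)) stop("no analog series found in ", input)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)

  selected <- switch(mode,
    multi = , selectivity = allSeries,
    single = {
      hit <- Filter(function(s) s@seriesId == seriesId, allSeries)
      if (!length(hit))
        stop("unknown series id '", seriesId, "'; available: ",
             paste(vapply(allSeries, function(s) s@seriesId, character(1)),
                   collapse = ", "))
      hit
    },
    merge = {
      if (length(mergePair) != 2L)
        stop("merge mode requires mergePair = c(seriesA, seriesB)")
      ids <- vapply(allSeries, function(s) s@seriesId, character(1))
      miss <- setdiff(mergePair, ids)
      if (length(miss))
        stop("unknown series id(s): ", paste(miss, collapse = ", "))
      list(combineSeries(allSeries[[match(mergePair[1], ids)]],
                         allSeries[[match(mergePair[2], ids)]]))
    })

  manifest <- data.frame(file = character(0), series = character(0),
                         stringsAsFactors = FALSE)
  analyses <- list()
  for (ser in selected) {
    an <- analyzeSeries(ser, cs, ...)
    analyses[[an@series@seriesId]] <- an
    if (mode == "selectivity") {
      labels <- unname(cs@targets)
      st <- if (is.null(selTargets)) labels[1:2] else selTargets
      views <- buildSelectivityViews(an, st[1], st[2])
      files <- character(0)
      for (tg in names(views)) {
        for (fmt in formats) {
          f <- file.path(outDir, sprintf("%s_reduced_%s.%s",
                                         an@series@seriesId, tg, fmt))
          exportGraph(views[[tg]], fmt, f)
          files <- c(files, f)
        }
      }
      rep <- file.path(outDir, sprintf("%s_subsets.tsv", an@series@seriesId))
      writeSubsetReport(an, rep)
      files <- c(files, rep)
    } else {
      files <- .exportSeriesArtifacts(an, outDir, graphKind, formats)
    }
    manifest <- rbind(manifest,
                      data.frame(file = files, series = an@series@seriesId,
                                 stringsAsFactors = FALSE))
    if (verbose)
      message(sprintf("%s: %d members, %d sites, %d subsets, %d stereo group(s)",
                      an@series@seriesId, length(an@series@memberIds),
                      an@core@nSites, length(an@partition@labels),
                      .countStereoGroups(an)))
  }
  manifestFile <- file.path(outDir, "manifest.tsv")
  utils::write.table(manifest, manifestFile, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(manifest = manifest, analyses = analyses))
}
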