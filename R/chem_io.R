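## SD file input, subset reports, graph exports.

.splitSdfRecords <- function(lines) {
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (!length(ends)) return(list(lines))
  starts <- c(1L, head(ends, -1) + 1L)
  recs <- Map(function(s, e) lines[s:(e - 1L)], starts, ends)
  ## trailing material without $$$$ terminator
  if (max(ends) < length(lines)) {
    tail <- lines[(max(ends) + 1L):length(lines)]
    if (any(nzchar(trimws(tail)))) recs <- c(recs, list(tail))
  }
  recs
}

.parseDataFields <- function(recLines) {
  mend <- grep("^M  END", recLines)
  if (!length(mend)) return(character(0))
  rest <- recLines[-seq_len(mend[1])]
  tags <- grep("^>", rest)
  out <- character(0)
  for (t in tags) {
    name <- sub("^>\\s*<([^>]*)>.*$", "\\1", rest[t])
    val <- if (t + 1 <= length(rest)) trimws(rest[t + 1]) else ""
    out[name] <- val
  }
  out
}

.parseOneRecord <- function(recLines, idx) {
  mend <- grep("^M  END", recLines)
  if (!length(mend)) return(NULL)
  molblock <- paste(recLines[seq_len(mend[1])], collapse = "\n")
  if (any(grepl("V3000", recLines[seq_len(min(4, length(recLines)))]))) {
    ## normalize V3000 connection tables to V2000 via OpenBabel
    molblock <- obConvert("SDF", "SDF", paste0(molblock, "\n$$$$\n"))
    molblock <- sub("\n\\$\\$\\$\\$.*$", "", molblock)
    molblock <- sub("\\n+$", "", molblock)
  }
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::read.SDFset(ChemmineR::read.SDFstr(
      c(strsplit(molblock, "\n", fixed = TRUE)[[1]], "$$$$")))[[1]]),
    error = function(e) NULL)
  mg <- if (!is.null(sdf))
    tryCatch(molgraphFromSDF(sdf, molblock), error = function(e) NULL)
  else NULL
  if (is.null(mg))   # e.g. bond-free molecules ChemmineR refuses to index
    mg <- tryCatch(molgraphFromRawMolblock(molblock), error = function(e) NULL)
  if (is.null(mg)) return(NULL)
  title <- trimws(strsplit(molblock, "\n", fixed = TRUE)[[1]][1])
  mg$title <- if (nzchar(title)) title else sprintf("CMP%03d", idx)
  mg
}

.largestFragment <- function(mg) {
  if (nrow(mg$bonds) == 0L && mg$n <= 1L) return(mg)
  g <- igraph::make_graph(edges = rbind(mg$bonds$a, mg$bonds$b),
                          n = mg$n, directed = FALSE)
  comp <- igraph::components(g)
  if (comp$no <= 1L) return(mg)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    ## tie: keep the fragment whose canonical SMILES sorts first
    smis <- vapply(best, function(ci) {
      sub <- subMolgraph(mg, which(comp$membership == ci))
      s <- subgraphSmiles(sub)
      if (is.na(s)) "~" else s
    }, character(1))
    best <- best[order(smis)][1]
  } else best <- best[1]
  atoms <- which(comp$membership == best)
  sub <- subMolgraph(mg, atoms)
  b <- mg$bonds[sub$srcBonds, , drop = FALSE]
  bonds <- data.frame(a = sub$bonds$a, b = sub$bonds$b, order = b$order,
                      wedge = b$wedge)
  mb <- writeMolblock(sub$elem, sub$charge, sub$x, sub$y, bonds,
                      title = mg$title)
  out <- tryCatch({
    reRead <- suppressWarnings(ChemmineR::read.SDFset(ChemmineR::read.SDFstr(
      c(strsplit(mb, "\n", fixed = TRUE)[[1]], "$$$$")))[[1]])
    molgraphFromSDF(reRead, mb)
  }, error = function(e) molgraphFromRawMolblock(mb))
  out$title <- mg$title
  out
}

#' Read an SD file into a CompoundSet
#'
#' Parses molecule blocks (V2000; V3000 blocks are normalized through
#' OpenBabel), preserves stereo annotations, keeps the largest fragment of
#' multi-fragment (salt) entries, and reads the configured potency SD tags.
#' Compounds missing every configured potency field are dropped with a
#' warning; unparsable blocks are skipped with a warning.
#'
#' @param path SD file path.
#' @param potencyFields character vector of SD property tags holding potency
#'   values (negative-log scale, e.g. pKi).
#' @param targetLabels target names parallel to `potencyFields` (defaults to
#'   the field names).
#' @return a [CompoundSet-class]
#' @examples
#' sdf <- tempfile(fileext = ".sdf")
#' generateSeriesSDF(defaultFixtureSpec(), sdf)
#' cs <- readCompounds(sdf, "pKi")
#' length(cs)
#' @export
readCompounds <- function(path, potencyFields, targetLabels = potencyFields) {
  if (!file.exists(path)) stop("cannot read SD file: ", path)
  if (!length(potencyFields)) stop("at least one potency field is required")
  if (length(targetLabels) != length(potencyFields))
    stop("potencyFields and targetLabels must have equal length")
  lines <- readLines(path, warn = FALSE)
  recs <- .splitSdfRecords(lines)
  compounds <- list(); ids <- character(0); pot <- NULL
  fields <- list()
  for (k in seq_along(recs)) {
    mg <- .parseOneRecord(recs[[k]], k)
    if (is.null(mg) || mg$n == 0L) {
      warning("skipping unparsable molecule block ", k, call. = FALSE)
      next
    }
    dat <- .parseDataFields(recs[[k]])
    vals <- suppressWarnings(as.numeric(dat[potencyFields]))
    vals[!is.finite(vals)] <- NA_real_
    if (all(is.na(vals))) {
      warning("dropping compound '", mg$title,
              "': no value in any configured potency field", call. = FALSE)
      next
    }
    mg <- .largestFragment(mg)
    mg <- withPrep(mg)
    mg$smiles <- canonicalSmiles(mg$molblock, stereo = TRUE)
    mg$constitution <- canonicalSmiles(mg$molblock, stereo = FALSE)
    id <- mg$title
    if (id %in% ids) {
      warning("duplicate compound id '", id, "' made unique", call. = FALSE)
      id <- make.unique(c(ids, id))[length(ids) + 1L]
      mg$title <- id
    }
    compounds[[length(compounds) + 1L]] <- mg
    ids <- c(ids, id)
    pot <- rbind(pot, vals)
    fields[[id]] <- dat
  }
  if (is.null(pot)) pot <- matrix(numeric(0), nrow = 0,
                                  ncol = length(potencyFields))
  dimnames(pot) <- NULL
  ## structural duplicates are reported, not removed
  smis <- vapply(compounds, function(m) m$smiles, character(1))
  dup <- smis[duplicated(smis) & !is.na(smis)]
  if (length(dup))
    message(length(dup), " compound(s) duplicate the structure of an ",
            "earlier record (kept as distinct records)")
  cs <- new("CompoundSet", compounds = compounds, ids = ids,
            targets = stats::setNames(targetLabels, potencyFields),
            potencies = pot, source = path)
  validObject(cs)
  cs
}

#' Write a CompoundSet back to an SD file
#'
#' Emits the stored molfile blocks unchanged plus the potency data fields, so
#' read/write/read round-trips preserve connectivity, stereo descriptors and
#' potency values byte-for-byte at the molblock level.
#'
#' @param cs a [CompoundSet-class]
#' @param path output path.
#' @export
writeCompounds <- function(cs, path) {
  fields <- names(cs@targets)
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_along(cs@ids)) {
    writeLines(cs@compounds[[i]]$molblock, con, sep = "\n")
    for (j in seq_along(fields)) {
      v <- cs@potencies[i, j]
      if (!is.na(v))
        writeLines(c(sprintf(">  <%s>", fields[j]), sprintf("%.10g", v), ""),
                   con, sep = "\n")
    }
    writeLines("$$$$", con, sep = "\n")
  }
  invisible(path)
}

## ---------------------------------------------------------------------------
## subset report

#' Write the per-subset compound report
#'
#' Tab-separated file with one row per compound: series id, subset label,
#' compound id, the R-group at each site (canonical SMILES with `*` as
#' attachment marker, "H" when unsubstituted), the potency value(s), and the
#' stereo-group index where the compound belongs to a set of stereoisomers.
#' Rows are sorted by subset (layer, then site numbers) and compound id;
#' output is byte-deterministic.
#'
#' @param analysis a [SeriesAnalysis-class] (see [analyzeSeries()]).
#' @param path output path.
#' @export
writeSubsetReport <- function(analysis, path) {
  part <- analysis@partition
  cs <- analysis@compounds
  n <- nSites(part)
  ord <- orderCombinations(part@combinations)
  header <- c("series_id", "subset", "compound_id",
              if (n) paste0("R", seq_len(n)),
              paste0("potency_", unname(cs@targets)), "stereo_index")
  rows <- character(0)
  for (k in ord) {
    ids <- sort(part@members[[k]])
    si <- subsetStereoIndices(analysis, part@labels[k])
    for (id in ids) {
      asg <- analysis@assignments[[id]]
      groups <- if (n) asg$groups[as.character(seq_len(n))] else character(0)
      pots <- sprintf("%.4g", potencies(cs)[id, ])
      pots[is.na(potencies(cs)[id, ])] <- ""
      sidx <- si[id]
      rows <- c(rows, paste(c(part@seriesId, part@labels[k], id, groups, pots,
                              if (is.na(sidx)) "" else as.character(sidx)),
                            collapse = "\t"))
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(header, collapse = "\t"), rows), con, sep = "\n")
  invisible(path)
}

## ---------------------------------------------------------------------------
## graph exports

.graphAsTables <- function(graph) {
  if (is(graph, "SarGraph")) {
    nodes <- graph@nodes
    nodes$id <- nodes$label
    edges <- graph@edges
    meta <- list(type = "SarGraph", kind = graph@kind,
                 seriesId = graph@seriesId, target = graph@target)
  } else if (is(graph, "RGroupTree")) {
    nodes <- graph@nodes
    nodes$id <- as.character(nodes$id)
    edges <- data.frame(
      from = as.character(nodes$parent[!is.na(nodes$parent)]),
      to = nodes$id[!is.na(nodes$parent)], stringsAsFactors = FALSE)
    meta <- list(type = "RGroupTree", subsetLabel = graph@subsetLabel,
                 layerOrder = graph@layerOrder, seriesId = graph@seriesId)
  } else stop("unsupported graph object of class ", class(graph))
  list(nodes = nodes, edges = edges, meta = meta)
}

.xmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

.attrType <- function(v) {
  if (is.logical(v)) "boolean" else if (is.numeric(v)) "double" else "string"
}

.fmtAttr <- function(v) {
  if (is.logical(v)) ifelse(v, "true", "false")
  else if (is.numeric(v)) sprintf("%.10g", v)
  else .xmlEscape(as.character(v))
}

.writeGraphml <- function(tab, path) {
  nodes <- tab$nodes; edges <- tab$edges
  keys <- setdiff(names(nodes), "id")
  lines <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
             "<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\">")
  for (k in keys)
    lines <- c(lines, sprintf(
      "  <key id=\"%s\" for=\"node\" attr.name=\"%s\" attr.type=\"%s\"/>",
      k, k, .attrType(nodes[[k]])))
  lines <- c(lines, "  <graph edgedefault=\"directed\">")
  for (i in seq_len(nrow(nodes))) {
    lines <- c(lines, sprintf("    <node id=\"%s\">", .xmlEscape(nodes$id[i])))
    for (k in keys) {
      v <- nodes[[k]][i]
      if (!is.na(v))
        lines <- c(lines, sprintf("      <data key=\"%s\">%s</data>",
                                  k, .fmtAttr(v)))
    }
    lines <- c(lines, "    </node>")
  }
  for (i in seq_len(nrow(edges)))
    lines <- c(lines, sprintf("    <edge source=\"%s\" target=\"%s\"/>",
                              .xmlEscape(edges$from[i]), .xmlEscape(edges$to[i])))
  lines <- c(lines, "  </graph>", "</graphml>")
  con <- file(path, open = "wb"); on.exit(close(con))
  writeLines(lines, con, sep = "\n")
}

.writeDot <- function(tab, path) {
  nodes <- tab$nodes; edges <- tab$edges
  keys <- setdiff(names(nodes), "id")
  q <- function(x) paste0("\"", gsub("\"", "\\\\\"", x), "\"")
  lines <- "digraph sar {"
  for (i in seq_len(nrow(nodes))) {
    attrs <- vapply(keys, function(k) {
      v <- nodes[[k]][i]
      sprintf("%s=%s", k, q(if (is.na(v)) "" else .fmtAttr(v)))
    }, character(1))
    lines <- c(lines, sprintf("  %s [%s];", q(nodes$id[i]),
                              paste(attrs, collapse = ", ")))
  }
  for (i in seq_len(nrow(edges)))
    lines <- c(lines, sprintf("  %s -> %s;", q(edges$from[i]), q(edges$to[i])))
  lines <- c(lines, "}")
  con <- file(path, open = "wb"); on.exit(close(con))
  writeLines(lines, con, sep = "\n")
}

#' Export a SAR graph or R-group tree
#'
#' Nodes carry their label, layer, compound count, mean potency, potency
#' range, empty flag and layout hints; R-group tree nodes additionally carry
#' the R-group, compound id, potency and stereo-group index. The JSON export
#' round-trips through [importGraphJSON()].
#'
#' @param graph a [SarGraph-class] or [RGroupTree-class].
#' @param format one of "graphml", "dot", "json".
#' @param path output path.
#' @export
exportGraph <- function(graph, format, path) {
  format <- tolower(format)
  if (!format %in% c("graphml", "dot", "json"))
    stop("unknown format '", format,
         "'; supported formats: graphml, dot, json")
  tab <- .graphAsTables(graph)
  if (format == "graphml") .writeGraphml(tab, path)
  else if (format == "dot") .writeDot(tab, path)
  else {
    payload <- c(tab$meta, list(nodes = tab$nodes, edges = tab$edges))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Re-import a JSON graph export
#'
#' @param path path of a file written by [exportGraph()] with
#'   `format = "json"`.
#' @return the reconstructed [SarGraph-class] or [RGroupTree-class].
#' @export
importGraphJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodes <- as.data.frame(obj$nodes, stringsAsFactors = FALSE)
  edges <- if (length(obj$edges))
    as.data.frame(obj$edges, stringsAsFactors = FALSE)
  else data.frame(from = character(0), to = character(0),
                  stringsAsFactors = FALSE)
  if (identical(obj$type, "SarGraph")) {
    nodes$id <- NULL
    new("SarGraph", kind = obj$kind, nodes = nodes, edges = edges,
        seriesId = obj$seriesId, target = obj$target)
  } else if (identical(obj$type, "RGroupTree")) {
    nodes$id <- as.integer(nodes$id)
    nodes$parent <- as.integer(nodes$parent)
    new("RGroupTree", subsetLabel = obj$subsetLabel,
        layerOrder = as.integer(obj$layerOrder), nodes = nodes,
        seriesId = obj$seriesId)
  } else stop("not a graph export: ", path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
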