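## Thin in-process bridge to OpenBabel via ChemmineOB's SWIG layer.
## ChemmineOB::convertFormat() routes every option through GENOPTIONS, which
## cannot express SMILES output options such as "i" (omit stereo/isotopes),
## so we drive OBConversion directly.

.ob <- function(name) utils::getFromNamespace(name, "ChemmineOB")

#' Convert a chemical string between formats with OpenBabel
#'
#' @param from,to OpenBabel format identifiers (e.g. "SDF", "CAN", "MOL2").
#' @param source input text in format `from`.
#' @param outopts character vector of OpenBabel output options
#'   (e.g. "i" for stereo-free SMILES).
#' @return output text; empty string when conversion fails.
#' @keywords internal
obConvert <- function(from, to, source, outopts = character()) {
  inStr <- .ob("istreamFromString")(source)
  outStr <- .ob("ostreamToString")()
  conv <- .ob("OBConversion")(inStr, outStr)
  on.exit(.ob("delete_OBConversion")(conv), add = TRUE)
  if (!.ob("OBConversion_SetInAndOutFormats")(conv, from, to))
    stop("OpenBabel cannot convert from ", from, " to ", to)
  for (o in outopts)
    .ob("OBConversion_AddOption")(conv, o, "OUTOPTIONS", "")
  .ob("OBConversion_Convert")(conv)
  .ob("stringFromOstream")(outStr)
}

## cache: canonical SMILES calls repeat heavily during decomposition
.smiCache <- new.env(parent = emptyenv())

#' Canonical SMILES of a molfile block
#'
#' @param molblock V2000 molfile text (no SD data fields).
#' @param stereo keep stereo markers? Constitution-level comparisons use
#'   `stereo = FALSE`.
#' @return canonical SMILES string, or NA when OpenBabel fails to parse.
#' @keywords internal
canonicalSmiles <- function(molblock, stereo = TRUE) {
  key <- paste0(if (stereo) "s:" else "c:", molblock)
  hit <- .smiCache[[key]]
  if (!is.null(hit)) return(hit)
  out <- obConvert("SDF", "CAN", molblock,
                   outopts = if (stereo) character() else "i")
  smi <- sub("[\t\n ].*$", "", out)
  smi <- if (nzchar(smi)) smi else NA_character_
  assign(key, smi, envir = .smiCache)
  smi
}

#' Aromatic bond perception via OpenBabel
#'
#' Converts a molfile to MOL2 (atom order preserved) and reads the bond type
#' column; returns a logical vector over the molfile's bond rows.
#' @keywords internal
perceiveAromaticBonds <- function(molblock, bonds) {
  nb <- nrow(bonds)
  if (nb == 0L) return(logical(0))
  mol2 <- obConvert("SDF", "MOL2", molblock)
  lines <- strsplit(mol2, "\n", fixed = TRUE)[[1]]
  bstart <- which(lines == "@<TRIPOS>BOND")
  arom <- logical(nb)
  if (length(bstart) != 1L) return(arom)
  i <- bstart + 1L
  while (i <= length(lines) && !startsWith(lines[i], "@")) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) >= 4L && f[4] == "ar") {
      a <- as.integer(f[2]); b <- as.integer(f[3])
      hit <- which((bonds$a == a & bonds$b == b) | (bonds$a == b & bonds$b == a))
      arom[hit] <- TRUE
    }
    i <- i + 1L
  }
  arom
}
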