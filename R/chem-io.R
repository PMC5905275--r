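# Reading, standardizing, deduplicating and writing molecule datasets.

#' Read molecules from SMILES, SDF or CSV files
#'
#' Unparsable entries are skipped with a message (their count is kept in the
#' `"skipped"` attribute). Identifiers are made unique. Labels are normalized
#' to lowercase.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"smiles"` (one SMILES per line,
#'   optional whitespace-separated id), `"sdf"` (V2000), or `"csv"` with
#'   columns `id`, `smiles` (or `smiles_raw`) and optional `label`, `source`.
#' @param source provenance tag stored with each record (defaults to the
#'   file name).
#' @return A [MoleculeSet-class] (not standardized yet).
#' @examples
#' f <- tempfile(fileext = ".smi")
#' writeLines(c("CCO ethanol", "c1ccccc1 benzene"), f)
#' ms <- parseMolecules(f)
#' @export
parseMolecules <- function(path, format = c("auto", "smiles", "sdf", "csv"),
                           source = basename(path)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", path))
    format <- switch(ext, smi = , smiles = "smiles", sdf = , mol = "sdf",
                     csv = "csv",
                     stop("cannot infer format from extension '", ext, "'"))
  }
  if (format == "smiles") {
    lines <- trimws(readLines(path, warn = FALSE))
    lines <- lines[nzchar(lines)]
    tok <- strsplit(lines, "[ \t]+")
    smi <- vapply(tok, `[`, character(1), 1L)
    id <- vapply(tok, function(t) if (length(t) > 1L) t[2L] else NA_character_,
                 character(1))
    id[is.na(id)] <- paste0("mol_", which(is.na(id)))
    lab <- NA_character_
  } else if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    smiCol <- intersect(c("smiles", "smiles_raw"), colnames(df))[1]
    if (!("id" %in% colnames(df)) || is.na(smiCol))
      stop("csv must have columns 'id' and 'smiles'")
    smi <- as.character(df[[smiCol]])
    id <- as.character(df$id)
    lab <- if ("label" %in% colnames(df)) df$label else NA_character_
    if ("source" %in% colnames(df)) source <- df$source
  } else {
    sdfset <- ChemmineR::read.SDFset(path)
    ok <- ChemmineR::validSDF(sdfset)
    nInvalid <- sum(!ok)
    sdfset <- sdfset[ok]
    if (length(sdfset) == 0L) stop("no parsable molecules in ", path)
    smi <- vapply(seq_along(sdfset), function(i) {
      out <- tryCatch(as.character(ChemmineR::sdf2smiles(sdfset[i])),
                      error = function(e) NA_character_)
      s <- sub("[ \t].*$", "", out[1])
      if (is.na(s) || !nzchar(s)) NA_character_ else trimws(s)
    }, character(1))
    id <- vapply(seq_along(sdfset), function(i) {
      tt <- ChemmineR::sdfid(sdfset[i])
      if (is.na(tt) || !nzchar(trimws(tt))) paste0("mol_", i) else trimws(tt)
    }, character(1))
    lab <- NA_character_
    if (nInvalid) message("skipped ", nInvalid, " invalid SDF entr",
                          if (nInvalid == 1L) "y" else "ies")
  }
  parsable <- !is.na(.canonicalSmiles(smi))
  nSkip <- sum(!parsable)
  if (nSkip) message("skipped ", nSkip, " unparsable entr",
                     if (nSkip == 1L) "y" else "ies")
  if (!any(parsable)) stop("zero parsable molecules in ", path)
  lab <- rep_len(lab, length(smi))
  if (length(source) > 1L) source <- rep_len(source, length(smi))[parsable]
  ms <- moleculeSet(id[parsable], smi[parsable], lab[parsable], source)
  attr(ms, "skipped") <- nSkip
  ms
}

# largest organic fragment after dropping waters; NA_character_ if nothing left
.selectFragment <- function(rawSmiles) {
  frags <- strsplit(rawSmiles, ".", fixed = TRUE)[[1]]
  frags <- frags[nzchar(frags)]
  can <- .canonicalSmiles(frags)
  if (anyNA(can)) return(NA_character_)
  can <- can[can != "O"]                      # water removal
  if (!length(can)) return("")
  if (length(can) == 1L) return(can)
  gs <- .molGraphs(can)
  organic <- vapply(gs, function(g) any(g$elem == "C"), logical(1))
  cand <- if (any(organic)) which(organic) else seq_along(can)
  sizes <- vapply(gs, .heavyAtomCount, numeric(1))
  can[cand[which.max(sizes[cand])]]
}

.MAX_NEUTRAL_VALENCE <- c(B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 5,
                          S = 6, Cl = 1, Br = 1, I = 1, As = 5, Se = 6)

# convert adjacent +/- formal-charge pairs into an incremented bond order
# where the resulting valences stay legal; returns possibly modified graph
.neutralizeChargePairs <- function(g, id = "?") {
  if (!any(g$charge > 0L) || !any(g$charge < 0L)) return(g)
  bondSum <- rep(0, g$n)
  for (k in seq_len(nrow(g$bonds))) {
    bondSum[g$bonds$a[k]] <- bondSum[g$bonds$a[k]] + g$bonds$order[k]
    bondSum[g$bonds$b[k]] <- bondSum[g$bonds$b[k]] + g$bonds$order[k]
  }
  touched <- rep(FALSE, g$n)
  blocked <- FALSE
  for (k in seq_len(nrow(g$bonds))) {
    a <- g$bonds$a[k]; b <- g$bonds$b[k]
    if (touched[a] || touched[b]) next
    qa <- g$charge[a]; qb <- g$charge[b]
    if (!((qa == 1L && qb == -1L) || (qa == -1L && qb == 1L))) next
    if (g$bonds$order[k] >= 3L) { blocked <- TRUE; next }
    maxA <- .MAX_NEUTRAL_VALENCE[g$elem[a]]
    maxB <- .MAX_NEUTRAL_VALENCE[g$elem[b]]
    if (is.na(maxA) || is.na(maxB) ||
        bondSum[a] + 1 > maxA || bondSum[b] + 1 > maxB) { blocked <- TRUE; next }
    g$bonds$order[k] <- g$bonds$order[k] + 1L
    g$charge[a] <- 0L; g$charge[b] <- 0L
    bondSum[a] <- bondSum[a] + 1; bondSum[b] <- bondSum[b] + 1
    touched[a] <- TRUE; touched[b] <- TRUE
  }
  if (blocked)
    warning("record ", id,
            ": adjacent charge pair left unmodified (valence would be illegal)")
  g
}

#' Standardize molecule records
#'
#' Applies, in order: (1) water fragments are dropped and, for remaining
#' multi-fragment structures, the largest organic fragment is kept
#' (counter-ions stripped); (2) aromaticity is perceived on rings;
#' (3) adjacent opposite formal charges are converted into an incremented
#' bond order where the resulting valence is legal; (4) the standardized
#' structure is stored as canonical SMILES (hydrogens tracked as counts on
#' the heavy-atom graph) and its InChIKey is computed. Standardization is
#' idempotent.
#'
#' @param mset a [MoleculeSet-class].
#' @param onError `"stop"` (default) or `"skip"` records that cannot be
#'   standardized (unparsable, or empty after water removal).
#' @return The MoleculeSet with `smiles_std` and `inchikey` populated.
#' @examples
#' ms <- standardizeMolecules(moleculeSet("m1", "CCO.O"))
#' stdSmiles(ms)   # "CCO"
#' @export
standardizeMolecules <- function(mset, onError = c("stop", "skip")) {
  onError <- match.arg(onError)
  rec <- mset@records
  std <- character(nrow(rec)); failed <- logical(nrow(rec))
  for (i in seq_len(nrow(rec))) {
    frag <- .selectFragment(rec$smiles_raw[i])
    if (is.na(frag)) {
      msg <- paste0("record ", rec$id[i], ": unparsable SMILES '",
                    rec$smiles_raw[i], "'")
      if (onError == "stop") stop(msg)
      warning(msg); failed[i] <- TRUE; next
    }
    if (!nzchar(frag)) {
      msg <- paste0("record ", rec$id[i], ": empty after standardization")
      if (onError == "stop") stop(msg)
      warning(msg); failed[i] <- TRUE; next
    }
    g <- .molGraph(frag)
    g2 <- .neutralizeChargePairs(g, id = rec$id[i])
    std[i] <- if (identical(g2$charge, g$charge)) frag else .graphToSmiles(g2)
  }
  keep <- which(!failed)
  rec <- rec[keep, , drop = FALSE]
  std <- std[keep]
  rec$smiles_std <- .canonicalSmiles(std)
  rec$inchikey <- .inchikey(rec$smiles_std)
  new("MoleculeSet", records = rec, motifAtoms = mset@motifAtoms[keep])
}

#' Remove duplicate structures by InChIKey
#'
#' Keeps the first occurrence of each distinct InChIKey. Duplicates whose
#' labels conflict (same InChIKey, different label) are removed entirely and
#' reported: ambiguous taste assignments cannot be trained on.
#'
#' @param mset a standardized [MoleculeSet-class].
#' @return The deduplicated MoleculeSet; removed conflicting InChIKeys are
#'   in the `"conflicts"` attribute.
#' @export
deduplicateMolecules <- function(mset) {
  rec <- mset@records
  if (anyNA(rec$inchikey)) stop("all records must be standardized (InChIKey present)")
  conflict <- vapply(split(rec$label, rec$inchikey),
                     function(l) length(unique(l)) > 1L, logical(1))
  conflictKeys <- names(conflict)[conflict]
  if (length(conflictKeys))
    message("removed ", length(conflictKeys),
            " InChIKey(s) with conflicting labels: ",
            paste(conflictKeys, collapse = ", "))
  keep <- !(rec$inchikey %in% conflictKeys) & !duplicated(rec$inchikey)
  out <- new("MoleculeSet", records = rec[keep, , drop = FALSE],
             motifAtoms = mset@motifAtoms[keep])
  attr(out, "conflicts") <- conflictKeys
  out
}

#' Write a MoleculeSet as CSV
#'
#' Columns: `id, smiles_raw, smiles_std, inchikey, label, source`. The file
#' can be read back with [parseMolecules()] (`format = "csv"`).
#'
#' @param mset a [MoleculeSet-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeMoleculesCSV <- function(mset, path) {
  utils::write.csv(mset@records, path, row.names = FALSE)
  invisible(path)
}
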