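# Seeded synthetic molecule sets with class-enriched substructure motifs.
# Molecules are assembled by chaining small decoration groups from a fixed
# vocabulary onto an optional motif prefix; every SMILES concatenation rule
# used here keeps the string valid (each group attaches to the previously
# written atom). Distinctness is enforced by InChIKey with bounded retries.

# continuation-safe decoration groups: appending any further group after one
# of these attaches to an atom that can still bond
.DECOR_VOCAB <- c("C", "CC", "CCC", "CO", "CN", "C(C)", "C(CC)", "C(O)",
                  "C(N)", "C(F)", "C(=O)", "COC", "CNC", "CC(C)",
                  "c1ccccc1", "C1CCCCC1")

#' Generate a labeled synthetic molecule set
#'
#' Builds `2 * nPerClass` distinct, standardizable molecules. Motif presence
#' is symmetric in the purity: a molecule of class *c* carries motif *c*
#' with probability `motifPurity` and the other class's motif with
#' probability `1 - motifPurity` (so purity 1 separates the classes
#' perfectly and purity 0.5 removes all class signal). Remaining structure
#' is random decoration from a fixed vocabulary. Deterministic per seed.
#' Planted-motif atom indices (on the standardized structure) are stored as
#' provenance in [motifAtoms()], and planted flags in the record table.
#'
#' @param spec a [FixtureSpec-class].
#' @return A standardized, labeled [MoleculeSet-class] of `2 * nPerClass`
#'   records with pairwise-distinct InChIKeys.
#' @examples
#' ms <- generateLabeledSet(fixtureSpec(nPerClass = 5, seed = 7))
#' @export
generateLabeledSet <- function(spec) {
  validObject(spec)
  motifs <- c(sweet = spec@motifSweet, bitter = spec@motifBitter)
  motifG <- lapply(motifs, function(s) {
    can <- .canonicalSmiles(s)
    if (is.na(can)) stop("motif does not parse: ", s)
    .molGraph(can)
  })
  set.seed(spec@seed)
  n <- spec@nPerClass
  labels <- rep(.TASTE_CLASSES, each = n)
  seen <- character(0)
  smiles <- character(2L * n); ikeys <- character(2L * n)
  planted <- matrix(FALSE, 2L * n, 2L,
                    dimnames = list(NULL, .TASTE_CLASSES))
  for (i in seq_len(2L * n)) {
    own <- labels[i]
    pS <- if (own == "sweet") spec@motifPurity else 1 - spec@motifPurity
    pB <- if (own == "bitter") spec@motifPurity else 1 - spec@motifPurity
    hasSweet <- stats::runif(1) < pS
    hasBitter <- stats::runif(1) < pB
    ok <- FALSE
    for (try in seq_len(200L)) {
      nTok <- sample(2:(spec@decorationDepth + 2L), 1L)
      # assembly order is class-independent so that, at purity 0.5, the two
      # classes draw from exactly the same molecule distribution
      parts <- c(if (hasSweet) motifs[["sweet"]],
                 if (hasBitter) motifs[["bitter"]],
                 sample(.DECOR_VOCAB, nTok, replace = TRUE))
      smi <- paste(parts, collapse = "")
      ik <- .inchikey(.canonicalSmiles(smi))
      if (!is.na(ik) && !(ik %in% seen)) {
        seen <- c(seen, ik)
        smiles[i] <- smi; ikeys[i] <- ik
        planted[i, "sweet"] <- hasSweet; planted[i, "bitter"] <- hasBitter
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("could not generate ", 2L * n, " distinct molecules; ",
           "increase decorationDepth")
  }
  ms <- moleculeSet(sprintf("%s_%03d", substr(labels, 1, 2),
                            c(seq_len(n), seq_len(n))),
                    smiles, labels, source = "synthetic")
  ms <- standardizeMolecules(ms)
  ms@records$planted_sweet <- planted[, "sweet"]
  ms@records$planted_bitter <- planted[, "bitter"]
  gs <- .molGraphs(stdSmiles(ms))
  ms@motifAtoms <- lapply(seq_along(gs), function(i) {
    out <- list()
    for (cls in .TASTE_CLASSES) {
      if (planted[i, cls]) {
        hit <- .matchMotif(motifG[[cls]], gs[[i]])
        if (!is.null(hit)) out[[cls]] <- hit
      }
    }
    out
  })
  validObject(ms)
  ms
}

#' Write a synthetic set as CSV plus a motif-provenance sidecar JSON
#'
#' The CSV is consumable by [parseMolecules()]; the sidecar
#' (`<path>.motifs.json`) records the motif SMILES and per-record planted
#' flags and atom indices.
#'
#' @param mset a [MoleculeSet-class] from [generateLabeledSet()].
#' @param path CSV output path.
#' @param spec the [FixtureSpec-class] used (stored in the sidecar).
#' @return `path`, invisibly.
#' @export
writeFixtureCSV <- function(mset, path, spec = NULL) {
  writeMoleculesCSV(mset, path)
  sidecar <- list(
    motifs = if (is.null(spec)) NULL
             else list(sweet = spec@motifSweet, bitter = spec@motifBitter,
                       purity = spec@motifPurity, seed = spec@seed),
    records = lapply(seq_len(length(mset)), function(i)
      list(id = molIds(mset)[i], motif_atoms = mset@motifAtoms[[i]])))
  jsonlite::write_json(sidecar, paste0(path, ".motifs.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Random label/prediction/score triples with known confusion counts
#'
#' Test harness for the metric formulas: each triple carries its own
#' ground-truth confusion cells, counted element-by-element at generation
#' time. The first triple is a perfect classifier, the second predicts all
#' sweet; the rest vary in length and agreement.
#'
#' @param n number of triples (>= 1).
#' @param seed integer seed.
#' @return list of `n` lists with `labels`, `predictions`, `scores`
#'   (sweet-class score), `counts` (tp/tn/fp/fn, sweet positive), `perfect`.
#' @export
generateConfusionCases <- function(n, seed = 1L) {
  stopifnot(n >= 1L)
  set.seed(as.integer(seed))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    repeat {
      len <- sample(20:150, 1L)
      labels <- sample(.TASTE_CLASSES, len, replace = TRUE)
      if (length(unique(labels)) == 2L) break
    }
    if (i == 1L) {                      # perfect classifier
      predictions <- labels
      scores <- ifelse(labels == "sweet", stats::runif(len, .8, 1),
                       stats::runif(len, 0, .2))
    } else if (i == 2L) {               # degenerate: everything sweet
      predictions <- rep("sweet", len)
      scores <- stats::runif(len, .5, 1)
    } else {
      q <- stats::runif(1)              # agreement level
      flip <- stats::runif(len) > q
      predictions <- ifelse(flip, sample(.TASTE_CLASSES, len, replace = TRUE),
                            labels)
      scores <- pmin(1, pmax(0, 0.5 * (predictions == "sweet") +
                                  stats::runif(len, 0, 0.5)))
    }
    tp <- 0L; tn <- 0L; fp <- 0L; fn <- 0L
    for (k in seq_len(len)) {           # independent element-wise count
      if (labels[k] == "sweet" && predictions[k] == "sweet") tp <- tp + 1L
      else if (labels[k] == "bitter" && predictions[k] == "bitter") tn <- tn + 1L
      else if (labels[k] == "bitter" && predictions[k] == "sweet") fp <- fp + 1L
      else fn <- fn + 1L
    }
    out[[i]] <- list(labels = labels, predictions = predictions,
                     scores = scores,
                     counts = list(tp = tp, tn = tn, fp = fp, fn = fn),
                     positive_class = "sweet", perfect = i == 1L)
  }
  out
}
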