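#' MoleculeSet: a table of compound records
#'
#' Container for a set of small molecules, one row per compound, carrying the
#' raw structure as read, the standardized structure, the InChIKey used for
#' duplicate detection, and an optional taste label (`"sweet"`, `"bitter"` or
#' `"unlabeled"`). Planted-motif provenance (used by the synthetic generator)
#' lives in the `motifAtoms` slot, one list element per record.
#'
#' @slot records data.frame with columns `id`, `smiles_raw`, `smiles_std`,
#'   `inchikey`, `label`, `source`.
#' @slot motifAtoms list, parallel to rows of `records`; each element is a
#'   (possibly empty) named list of integer atom-index vectors.
#' @export
setClass("MoleculeSet",
         representation(records = "data.frame", motifAtoms = "list"))

.MOL_COLS <- c("id", "smiles_raw", "smiles_std", "inchikey", "label", "source")
.INCHIKEY_RE <- "^[A-Z]{14}-[A-Z]{10}-[A-Z]$"

setValidity("MoleculeSet", function(object) {
  rec <- object@records
  if (!all(.MOL_COLS %in% colnames(rec)))
    return(paste("records must have columns:", paste(.MOL_COLS, collapse = ", ")))
  if (!all(rec$label %in% c(.TASTE_CLASSES, "unlabeled")))
    return("labels must be 'sweet', 'bitter' or 'unlabeled'")
  ik <- rec$inchikey[!is.na(rec$inchikey)]
  if (length(ik) && !all(grepl(.INCHIKEY_RE, ik)))
    return("malformed InChIKey present")
  if (length(object@motifAtoms) && length(object@motifAtoms) != nrow(rec))
    return("motifAtoms length must match number of records")
  TRUE
})

#' Construct a MoleculeSet from vectors or a data.frame
#'
#' @param id character identifiers (made unique if needed).
#' @param smiles raw SMILES strings.
#' @param label taste labels; `NA` becomes `"unlabeled"`.
#' @param source free-text provenance tag.
#' @return A [MoleculeSet-class] object (not yet standardized).
#' @examples
#' ms <- moleculeSet(c("m1", "m2"), c("CCO", "c1ccccc1"),
#'                   label = c("sweet", "bitter"))
#' @export
moleculeSet <- function(id, smiles, label = NA_character_, source = "user") {
  n <- length(smiles)
  if (length(id) != n) stop("id and smiles lengths differ")
  label <- tolower(as.character(label))
  label <- rep_len(ifelse(is.na(label) | label == "", "unlabeled", label), n)
  bad <- !label %in% c(.TASTE_CLASSES, "unlabeled")
  if (any(bad))
    stop("unknown label(s): ", paste(unique(label[bad]), collapse = ", "))
  rec <- data.frame(id = make.unique(as.character(id), sep = "_"),
                    smiles_raw = as.character(smiles),
                    smiles_std = NA_character_,
                    inchikey = NA_character_,
                    label = label,
                    source = rep_len(as.character(source), n),
                    stringsAsFactors = FALSE)
  new("MoleculeSet", records = rec, motifAtoms = rep(list(list()), n))
}

#' @describeIn MoleculeSet-class number of records
#' @param x a MoleculeSet
#' @export
setMethod("length", "MoleculeSet", function(x) nrow(x@records))

#' @describeIn MoleculeSet-class subset records
#' @param i indices
#' @param j,drop,... ignored
#' @export
setMethod("[", "MoleculeSet", function(x, i, j, ..., drop = FALSE) {
  idx <- seq_len(length(x))[i]
  new("MoleculeSet", records = x@records[idx, , drop = FALSE],
      motifAtoms = x@motifAtoms[idx])
})

setMethod("show", "MoleculeSet", function(object) {
  rec <- object@records
  nstd <- sum(!is.na(rec$smiles_std))
  cat("MoleculeSet with", nrow(rec), "records (", nstd, "standardized )\n")
  if (nrow(rec)) {
    tab <- table(rec$label)
    cat("  labels:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
    print(utils::head(rec[, c("id", "smiles_raw", "smiles_std", "label")], 4))
    if (nrow(rec) > 4) cat("  ...\n")
  }
})

#' Accessors for MoleculeSet
#'
#' @param x a [MoleculeSet-class].
#' @return Character vectors (one element per record), or for `molRecords`
#'   the underlying data.frame, for `motifAtoms` the provenance list.
#' @name molecule-accessors
NULL

#' @rdname molecule-accessors
#' @export
molIds <- function(x) x@records$id
#' @rdname molecule-accessors
#' @export
rawSmiles <- function(x) x@records$smiles_raw
#' @rdname molecule-accessors
#' @export
stdSmiles <- function(x) x@records$smiles_std
#' @rdname molecule-accessors
#' @export
inchiKeys <- function(x) x@records$inchikey
#' @rdname molecule-accessors
#' @export
tasteLabels <- function(x) x@records$label
#' @rdname molecule-accessors
#' @export
molRecords <- function(x) x@records
#' @rdname molecule-accessors
#' @export
motifAtoms <- function(x) x@motifAtoms
#' @rdname molecule-accessors
#' @export
isStandardized <- function(x) !is.na(x@records$smiles_std)

#' BitFingerprint: a fixed-length binary substructure encoding
#'
#' @slot kind one of `"morgan"`, `"morgan_feat"`, `"atompair"`, `"torsion"`.
#' @slot nBits total bit-vector length (2048 for the circular kinds, 1024
#'   for atom-pair and torsion).
#' @slot onBits sorted 0-based indices of set bits.
#' @export
setClass("BitFingerprint",
         representation(kind = "character", nBits = "integer",
                        onBits = "integer"))

setValidity("BitFingerprint", function(object) {
  if (!object@kind %in% .FP_KINDS) return("unknown fingerprint kind")
  if (object@nBits != .FP_NBITS[[object@kind]])
    return(sprintf("kind '%s' must have %d bits", object@kind,
                   .FP_NBITS[[object@kind]]))
  ob <- object@onBits
  if (length(ob) && (any(ob < 0L) || any(ob >= object@nBits)))
    return("on-bit index out of range")
  if (is.unsorted(ob, strictly = TRUE)) return("onBits must be sorted, unique")
  TRUE
})

setMethod("show", "BitFingerprint", function(object) {
  cat(sprintf("BitFingerprint kind=%s nBits=%d density=%d/%d\n",
              object@kind, object@nBits, length(object@onBits), object@nBits))
})

#' RFConfig: Random-Forest training configuration
#'
#' Captures the forest hyperparameters: number of trees (default 1000),
#' Gini split criterion, square-root attribute sampling per split, the
#' fingerprint kind used as the descriptor, and the seed controlling all
#' randomness. Confidence scores follow the soft-voting rule (mean of the
#' trees' class-probability estimates).
#'
#' @slot nTrees number of trees.
#' @slot fingerprint fingerprint kind used for descriptors.
#' @slot seed integer seed recorded in every artifact.
#' @slot splitCriterion fixed to `"gini"`.
#' @slot mtryRule fixed to `"sqrt"`.
#' @slot votingRule fixed to `"soft"`.
#' @export
setClass("RFConfig",
         representation(nTrees = "integer", fingerprint = "character",
                        seed = "integer", splitCriterion = "character",
                        mtryRule = "character", votingRule = "character"))

setValidity("RFConfig", function(object) {
  if (object@nTrees < 1L) return("nTrees must be >= 1")
  if (!object@fingerprint %in% .FP_KINDS) return("unknown fingerprint kind")
  if (object@splitCriterion != "gini") return("split criterion is fixed to gini")
  if (object@mtryRule != "sqrt") return("attribute sampling is fixed to sqrt")
  TRUE
})

#' Create an RFConfig
#'
#' @param nTrees number of trees in the forest (default 1000).
#' @param fingerprint descriptor kind, one of
#'   `"morgan"`, `"morgan_feat"`, `"atompair"`, `"torsion"`.
#' @param seed integer seed for reproducibility.
#' @return An [RFConfig-class] object.
#' @examples
#' cfg <- rfConfig(nTrees = 500, seed = 42)
#' @export
rfConfig <- function(nTrees = 1000L, fingerprint = "morgan", seed = 1L) {
  new("RFConfig", nTrees = as.integer(nTrees),
      fingerprint = match.arg(fingerprint, .FP_KINDS),
      seed = as.integer(seed), splitCriterion = "gini",
      mtryRule = "sqrt", votingRule = "soft")
}

setMethod("show", "RFConfig", function(object) {
  cat(sprintf(
    "RFConfig: %d trees, gini splits, sqrt attribute sampling,\n  fingerprint=%s, seed=%d, voting=%s\n",
    object@nTrees, object@fingerprint, object@seed, object@votingRule))
})

#' TasteForest: a trained Random-Forest taste classifier
#'
#' Holds the fitted ensemble, its configuration, the class labels, and the
#' retained training fingerprints needed for the Tanimoto applicability
#' domain.
#'
#' @slot forest the fitted ranger ensemble.
#' @slot config the [RFConfig-class] used for training.
#' @slot classes the ordered class pair, `c("bitter", "sweet")`.
#' @slot trainFP logical matrix of training fingerprints (rows = molecules).
#' @slot trainIds,trainLabels identifiers and labels of the training rows.
#' @slot version bundle format-version string.
#' @export
setClass("TasteForest",
         representation(forest = "ANY", config = "RFConfig",
                        classes = "character", trainFP = "matrix",
                        trainIds = "character", trainLabels = "character",
                        version = "character"))

setValidity("TasteForest", function(object) {
  if (length(object@classes) != 2L || anyDuplicated(object@classes))
    return("classes must be two distinct labels")
  if (nrow(object@trainFP) == 0L) return("training fingerprints must be retained")
  if (nrow(object@trainFP) != length(object@trainLabels))
    return("trainFP rows and trainLabels lengths differ")
  TRUE
})

setMethod("show", "TasteForest", function(object) {
  tab <- table(object@trainLabels)
  cat(sprintf("TasteForest (%s): %d trees on %d molecules (%s)\n",
              object@config@fingerprint, object@config@nTrees,
              nrow(object@trainFP),
              paste(names(tab), tab, sep = "=", collapse = ", ")))
})

#' Accessors for TasteForest
#' @param x a [TasteForest-class].
#' @name forest-accessors
NULL

#' @rdname forest-accessors
#' @export
modelConfig <- function(x) x@config
#' @rdname forest-accessors
#' @export
modelClasses <- function(x) x@classes
#' @rdname forest-accessors
#' @export
trainingFingerprints <- function(x) x@trainFP
#' @rdname forest-accessors
#' @export
trainingSummary <- function(x) table(x@trainLabels)

#' FixtureSpec: recipe for a synthetic labeled molecule set
#'
#' Describes a two-class synthetic compound set with class-enriched
#' substructure motifs. Motif presence is symmetric in `motifPurity`:
#' a molecule of class *c* carries motif *c* with probability `motifPurity`
#' and the other class's motif with probability `1 - motifPurity`, so purity
#' 0.5 yields exchangeable (unlearnable) classes and purity 1.0 a perfectly
#' separable set.
#'
#' @slot nPerClass molecules per class.
#' @slot motifSweet,motifBitter SMILES substructure motifs planted in each class.
#' @slot motifPurity class-conditional motif probability in (0.5, 1].
#' @slot decorationDepth maximum number of random decoration groups.
#' @slot seed integer seed.
#' @export
setClass("FixtureSpec",
         representation(nPerClass = "integer", motifSweet = "character",
                        motifBitter = "character", motifPurity = "numeric",
                        decorationDepth = "integer", seed = "integer"))

setValidity("FixtureSpec", function(object) {
  if (object@nPerClass < 1L) return("nPerClass must be positive")
  if (object@motifPurity <= 0 || object@motifPurity > 1)
    return("motifPurity must be in (0, 1]")
  if (object@decorationDepth < 1L) return("decorationDepth must be >= 1")
  TRUE
})

#' Create a FixtureSpec
#'
#' Defaults plant a sulfonamide-like motif in the sweet class (echoing
#' saccharin-type sweeteners) and a fused N-heterocycle (quinoline, an
#' alkaloid core) in the bitter class.
#'
#' @param nPerClass molecules per class (default 300).
#' @param motifSweet,motifBitter motif SMILES.
#' @param motifPurity class-conditional motif probability (default 0.9).
#' @param decorationDepth maximum random decoration groups (default 3).
#' @param seed integer seed.
#' @return A [FixtureSpec-class].
#' @examples
#' sp <- fixtureSpec(nPerClass = 20, seed = 7)
#' @export
fixtureSpec <- function(nPerClass = 300L, motifSweet = "NS(=O)(=O)",
                        motifBitter = "c1ccc2ncccc2c1", motifPurity = 0.9,
                        decorationDepth = 3L, seed = 1L) {
  new("FixtureSpec", nPerClass = as.integer(nPerClass),
      motifSweet = motifSweet, motifBitter = motifBitter,
      motifPurity = as.numeric(motifPurity),
      decorationDepth = as.integer(decorationDepth), seed = as.integer(seed))
}

setMethod("show", "FixtureSpec", function(object) {
  cat(sprintf(
    "FixtureSpec: %d/class, motifs sweet=%s bitter=%s, purity=%.2f, seed=%d\n",
    object@nPerClass, object@motifSweet, object@motifBitter,
    object@motifPurity, object@seed))
})
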