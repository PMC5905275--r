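# Class-conditional feature discrimination on fingerprint bits: per-bit
# relative frequencies in each class, the active-feature rule (a bit is
# active for a class when it is over-represented there and under-represented
# in the other class, both strictly relative to the class-mean frequencies),
# Bayesian P(class | feature) ratios, top-k extraction, a 1 - Pearson
# dissimilarity on score vectors, and back-mapping from bits to atom
# environments.

#' Per-bit class-conditional relative frequencies
#'
#' For every bit, the fraction of each class's molecules that carry the bit.
#' The per-class average relative frequency over all bits (used by the
#' active-feature rule) is attached as the `"classMeans"` attribute.
#'
#' @param m binary fingerprint matrix ([fingerprintMatrix()]).
#' @param labels class labels, one per row; both classes must be present.
#' @return data.frame with `bit` (0-based), `freq_sweet`, `freq_bitter`.
#' @export
relativeFrequencies <- function(m, labels) {
  if (nrow(m) != length(labels)) stop("matrix rows and labels lengths differ")
  if (!all(.TASTE_CLASSES %in% labels)) stop("both classes must be present")
  fs <- colMeans(m[labels == "sweet", , drop = FALSE])
  fb <- colMeans(m[labels == "bitter", , drop = FALSE])
  out <- data.frame(bit = seq_len(ncol(m)) - 1L,
                    freq_sweet = unname(fs), freq_bitter = unname(fb))
  attr(out, "classMeans") <- c(sweet = mean(fs), bitter = mean(fb))
  out
}

#' Assign active-feature classes
#'
#' A bit is active for sweet iff `freq_sweet > mean_sweet` and
#' `freq_bitter < mean_bitter` (strict inequalities; boundary equality is
#' inactive), symmetrically for bitter; `"both"` if it satisfies both rules,
#' `"none"` otherwise.
#'
#' @param scores data.frame from [relativeFrequencies()].
#' @param classMeans named vector `c(sweet =, bitter =)`; defaults to the
#'   attribute carried by `scores`.
#' @return `scores` with an `active_for` column added.
#' @export
activeFeatures <- function(scores, classMeans = attr(scores, "classMeans")) {
  if (is.null(classMeans)) stop("class means are missing")
  ms <- classMeans[["sweet"]]; mb <- classMeans[["bitter"]]
  sw <- scores$freq_sweet > ms & scores$freq_bitter < mb
  bt <- scores$freq_bitter > mb & scores$freq_sweet < ms
  scores$active_for <- ifelse(sw & bt, "both",
                       ifelse(sw, "sweet", ifelse(bt, "bitter", "none")))
  scores
}

#' Bayesian class-conditional feature probabilities
#'
#' For every bit carried by at least one molecule,
#' `P(class | feature) = (molecules of that class with the bit on) /
#' (all molecules with the bit on)`. Bits that occur nowhere get `NA`
#' (undefined, never 0/0 coerced). With `smoothing > 0`, a Laplace term is
#' added to both counts (off by default; the plain ratio is the reference
#' behavior).
#'
#' @param m binary fingerprint matrix.
#' @param labels class labels per row.
#' @param smoothing Laplace pseudo-count (default 0).
#' @return data.frame with `bit`, `p_sweet_given_f`, `p_bitter_given_f`.
#' @export
bayesFeatureScores <- function(m, labels, smoothing = 0) {
  if (nrow(m) != length(labels)) stop("matrix rows and labels lengths differ")
  if (!all(.TASTE_CLASSES %in% labels)) stop("both classes must be present")
  nS <- colSums(m[labels == "sweet", , drop = FALSE])
  nB <- colSums(m[labels == "bitter", , drop = FALSE])
  tot <- nS + nB
  pS <- (nS + smoothing) / (tot + 2 * smoothing)
  pB <- (nB + smoothing) / (tot + 2 * smoothing)
  if (smoothing == 0) {              # unsmoothed 0/0 is undefined, never 0
    pS[tot == 0] <- NA_real_; pB[tot == 0] <- NA_real_
  }
  data.frame(bit = seq_len(ncol(m)) - 1L,
             p_sweet_given_f = unname(pS), p_bitter_given_f = unname(pB))
}

#' Combined per-bit feature report
#'
#' Merges [relativeFrequencies()], [activeFeatures()] and
#' [bayesFeatureScores()] into one table, ready for CSV export.
#'
#' @param m binary fingerprint matrix.
#' @param labels class labels per row.
#' @return data.frame: `bit`, `freq_sweet`, `freq_bitter`,
#'   `p_sweet_given_f`, `p_bitter_given_f`, `active_for`; class means kept as
#'   the `"classMeans"` attribute.
#' @export
featureReport <- function(m, labels) {
  rf <- activeFeatures(relativeFrequencies(m, labels))
  bs <- bayesFeatureScores(m, labels)
  out <- cbind(rf[, c("bit", "freq_sweet", "freq_bitter")],
               bs[, c("p_sweet_given_f", "p_bitter_given_f")],
               active_for = rf$active_for)
  attr(out, "classMeans") <- attr(rf, "classMeans")
  out
}

#' Top-k active features of a class
#'
#' Bits active for the class, ranked by own-class relative frequency
#' descending, ties broken by ascending bit index; each entry carries both
#' classes' frequencies (paired-display style).
#'
#' @param scores data.frame with `active_for` assigned (see
#'   [activeFeatures()] or [featureReport()]).
#' @param class `"sweet"` or `"bitter"`.
#' @param k number of features; if it exceeds the available active bits, all
#'   are returned with a warning.
#' @return data.frame of at most `k` rows.
#' @export
topFeatures <- function(scores, class = c("sweet", "bitter"), k = 10L) {
  class <- match.arg(class)
  if (is.null(scores$active_for)) stop("scores must carry active_for")
  act <- scores[scores$active_for == class, , drop = FALSE]
  own <- paste0("freq_", class)
  act <- act[order(-act[[own]], act$bit), , drop = FALSE]
  if (k > nrow(act)) {
    warning("only ", nrow(act), " active bits for class '", class,
            "'; returning all")
    k <- nrow(act)
  }
  out <- utils::head(act, k)
  rownames(out) <- NULL
  out
}

#' Feature dissimilarity: 1 - Pearson correlation
#'
#' Generic over score vectors (per-class frequency pairs, per-compound
#' profiles, ...): the uncommon-feature score between two features.
#'
#' @param a,b numeric vectors of equal length >= 2 with non-zero variance.
#' @return dissimilarity in `[0, 2]`.
#' @examples
#' featureDissimilarity(c(1, 2, 3), c(1, 2, 4))  # about 0.018
#' @export
featureDissimilarity <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2L)
    stop("need equal-length vectors of length >= 2")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero-variance vector: correlation undefined")
  1 - stats::cor(a, b)
}

#' Map a fingerprint bit back to atom environments
#'
#' For the circular kinds, every atom environment of the molecule that folds
#' to the requested bit is returned with its central atom, radius, the atom
#' indices it spans, and a substructure string (canonical SMILES of the
#' environment subgraph).
#'
#' @param x single-record standardized [MoleculeSet-class] or one SMILES.
#' @param bit 0-based bit index; must be on in this molecule's fingerprint.
#' @param kind `"morgan"` or `"morgan_feat"` (circular kinds only).
#' @return data.frame with `bit`, `atom`, `radius`, `substructure`, and a
#'   list-column `atoms` of environment atom indices.
#' @export
bitToSubstructure <- function(x, bit, kind = c("morgan", "morgan_feat")) {
  kind <- match.arg(kind)
  smi <- .oneStdSmiles(x)
  g <- .molGraph(smi)
  fp <- .fpFromGraph(g, kind, withEnvironments = TRUE)
  env <- attr(fp, "environments")
  hit <- env[env$bit == bit, , drop = FALSE]
  if (nrow(hit) == 0L)
    stop("bit ", bit, " is not set for this molecule (kind ", kind, ")")
  adj <- lapply(seq_len(g$n), function(i) {
    k <- which(g$bonds$a == i | g$bonds$b == i)
    ifelse(g$bonds$a[k] == i, g$bonds$b[k], g$bonds$a[k])
  })
  envAtoms <- function(center, radius) {
    atoms <- center
    frontier <- center
    for (r in seq_len(radius)) {
      frontier <- setdiff(unique(unlist(adj[frontier])), atoms)
      atoms <- c(atoms, frontier)
    }
    sort(atoms)
  }
  rows <- lapply(seq_len(nrow(hit)), function(k) {
    at <- envAtoms(hit$atom[k], hit$radius[k])
    sub <- .subgraphSmiles(g, at)
    data.frame(bit = bit, atom = hit$atom[k], radius = hit$radius[k],
               substructure = sub)
  })
  out <- do.call(rbind, rows)
  out$atoms <- lapply(seq_len(nrow(hit)),
                      function(k) envAtoms(hit$atom[k], hit$radius[k]))
  out
}

# canonical SMILES of the induced subgraph on `atoms`
.subgraphSmiles <- function(g, atoms) {
  remap <- match(seq_len(g$n), atoms)
  keep <- g$bonds$a %in% atoms & g$bonds$b %in% atoms
  sub <- list(n = length(atoms), elem = g$elem[atoms],
              charge = g$charge[atoms],
              bonds = data.frame(a = remap[g$bonds$a[keep]],
                                 b = remap[g$bonds$b[keep]],
                                 order = g$bonds$order[keep],
                                 arom = g$bonds$arom[keep]))
  s <- .graphToSmiles(sub, aromaticAsFour = TRUE)
  if (is.na(s)) {
    # partial aromatic fragments cannot be kekulized into a standalone
    # SMILES; fall back to a descriptive atom string (aromatic lowercase)
    e <- sub$elem
    e[g$arom[atoms]] <- tolower(e[g$arom[atoms]])
    paste(e, collapse = "")
  } else s
}
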