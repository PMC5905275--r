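# Shared fixtures (memoised; everything is generated in code) and the
# independent oracles the operation tests compare against. Oracles are
# deliberately naive: element-wise loops and textbook formulas, no shared
# code with the package internals.

.fixtureCache <- new.env(parent = emptyenv())

fixtureOnce <- function(name, expr) {
  if (!exists(name, envir = .fixtureCache))
    assign(name, force(expr), envir = .fixtureCache)
  get(name, envir = .fixtureCache)
}

# 2 x 20 molecules, strong motif signal
midFixture <- function() fixtureOnce("mid", suppressMessages(
  generateLabeledSet(fixtureSpec(nPerClass = 20, seed = 7))))

# 2 x 20, perfectly separable, lightly decorated
pureFixture <- function() fixtureOnce("pure", suppressMessages(
  generateLabeledSet(fixtureSpec(nPerClass = 20, motifPurity = 1,
                                 decorationDepth = 1, seed = 13))))

# small hand-labeled set of common molecules (labels arbitrary but fixed)
tinySet <- function() fixtureOnce("tiny", {
  smi <- c("CCO", "CCCO", "CC(=O)O", "CCN", "c1ccccc1",
           "c1ccncc1", "CCOC", "CC(C)O", "CCS", "CCCC")
  lab <- rep(c("sweet", "bitter"), each = 5)
  suppressMessages(standardizeMolecules(
    moleculeSet(paste0("t", 1:10), smi, lab)))
})

# --- metric oracles ---------------------------------------------------------

bruteConfusion <- function(labels, predictions, positive) {
  tp <- tn <- fp <- fn <- 0L
  for (k in seq_along(labels)) {
    if (labels[k] == positive && predictions[k] == positive) tp <- tp + 1L
    else if (labels[k] != positive && predictions[k] != positive) tn <- tn + 1L
    else if (labels[k] != positive && predictions[k] == positive) fp <- fp + 1L
    else fn <- fn + 1L
  }
  list(tp = tp, tn = tn, fp = fp, fn = fn)
}

brutePanel <- function(tp, tn, fp, fn) {
  n <- tp + tn + fp + fn
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  sens <- div(tp, tp + fn); spec <- div(tn, tn + fp); prec <- div(tp, tp + fp)
  po <- (tp + tn) / n
  pe <- ((tp + fp) / n) * ((tp + fn) / n) + ((fn + tn) / n) * ((fp + tn) / n)
  list(accuracy = po, sensitivity = sens, specificity = spec,
       precision = prec,
       f_measure = if (is.na(prec) || is.na(sens) || prec + sens == 0)
         NA_real_ else 2 * prec * sens / (prec + sens),
       ner = mean(c(sens, spec)),
       cohens_kappa = if (pe == 1) NA_real_ else (po - pe) / (1 - pe))
}

# trapezoidal area under the empirical ROC curve (tie-grouped thresholds)
aucTrapezoid <- function(labels, scores, positive = "sweet") {
  ord <- order(scores, decreasing = TRUE)
  isPos <- labels[ord] == positive
  s <- scores[ord]
  nP <- sum(isPos); nN <- sum(!isPos)
  last <- which(!duplicated(s, fromLast = TRUE))   # end of each tie group
  tpr <- c(0, cumsum(isPos)[last] / nP)
  fpr <- c(0, cumsum(!isPos)[last] / nN)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# --- feature-analysis oracles -----------------------------------------------

naiveFrequencies <- function(m, labels) {
  nb <- ncol(m)
  fs <- fb <- numeric(nb)
  for (j in seq_len(nb)) {
    cs <- cb <- 0L; ns <- nb2 <- 0L
    for (i in seq_len(nrow(m))) {
      if (labels[i] == "sweet") { ns <- ns + 1L; if (m[i, j]) cs <- cs + 1L }
      else { nb2 <- nb2 + 1L; if (m[i, j]) cb <- cb + 1L }
    }
    fs[j] <- cs / ns; fb[j] <- cb / nb2
  }
  list(freq_sweet = fs, freq_bitter = fb,
       mean_sweet = mean(fs), mean_bitter = mean(fb))
}

naiveActive <- function(fs, fb, ms, mb) {
  out <- character(length(fs))
  for (j in seq_along(fs)) {
    sw <- fs[j] > ms && fb[j] < mb
    bt <- fb[j] > mb && fs[j] < ms
    out[j] <- if (sw && bt) "both" else if (sw) "sweet" else if (bt) "bitter"
              else "none"
  }
  out
}

naiveBayes <- function(m, labels) {
  nb <- ncol(m)
  ps <- pb <- rep(NA_real_, nb)
  for (j in seq_len(nb)) {
    ns <- sum(m[labels == "sweet", j]); nall <- sum(m[, j])
    if (nall > 0) { ps[j] <- ns / nall; pb[j] <- (nall - ns) / nall }
  }
  list(p_sweet = ps, p_bitter = pb)
}

randomBitFingerprint <- function(kind = "morgan", density = 40) {
  nb <- if (kind %in% c("morgan", "morgan_feat")) 2048L else 1024L
  new("BitFingerprint", kind = kind, nBits = nb,
      onBits = sort(sample.int(nb, density) - 1L))
}

# TRUE when at least one of the class's top-k active bits maps back (via
# bitToSubstructure) to an atom environment anchored in a planted motif:
# the environment's central atom is a motif atom. (Top discriminative bits
# legitimately include the motif's attachment context, so full containment
# of the environment in the motif is only required of radius-0/1 interior
# bits, tested separately.)
motifTraceable <- function(ms, m, scores, cls, k = 10) {
  top <- topFeatures(scores, cls, k)
  idx <- which(tasteLabels(ms) == cls &
               vapply(motifAtoms(ms), function(a) !is.null(a[[cls]]),
                      logical(1)))
  for (b in top$bit) {
    for (i in idx) {
      if (!m[i, b + 1]) next
      sub <- suppressWarnings(bitToSubstructure(ms[i], b, "morgan"))
      if (any(sub$atom %in% motifAtoms(ms)[[i]][[cls]])) return(TRUE)
    }
  }
  FALSE
}

# hand-built SDF text: n simple molecules, controllable title lines
makeSDFText <- function(smiles, titles) {
  blocks <- vapply(seq_along(smiles), function(i) {
    txt <- ChemmineOB::convertFormat("SMI", "SDF", paste0(smiles[i], "\n"))
    lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
    lines[1] <- titles[i]
    paste(lines, collapse = "\n")
  }, character(1))
  paste(blocks, collapse = "\n")
}
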