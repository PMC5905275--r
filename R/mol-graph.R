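# Internal molecule-graph layer.
#
# All structure handling goes through OpenBabel (via ChemmineOB/ChemmineR)
# for parsing, canonical SMILES and InChIKey. Fingerprinting needs a heavy-atom
# graph with implicit-hydrogen counts and aromaticity flags; OpenBabel writes
# Kekule bond orders into MDL blocks, so aromatic perception is re-done here
# (Huckel count on small rings) to make descriptors independent of the Kekule
# form a SMILES happened to be written in.

.obConvert <- function(from, to, text) {
  out <- tryCatch(ChemmineOB::convertFormat(from, to, text),
                  error = function(e) "")
  out
}

# canonical SMILES of one SMILES string; NA if unparsable
.canonicalSmiles <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_character_)
    out <- .obConvert("SMI", "CAN", paste0(s, "\n"))
    line <- sub("[ \t].*$", "", strsplit(out, "\n", fixed = TRUE)[[1]][1])
    line <- trimws(line)
    if (!nzchar(line)) NA_character_ else line
  }, character(1), USE.NAMES = FALSE)
}

.inchikey <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_character_)
    out <- .obConvert("SMI", "INCHIKEY", paste0(s, "\n"))
    line <- trimws(strsplit(out, "\n", fixed = TRUE)[[1]][1])
    if (is.na(line) || !grepl(.INCHIKEY_RE, line)) NA_character_ else line
  }, character(1), USE.NAMES = FALSE)
}

# MDL old-style charge codes <-> formal charge
.CHG_FROM_CODE <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                    `5` = -1L, `6` = -2L, `7` = -3L)
.codeFromCharge <- function(q) {
  code <- c(`3` = 1L, `2` = 2L, `1` = 3L, `0` = 0L, `-1` = 5L, `-2` = 6L,
            `-3` = 7L)
  unname(code[as.character(q)])
}

.DEFAULT_VALENCE <- c(B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3,
                      S = 2, Cl = 1, Br = 1, I = 1, As = 3, Se = 2)
.ATOMIC_NUMBER <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14,
                    P = 15, S = 16, Cl = 17, Br = 35, I = 53, As = 33,
                    Se = 34, Na = 11, K = 19, Li = 3, Ca = 20, Mg = 12)

.implicitH <- function(elem, charge, bondSum) {
  mapply(function(e, q, bs) {
    if (e == "C") {
      v <- 4 - abs(q)
    } else if (e == "S") {
      allowed <- c(2, 4, 6) + q
      ok <- allowed[allowed >= bs]
      v <- if (length(ok)) min(ok) else bs
    } else if (e == "P") {
      allowed <- c(3, 5) + q
      ok <- allowed[allowed >= bs]
      v <- if (length(ok)) min(ok) else bs
    } else if (e %in% names(.DEFAULT_VALENCE)) {
      v <- .DEFAULT_VALENCE[[e]] + q
    } else {
      v <- bs   # metals etc.: no implicit hydrogens
    }
    max(0L, as.integer(round(v - bs)))
  }, elem, charge, bondSum, USE.NAMES = FALSE)
}

# enumerate simple cycles of length 3..maxLen (vertex vectors), deduplicated
.simpleCycles <- function(n, bonds, maxLen = 7L) {
  if (nrow(bonds) == 0L || n < 3L) return(list())
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    a <- bonds$a[k]; b <- bonds$b[k]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  cycles <- list()
  extend <- function(path) {
    v <- path[length(path)]
    for (w in adj[[v]]) {
      if (w == path[1L] && length(path) >= 3L) {
        if (path[2L] < path[length(path)])   # one direction only
          cycles[[length(cycles) + 1L]] <<- path
      } else if (w > path[1L] && !(w %in% path) && length(path) < maxLen) {
        extend(c(path, w))
      }
    }
  }
  for (start in seq_len(n)) if (length(adj[[start]]) >= 2L) extend(start)
  cycles
}

# Huckel-style aromatic perception; returns list(atomArom, bondArom)
.perceiveAromatic <- function(elem, charge, hcount, degree, bonds, cycles) {
  nB <- nrow(bonds)
  atomArom <- rep(FALSE, length(elem))
  bondArom <- rep(FALSE, nB)
  if (!length(cycles)) return(list(atom = atomArom, bond = bondArom))
  bkey <- paste(pmin(bonds$a, bonds$b), pmax(bonds$a, bonds$b))
  bidx <- stats::setNames(seq_len(nB), bkey)
  # Iterate to a fixpoint: in fused systems a ring atom's Kekule double bond
  # may lie in the neighboring ring, so it only counts one pi electron here
  # once that neighbor has been recognized as aromatic.
  repeat {
    changed <- FALSE
    for (cy in cycles) {
      if (all(atomArom[cy])) next
      ok <- TRUE; pis <- 0L
      for (v in cy) {
        e <- elem[v]
        if (!e %in% c("C", "N", "O", "S", "Se", "P", "B")) { ok <- FALSE; break }
        inc <- which(bonds$a == v | bonds$b == v)
        if (any(bonds$order[inc] >= 3L)) { ok <- FALSE; break }
        if (e %in% c("O", "S", "Se") && (degree[v] + hcount[v]) > 2L) { ok <- FALSE; break }
        if (e %in% c("C", "N", "B", "P") && (degree[v] + hcount[v]) > 3L) { ok <- FALSE; break }
        dbl <- inc[bonds$order[inc] == 2L]
        if (length(dbl)) {
          partners <- ifelse(bonds$a[dbl] == v, bonds$b[dbl], bonds$a[dbl])
          if (any(partners %in% cy) || any(atomArom[partners])) {
            pis <- pis + 1L
          } else if (e == "C") {
            pis <- pis + 0L         # exocyclic C=X keeps sp2 carbon, no pi in ring
          } else { ok <- FALSE; break }
        } else {
          if (e == "C") {
            if (charge[v] == -1L) pis <- pis + 2L
            else if (charge[v] == 1L) pis <- pis + 0L
            else { ok <- FALSE; break }
          } else if (e == "B") {
            pis <- pis + 0L
          } else {
            pis <- pis + 2L         # heteroatom lone pair
          }
        }
      }
      if (ok && pis %% 4L == 2L) {
        changed <- changed || !all(atomArom[cy])
        atomArom[cy] <- TRUE
        m <- length(cy)
        for (k in seq_len(m)) {
          a <- cy[k]; b <- cy[if (k == m) 1L else k + 1L]
          bondArom[bidx[[paste(min(a, b), max(a, b))]]] <- TRUE
        }
      }
    }
    if (!changed) break
  }
  list(atom = atomArom, bond = bondArom)
}

# single heavy atom (zero bonds), e.g. "C", "Cl", "[Na+]", "[NH4+]":
# handled directly because MDL blocks without bonds do not round-trip
.SINGLE_ATOM_RE <- "^(\\[)?([A-Z][a-z]?)(H([0-9]*))?([+-][0-9]*|\\+\\+|--)?(\\])?$"

.singleAtomGraph <- function(smiles) {
  m <- regmatches(smiles, regexec(.SINGLE_ATOM_RE, smiles))[[1]]
  elem <- m[3]
  chgTok <- m[6]
  charge <- if (!nzchar(chgTok)) 0L
            else if (chgTok == "+") 1L else if (chgTok == "-") -1L
            else if (chgTok == "++") 2L else if (chgTok == "--") -2L
            else as.integer(paste0(substr(chgTok, 1, 1),
                                   substring(chgTok, 2)))
  hcount <- if (nzchar(m[4])) {
    if (nzchar(m[5])) as.integer(m[5]) else 1L
  } else if (nzchar(m[2])) 0L else .implicitH(elem, charge, 0)
  z <- unname(.ATOMIC_NUMBER[elem]); if (is.na(z)) z <- 0
  list(n = 1L, elem = elem, z = as.integer(z), charge = as.integer(charge),
       hcount = as.integer(hcount), degree = 0L, nPi = 0L,
       inRing = FALSE, arom = FALSE,
       bonds = data.frame(a = integer(), b = integer(), order = integer(),
                          arom = logical()))
}

# Parse SMILES strings into heavy-atom graphs.
# Returns a list of graphs; each graph is a list with fields:
#   n, elem, z, charge, hcount, degree, nPi, inRing, arom,
#   bonds (data.frame a, b, order, arom)
.molGraphs <- function(smiles) {
  stopifnot(length(smiles) >= 1L)
  single <- grepl(.SINGLE_ATOM_RE, smiles)
  out <- vector("list", length(smiles))
  for (i in which(single)) out[[i]] <- .singleAtomGraph(smiles[i])
  multi <- which(!single)
  if (length(multi)) {
    batch <- smiles[multi]
    names(batch) <- paste0("m", seq_along(batch))
    sdfset <- suppressWarnings(ChemmineR::smiles2sdf(batch))
    for (k in seq_along(multi))
      out[[multi[k]]] <- .graphFromSDF(sdfset[[k]])
  }
  out
}

.molGraph <- function(smiles) .molGraphs(smiles)[[1]]

.graphFromSDF <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elem <- sub("_.*$", "", rownames(ab))
  n <- length(elem)
  charge <- rep(0L, n)
  if ("C6" %in% colnames(ab)) {
    code <- as.character(as.integer(ab[, "C6"]))
    charge <- unname(.CHG_FROM_CODE[code])
    charge[is.na(charge)] <- 0L
  }
  if (n == 0L) stop("empty molecule")
  if (is.null(dim(bb))) bb <- matrix(bb, nrow = as.integer(length(bb) > 0))
  if (ncol(bb) < 3L) bb <- matrix(numeric(0), nrow = 0, ncol = 3)
  if (nrow(bb)) {
    bonds <- data.frame(a = as.integer(bb[, 1]), b = as.integer(bb[, 2]),
                        order = as.integer(bb[, 3]))
  } else {
    bonds <- data.frame(a = integer(), b = integer(), order = integer())
  }
  # fold explicit hydrogens into neighbor H counts, drop them from the graph
  explicitH <- rep(0L, n)
  if (any(elem == "H")) {
    hIdx <- which(elem == "H")
    for (k in seq_len(nrow(bonds))) {
      if (bonds$a[k] %in% hIdx && !(bonds$b[k] %in% hIdx))
        explicitH[bonds$b[k]] <- explicitH[bonds$b[k]] + 1L
      if (bonds$b[k] %in% hIdx && !(bonds$a[k] %in% hIdx))
        explicitH[bonds$a[k]] <- explicitH[bonds$a[k]] + 1L
    }
    keep <- setdiff(seq_len(n), hIdx)
    remap <- match(seq_len(n), keep)
    bonds <- bonds[!(bonds$a %in% hIdx) & !(bonds$b %in% hIdx), , drop = FALSE]
    bonds$a <- remap[bonds$a]; bonds$b <- remap[bonds$b]
    elem <- elem[keep]; charge <- charge[keep]; explicitH <- explicitH[keep]
    n <- length(keep)
  }
  degree <- tabulate(c(bonds$a, bonds$b), nbins = n)
  bondSum <- rep(0, n)
  for (k in seq_len(nrow(bonds))) {
    bondSum[bonds$a[k]] <- bondSum[bonds$a[k]] + bonds$order[k]
    bondSum[bonds$b[k]] <- bondSum[bonds$b[k]] + bonds$order[k]
  }
  hcount <- .implicitH(elem, charge, bondSum + explicitH) + explicitH
  cycles <- .simpleCycles(n, bonds)
  arom <- .perceiveAromatic(elem, charge, hcount, degree, bonds, cycles)
  bonds$arom <- arom$bond
  nPi <- rep(0L, n)
  inRing <- rep(FALSE, n)
  for (cy in cycles) inRing[cy] <- TRUE
  if (nrow(bonds)) {
    multi <- which(bonds$order >= 2L | bonds$arom)
    for (k in multi) {
      nPi[bonds$a[k]] <- nPi[bonds$a[k]] + 1L
      nPi[bonds$b[k]] <- nPi[bonds$b[k]] + 1L
    }
  }
  z <- unname(.ATOMIC_NUMBER[elem])
  z[is.na(z)] <- 0
  list(n = n, elem = elem, z = as.integer(z), charge = charge,
       hcount = as.integer(hcount), degree = as.integer(degree),
       nPi = nPi, inRing = inRing, arom = arom$atom, bonds = bonds)
}

# Write a graph back to an MDL molblock (V2000). Aromatic bonds can be
# emitted as order 4 (OpenBabel re-perceives them), used for substructure
# rendering; otherwise Kekule orders are kept.
.graphToSDF <- function(g, aromaticAsFour = FALSE, title = "mol") {
  n <- g$n; nb <- nrow(g$bonds)
  lines <- c(title, "  tasteRF", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
  for (i in seq_len(n)) {
    lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                              0, 0, 0, g$elem[i]))
  }
  for (k in seq_len(nb)) {
    o <- g$bonds$order[k]
    if (aromaticAsFour && g$bonds$arom[k]) o <- 4L
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0",
                              g$bonds$a[k], g$bonds$b[k], o))
  }
  chg <- which(g$charge != 0L)
  if (length(chg)) {
    for (grp in split(chg, ceiling(seq_along(chg) / 8))) {
      lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(grp)),
                               paste0(sprintf("%4d%4d", grp, g$charge[grp]),
                                      collapse = "")))
    }
  }
  paste(c(lines, "M  END", "$$$$", ""), collapse = "\n")
}

# canonical SMILES for a graph (via molblock -> OpenBabel)
.graphToSmiles <- function(g, aromaticAsFour = FALSE) {
  out <- .obConvert("SDF", "CAN", .graphToSDF(g, aromaticAsFour))
  line <- sub("[ \t].*$", "", strsplit(out, "\n", fixed = TRUE)[[1]][1])
  line <- trimws(line)
  if (!nzchar(line)) NA_character_ else line
}

.heavyAtomCount <- function(g) sum(g$elem != "H")

# match a motif graph into a molecule graph (exact element + formal charge on
# atoms, bond order with aromatic bonds pooled); first match returned as atom
# indices of `g`, or NULL. igraph's vf2 maps color1 to the *target* graph.
.matchMotif <- function(motif, g) {
  if (motif$n > g$n || nrow(motif$bonds) > nrow(g$bonds)) return(NULL)
  vcol <- function(gr) as.integer(gr$z * 16L + (gr$charge + 4L))
  ecol <- function(gr) as.integer(ifelse(gr$bonds$arom, 4L, gr$bonds$order))
  mkg <- function(gr) igraph::make_graph(edges = as.vector(t(as.matrix(
    gr$bonds[, c("a", "b")]))), n = gr$n, directed = FALSE)
  m <- tryCatch(igraph::subgraph_isomorphisms(
    mkg(motif), mkg(g), method = "vf2",
    vertex.color1 = vcol(g), vertex.color2 = vcol(motif),
    edge.color1 = ecol(g), edge.color2 = ecol(motif)),
    error = function(e) list())
  if (!length(m)) return(NULL)
  as.integer(m[[1]])
}
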