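# Hashed binary substructure fingerprints.
#
# Four kinds, all computed on the standardized heavy-atom graph with
# implicit-hydrogen counts and aromatic flags:
#   morgan      - circular environments, radius 0..2, element-based atom
#                 invariants, folded to 2048 bits (ECFP4-style)
#   morgan_feat - same circle growth with pharmacophoric (functional-class)
#                 atom invariants (FCFP-style), 2048 bits
#   atompair    - hashed (atom type, atom type, topological distance)
#                 triples, 1024 bits
#   torsion     - hashed linear 4-atom paths, 1024 bits
# Folding uses OR semantics (binary presence, not counts). Invariants depend
# only on the molecular graph, never on atom input order.

.HASH_MOD <- 2147483647    # 2^31 - 1; all arithmetic stays exact in doubles

.hashInts <- function(ints, seed = 17) {
  h <- seed
  for (v in ints) h <- (h * 31 + v + 1) %% .HASH_MOD
  h
}

.MORGAN_RADIUS <- 2L

# adjacency with bond codes (aromatic pooled as 4)
.adjacency <- function(g) {
  adj <- vector("list", g$n)
  if (nrow(g$bonds)) {
    code <- ifelse(g$bonds$arom, 4L, g$bonds$order)
    for (k in seq_len(nrow(g$bonds))) {
      a <- g$bonds$a[k]; b <- g$bonds$b[k]
      adj[[a]] <- rbind(adj[[a]], c(b, code[k]))
      adj[[b]] <- rbind(adj[[b]], c(a, code[k]))
    }
  }
  adj
}

# element-based initial invariants (ECFP-like)
.initialInvariants <- function(g) {
  vapply(seq_len(g$n), function(i) {
    .hashInts(c(g$z[i], g$degree[i], g$hcount[i], g$charge[i] + 8,
                as.integer(g$inRing[i]), as.integer(g$arom[i])), seed = 17)
  }, numeric(1))
}

# pharmacophoric initial invariants: donor, acceptor, aromatic, halogen,
# basic, acidic (FCFP-like functional classes)
.featureInvariants <- function(g) {
  nbrsOf <- function(i) {
    k <- which(g$bonds$a == i | g$bonds$b == i)
    ifelse(g$bonds$a[k] == i, g$bonds$b[k], g$bonds$a[k])
  }
  hasDoubleO <- function(i) {
    k <- which((g$bonds$a == i | g$bonds$b == i) & g$bonds$order == 2L)
    any(g$elem[ifelse(g$bonds$a[k] == i, g$bonds$b[k], g$bonds$a[k])] == "O")
  }
  vapply(seq_len(g$n), function(i) {
    e <- g$elem[i]
    donor <- e %in% c("N", "O") && g$hcount[i] > 0L
    acceptor <- e %in% c("N", "O") && g$charge[i] <= 0L
    halogen <- e %in% c("F", "Cl", "Br", "I")
    nb <- nbrsOf(i)
    amideLike <- e == "N" && any(vapply(nb, function(j)
      g$elem[j] %in% c("C", "S") && hasDoubleO(j), logical(1)))
    basic <- e == "N" && !g$arom[i] && g$nPi[i] == 0L && !amideLike
    acidic <- e == "O" && g$hcount[i] > 0L && any(vapply(nb, function(j)
      g$elem[j] %in% c("C", "S", "P") && hasDoubleO(j), logical(1)))
    .hashInts(c(donor, acceptor, g$arom[i], halogen, basic, acidic), seed = 29)
  }, numeric(1))
}

# circular fingerprint; returns list(bits, env = data.frame(bit, atom, radius))
.fpCircular <- function(g, nBits, featInvariants = FALSE) {
  inv <- if (featInvariants) .featureInvariants(g) else .initialInvariants(g)
  adj <- .adjacency(g)
  bits <- integer(0); atomIdx <- integer(0); radii <- integer(0); codes <- numeric(0)
  record <- function(invs, r) {
    bits <<- c(bits, as.integer(invs %% nBits))
    atomIdx <<- c(atomIdx, seq_len(g$n))
    radii <<- c(radii, rep(r, g$n))
    codes <<- c(codes, invs)
  }
  record(inv, 0L)
  for (r in seq_len(.MORGAN_RADIUS)) {
    inv <- vapply(seq_len(g$n), function(i) {
      nb <- adj[[i]]
      if (is.null(nb)) return(.hashInts(c(inv[i]), seed = 3 + r))
      pairs <- cbind(nb[, 2], inv[nb[, 1]])
      pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
      .hashInts(c(inv[i], as.vector(t(pairs))), seed = 3 + r)
    }, numeric(1))
    record(inv, r)
  }
  list(bits = sort(unique(bits)),
       env = data.frame(bit = bits, atom = atomIdx, radius = radii,
                        code = codes))
}

# atom type used by atom-pair and torsion kinds
.pairAtomTypes <- function(g) {
  vapply(seq_len(g$n), function(i)
    .hashInts(c(g$z[i], min(g$degree[i], 7L), min(g$nPi[i], 3L)), seed = 41),
    numeric(1))
}

.fpAtomPair <- function(g, nBits) {
  if (g$n < 2L || nrow(g$bonds) == 0L) return(integer(0))
  t <- .pairAtomTypes(g)
  ig <- igraph::graph_from_edgelist(as.matrix(g$bonds[, c("a", "b")]),
                                    directed = FALSE)
  d <- igraph::distances(ig)
  bits <- integer(0)
  for (i in seq_len(g$n - 1L)) for (j in (i + 1L):g$n) {
    dij <- d[i, j]
    if (!is.finite(dij) || dij > 30) next
    code <- .hashInts(c(min(t[i], t[j]), max(t[i], t[j]), dij), seed = 53)
    bits <- c(bits, as.integer(code %% nBits))
  }
  sort(unique(bits))
}

.fpTorsion <- function(g, nBits) {
  if (g$n < 4L || nrow(g$bonds) < 3L) return(integer(0))
  t <- .pairAtomTypes(g)
  nbrs <- vector("list", g$n)
  for (k in seq_len(nrow(g$bonds))) {
    a <- g$bonds$a[k]; b <- g$bonds$b[k]
    nbrs[[a]] <- c(nbrs[[a]], b); nbrs[[b]] <- c(nbrs[[b]], a)
  }
  bits <- integer(0)
  for (k in seq_len(nrow(g$bonds))) {
    b <- g$bonds$a[k]; c_ <- g$bonds$b[k]
    for (a in setdiff(nbrs[[b]], c_)) for (d in setdiff(nbrs[[c_]], b)) {
      if (a == d) next
      fwd <- c(t[a], t[b], t[c_], t[d])
      rev <- base::rev(fwd)
      seq4 <- if (isTRUE(all(fwd == rev)) ||
                  .lexLess(fwd, rev)) fwd else rev
      code <- .hashInts(seq4, seed = 67)
      bits <- c(bits, as.integer(code %% nBits))
    }
  }
  sort(unique(bits))
}

.lexLess <- function(x, y) {
  for (i in seq_along(x)) {
    if (x[i] < y[i]) return(TRUE)
    if (x[i] > y[i]) return(FALSE)
  }
  FALSE
}

.fpFromGraph <- function(g, kind, withEnvironments = FALSE) {
  nBits <- .FP_NBITS[[kind]]
  env <- NULL
  on <- switch(kind,
    morgan = {
      r <- .fpCircular(g, nBits, featInvariants = FALSE)
      env <- r$env; r$bits
    },
    morgan_feat = {
      r <- .fpCircular(g, nBits, featInvariants = TRUE)
      env <- r$env; r$bits
    },
    atompair = .fpAtomPair(g, nBits),
    torsion = .fpTorsion(g, nBits),
    stop("unknown fingerprint kind: ", kind))
  fp <- new("BitFingerprint", kind = kind, nBits = nBits,
            onBits = as.integer(on))
  if (withEnvironments && !is.null(env)) attr(fp, "environments") <- env
  fp
}

#' Compute a binary substructure fingerprint
#'
#' @param x a standardized single-record [MoleculeSet-class], or one SMILES
#'   string (taken as already standardized).
#' @param kind `"morgan"` (2048 bits), `"morgan_feat"` (2048),
#'   `"atompair"` (1024) or `"torsion"` (1024).
#' @param withEnvironments for the circular kinds, keep the per-atom
#'   environment-to-bit map (used by [bitToSubstructure()]).
#' @return A [BitFingerprint-class].
#' @examples
#' fp <- computeFingerprint("CCO", "morgan")
#' @export
computeFingerprint <- function(x, kind = .FP_KINDS, withEnvironments = FALSE) {
  kind <- match.arg(kind)
  smi <- .oneStdSmiles(x)
  .fpFromGraph(.molGraph(smi), kind, withEnvironments)
}

.oneStdSmiles <- function(x) {
  if (is(x, "MoleculeSet")) {
    if (length(x) != 1L) stop("expected a single-record MoleculeSet")
    if (!isStandardized(x)) stop("record must be standardized first")
    return(stdSmiles(x))
  }
  if (is.character(x) && length(x) == 1L) return(x)
  stop("x must be a single SMILES or a single-record MoleculeSet")
}

#' Fingerprint matrix for a molecule set
#'
#' @param mset a standardized [MoleculeSet-class] (or character vector of
#'   standardized SMILES).
#' @param kind fingerprint kind.
#' @return Logical matrix, rows = molecules (named by id), columns = bits
#'   (`bit0 ... bit{n-1}`); entry `[i, j]` is `TRUE` iff bit `j - 1` is on.
#' @export
fingerprintMatrix <- function(mset, kind = .FP_KINDS) {
  kind <- match.arg(kind)
  if (is(mset, "MoleculeSet")) {
    if (length(mset) == 0L) stop("empty molecule set")
    if (!all(isStandardized(mset))) stop("all records must be standardized")
    smi <- stdSmiles(mset); ids <- molIds(mset)
  } else {
    if (!length(mset)) stop("empty molecule set")
    smi <- as.character(mset); ids <- paste0("mol_", seq_along(smi))
  }
  nBits <- .FP_NBITS[[kind]]
  gs <- .molGraphs(smi)
  m <- matrix(FALSE, nrow = length(smi), ncol = nBits,
              dimnames = list(ids, paste0("bit", seq_len(nBits) - 1L)))
  for (i in seq_along(gs)) {
    fp <- .fpFromGraph(gs[[i]], kind)
    m[i, fp@onBits + 1L] <- TRUE
  }
  attr(m, "kind") <- kind
  m
}

#' Tanimoto similarity of two fingerprints
#'
#' `|A intersect B| / |A union B|` over the on-bit sets; defined as 1 when
#' both fingerprints are empty.
#'
#' @param a,b [BitFingerprint-class] objects of the same kind and size.
#' @return Similarity in `[0, 1]`.
#' @examples
#' tanimoto(computeFingerprint("CCO"), computeFingerprint("CCO"))  # 1
#' @export
tanimoto <- function(a, b) {
  stopifnot(is(a, "BitFingerprint"), is(b, "BitFingerprint"))
  if (a@kind != b@kind || a@nBits != b@nBits)
    stop("fingerprints have mismatched kind or size")
  u <- length(union(a@onBits, b@onBits))
  if (u == 0L) return(1)
  length(intersect(a@onBits, b@onBits)) / u
}

#' Write a fingerprint matrix as CSV (id + one 0/1 column per bit)
#'
#' @param m matrix from [fingerprintMatrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeFingerprintCSV <- function(m, path) {
  df <- data.frame(id = rownames(m), 1L * m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
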