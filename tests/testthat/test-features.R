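# small deterministic matrix: 4 sweet rows then 4 bitter rows, 6 bits
.featDemo <- function() {
  m <- matrix(FALSE, 8, 6, dimnames = list(NULL, paste0("bit", 0:5)))
  m[1:4, 1] <- TRUE                       # bit0: all sweet, no bitter
  m[1:3, 2] <- TRUE                       # bit1: 3/4 sweet
  m[c(1, 5), 3] <- TRUE                   # bit2: 1 sweet + 1 bitter
  m[5:8, 4] <- TRUE                       # bit3: all bitter
  # bit4: nowhere; bit5: everywhere
  m[, 6] <- TRUE
  list(m = m, labels = rep(c("sweet", "bitter"), each = 4))
}

test_that("relative frequencies count class fractions per bit", {
  d <- .featDemo()
  rf <- relativeFrequencies(d$m, d$labels)
  expect_equal(rf$freq_sweet[1], 1); expect_equal(rf$freq_bitter[1], 0)
  expect_equal(rf$freq_sweet[2], 0.75)
  expect_equal(rf$freq_sweet[5], 0); expect_equal(rf$freq_bitter[5], 0)
  cm <- attr(rf, "classMeans")
  expect_equal(unname(cm["sweet"]), mean(rf$freq_sweet))
  expect_error(relativeFrequencies(d$m, rep("sweet", 8)), "both classes")
})

test_that("active-feature rule is strict on both sides", {
  scores <- data.frame(bit = 0:2,
                       freq_sweet = c(0.6, 0.1, 0.05),
                       freq_bitter = c(0.02, 0.1, 0.3))
  out <- activeFeatures(scores, c(sweet = 0.1, bitter = 0.1))
  expect_equal(out$active_for, c("sweet", "none", "bitter"))
  # boundary equality (freq == mean) is inactive
  eq <- activeFeatures(data.frame(bit = 0, freq_sweet = 0.1,
                                  freq_bitter = 0.05),
                       c(sweet = 0.1, bitter = 0.1))
  expect_equal(eq$active_for, "none")
  expect_error(activeFeatures(scores[, 1:3], NULL), "missing")
})

test_that("frequencies, active rule and Bayes scores match naive loops", {
  set.seed(21)
  for (k in 1:10) {
    m <- matrix(runif(100 * 64) < runif(1, 0.05, 0.4), 100, 64)
    labels <- sample(c("sweet", "bitter"), 100, replace = TRUE)
    if (length(unique(labels)) < 2) next
    o <- naiveFrequencies(m, labels)
    rf <- relativeFrequencies(m, labels)
    expect_equal(rf$freq_sweet, o$freq_sweet)
    expect_equal(rf$freq_bitter, o$freq_bitter)
    af <- activeFeatures(rf)
    expect_identical(af$active_for,
                     naiveActive(o$freq_sweet, o$freq_bitter,
                                 o$mean_sweet, o$mean_bitter))
    bs <- bayesFeatureScores(m, labels)
    ob <- naiveBayes(m, labels)
    expect_equal(bs$p_sweet_given_f, ob$p_sweet)
    expect_equal(bs$p_bitter_given_f, ob$p_bitter)
  }
})

test_that("Bayes scores are pure ratios that sum to one where defined", {
  d <- .featDemo()
  bs <- bayesFeatureScores(d$m, d$labels)
  expect_equal(bs$p_sweet_given_f[3], 0.5)
  expect_equal(bs$p_bitter_given_f[4], 1)
  expect_true(is.na(bs$p_sweet_given_f[5]))   # bit occurs nowhere
  occ <- !is.na(bs$p_sweet_given_f)
  expect_equal(bs$p_sweet_given_f[occ] + bs$p_bitter_given_f[occ],
               rep(1, sum(occ)))
  # Laplace smoothing is optional and off by default
  sm <- bayesFeatureScores(d$m, d$labels, smoothing = 1)
  expect_equal(sm$p_sweet_given_f[1], 5 / 6)
  expect_false(anyNA(sm$p_sweet_given_f))
})

test_that("top features rank by own-class frequency with index tie-breaks", {
  scores <- data.frame(bit = c(3L, 0L, 7L, 5L, 9L),
                       freq_sweet = c(0.5, 0.8, 0.5, 0.2, 0.1),
                       freq_bitter = c(0, 0, 0, 0, 0.5),
                       active_for = c("sweet", "sweet", "sweet", "sweet",
                                      "bitter"))
  top <- topFeatures(scores, "sweet", 3)
  expect_equal(top$bit, c(0L, 3L, 7L))      # tie 0.5/0.5 -> lower index first
  expect_true(all(diff(top$freq_sweet) <= 0))
  expect_warning(all4 <- topFeatures(scores, "sweet", 10), "returning all")
  expect_equal(nrow(all4), 4L)
  expect_equal(nrow(topFeatures(scores, "bitter", 1)), 1L)
})

test_that("feature dissimilarity is 1 - Pearson correlation", {
  expect_equal(featureDissimilarity(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(featureDissimilarity(c(1, 2, 3), c(3, 2, 1)), 2)
  expect_equal(featureDissimilarity(c(1, 2, 3), c(1, 2, 4)),
               1 - 1.5 * sqrt(3 / 7))      # hand-computed Pearson r
  expect_error(featureDissimilarity(c(1, 1, 1), c(1, 2, 3)), "zero-variance")
  expect_error(featureDissimilarity(1, 2), "length")
})

test_that("per-class bit frequencies sum to the mean on-bit count", {
  ms <- midFixture()
  m <- fingerprintMatrix(ms, "morgan")
  lab <- tasteLabels(ms)
  rf <- relativeFrequencies(m, lab)
  for (cls in c("sweet", "bitter")) {
    expect_equal(sum(rf[[paste0("freq_", cls)]]),
                 mean(rowSums(m[lab == cls, ])))
  }
})

test_that("bits map back to atom environments as substructure strings", {
  std <- stdSmiles(standardizeMolecules(moleculeSet("e", "CCO")))
  fp <- computeFingerprint(std, "morgan", withEnvironments = TRUE)
  env <- attr(fp, "environments")
  bit0 <- env$bit[env$radius == 0][1]
  sub <- bitToSubstructure(std, bit0, "morgan")
  expect_true(all(c("bit", "atom", "radius", "substructure") %in%
                  colnames(sub)))
  r0 <- sub[sub$radius == 0, ][1, ]
  expect_length(r0$atoms[[1]], 1L)          # radius-0 environment: one atom
  expect_match(r0$substructure, "^\\[?[A-Za-z]+\\]?$")
  offBit <- setdiff(0:2047, fp@onBits)[1]
  expect_error(bitToSubstructure(std, offBit, "morgan"), "not set")
  expect_error(bitToSubstructure(std, bit0, "torsion"))
})

test_that("planted motifs surface in the top active features", {
  ms <- pureFixture()
  m <- fingerprintMatrix(ms, "morgan")
  fr <- activeFeatures(relativeFrequencies(m, tasteLabels(ms)))
  for (cls in c("sweet", "bitter")) {
    top <- topFeatures(fr, cls, 10)
    idx <- which(tasteLabels(ms) == cls &
                 vapply(motifAtoms(ms),
                        function(a) !is.null(a[[cls]]), logical(1)))
    traceable <- FALSE
    for (b in top$bit) {
      for (i in idx) {
        if (!m[i, b + 1]) next
        sub <- bitToSubstructure(ms[i], b, "morgan")
        ok <- vapply(sub$atoms, function(at)
          all(at %in% motifAtoms(ms)[[i]][[cls]]), logical(1))
        if (any(ok)) { traceable <- TRUE; break }
      }
      if (traceable) break
    }
    expect_true(traceable, label = paste("motif recovery for", cls))
  }
})
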