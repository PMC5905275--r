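---
title: "Classifying sweet and bitter molecules with fingerprint Random Forests"
author: "tasteRF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying sweet and bitter molecules with fingerprint Random Forests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Whether a small molecule tastes sweet or bitter is a classic
structure–activity question: both taste qualities occur across most chemical
classes, single functional-group changes can flip the balance between them,
and human tasting panels are slow, expensive and ethically constrained for
novel chemistry. `tasteRF` implements a binary structure-based classifier
for this problem: molecules are encoded as hashed binary substructure
fingerprints and a Random Forest votes sweet versus bitter, returning a
continuous confidence score in $[0,1]$ that downstream screening can
threshold.

The package covers the full workflow: structure standardization and
InChIKey deduplication, four fingerprint encodings, stratified splitting and
cross-validated model evaluation with a complete metric panel,
class-conditional feature-discrimination analysis with substructure
back-mapping, Tanimoto applicability-domain assessment, and
confidence-thresholded batch screening. A seeded synthetic-molecule
generator makes every stage testable end to end without any external
database.

## Standardization and deduplication

`standardizeMolecules()` applies, in order:

1. **Water removal and fragment selection.** Water fragments are dropped;
   if several fragments remain (salts, counter-ions, mixtures), the largest
   organic fragment is kept. Fingerprints of multi-component structures mix
   unrelated substructures, so this is standard QSAR hygiene even though
   only the water rule is strictly required for taste data.
2. **Aromatic perception.** Aromaticity is re-perceived on the molecular
   graph with a Hückel-style electron count over rings of size 3–7,
   iterated to a fixpoint so that fused systems (naphthalene, quinoline)
   are recognized regardless of which Kekulé form a SMILES happened to use.
   This makes all downstream descriptors Kekulé-invariant.
3. **Charge-pair neutralization.** Adjacent opposite formal charges are
   converted into an incremented bond order, but only when the resulting
   valences are chemically legal; a nitro group written in charged form is
   left untouched (with a warning) because nitrogen would become
   pentavalent. Non-adjacent zwitterions (amino acids) pass through
   unchanged.
4. **Canonical form.** The standardized structure is stored as canonical
   SMILES and its InChIKey is computed (both via OpenBabel). Hydrogens are
   tracked as per-atom counts on the heavy-atom graph rather than as
   explicit atoms: every descriptor in the package is defined on the
   heavy-atom graph with implicit-hydrogen counts.

Standardization is idempotent, and `deduplicateMolecules()` collapses
records by InChIKey. Records with the same InChIKey but conflicting taste
labels are removed entirely — an ambiguous training point teaches the model
nothing — and reported.

## Fingerprints

Four binary encodings, computed natively on the standardized heavy-atom
graph:

| kind          | bits | encodes                                              |
|---------------|------|------------------------------------------------------|
| `morgan`      | 2048 | circular atom environments, radius 0–2 (ECFP4-style) |
| `morgan_feat` | 2048 | same circles over pharmacophoric atom classes (FCFP-style) |
| `atompair`    | 1024 | atom-type pairs with topological distance            |
| `torsion`     | 1024 | linear 4-atom paths                                  |

Design choices that matter:

* **Morgan radius 2** (the ECFP4 community default), for both circular
  kinds. Initial atom invariants are element, heavy degree, hydrogen count,
  formal charge, ring membership and aromaticity; the pharmacophoric
  variant replaces these with donor/acceptor/aromatic/halogen/basic/acidic
  flags from simple structural rules.
* **Folding with OR semantics.** Environment codes are folded onto the
  declared bit length by modular hashing; fingerprints are presence/absence
  vectors, never counts.
* **Order invariance.** Invariants depend only on the molecular graph
  (neighbor multisets are sorted before hashing), so any SMILES of the same
  molecule yields identical bits; hydrogen counts are derived from a
  valence model and are themselves Kekulé-invariant.
* Aromatic bonds carry a single bond code distinct from single/double, so
  Kekulé alternation never leaks into a bit.

`tanimoto()` computes $|A\cap B| / |A\cup B|$ on on-bit sets (defined as 1
when both are empty), and `fingerprintMatrix()` builds the molecules × bits
design matrix.

## The classifier

`trainTasteForest()` grows a Random Forest — by default **1000 trees**,
**Gini** splits, and **√p attribute sampling** per split — on the
fingerprint matrix (engine: `ranger`, single-threaded and seeded, so every
artifact is reproducible bit for bit). The forest is a probability forest:
the confidence score is a *soft vote*, the mean of the trees' leaf class
frequencies, which yields a smooth score for thresholding at the screening
operating points (0.60 / 0.75 / 0.95). With fully grown classification
trees the soft vote and the raw vote fraction coincide almost everywhere;
the bundle records the voting rule. A score tie at exactly 0.5 is assigned
to bitter — the larger class in the motivating taste datasets —
deterministically.

`stratifiedSplit()` reserves `round(classSize × fraction)` molecules per
class (round-half-even, R's `round()`), so 517 sweet + 685 bitter at 0.2
gives 103 + 137 test molecules. `crossValidate()` produces out-of-sample
predictions either by leave-one-out (`method = "loo"`, one forest per
molecule — the reference mode for modest datasets) or by seeded stratified
k-fold (default `k = 10`), which is what we use at n ≥ a few hundred, where
LOO's n forest fits buy little: at the package's default study size
(600 molecules) 10-fold estimates are already stable and two orders of
magnitude cheaper. `compareFingerprints()` repeats the same
cross-validation per fingerprint kind and returns the metric panel sorted
by AUC; which kind wins is data-dependent, so the package makes the
comparison cheap instead of hard-coding a favourite.

## The evaluation panel

`metricsPanel()` reports, for a chosen positive class: accuracy,
sensitivity (= recall, TP/(TP+FN)), specificity, precision, F-measure, the
non-error rate (NER — the mean of sensitivity and specificity, i.e.
balanced accuracy) and Cohen's kappa
$\kappa = (p_o - p_e)/(1 - p_e)$ with $p_o$ the accuracy and $p_e$ the
chance agreement from the marginals. Ratios with zero denominators are
reported as `NA`, never coerced to 0. `rocAUC()` uses the rank
(Mann–Whitney) formula with ties counting ½, which equals trapezoidal
integration of the empirical ROC curve exactly; the test suite asserts this
identity to 1e-12 and checks the whole panel against an independent
brute-force recount. All rates are stored as fractions; percent formatting
is presentation, not data. `metricsTable()` reports both class
perspectives at once — the sweet-positive sensitivity is by definition the
bitter-positive specificity, a useful internal consistency check.

## Feature discrimination

For each fingerprint bit, `relativeFrequencies()` computes the fraction of
each class's molecules carrying it. A bit is **active** for a class
(`activeFeatures()`) when its frequency in that class is *strictly above*
that class's mean bit frequency **and** *strictly below* the other class's
mean — the boundary cases are inactive, reading "higher/lower than"
literally. `bayesFeatureScores()` gives the complementary view
$P(\text{class} \mid \text{bit})$ as a pure count ratio (bits carried by no
molecule are undefined, `NA`; optional Laplace smoothing is off by
default). `topFeatures()` ranks a class's active bits by own-class
frequency (ties to the lower bit index), and `featureDissimilarity()`
scores how independently two features behave as 1 − Pearson correlation of
their score vectors; the vectors' composition (class-frequency pairs,
per-molecule profiles) is deliberately the caller's choice, since more than
one convention is defensible.

`bitToSubstructure()` inverts the hashing for the circular kinds: every
atom environment of a molecule that folds to a given bit is returned with
its central atom, radius, atom set and a substructure string. Note that
folding is many-to-one — a bit can be set by unrelated environments — so
interpretation should always look at the returned environments, not just
the bit index.

## Applicability domain and screening

`adAssess()` reports, per query, the maximum Tanimoto similarity (on the
model's fingerprint) to any retained training molecule and the nearest
neighbor's identity. The default in-domain cutoff is **0.25** max-Tanimoto
— a permissive, commonly used choice; it is a reported parameter, not a
hard filter: out-of-domain compounds are still predicted but flagged,
because the screening workflow controls false calls through the confidence
threshold rather than by discarding queries. `screenLibrary()` and
`thresholdSweep()` summarize per-class counts of confident calls at
operating points (defaults 0.60, 0.75, 0.95); retained counts are
guaranteed non-increasing in the threshold, and below-threshold compounds
stay in the output with a flag.

## The synthetic generator

`generateLabeledSet()` emulates a two-class structure–taste dataset:
molecules are assembled from random small decoration groups, and
class-enriched substructure motifs are planted — by default a
sulfonamide fragment (`NS(=O)(=O)`, echoing saccharin-type sweeteners) for
the sweet class and quinoline (an alkaloid core) for the bitter class.
Defaults are 300 molecules per class and motif purity 0.9, the package's
reference study conditions: large enough for stable 10-fold estimates,
small enough that the whole pipeline runs in about a minute.

Two semantics decisions deserve a note:

* **Purity is symmetric.** A molecule of class *c* carries motif *c* with
  probability `motifPurity` and the *other* class's motif with probability
  `1 − motifPurity`. Purity 1 therefore separates the classes perfectly
  while purity 0.5 makes the two classes *exchangeable* — the correct null:
  had the cross-class rate been fixed at 0, a "0.5 purity" set would still
  be learnable at AUC ≈ 0.75.
* **Assembly order is class-independent** (sweet motif, then bitter motif,
  then decorations). The order determines attachment topology, and a
  class-dependent order leaks a detectable signal even when motif
  frequencies are perfectly symmetric — measurably so (null AUC ≈ 0.7
  instead of ≈ 0.5 in an early version of the generator).

Distinctness is enforced by InChIKey with bounded regeneration, and every
record carries provenance: planted flags plus the motif's atom indices on
the standardized structure (recovered by colored subgraph isomorphism), so
feature-recovery tests can assert that top-ranked bits map back to planted
chemistry. What the generator does *not* emulate: realistic taste
chemistry, property-matched decoys, tautomers, stereochemistry, or the
class imbalance and diversity of curated sweet/bitter databases. Passing
tests on these fixtures demonstrate that the machinery recovers a planted
signal and stays calibrated under a true null — not that any particular
accuracy will transfer to real compounds.

`generateConfusionCases()` is the metric-suite counterpart: random
label/prediction/score triples with independently counted ground-truth
confusion cells.

## Numerical and degenerate-input choices

* Hashing uses a polynomial accumulator modulo $2^{31}-1$, exact in double
  arithmetic and platform-independent.
* `tanimoto()` of two empty fingerprints is 1 (identical objects); the
  empty-vs-nonempty case is 0 naturally.
* Prediction ties (score exactly 0.5) go to bitter; `rocAUC()` ties count
  ½; `topFeatures()` ties break to the lower bit index — all
  deterministic.
* Single-atom molecules (e.g. bare ions after fragment stripping) are
  handled directly, since zero-bond structures do not round-trip through
  MDL blocks; they simply have no pair/torsion features.
* Undefined metric ratios are `NA`; undefined feature probabilities
  (bit nowhere present) are `NA` unless smoothing is requested.
* Cross-validation folds, bootstrap draws and fixture generation all flow
  from explicit integer seeds; nothing reads the global RNG state without
  setting it.

## Known limitations

* Aromatic perception covers simple and ortho-fused rings up to size 7; it
  does not attempt macrocyclic aromaticity (azulene's 10-perimeter,
  porphyrins) or charge-delocalized edge cases beyond cyclopentadienyl and
  tropylium.
* The pharmacophoric atom typing behind `morgan_feat` uses deliberately
  simple donor/acceptor/acid/base rules; it is a reasonable functional-class
  encoding, not a tuned pharmacophore model.
* Tautomer canonicalization, stereochemistry repair and 3D structure
  generation are out of scope; InChIKey deduplication already collapses
  most tautomer pairs.
* The model bundle stores the ensemble with R serialization; bundles are
  artifacts of a given package version, not an interchange format.
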