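# Random-Forest training, prediction, cross-validation and per-fingerprint
# comparison. The ensemble is a probability forest (Gini splits, sqrt
# attribute sampling), so confidence scores are soft votes: the mean of the
# trees' class-probability estimates. Ties at 0.5 are assigned to bitter
# (the larger training class) deterministically.

#' Stratified train/test split
#'
#' Per-class test counts equal `round(classSize * testFraction)`
#' (round-half-even); the union of the two parts is the input set.
#'
#' @param mset labeled [MoleculeSet-class] (every record sweet or bitter,
#'   at least 2 per class).
#' @param testFraction fraction in (0, 1), default 0.2.
#' @param seed integer seed; the same seed reproduces the same partition.
#' @return list with elements `train` and `test` (MoleculeSets).
#' @export
stratifiedSplit <- function(mset, testFraction = 0.2, seed = 1L) {
  stopifnot(testFraction > 0, testFraction < 1)
  lab <- tasteLabels(mset)
  if (!all(lab %in% .TASTE_CLASSES))
    stop("all records must be labeled sweet or bitter")
  testIdx <- integer(0)
  set.seed(as.integer(seed))
  for (cls in .TASTE_CLASSES) {
    idx <- which(lab == cls)
    if (length(idx) < 2L) stop("class '", cls, "' too small to split")
    nTest <- as.integer(round(length(idx) * testFraction))
    testIdx <- c(testIdx, sort(idx)[sample.int(length(idx), nTest)])
  }
  list(train = mset[setdiff(seq_along(lab), testIdx)],
       test = mset[sort(testIdx)])
}

.forestFromMatrix <- function(m, labels, config) {
  y <- factor(labels, levels = .TASTE_CLASSES)
  ranger::ranger(y = y, x = as.data.frame(m),
                 num.trees = config@nTrees,
                 mtry = floor(sqrt(ncol(m))),
                 splitrule = "gini",
                 probability = TRUE,
                 seed = config@seed,
                 num.threads = 1)
}

#' Train a Random-Forest taste classifier
#'
#' Grows `config@nTrees` trees, each on a bootstrap sample of the training
#' rows, with Gini splits and sqrt-of-features candidate attributes per
#' split. Training fingerprints are retained in the model for the
#' applicability domain. Deterministic given the config seed.
#'
#' @param mset labeled, standardized [MoleculeSet-class] (>= 2 per class).
#' @param config an [RFConfig-class].
#' @return A [TasteForest-class].
#' @export
trainTasteForest <- function(mset, config = rfConfig()) {
  lab <- tasteLabels(mset)
  if (!all(lab %in% .TASTE_CLASSES))
    stop("all records must be labeled sweet or bitter")
  if (length(unique(lab)) < 2L) stop("training data must contain both classes")
  m <- fingerprintMatrix(mset, config@fingerprint)
  new("TasteForest",
      forest = .forestFromMatrix(m, lab, config),
      config = config, classes = .TASTE_CLASSES,
      trainFP = m, trainIds = molIds(mset), trainLabels = lab,
      version = .BUNDLE_FORMAT)
}

.predictMatrix <- function(model, m, ids) {
  if (nrow(m) == 0L)
    return(data.frame(id = character(), predicted_class = character(),
                      confidence = numeric(), score_sweet = numeric(),
                      score_bitter = numeric()))
  p <- stats::predict(model@forest, data = as.data.frame(m),
                      num.threads = 1)$predictions
  sSweet <- p[, "sweet"]; sBitter <- p[, "bitter"]
  cls <- ifelse(sSweet > sBitter, "sweet", "bitter")   # tie -> bitter
  data.frame(id = ids, predicted_class = cls,
             confidence = pmax(sSweet, sBitter),
             score_sweet = sSweet, score_bitter = sBitter,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Predict taste classes with confidence scores
#'
#' Class scores are soft votes (mean of the trees' class-probability
#' estimates) and sum to 1; the confidence is the score of the predicted
#' class; ties at 0.5 go to bitter.
#'
#' @param model a [TasteForest-class].
#' @param mset standardized [MoleculeSet-class] (may be empty).
#' @return data.frame with `id`, `predicted_class`, `confidence`,
#'   `score_sweet`, `score_bitter`, in input row order.
#' @export
predictTaste <- function(model, mset) {
  if (length(mset) == 0L)
    return(.predictMatrix(model, matrix(nrow = 0, ncol = 0), character(0)))
  m <- fingerprintMatrix(mset, model@config@fingerprint)
  .predictMatrix(model, m, molIds(mset))
}

#' Cross-validated out-of-sample predictions
#'
#' `method = "loo"` trains one model per held-out molecule (the
#' paper-faithful leave-one-out mode); `method = "kfold"` uses seeded
#' stratified folds (default 10), the practical choice for larger sets.
#'
#' @param mset labeled, standardized [MoleculeSet-class].
#' @param config an [RFConfig-class]; its seed drives fold assignment and
#'   every forest.
#' @param method `"kfold"` or `"loo"`.
#' @param folds number of folds for `"kfold"`.
#' @return data.frame as [predictTaste()] plus a `label` column, one
#'   out-of-sample prediction per record, in input order.
#' @export
crossValidate <- function(mset, config = rfConfig(),
                          method = c("kfold", "loo"), folds = 10L) {
  method <- match.arg(method)
  lab <- tasteLabels(mset)
  if (!all(lab %in% .TASTE_CLASSES))
    stop("all records must be labeled sweet or bitter")
  if (min(table(factor(lab, .TASTE_CLASSES))) < 2L)
    stop("need at least 2 records per class")
  n <- length(mset)
  m <- fingerprintMatrix(mset, config@fingerprint)
  if (method == "loo") {
    foldOf <- seq_len(n)
  } else {
    folds <- min(as.integer(folds), n)
    foldOf <- integer(n)
    set.seed(config@seed)
    for (cls in .TASTE_CLASSES) {      # stratified assignment
      idx <- which(lab == cls)
      foldOf[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  }
  out <- vector("list", max(foldOf))
  for (f in sort(unique(foldOf))) {
    hold <- which(foldOf == f)
    trIdx <- setdiff(seq_len(n), hold)
    if (length(unique(lab[trIdx])) < 2L)
      stop("a fold left a single-class training set; use fewer folds")
    fit <- .forestFromMatrix(m[trIdx, , drop = FALSE], lab[trIdx], config)
    tmp <- new("TasteForest", forest = fit, config = config,
                        classes = .TASTE_CLASSES,
                        trainFP = m[trIdx, , drop = FALSE],
                        trainIds = molIds(mset)[trIdx],
                        trainLabels = lab[trIdx], version = .BUNDLE_FORMAT)
    pred <- .predictMatrix(tmp, m[hold, , drop = FALSE], molIds(mset)[hold])
    pred$label <- lab[hold]
    pred$.row <- hold
    out[[f]] <- pred
  }
  res <- do.call(rbind, out)
  res <- res[order(res$.row), ]
  res$.row <- NULL
  rownames(res) <- NULL
  res
}

#' Leave-one-out cross-validation
#'
#' Convenience wrapper: [crossValidate()] with `method = "loo"`.
#'
#' @inheritParams crossValidate
#' @return See [crossValidate()].
#' @export
looCV <- function(mset, config = rfConfig()) {
  crossValidate(mset, config, method = "loo")
}

#' Compare fingerprint kinds by cross-validated performance
#'
#' Runs the same cross-validation (same seed) once per fingerprint kind and
#' reports the sweet-positive metric panel, sorted by AUC descending.
#'
#' @param mset labeled, standardized [MoleculeSet-class].
#' @param kinds at least two fingerprint kinds.
#' @param config an [RFConfig-class]; its `fingerprint` slot is overridden
#'   per row.
#' @param method,folds passed to [crossValidate()].
#' @return data.frame, one row per kind, columns as [metricsTable()] plus
#'   `fingerprint`.
#' @export
compareFingerprints <- function(mset, kinds = .FP_KINDS, config = rfConfig(),
                                method = c("kfold", "loo"), folds = 10L) {
  if (length(kinds) < 2L) stop("need at least two fingerprint kinds")
  kinds <- match.arg(kinds, .FP_KINDS, several.ok = TRUE)
  method <- match.arg(method)
  rows <- lapply(kinds, function(k) {
    cfg <- rfConfig(nTrees = config@nTrees, fingerprint = k,
                    seed = config@seed)
    cv <- crossValidate(mset, cfg, method = method, folds = folds)
    r <- metricsTable(cv$label, cv$predicted_class, cv$score_sweet)
    cbind(fingerprint = k, r[r$positive_class == "sweet", , drop = FALSE])
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$roc_auc), ]
  rownames(out) <- NULL
  out
}

#' Save / load a trained model bundle
#'
#' The bundle is a single RDS archive holding a metadata list (format
#' version, config, classes, class counts, voting rule) together with the
#' serialized ensemble and the retained training fingerprint matrix.
#'
#' @param model a [TasteForest-class].
#' @param path bundle file path.
#' @return `saveTasteForest`: `path`, invisibly. `readTasteForest`: the
#'   restored [TasteForest-class].
#' @export
saveTasteForest <- function(model, path) {
  meta <- list(format = model@version,
               classes = model@classes,
               counts = as.list(table(model@trainLabels)),
               nTrees = model@config@nTrees,
               fingerprint = model@config@fingerprint,
               seed = model@config@seed,
               voting = model@config@votingRule)
  saveRDS(list(meta = meta, forest = model@forest, trainFP = model@trainFP,
               trainIds = model@trainIds, trainLabels = model@trainLabels),
          path)
  invisible(path)
}

#' @rdname saveTasteForest
#' @export
readTasteForest <- function(path) {
  b <- readRDS(path)
  if (!identical(b$meta$format, .BUNDLE_FORMAT))
    stop("unsupported bundle format: ", b$meta$format)
  cfg <- rfConfig(nTrees = b$meta$nTrees, fingerprint = b$meta$fingerprint,
                  seed = b$meta$seed)
  new("TasteForest", forest = b$forest, config = cfg,
      classes = b$meta$classes, trainFP = b$trainFP,
      trainIds = b$trainIds, trainLabels = b$trainLabels,
      version = b$meta$format)
}
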