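# Tanimoto applicability-domain assessment against the retained training
# fingerprints, and confidence-thresholded batch screening. Out-of-domain
# queries are still predicted but flagged: the applicability domain is
# advisory, confidence thresholds do the filtering.

# Tanimoto similarities of each query row against each training row,
# vectorized over the 0/1 matrices.
.tanimotoToTraining <- function(qm, tm) {
  qi <- 1 * qm; ti <- 1 * tm
  inter <- qi %*% t(ti)
  qs <- rowSums(qi); ts <- rowSums(ti)
  uni <- outer(qs, ts, `+`) - inter
  sims <- ifelse(uni == 0, 1, inter / uni)   # both empty -> identical
  sims
}

#' Applicability-domain assessment
#'
#' For each query, the maximum Tanimoto similarity (on the model's
#' fingerprint kind) to any retained training fingerprint, with the nearest
#' training molecule; a query is in-domain when that similarity reaches the
#' threshold.
#'
#' @param model a [TasteForest-class] with retained training fingerprints.
#' @param mset standardized query [MoleculeSet-class].
#' @param threshold max-Tanimoto cutoff in `[0, 1]` (default 0.25, a
#'   permissive common choice; always echoed in the output).
#' @return data.frame: `id`, `max_similarity`, `nearest_training_id`,
#'   `in_domain`, `threshold`.
#' @export
adAssess <- function(model, mset, threshold = 0.25) {
  if (nrow(model@trainFP) == 0L) stop("model has no retained training fingerprints")
  stopifnot(threshold >= 0, threshold <= 1)
  qm <- fingerprintMatrix(mset, model@config@fingerprint)
  sims <- .tanimotoToTraining(qm, model@trainFP)
  best <- apply(sims, 1L, which.max)
  maxSim <- sims[cbind(seq_len(nrow(sims)), best)]
  data.frame(id = molIds(mset),
             max_similarity = unname(maxSim),
             nearest_training_id = model@trainIds[best],
             in_domain = unname(maxSim >= threshold),
             threshold = threshold,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Confidence-thresholded library screening
#'
#' Predicts every library compound; compounds below the confidence threshold
#' stay in the output with `above_threshold = FALSE` but are excluded from
#' the summary counts. Applicability-domain columns are included.
#'
#' @param model a [TasteForest-class].
#' @param mset standardized library [MoleculeSet-class].
#' @param confidenceThreshold cutoff in `[0.5, 1]`.
#' @param adThreshold applicability-domain cutoff (see [adAssess()]).
#' @return list with `predictions` (data.frame: `id`, `predicted_class`,
#'   `confidence`, `score_sweet`, `score_bitter`, `above_threshold`,
#'   `max_similarity`, `nearest_training_id`, `in_domain`) and `summary`
#'   (list: `threshold`, `n_total`, `n_bitter_above`, `n_sweet_above`,
#'   `fraction_bitter`, `fraction_sweet`; fractions over `n_total`).
#' @export
screenLibrary <- function(model, mset, confidenceThreshold = 0.6,
                          adThreshold = 0.25) {
  if (confidenceThreshold < 0.5 || confidenceThreshold > 1)
    stop("confidence threshold must be in [0.5, 1]")
  pred <- predictTaste(model, mset)
  ad <- adAssess(model, mset, adThreshold)
  pred$above_threshold <- pred$confidence >= confidenceThreshold
  pred$max_similarity <- ad$max_similarity
  pred$nearest_training_id <- ad$nearest_training_id
  pred$in_domain <- ad$in_domain
  list(predictions = pred,
       summary = .screenSummary(pred, confidenceThreshold))
}

.screenSummary <- function(pred, threshold) {
  above <- pred$confidence >= threshold
  nb <- sum(above & pred$predicted_class == "bitter")
  ns <- sum(above & pred$predicted_class == "sweet")
  n <- nrow(pred)
  list(threshold = threshold, n_total = n,
       n_bitter_above = nb, n_sweet_above = ns,
       fraction_bitter = if (n) nb / n else NA_real_,
       fraction_sweet = if (n) ns / n else NA_real_)
}

#' Screen a library at several confidence thresholds
#'
#' One prediction pass, one summary per threshold; retained counts are
#' non-increasing in the threshold.
#'
#' @param model a [TasteForest-class].
#' @param mset standardized library [MoleculeSet-class].
#' @param thresholds ascending confidence cutoffs,
#'   e.g. `c(0.60, 0.75, 0.95)`.
#' @return data.frame, one row per threshold, with the summary fields.
#' @export
thresholdSweep <- function(model, mset, thresholds = c(0.60, 0.75, 0.95)) {
  if (is.unsorted(thresholds)) stop("thresholds must be sorted ascending")
  if (any(thresholds < 0.5 | thresholds > 1))
    stop("thresholds must be in [0.5, 1]")
  pred <- predictTaste(model, mset)
  do.call(rbind, lapply(thresholds, function(t)
    as.data.frame(.screenSummary(pred, t))))
}
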