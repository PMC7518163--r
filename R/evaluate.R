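# Model evaluation: rank-based AUC and repeated 70/30 holdout.

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with midranks for ties: the probability
#' that a random presence score outranks a random absence score, counting
#' ties as one half.
#'
#' @param scoresPresence,scoresAbsence numeric score vectors, both
#'   non-empty.
#' @return AUC in `[0, 1]`.
#' @examples
#' auc(c(0.8, 0.4), c(0.6, 0.2))   # 0.75
#' @export
auc <- function(scoresPresence, scoresAbsence) {
  if (!length(scoresPresence) || !length(scoresAbsence))
    sdmStop("sdmEvaluationError", "both score vectors must be non-empty")
  np <- length(scoresPresence); na <- length(scoresAbsence)
  r <- rank(c(scoresPresence, scoresAbsence), ties.method = "average")
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * na)
}

#' Repeated stratified holdout evaluation
#'
#' For each repeat, splits presences and pseudo-absences separately at the
#' training fraction (default 70/30), fits the learner on the training
#' part, and computes the AUC on the held-out part. Repeat `i` uses
#' pseudo-absence replicate `((i - 1) mod n_draws) + 1`, so with the
#' default 10 repeats and 10 replicate draws every draw is exercised once.
#' A repeat whose split empties a class is skipped with a warning.
#'
#' @param spec a [learnerSpec()].
#' @param presenceTable predictor table of the presences.
#' @param paDraws list of pseudo-absence predictor tables (the replicate
#'   draws), or a single table.
#' @param fraction training fraction in (0, 1); default 0.7.
#' @param nRepeats number of holdout repeats; default 10.
#' @param seed RNG seed controlling splits and fits.
#' @return an [EvaluationResult].
#' @export
repeatedHoldout <- function(spec, presenceTable, paDraws, fraction = 0.7,
                            nRepeats = 10L, seed = 1L) {
  if (!is.list(paDraws) || is.data.frame(paDraws)) paDraws <- list(paDraws)
  if (fraction <= 0 || fraction >= 1)
    sdmStop("sdmConfigError", "fraction must lie in (0, 1)")
  if (nRepeats < 1L)
    sdmStop("sdmConfigError", "nRepeats must be >= 1")
  aucs <- numeric(0)
  for (i in seq_len(nRepeats)) {
    pa <- paDraws[[(i - 1L) %% length(paDraws) + 1L]]
    np <- nrow(presenceTable); na <- nrow(pa)
    set.seed(seed + i)
    trP <- sample(np, floor(fraction * np))
    trA <- sample(na, floor(fraction * na))
    if (length(trP) %in% c(0L, np) || length(trA) %in% c(0L, na)) {
      warning(sprintf("holdout repeat %d skipped: a class was emptied", i))
      next
    }
    specI <- learnerSpec(spec$family, spec$hyper, seed = seed + 1000L + i)
    fit <- fitLearner(specI, presenceTable[trP, , drop = FALSE],
                      pa[trA, , drop = FALSE])
    sp <- predictProbability(fit, presenceTable[-trP, , drop = FALSE])
    sa <- predictProbability(fit, pa[-trA, , drop = FALSE])
    aucs <- c(aucs, auc(sp[!is.na(sp)], sa[!is.na(sa)]))
  }
  if (!length(aucs))
    sdmStop("sdmEvaluationError", "all holdout repeats were skipped")
  new("EvaluationResult", aucs = aucs, meanAuc = mean(aucs),
      fraction = fraction, nRepeats = as.integer(nRepeats))
}

#' @export
setMethod("show", "EvaluationResult", function(object) {
  cat(sprintf(
    "EvaluationResult: mean AUC %.3f over %d repeats (%.0f/%.0f split)\n",
    object@meanAuc, length(object@aucs), 100 * object@fraction,
    100 * (1 - object@fraction)))
})
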