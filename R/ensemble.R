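# Ensemble construction: replicate averaging, AUC gating, mean and
# variance (uncertainty) maps.

# stack value matrices into an nRows x nCols x nLayers array (robust to
# degenerate 1x1 grids, unlike simplify2array)
layerArray <- function(mats) {
  array(unlist(mats), dim = c(nrow(mats[[1]]), ncol(mats[[1]]),
                              length(mats)))
}

meanOfLayers <- function(layers, name = "mean") {
  g <- layers[[1]]@grid
  arr <- layerArray(lapply(layers, function(l) l@values))
  n <- apply(!is.na(arr), c(1, 2), sum)
  s <- apply(arr, c(1, 2), function(v) sum(v, na.rm = TRUE))
  envLayer(name, g, ifelse(n > 0, s / n, NA_real_), units = "probability")
}

#' Average an algorithm family's replicate models
#'
#' Cellwise arithmetic mean of the replicate suitability maps; the family's
#' AUC is the arithmetic mean of the replicate evaluation means.
#'
#' @param family family label.
#' @param replicateMaps list of suitability [EnvLayer]s on one grid.
#' @param replicateAucs numeric vector of the replicates' (mean) AUCs.
#' @param models optional list of the replicate [FittedLearner]s (kept for
#'   importance and partial-effect prediction).
#' @return a [FamilyModel].
#' @export
aggregateFamily <- function(family, replicateMaps, replicateAucs,
                            models = list()) {
  if (!length(replicateMaps))
    sdmStop("sdmConfigError", "need at least one replicate map")
  g <- replicateMaps[[1]]@grid
  for (l in replicateMaps)
    if (!sameGrid(l@grid, g))
      sdmStop("sdmExtentError", "replicate maps are not on one grid")
  new("FamilyModel", family = family,
      map = meanOfLayers(replicateMaps, name = family),
      meanAuc = mean(replicateAucs),
      nReplicates = length(replicateMaps), models = models)
}

#' Build the AUC-gated ensemble
#'
#' Families whose mean AUC is strictly greater than the threshold
#' contribute; the ensemble map is their unweighted cellwise mean. With at
#' least two contributors a per-cell population variance uncertainty map is
#' attached (see [uncertaintyMap()]).
#'
#' @param familyModels list of [FamilyModel].
#' @param aucThreshold inclusion gate; default 0.7, compared strictly.
#' @return an [EnsembleResult].
#' @export
buildEnsemble <- function(familyModels, aucThreshold = 0.7) {
  if (!length(familyModels))
    sdmStop("sdmConfigError", "need at least one family model")
  fams <- vapply(familyModels, function(f) f@family, character(1))
  aucs <- vapply(familyModels, function(f) f@meanAuc, numeric(1))
  inc <- aucs > aucThreshold
  if (!any(inc))
    sdmStop("sdmEmptyEnsembleError",
            "no family exceeds AUC %g (AUCs: %s)", aucThreshold,
            paste(sprintf("%s=%.3f", fams, aucs), collapse = ", "))
  included <- familyModels[inc]
  meanMap <- meanOfLayers(lapply(included, function(f) f@map),
                          name = "ensemble")
  unc <- if (sum(inc) >= 2) uncertaintyMap(included) else NULL
  new("EnsembleResult", meanMap = meanMap, uncertaintyMap = unc,
      included = fams[inc],
      excluded = data.frame(family = fams[!inc], meanAuc = aucs[!inc],
                            reason = rep(sprintf("mean AUC <= %g",
                                                 aucThreshold), sum(!inc)),
                            stringsAsFactors = FALSE),
      aucThreshold = aucThreshold, families = included)
}

#' Between-algorithm uncertainty map
#'
#' Per-cell population variance (divide by n) of the suitability maps of
#' the included family models. Areas of agreement have low variance; with
#' members in `[0, 1]` the variance cannot exceed 0.25.
#'
#' @param familyModels list of at least two [FamilyModel] (or [EnvLayer])
#'   objects on one grid.
#' @return an [EnvLayer] of per-cell variances.
#' @export
uncertaintyMap <- function(familyModels) {
  if (length(familyModels) < 2)
    sdmStop("sdmEvaluationError",
            "uncertainty is undefined for fewer than two families")
  maps <- lapply(familyModels, function(f)
    if (is(f, "FamilyModel")) f@map else f)
  g <- maps[[1]]@grid
  arr <- layerArray(lapply(maps, function(l) l@values))
  v <- apply(arr, c(1, 2), function(z) mean((z - mean(z))^2))
  envLayer("uncertainty", g, v, units = "variance")
}

#' @export
setMethod("show", "FamilyModel", function(object) {
  cat(sprintf("FamilyModel %s: mean AUC %.3f over %d replicates\n",
              object@family, object@meanAuc, object@nReplicates))
})

#' @export
setMethod("show", "EnsembleResult", function(object) {
  cat(sprintf("EnsembleResult: %d included (AUC > %g): %s\n",
              length(object@included), object@aucThreshold,
              paste(object@included, collapse = ", ")))
  if (nrow(object@excluded))
    cat(sprintf("  excluded: %s\n",
                paste(sprintf("%s (%.3f)", object@excluded$family,
                              object@excluded$meanAuc), collapse = ", ")))
})

#' @export
setMethod("predictProbability", "FamilyModel", function(object, table) {
  if (!length(object@models))
    sdmStop("sdmConfigError",
            "FamilyModel holds no replicate models; cannot predict at points")
  ps <- lapply(object@models, predictProbability, table = table)
  p <- Reduce(`+`, ps) / length(ps)
  attr(p, "nMissing") <- attr(ps[[1]], "nMissing")
  p
})

#' @export
setMethod("predictProbability", "EnsembleResult", function(object, table) {
  ps <- lapply(object@families, predictProbability, table = table)
  p <- Reduce(`+`, ps) / length(ps)
  attr(p, "nMissing") <- attr(ps[[1]], "nMissing")
  p
})
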