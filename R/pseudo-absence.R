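# Algorithm-family-specific pseudo-absence (background) sampling.

.FAMILIES <- c("ANN", "CTA", "GBM", "GLM", "MARS", "RF", "SVM")

#' Pseudo-absence design for a learner family
#'
#' Machine-learning families (ANN, RF, SVM), the classification family
#' (CTA) and the boosted-tree family (GBM) draw as many background points
#' as there are presences; the regression families (GLM, MARS) draw a fixed
#' large count (default 1000). Every design is replicated 10 times by
#' default, each replicate an independent uniform draw.
#'
#' @param family one of `ANN, CTA, GBM, GLM, MARS, RF, SVM`.
#' @param nReplicates number of replicate draws.
#' @param fixedCount background count for the regression designs.
#' @param excludePresenceCells make presence cells ineligible (default
#'   `TRUE`; set `FALSE` to emulate samplers that draw anywhere).
#' @param seed base RNG seed.
#' @return a [PseudoAbsenceDesign].
#' @export
designForFamily <- function(family, nReplicates = 10L, fixedCount = 1000L,
                            excludePresenceCells = TRUE, seed = 1L) {
  if (!family %in% .FAMILIES)
    sdmStop("sdmConfigError", "unknown learner family '%s'; available: %s",
            family, paste(.FAMILIES, collapse = ", "))
  cls <- switch(family,
    ANN = , RF = , SVM = "machine_learning",
    CTA = "classification",
    GBM = "machine_learning",   # presence-matched counts, like the ML group
    GLM = , MARS = "regression")
  rule <- if (cls == "regression") "fixed" else "equal"
  new("PseudoAbsenceDesign", familyClass = cls, countRule = rule,
      fixedCount = as.integer(fixedCount),
      nReplicates = as.integer(nReplicates),
      excludePresenceCells = excludePresenceCells, seed = as.integer(seed))
}

#' Draw replicate pseudo-absence point sets
#'
#' Samples cells uniformly without replacement from the valid cells of the
#' stack (optionally excluding cells holding a presence) and places one
#' point at each sampled cell's centre. Replicate `r` is drawn under seed
#' `seed + r`, so runs are reproducible and replicates mutually distinct in
#' general.
#'
#' @param design a [PseudoAbsenceDesign].
#' @param stack the [EnvStack] defining validity.
#' @param presences an [OccurrenceSet] (sets the count for equal-count
#'   designs and the exclusion cells).
#' @return list of data.frames (`lon`, `lat`, `replicate`), one per
#'   replicate, each with attribute `cells` (linear cell indices).
#' @export
drawReplicates <- function(design, stack, presences) {
  stopifnot(is(design, "PseudoAbsenceDesign"), is(stack, "EnvStack"),
            is(presences, "OccurrenceSet"))
  g <- gridOf(stack)
  msk <- envMask(stack)
  eligible <- which(t(msk))   # linear row-major indices (row-major by cell())
  pres <- occRecords(presences)
  presCells <- cellFromLonLat(g, pres$lon, pres$lat)$cell
  if (design@excludePresenceCells)
    eligible <- setdiff(eligible, presCells[!is.na(presCells)])
  count <- if (design@countRule == "equal") nrow(pres) else design@fixedCount
  if (count < 1L)
    sdmStop("sdmConfigError", "pseudo-absence count is zero")
  if (length(eligible) < count)
    sdmStop("sdmInfeasibleDesignError",
            "need %d eligible cells but only %d available (deficit %d)",
            count, length(eligible), count - length(eligible))
  lapply(seq_len(design@nReplicates), function(r) {
    set.seed(design@seed + r)
    cells <- sample(eligible, count, replace = FALSE)
    row <- (cells - 1L) %/% g@nCols + 1L
    col <- (cells - 1L) %% g@nCols + 1L
    ctr <- cellCenter(g, row, col)
    out <- data.frame(lon = ctr$lon, lat = ctr$lat, replicate = r)
    attr(out, "cells") <- cells
    out
  })
}

#' @export
setMethod("show", "PseudoAbsenceDesign", function(object) {
  cat(sprintf(
    "PseudoAbsenceDesign: %s, %s count%s, %d replicates, exclusion %s\n",
    object@familyClass, object@countRule,
    if (object@countRule == "fixed") sprintf(" (%d)", object@fixedCount)
    else "",
    object@nReplicates, if (object@excludePresenceCells) "on" else "off"))
})
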