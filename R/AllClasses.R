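#' @import methods
NULL

#' GridSpec: geometry of a regular geographic grid
#'
#' Describes a regular latitude/longitude grid anchored at its north-west
#' corner. Cells are indexed row-major from the NW corner (row 1 is the
#' northernmost row) and are half-open: cell (r, c) covers
#' `[originLon + (c-1) * res, originLon + c * res)` in longitude and
#' `(originLat - r * res, originLat - (r-1) * res]` in latitude, so a point
#' lying exactly on a shared edge belongs to the cell to its east/south.
#'
#' @slot originLon west edge of the grid, decimal degrees.
#' @slot originLat north edge of the grid, decimal degrees.
#' @slot res cell size, decimal degrees (square cells).
#' @slot nRows,nCols grid dimensions.
#' @slot datum datum label; only geographic WGS84 grids are supported.
#' @export
setClass("GridSpec",
  representation(
    originLon = "numeric", originLat = "numeric", res = "numeric",
    nRows = "integer", nCols = "integer", datum = "character"
  ),
  prototype(datum = "WGS84")
)

setValidity("GridSpec", function(object) {
  msg <- character()
  if (length(object@res) != 1 || !is.finite(object@res) || object@res <= 0)
    msg <- c(msg, "res must be a single positive number")
  if (object@nRows < 1L || object@nCols < 1L)
    msg <- c(msg, "nRows and nCols must be >= 1")
  if (length(object@originLon) != 1 || length(object@originLat) != 1 ||
      !all(is.finite(c(object@originLon, object@originLat))))
    msg <- c(msg, "origin must be finite")
  if (length(msg)) msg else TRUE
})

#' EnvLayer: one environmental predictor on a grid
#'
#' A single-band raster layer: a named real-valued matrix on a [GridSpec],
#' with `NA` marking nodata cells.
#'
#' @slot name predictor label (e.g. `"sst"`).
#' @slot units unit string (e.g. `"degC"`); may be empty.
#' @slot grid a [GridSpec].
#' @slot values numeric matrix of dimension `nRows x nCols`; `NA` is nodata.
#' @export
setClass("EnvLayer",
  representation(
    name = "character", units = "character",
    grid = "GridSpec", values = "matrix"
  )
)

setValidity("EnvLayer", function(object) {
  g <- object@grid
  if (!identical(dim(object@values), c(g@nRows, g@nCols)))
    return(sprintf("values must be a %d x %d matrix", g@nRows, g@nCols))
  if (!is.numeric(object@values))
    return("values must be numeric")
  TRUE
})

#' EnvStack: aligned multi-layer predictor stack
#'
#' An ordered collection of [EnvLayer] objects sharing one identical
#' [GridSpec], with unique layer names. A cell is valid iff no layer is
#' nodata there; see [envMask()].
#'
#' @slot layers named list of [EnvLayer].
#' @export
setClass("EnvStack", representation(layers = "list"))

setValidity("EnvStack", function(object) {
  ls <- object@layers
  if (length(ls) == 0L) return("stack must contain at least one layer")
  if (!all(vapply(ls, is, logical(1), "EnvLayer")))
    return("all elements must be EnvLayer objects")
  nm <- unname(vapply(ls, function(l) l@name, character(1)))
  if (anyDuplicated(nm)) return("layer names must be unique")
  if (!identical(names(ls), nm)) return("list names must equal layer names")
  g1 <- ls[[1]]@grid
  same <- vapply(ls, function(l) identical(unname(gridKey(l@grid)),
                                           unname(gridKey(g1))), logical(1))
  if (!all(same)) return("all layers must share one identical GridSpec")
  TRUE
})

#' OccurrenceSet: season-tagged presence records for one species
#'
#' @slot species species label.
#' @slot season `"summer"`, `"winter"` or `"all"`.
#' @slot records data.frame with columns `species, lon, lat, date, source`.
#' @slot thinned logical: has grid-cell spatial thinning been applied.
#' @export
setClass("OccurrenceSet",
  representation(species = "character", season = "character",
                 records = "data.frame", thinned = "logical"),
  prototype(thinned = FALSE)
)

setValidity("OccurrenceSet", function(object) {
  need <- c("species", "lon", "lat", "date", "source")
  if (!all(need %in% names(object@records)))
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  if (!object@season %in% c("summer", "winter", "all"))
    return("season must be 'summer', 'winter' or 'all'")
  r <- object@records
  if (nrow(r) && (any(r$lon < -180 | r$lon > 180, na.rm = TRUE) ||
                  any(r$lat < -90 | r$lat > 90, na.rm = TRUE)))
    return("coordinates out of range")
  TRUE
})

#' PseudoAbsenceDesign: family-specific background sampling design
#'
#' Encodes how pseudo-absences are drawn for one learner family class:
#' machine-learning and classification families use as many background
#' points as presences; regression families use a fixed large count
#' (default 1000). Each design is replicated (default 10 times).
#'
#' @slot familyClass `"machine_learning"`, `"classification"` or `"regression"`.
#' @slot countRule `"equal"` (match presences) or `"fixed"`.
#' @slot fixedCount background count for `"fixed"` designs.
#' @slot nReplicates number of independent draws.
#' @slot excludePresenceCells if `TRUE`, cells holding a presence are
#'   ineligible.
#' @slot seed base RNG seed; replicate `r` uses `seed + r`.
#' @export
setClass("PseudoAbsenceDesign",
  representation(familyClass = "character", countRule = "character",
                 fixedCount = "integer", nReplicates = "integer",
                 excludePresenceCells = "logical", seed = "integer"),
  prototype(fixedCount = 1000L, nReplicates = 10L,
            excludePresenceCells = TRUE, seed = 1L)
)

setValidity("PseudoAbsenceDesign", function(object) {
  if (!object@familyClass %in%
      c("machine_learning", "classification", "regression"))
    return("unknown familyClass")
  if (!object@countRule %in% c("equal", "fixed"))
    return("countRule must be 'equal' or 'fixed'")
  if (object@nReplicates < 1L) return("nReplicates must be >= 1")
  if (object@fixedCount < 1L) return("fixedCount must be >= 1")
  TRUE
})

#' FittedLearner: one fitted base model
#'
#' @slot family one of `ANN, CTA, GBM, GLM, MARS, RF, SVM`.
#' @slot variables predictor names used at fit time.
#' @slot nPresence,nAbsence training class sizes.
#' @slot hyper hyperparameter list actually used.
#' @slot seed RNG seed the fit was run under.
#' @slot fit opaque fitted state (family-specific).
#' @export
setClass("FittedLearner",
  representation(family = "character", variables = "character",
                 nPresence = "integer", nAbsence = "integer",
                 hyper = "list", seed = "integer", fit = "ANY")
)

#' EvaluationResult: repeated-holdout AUC summary
#'
#' @slot aucs per-repeat AUC values.
#' @slot meanAuc arithmetic mean of `aucs`.
#' @slot fraction training fraction of the split.
#' @slot nRepeats number of holdout repeats attempted.
#' @export
setClass("EvaluationResult",
  representation(aucs = "numeric", meanAuc = "numeric",
                 fraction = "numeric", nRepeats = "integer")
)

setValidity("EvaluationResult", function(object) {
  if (length(object@aucs) &&
      any(object@aucs < 0 | object@aucs > 1, na.rm = TRUE))
    return("AUC values must lie in [0, 1]")
  TRUE
})

#' FamilyModel: one family's replicate-averaged suitability surface
#'
#' Holds the cellwise mean suitability map over an algorithm family's
#' pseudo-absence replicates, the family's mean holdout AUC, and the
#' replicate models themselves (used for permutation importance and
#' partial-effect prediction).
#'
#' @slot family family label.
#' @slot map replicate-averaged suitability [EnvLayer] (values in `[0,1]`).
#' @slot meanAuc mean holdout AUC over replicates/repeats.
#' @slot nReplicates number of replicate models averaged.
#' @slot models list of [FittedLearner] (may be empty when built from maps).
#' @export
setClass("FamilyModel",
  representation(family = "character", map = "EnvLayer", meanAuc = "numeric",
                 nReplicates = "integer", models = "list"),
  prototype(models = list())
)

#' EnsembleResult: AUC-gated ensemble of family models
#'
#' @slot meanMap unweighted cellwise mean suitability over included families.
#' @slot uncertaintyMap per-cell population variance across included family
#'   maps (`NULL` when fewer than two families are included).
#' @slot included labels of families whose mean AUC exceeded the threshold.
#' @slot excluded data.frame (family, meanAuc, reason) for the rest.
#' @slot aucThreshold the gate that was applied (strictly greater-than).
#' @slot families list of the included [FamilyModel] objects.
#' @export
setClass("EnsembleResult",
  representation(meanMap = "EnvLayer", uncertaintyMap = "ANY",
                 included = "character", excluded = "data.frame",
                 aucThreshold = "numeric", families = "list")
)
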