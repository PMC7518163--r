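# Model diagnostics: permutation variable importance and partial-effect
# response curves.

#' Permutation variable importance
#'
#' For each predictor v, the importance index is the average over
#' `nPermutations` of `1 - Cor(P_f, P_v)`, where `P_f` is the model's
#' prediction on the table and `P_v` the prediction after shuffling column
#' v. A variable the model ignores scores exactly 0. Sampling noise can
#' push the correlation slightly negative (index > 1) or the index slightly
#' negative; indices are clamped to `[0, 1]` and flagged. Shares are the
#' indices normalised to percentages.
#'
#' All permuted tables are predicted in one batched call per model, which
#' matters when `object` is an ensemble over many replicate models.
#'
#' @param object a [FittedLearner], [FamilyModel] or [EnsembleResult].
#' @param table evaluation table with the training predictor columns.
#' @param nPermutations permutations averaged per variable; default 10.
#' @param seed RNG seed for the shuffles.
#' @param method correlation type: `"pearson"` (default) or `"spearman"`.
#' @return data.frame of class `ImportanceTable` with columns `variable`,
#'   `importance` (clamped index), `share` (percent); attributes
#'   `nPermutations`, `seed`, `clamped`.
#' @export
permutationImportance <- function(object, table, nPermutations = 10L,
                                  seed = 1L,
                                  method = c("pearson", "spearman")) {
  method <- match.arg(method)
  vars <- importanceVars(object)
  x <- table[stats::complete.cases(table[vars]), , drop = FALSE]
  if (nrow(x) < 10)
    sdmStop("sdmConfigError",
            "importance needs at least 10 complete rows (have %d)", nrow(x))
  set.seed(seed)
  perms <- replicate(nPermutations, sample.int(nrow(x)), simplify = FALSE)
  # batch: original table + one block per (variable, permutation)
  blocks <- list(x)
  key <- list()
  for (v in vars) for (k in seq_len(nPermutations)) {
    xb <- x
    xb[[v]] <- xb[[v]][perms[[k]]]
    blocks[[length(blocks) + 1]] <- xb
    key[[length(key) + 1]] <- c(v, k)
  }
  big <- do.call(rbind, blocks)
  p <- predictProbability(object, big)
  n <- nrow(x)
  pf <- p[seq_len(n)]
  warned <- FALSE
  raw <- numeric(length(vars)); names(raw) <- vars
  for (j in seq_along(key)) {
    v <- key[[j]][1]
    pv <- p[(j * n + 1):((j + 1) * n)]
    cc <- if (stats::sd(pf) == 0 || stats::sd(pv) == 0) NA_real_
          else stats::cor(pf, pv, method = method)
    if (is.na(cc)) {
      if (!warned) {
        warning("constant predictions: correlation undefined, importance 0")
        warned <- TRUE
      }
      cc <- 1
    }
    raw[v] <- raw[v] + (1 - cc) / nPermutations
  }
  clamped <- raw < 0 | raw > 1
  imp <- pmin(pmax(raw, 0), 1)
  share <- if (sum(imp) > 0) 100 * imp / sum(imp) else rep(0, length(imp))
  structure(
    data.frame(variable = vars, importance = unname(imp),
               share = unname(share), stringsAsFactors = FALSE),
    nPermutations = nPermutations, seed = seed,
    clamped = vars[clamped],
    class = c("ImportanceTable", "data.frame"))
}

importanceVars <- function(object) {
  if (is(object, "FittedLearner")) return(object@variables)
  if (is(object, "FamilyModel")) return(object@models[[1]]@variables)
  if (is(object, "EnsembleResult"))
    return(object@families[[1]]@models[[1]]@variables)
  sdmStop("sdmConfigError", "cannot determine predictor set of object")
}

#' Partial-effect response curve
#'
#' Evaluates the model along one predictor over `nGrid` evenly spaced
#' values spanning its observed range, with every other predictor held at
#' its column mean. For an ensemble the curve is the mean of the included
#' families' curves (equivalently, the ensemble prediction on the grid).
#'
#' @param object a [FittedLearner], [FamilyModel] or [EnsembleResult].
#' @param table table supplying the observed ranges and means.
#' @param variable predictor to profile.
#' @param nGrid number of grid points (>= 2); default 50.
#' @return data.frame of class `PartialEffectCurve` with columns
#'   `variable`, `x` (strictly increasing), `response` (in `[0, 1]`).
#' @export
partialEffect <- function(object, table, variable, nGrid = 50L) {
  vars <- importanceVars(object)
  if (!variable %in% vars)
    sdmStop("sdmConfigError", "'%s' is not a model predictor", variable)
  if (nGrid < 2) sdmStop("sdmConfigError", "nGrid must be >= 2")
  col <- table[[variable]]
  col <- col[is.finite(col)]
  if (!length(col))
    sdmStop("sdmDiagnosticError", "variable '%s' is all-missing", variable)
  grid <- seq(min(col), max(col), length.out = nGrid)
  nd <- as.data.frame(lapply(table[vars], function(z)
    rep(mean(z, na.rm = TRUE), nGrid)))
  nd[[variable]] <- grid
  resp <- predictProbability(object, nd)
  structure(
    data.frame(variable = variable, x = grid, response = as.numeric(resp),
               stringsAsFactors = FALSE),
    class = c("PartialEffectCurve", "data.frame"))
}
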