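# The seven base learner families.
#
# Each family is an entry in a plug-in registry with a `fit` and a `predict`
# function; the ensemble runs with any subset of families. Bindings:
#   ANN  single-hidden-layer perceptron, logistic output      (nnet)
#   CTA  classification tree with probability leaves          (rpart)
#   GBM  gradient-boosted trees, logistic loss                (xgboost)
#   GLM  binomial regression, logit link                      (stats::glm)
#   MARS forward-stagewise hinge-basis expansion + logit link (in-package)
#   RF   probability random forest                            (ranger)
#   SVM  RBF margin classifier, Platt-calibrated              (e1071)

.metaCols <- c("lon", "lat", "replicate", "inExtent", "valid")

prepX <- function(table, variables = NULL) {
  if (is.null(variables)) variables <- setdiff(names(table), .metaCols)
  miss <- setdiff(variables, names(table))
  if (length(miss))
    sdmStop("sdmConfigError", "table lacks predictor column(s): %s",
            paste(miss, collapse = ", "))
  table[variables]
}

#' Learner specification
#'
#' @param family one of `ANN, CTA, GBM, GLM, MARS, RF, SVM`.
#' @param hyper named list of hyperparameter overrides; names are validated
#'   against the family's schema (see [learnerDefaults()]).
#' @param seed RNG seed for the fit.
#' @return list of class `LearnerSpec`.
#' @export
learnerSpec <- function(family, hyper = list(), seed = 1L) {
  if (!family %in% .FAMILIES)
    sdmStop("sdmConfigError", "unknown learner family '%s'; available: %s",
            family, paste(.FAMILIES, collapse = ", "))
  def <- learnerDefaults(family)
  bad <- setdiff(names(hyper), names(def))
  if (length(bad))
    sdmStop("sdmConfigError", "unknown %s hyperparameter(s): %s", family,
            paste(bad, collapse = ", "))
  def[names(hyper)] <- hyper
  structure(list(family = family, hyper = def, seed = as.integer(seed)),
            class = "LearnerSpec")
}

#' Default hyperparameters of a learner family
#'
#' @param family family label.
#' @return named list of defaults (the family's hyperparameter schema).
#' @export
learnerDefaults <- function(family) {
  switch(family,
    ANN = list(size = 5L, decay = 0.01, maxit = 200L),
    CTA = list(cp = 0.01, minsplit = 10L),
    GBM = list(nrounds = 100L, eta = 0.1, max_depth = 3L),
    GLM = list(),
    MARS = list(maxTerms = 11L, nKnots = 10L),
    RF = list(numTrees = 500L, mtry = NA_integer_),
    SVM = list(cost = 1, gamma = NA_real_),
    sdmStop("sdmConfigError", "unknown learner family '%s'", family))
}

.learnerRegistry <- list(
  ANN = list(
    fit = function(x, y, h, seed) {
      set.seed(seed)
      nnet::nnet(as.matrix(x), y, size = h$size, decay = h$decay,
                 maxit = h$maxit, entropy = TRUE, trace = FALSE)
    },
    predict = function(fit, x) as.numeric(predict(fit, as.matrix(x)))
  ),
  CTA = list(
    fit = function(x, y, h, seed) {
      set.seed(seed)
      d <- cbind(.y = factor(y, levels = c(0, 1)), x)
      rpart::rpart(.y ~ ., data = d, method = "class",
                   control = rpart::rpart.control(cp = h$cp,
                                                  minsplit = h$minsplit))
    },
    predict = function(fit, x) as.numeric(predict(fit, x)[, "1"])
  ),
  GBM = list(
    fit = function(x, y, h, seed) {
      set.seed(seed)
      dtrain <- xgboost::xgb.DMatrix(as.matrix(x), label = y)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", eta = h$eta,
                      max_depth = h$max_depth, nthread = 1),
        data = dtrain, nrounds = h$nrounds, verbose = 0)
    },
    predict = function(fit, x)
      as.numeric(predict(fit, xgboost::xgb.DMatrix(as.matrix(x))))
  ),
  GLM = list(
    fit = function(x, y, h, seed) {
      d <- cbind(.y = y, x)
      suppressWarnings(stats::glm(.y ~ ., data = d,
                                  family = stats::binomial()))
    },
    predict = function(fit, x)
      as.numeric(suppressWarnings(predict(fit, x, type = "response")))
  ),
  MARS = list(
    fit = function(x, y, h, seed)
      fitMarsLogit(x, y, maxTerms = h$maxTerms, nKnots = h$nKnots),
    predict = function(fit, x) predictMarsLogit(fit, x)
  ),
  RF = list(
    fit = function(x, y, h, seed) {
      d <- cbind(.y = factor(y, levels = c(0, 1)), x)
      mtry <- if (is.na(h$mtry)) floor(sqrt(ncol(x))) else h$mtry
      ranger::ranger(.y ~ ., data = d, num.trees = h$numTrees,
                     mtry = mtry, probability = TRUE, seed = seed,
                     num.threads = 1)
    },
    predict = function(fit, x)
      as.numeric(predict(fit, x, num.threads = 1)$predictions[, "1"])
  ),
  SVM = list(
    fit = function(x, y, h, seed) {
      set.seed(seed)
      gamma <- if (is.na(h$gamma)) 1 / ncol(x) else h$gamma
      e1071::svm(as.matrix(x), factor(y, levels = c(0, 1)),
                 kernel = "radial", cost = h$cost, gamma = gamma,
                 probability = TRUE)
    },
    predict = function(fit, x) {
      p <- predict(fit, as.matrix(x), probability = TRUE)
      as.numeric(attr(p, "probabilities")[, "1"])
    }
  )
)

#' Available learner families
#'
#' @return character vector of registered family labels.
#' @export
learnerFamilies <- function() names(.learnerRegistry)

#' Fit one base learner
#'
#' Binds the presence table (label 1) and pseudo-absence table (label 0),
#' drops coordinate/bookkeeping columns, and fits the family's algorithm.
#' The fit is deterministic given `spec$seed`.
#'
#' @param spec a [learnerSpec()].
#' @param presenceTable,paTable predictor tables sharing the same predictor
#'   columns (e.g. from [extractAtPoints()]).
#' @return a [FittedLearner].
#' @export
fitLearner <- function(spec, presenceTable, paTable) {
  stopifnot(inherits(spec, "LearnerSpec"))
  vars <- setdiff(intersect(names(presenceTable), names(paTable)), .metaCols)
  if (!length(vars))
    sdmStop("sdmConfigError", "no shared predictor columns")
  xp <- prepX(presenceTable, vars)
  xa <- prepX(paTable, vars)
  xp <- xp[stats::complete.cases(xp), , drop = FALSE]
  xa <- xa[stats::complete.cases(xa), , drop = FALSE]
  if (nrow(xp) < 5 || nrow(xa) < 5)
    sdmStop("sdmFitError",
            "need at least 5 complete rows per class (have %d presence, %d absence)",
            nrow(xp), nrow(xa))
  x <- rbind(xp, xa)
  y <- c(rep(1, nrow(xp)), rep(0, nrow(xa)))
  reg <- .learnerRegistry[[spec$family]]
  fit <- reg$fit(x, y, spec$hyper, spec$seed)
  new("FittedLearner", family = spec$family, variables = vars,
      nPresence = nrow(xp), nAbsence = nrow(xa), hyper = spec$hyper,
      seed = spec$seed, fit = fit)
}

#' Predict occurrence probability
#'
#' Returns suitability values in `[0, 1]`, one per row of `table`. Rows
#' with missing predictor values yield `NA`, reported through the
#' `"nMissing"` attribute. For a [FamilyModel] the prediction is the mean
#' over its replicate models; for an [EnsembleResult] the mean over the
#' included families' predictions.
#'
#' @param object a [FittedLearner], [FamilyModel] or [EnsembleResult].
#' @param table predictor table with the training columns.
#' @return numeric vector in `[0, 1]` with attribute `nMissing`.
#' @export
setMethod("predictProbability", "FittedLearner", function(object, table) {
  x <- prepX(table, object@variables)
  ok <- stats::complete.cases(x)
  p <- rep(NA_real_, nrow(x))
  if (any(ok)) {
    reg <- .learnerRegistry[[object@family]]
    p[ok] <- reg$predict(object@fit, x[ok, , drop = FALSE])
  }
  p <- pmin(pmax(p, 0), 1)
  attr(p, "nMissing") <- sum(!ok)
  p
})

#' Predict a suitability raster
#'
#' Applies the model at every valid cell centre of the stack; masked cells
#' are nodata. Identical to routing [extractAtPoints()] through
#' [predictProbability()].
#'
#' @param object a [FittedLearner], [FamilyModel] or [EnsembleResult].
#' @param stack an [EnvStack] whose layer names cover the training
#'   variables.
#' @return a suitability [EnvLayer] with values in `[0, 1]`.
#' @export
predictRaster <- function(object, stack) {
  g <- gridOf(stack)
  msk <- envMask(stack)
  ctr <- allCellCenters(g)
  keep <- as.vector(t(msk))      # row-major order matching allCellCenters
  tab <- extractAtPoints(stack, ctr$lon[keep], ctr$lat[keep])
  p <- predictProbability(object, tab)
  vals <- rep(NA_real_, nrow(ctr))
  vals[keep] <- p
  m <- matrix(vals, nrow = g@nRows, ncol = g@nCols, byrow = TRUE)
  envLayer("suitability", g, m, units = "probability")
}

#' @export
setMethod("show", "FittedLearner", function(object) {
  cat(sprintf("FittedLearner %s: %d presences vs %d absences, %d predictors\n",
              object@family, object@nPresence, object@nAbsence,
              length(object@variables)))
})

## --- minimal MARS (forward-stagewise hinge basis + logistic link) ---------

# Forward pass: greedily add reflected hinge pairs max(0, x - t) /
# max(0, t - x) chosen by OLS screening on the 0/1 labels (the classical
# forward pass), then calibrate the selected basis with one binomial GLM.

marsBasis <- function(terms, x) {
  B <- matrix(1, nrow(x), 1 + length(terms))
  for (k in seq_along(terms)) {
    tm <- terms[[k]]
    B[, k + 1] <- pmax(0, tm$dir * (x[[tm$var]] - tm$knot))
  }
  B
}

fitMarsLogit <- function(x, y, maxTerms = 11L, nKnots = 10L) {
  x <- as.data.frame(x)
  cand <- list()
  for (v in names(x)) {
    kn <- unique(stats::quantile(x[[v]], probs = seq(0.05, 0.95,
                                                     length.out = nKnots),
                                 names = FALSE, type = 7))
    for (t in kn) cand[[length(cand) + 1]] <- list(var = v, knot = t)
  }
  terms <- list()
  B <- matrix(1, nrow(x), 1)
  rss <- sum((y - mean(y))^2)
  while (ncol(B) + 2 <= maxTerms) {
    best <- NULL; bestRss <- rss
    for (cn in cand) {
      h1 <- pmax(0, x[[cn$var]] - cn$knot)
      h2 <- pmax(0, cn$knot - x[[cn$var]])
      f <- stats::lm.fit(cbind(B, h1, h2), y)
      r <- sum(f$residuals^2)
      if (r < bestRss - 1e-12) { bestRss <- r; best <- cn }
    }
    if (is.null(best) || (rss - bestRss) < 1e-6 * max(rss, 1e-12)) break
    terms[[length(terms) + 1]] <- list(var = best$var, knot = best$knot,
                                       dir = 1)
    terms[[length(terms) + 1]] <- list(var = best$var, knot = best$knot,
                                       dir = -1)
    B <- marsBasis(terms, x)
    rss <- bestRss
  }
  gfit <- suppressWarnings(
    stats::glm.fit(B, y, family = stats::binomial()))
  beta <- gfit$coefficients
  beta[is.na(beta)] <- 0
  structure(list(terms = terms, beta = beta), class = "marsLogit")
}

predictMarsLogit <- function(fit, x) {
  B <- marsBasis(fit$terms, as.data.frame(x))
  as.numeric(stats::plogis(B %*% fit$beta))
}
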