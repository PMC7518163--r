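# Fixture builders shared across test files. Everything is generated in
# code; nothing is read from disk except files the tests themselves write.

# small aligned stack with deterministic values and an optional nodata block
tinyStack <- function(nRows = 10, nCols = 12, res = 0.5, originLon = 10,
                      originLat = -20, layers = c("a", "b"), seed = 1,
                      nodataCells = NULL) {
  g <- gridSpec(originLon, originLat, res, nRows, nCols)
  set.seed(seed)
  ls <- lapply(seq_along(layers), function(i) {
    m <- matrix(rnorm(nRows * nCols, mean = i), nRows, nCols)
    if (!is.null(nodataCells)) m[nodataCells] <- NA
    envLayer(layers[i], g, m)
  })
  envStack(ls)
}

# occurrence records data.frame in the canonical schema
makeRecords <- function(lon, lat, species = "sp", date = as.Date("2015-11-03"),
                        source = "synthetic") {
  data.frame(species = rep(species, length.out = length(lon)),
             lon = lon, lat = lat,
             date = rep(as.Date(date), length.out = length(lon)),
             source = rep(source, length.out = length(lon)),
             stringsAsFactors = FALSE)
}

makeOccSet <- function(lon, lat, season = "summer", ...) {
  occurrenceSet("sp", makeRecords(lon, lat, ...), season = season)
}

# separable two-class predictor tables (presence high x1, absence low x1)
separableTables <- function(n = 30, seed = 1) {
  set.seed(seed)
  pres <- data.frame(x1 = rnorm(n, 3), x2 = rnorm(n))
  abs <- data.frame(x1 = rnorm(n, -3), x2 = rnorm(n))
  list(pres = pres, abs = abs)
}

# a FittedLearner wrapping a known-coefficient logistic model:
# p = plogis(b0 + b1*x1 + b2*x2 ...)
knownGlm <- function(beta, variables) {
  d <- as.data.frame(matrix(rnorm(20 * length(variables)), 20,
                            dimnames = list(NULL, variables)))
  d$.y <- rbinom(20, 1, 0.5)
  fit <- suppressWarnings(
    stats::glm(.y ~ ., data = d, family = stats::binomial()))
  fit$coefficients[] <- beta   # (intercept, then one per variable)
  new("FittedLearner", family = "GLM", variables = variables,
      nPresence = 10L, nAbsence = 10L, hyper = list(), seed = 1L, fit = fit)
}

# brute-force AUC by exhaustive pair counting
pairCountAuc <- function(p, a) {
  s <- 0
  for (x in p) for (y in a) s <- s + (x > y) + 0.5 * (x == y)
  s / (length(p) * length(a))
}
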