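test_that("GLM separates linearly separable toy data", {
  d <- separableTables(n = 30, seed = 1)
  fit <- fitLearner(learnerSpec("GLM", seed = 1), d$pres, d$abs)
  expect_true(all(predictProbability(fit, d$pres) >= 0.5))
  expect_true(all(predictProbability(fit, d$abs) < 0.5))
})

test_that("every family is deterministic under its seed", {
  d <- separableTables(n = 25, seed = 3)
  set.seed(99)
  newd <- data.frame(x1 = rnorm(15), x2 = rnorm(15))
  for (fam in learnerFamilies()) {
    f1 <- fitLearner(learnerSpec(fam, seed = 7), d$pres, d$abs)
    p1 <- predictProbability(f1, newd)
    f2 <- fitLearner(learnerSpec(fam, seed = 7), d$pres, d$abs)
    p2 <- predictProbability(f2, newd)
    expect_identical(p1, p2, label = fam)
  }
})

test_that("predictions stay in [0,1] for all families under fuzzed inputs", {
  set.seed(5)
  pres <- data.frame(x1 = rnorm(40, 1), x2 = runif(40) * 100,
                     x3 = rexp(40))
  abs <- data.frame(x1 = rnorm(40, -1), x2 = runif(40) * 100,
                    x3 = rexp(40, 2))
  extreme <- data.frame(x1 = c(-1e4, 1e4, 0), x2 = c(-1e6, 1e6, 50),
                        x3 = c(0, 1e5, 1))
  for (fam in learnerFamilies()) {
    fit <- fitLearner(learnerSpec(fam, seed = 2), pres, abs)
    for (tab in list(pres, abs, extreme)) {
      p <- predictProbability(fit, tab)
      expect_true(all(p >= 0 & p <= 1), label = fam)
    }
  }
})

test_that("training-row predictions are consistent between fit and predict", {
  d <- separableTables(n = 20, seed = 11)
  fit <- fitLearner(learnerSpec("GLM", seed = 1), d$pres, d$abs)
  p1 <- predictProbability(fit, rbind(d$pres, d$abs))
  p2 <- predictProbability(fit, rbind(d$pres, d$abs))
  expect_identical(p1, p2)
  expect_equal(as.numeric(p1[1:20]),
               unname(fitted(fit@fit)[1:20]), tolerance = 1e-12)
})

test_that("rows with missing predictors yield flagged missing outputs", {
  d <- separableTables(n = 20, seed = 2)
  fit <- fitLearner(learnerSpec("RF", seed = 1), d$pres, d$abs)
  tab <- rbind(d$pres[1:3, ], data.frame(x1 = NA, x2 = 1))
  p <- predictProbability(fit, tab)
  expect_true(is.na(p[4]))
  expect_false(anyNA(p[1:3]))
  expect_equal(attr(p, "nMissing"), 1L)
})

test_that("GLM prediction equals the inverse-logit closed form", {
  beta <- c(0.4, -1.2, 2.5)
  fit <- knownGlm(beta, c("x1", "x2"))
  row <- data.frame(x1 = c(0.3, -2, 1.7), x2 = c(1.1, 0, -0.4))
  expected <- plogis(beta[1] + beta[2] * row$x1 + beta[3] * row$x2)
  expect_equal(as.numeric(predictProbability(fit, row)), expected,
               tolerance = 1e-9)
})

test_that("permuted labels give near-chance holdout AUC", {
  # presences and absences from one distribution: no learnable signal
  set.seed(31)
  pool <- data.frame(x1 = rnorm(120), x2 = rnorm(120))
  pres <- pool[1:60, ]
  abs <- pool[61:120, ]
  for (fam in c("GLM", "CTA")) {
    ev <- repeatedHoldout(learnerSpec(fam, seed = 1), pres, list(abs),
                          nRepeats = 20L, seed = 17)
    expect_gt(ev@meanAuc, 0.35)
    expect_lt(ev@meanAuc, 0.65)
  }
})

test_that("degenerate and misconfigured fits fail loudly", {
  d <- separableTables(n = 10)
  expect_error(fitLearner(learnerSpec("GLM"), d$pres[1:3, ], d$abs),
               class = "sdmFitError")
  err <- tryCatch(learnerSpec("XGB"), error = identity)
  expect_s3_class(err, "sdmConfigError")
  expect_match(conditionMessage(err), "ANN")   # lists available families
  expect_error(learnerSpec("RF", list(bogus = 1)), class = "sdmConfigError")
})

test_that("raster prediction equals the point-wise route and keeps the mask", {
  st <- tinyStack(nRows = 7, nCols = 8, layers = c("x1", "x2"), seed = 4,
                  nodataCells = cbind(c(2, 2, 5), c(1, 2, 8)))
  d <- separableTables(n = 25, seed = 6)
  for (fam in c("GLM", "CTA", "MARS")) {
    fit <- fitLearner(learnerSpec(fam, seed = 3), d$pres, d$abs)
    map <- predictRaster(fit, st)
    g <- gridOf(st)
    msk <- envMask(st)
    expect_identical(is.na(envValues(map)), !msk)
    ctr <- EnsembleSDM:::allCellCenters(g)
    tab <- extractAtPoints(st, ctr$lon, ctr$lat)
    pw <- predictProbability(fit, tab)
    expect_equal(as.vector(t(envValues(map)))[tab$valid],
                 as.numeric(pw[tab$valid]), tolerance = 1e-12)
  }
})

test_that("the MARS forward pass recovers a hinge-shaped response", {
  set.seed(13)
  n <- 300
  x <- data.frame(x1 = runif(n, -2, 2), x2 = rnorm(n))
  p <- plogis(3 * pmax(0, x$x1 - 0.5) - 1)
  y <- rbinom(n, 1, p)
  fit <- EnsembleSDM:::fitMarsLogit(x, y)
  xs <- data.frame(x1 = seq(-2, 2, length.out = 50), x2 = 0)
  ph <- EnsembleSDM:::predictMarsLogit(fit, xs)
  # flat below the knot, rising above it
  expect_lt(diff(range(ph[xs$x1 < 0])), 0.15)
  expect_gt(ph[50] - ph[25], 0.3)
})
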