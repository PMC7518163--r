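smallCfg <- function(seed = 1, ...) {
  synthEnvConfig(grid = gridSpec(15, -24, 0.083, 40, 36), seed = seed, ...)
}

test_that("stack generation is deterministic under its seed", {
  s1 <- synthEnvStack(smallCfg(seed = 4))
  s2 <- synthEnvStack(smallCfg(seed = 4))
  expect_identical(lapply(s1@layers, envValues), lapply(s2@layers, envValues))
  s3 <- synthEnvStack(smallCfg(seed = 5))
  expect_false(identical(envValues(s1@layers$sst), envValues(s3@layers$sst)))
})

test_that("the default roster and land mask match the configured recipe", {
  st <- synthEnvStack(synthEnvConfig(seed = 1))
  expect_identical(layerNames(st),
                   c("bathymetry", "slope", "dist_shore", "chl_a", "sst",
                     "salinity", "uo", "vo"))
  msk <- envMask(st)
  expect_true(all(!msk[, 1:12]))    # western land band is nodata everywhere
  expect_true(all(msk[, 13:100]))
})

test_that("latitudinal-gradient layers decrease monotonically southwards", {
  cfg <- smallCfg(seed = 2,
                  recipes = list(sst = list(type = "latgrad", from = 26,
                                            to = 12)),
                  landMask = list(type = "none"))
  st <- synthEnvStack(cfg)
  v <- envValues(st@layers$sst)
  expect_true(all(diff(v[, 1]) < 0))
  expect_equal(v[1, 1], 26)
  expect_equal(v[40, 1], 12)
})

test_that("smoothed fields are autocorrelated; raw noise is not", {
  lag1 <- function(m) {
    a <- as.vector(m[, -ncol(m)]); b <- as.vector(m[, -1])
    cor(a, b)
  }
  acSmooth <- acRaw <- numeric(10)
  for (s in 1:10) {
    cfg <- smallCfg(seed = s,
                    recipes = list(f = list(type = "grf", corLength = 6,
                                            mean = 0, sd = 1)),
                    landMask = list(type = "none"))
    acSmooth[s] <- lag1(envValues(synthEnvStack(cfg)@layers$f))
    set.seed(s)
    acRaw[s] <- lag1(matrix(rnorm(40 * 36), 40, 36))
  }
  expect_true(all(acSmooth > 0.3))
  expect_true(all(abs(acRaw) < 0.15))
})

test_that("suitability peaks at the optimum and falls as the Gaussian form", {
  g <- gridSpec(0, 2, 1, 1, 3)
  sst <- envLayer("sst", g, matrix(c(20, 21.2, 23), 1, 3))
  st <- envStack(sst)
  vs <- virtualSpecies(drivers = list(
    sst = list(type = "gaussian", mu = 20, sd = 1.2)))
  s <- virtualSpeciesSuitability(st, vs)
  expect_equal(s@values[1, 1], 1)
  expect_equal(s@values[1, 2], exp(-0.5), tolerance = 1e-12)  # mu + sigma
})

test_that("non-driver layers have no effect on suitability", {
  st <- synthEnvStack(smallCfg(seed = 3))
  vs <- virtualSpecies()
  s1 <- virtualSpeciesSuitability(st, vs)
  st2 <- st
  st2@layers$salinity@values <- st2@layers$salinity@values + 100
  s2 <- virtualSpeciesSuitability(st2, vs)
  expect_identical(envValues(s1), envValues(s2))
})

test_that("presence sampling follows the suitability weights", {
  g <- gridSpec(0, 1, 1, 1, 2)
  s <- envLayer("s", g, matrix(c(0.8, 0.2), 1, 2))
  occ <- samplePresences(s, 10000, seed = 3)
  share <- mean(occRecords(occ)$lon < 1)
  expect_equal(share, 0.8, tolerance = 0.02)
  # n = 0 gives an empty set; all-zero suitability errors
  expect_equal(nRecords(samplePresences(s, 0)), 0L)
  zero <- envLayer("s", g, matrix(0, 1, 2))
  expect_error(samplePresences(zero, 5), class = "sdmSamplingError")
})

test_that("sampled records land on valid cells with in-season dates", {
  st <- synthEnvStack(smallCfg(seed = 6))
  vs <- virtualSpecies()
  tr <- virtualSpeciesSuitability(st, vs)
  occ <- samplePresences(tr, 200, seed = 9, season = "winter")
  r <- occRecords(occ)
  idx <- cellFromLonLat(gridOf(st), r$lon, r$lat)
  expect_false(anyNA(idx$cell))
  expect_true(all(envMask(st)[cbind(idx$row, idx$col)]))
  months <- as.integer(format(r$date, "%m"))
  expect_true(all(months %in% 4:9))
  expect_identical(unique(r$source), "synthetic")
})

test_that("coastal bias pulls samples towards the coast", {
  st <- synthEnvStack(synthEnvConfig(seed = 2))
  vs <- virtualSpecies()
  tr <- virtualSpeciesSuitability(st, vs)
  dl <- st@layers$dist_shore
  medDist <- function(occ) {
    tab <- extractAtPoints(st, occRecords(occ)$lon, occRecords(occ)$lat)
    median(tab$dist_shore)
  }
  closer <- logical(5)
  for (s in 1:5) {
    plain <- samplePresences(tr, 250, seed = 100 + s)
    biased <- samplePresences(tr, 250, bias = list(lambda = 60),
                              distLayer = dl, seed = 100 + s)
    closer[s] <- medDist(biased) < medDist(plain)
  }
  expect_true(all(closer))
})

test_that("shrinking the sample degrades holdout AUC on average", {
  aucAt <- function(n, s) {
    cfg <- synthEnvConfig(seed = s)
    st <- synthEnvStack(cfg)
    tr <- virtualSpeciesSuitability(st, virtualSpecies())
    occ <- samplePresences(tr, n, seed = 300 + s)
    th <- thinToGrid(occ, gridOf(st))
    p <- occRecords(th)
    pt <- extractAtPoints(st, p$lon, p$lat)
    pt <- pt[pt$valid, , drop = FALSE]
    draws <- drawReplicates(designForFamily("GLM", seed = 400 + s), st, th)
    paT <- lapply(draws[1:3], function(d) {
      x <- extractAtPoints(st, d$lon, d$lat)
      x[x$valid, , drop = FALSE]
    })
    repeatedHoldout(learnerSpec("GLM", seed = 2), pt, paT, nRepeats = 3L,
                    seed = 500 + s)@meanAuc
  }
  big <- vapply(1:5, function(s) aucAt(300, s), numeric(1))
  small <- vapply(1:5, function(s) aucAt(30, s), numeric(1))
  expect_gt(mean(big), mean(small))
})
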