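# brute-force centre-lookup oracle for nearest-neighbour resampling
bruteResample <- function(layer, target) {
  out <- matrix(NA_real_, target@nRows, target@nCols)
  sg <- layer@grid
  for (r in seq_len(target@nRows)) for (c in seq_len(target@nCols)) {
    lon <- target@originLon + (c - 0.5) * target@res
    lat <- target@originLat - (r - 0.5) * target@res
    for (sr in seq_len(sg@nRows)) for (sc in seq_len(sg@nCols)) {
      inLon <- lon >= sg@originLon + (sc - 1) * sg@res &&
               lon < sg@originLon + sc * sg@res
      inLat <- lat > sg@originLat - sr * sg@res &&
               lat <= sg@originLat - (sr - 1) * sg@res
      if (inLon && inLat) out[r, c] <- layer@values[sr, sc]
    }
  }
  out
}

test_that("resampling a layer onto its own grid is the identity", {
  st <- tinyStack(nodataCells = cbind(c(2, 5), c(3, 1)))
  l <- st@layers$a
  expect_identical(envValues(resampleNearest(l, gridOf(st))), envValues(l))
})

test_that("upsampling 2x2 to half the cell size yields 2x2 blocks", {
  g <- gridSpec(0, 4, 2, 2, 2)
  l <- envLayer("x", g, matrix(c(1, 3, 2, NA), 2, 2))
  t <- gridSpec(0, 4, 1, 4, 4)
  r <- resampleNearest(l, t)
  expect_equal(envValues(r),
               matrix(c(1, 1, 3, 3,
                        1, 1, 3, 3,
                        2, 2, NA, NA,
                        2, 2, NA, NA), 4, 4))
})

test_that("nearest-neighbour resampling matches the brute-force oracle", {
  for (seed in 1:3) {
    set.seed(seed)
    g <- gridSpec(runif(1, -10, 0), runif(1, 0, 10), 0.7, 20, 20)
    m <- matrix(rnorm(400), 20, 20)
    m[sample(400, 30)] <- NA
    l <- envLayer("x", g, m)
    t <- gridSpec(g@originLon + runif(1, -1, 1), g@originLat + runif(1, -1, 1),
                  0.45, 20, 20)
    expect_equal(envValues(resampleNearest(l, t)), bruteResample(l, t))
  }
})

test_that("disjoint source and target extents raise an extent error", {
  l <- envLayer("x", gridSpec(0, 0, 1, 2, 2), matrix(1, 2, 2))
  expect_error(resampleNearest(l, gridSpec(50, 50, 1, 2, 2)),
               class = "sdmExtentError")
})

test_that("clipping to the full extent is the identity", {
  st <- tinyStack()
  e <- gridExtent(gridOf(st))
  cl <- clipToExtent(st, e["lonMin"], e["lonMax"], e["latMin"], e["latMax"])
  expect_identical(lapply(cl@layers, envValues), lapply(st@layers, envValues))
})

test_that("clipping a 10x10 grid to its NW quadrant keeps the right corner", {
  g <- gridSpec(0, 10, 1, 10, 10)
  m <- matrix(as.numeric(seq_len(100)), 10, 10)
  st <- envStack(envLayer("x", g, m))
  cl <- clipToExtent(st, 0, 5, 5, 10)
  gg <- gridOf(cl)
  expect_equal(c(gg@nRows, gg@nCols), c(5L, 5L))
  expect_equal(c(gg@originLon, gg@originLat), c(0, 10))
  expect_identical(envValues(cl@layers$x), m[1:5, 1:5])
})

test_that("nested clips collapse to one clip with the inner box", {
  st <- tinyStack(nRows = 12, nCols = 14)
  a <- clipToExtent(st, 10.5, 15.9, -25.5, -20.4)
  ab <- clipToExtent(a, 11.2, 14.1, -24.4, -21.3)
  b <- clipToExtent(st, 11.2, 14.1, -24.4, -21.3)
  expect_identical(envValues(ab@layers$a), envValues(b@layers$a))
  expect_identical(unname(EnsembleSDM:::gridKey(gridOf(ab))),
                   unname(EnsembleSDM:::gridKey(gridOf(b))))
})

test_that("the southern-African study box spans 80 deg lon by 22 deg lat", {
  # synthetic 1-degree global grid clipped to 0-80E / 38-16S
  g <- gridSpec(-180, 90, 1, 180, 360)
  st <- envStack(envLayer("x", g, matrix(0, 180, 360)))
  cl <- clipToExtent(st, 0, 80, -38, -16)
  gg <- gridOf(cl)
  expect_equal(gg@nCols * gg@res, 80)
  expect_equal(gg@nRows * gg@res, 22)
})

test_that("seasonal means average matching months and skip nodata per cell", {
  g <- gridSpec(0, 2, 1, 2, 2)
  mk <- function(v) envLayer("chl_a", g, matrix(v, 2, 2))
  # single matching month: identity
  out <- seasonalMean(list(mk(4), mk(9)), month = c(11, 5),
                      year = c(2004, 2004), season = "summer")
  expect_equal(envValues(out), matrix(4, 2, 2))
  # two matching months average
  out <- seasonalMean(list(mk(10), mk(20)), month = c(11, 12),
                      year = c(2004, 2004), season = "summer")
  expect_equal(envValues(out), matrix(15, 2, 2))
  # a nodata month at one cell: mean of the finite rest
  ms <- lapply(c(1, 2, 3, 10, 11, 12), function(i) mk(i))
  ms[[2]]@values[1, 1] <- NA
  out <- seasonalMean(ms, month = c(1, 2, 3, 10, 11, 12), year = rep(2004, 6),
                      season = "summer")
  expect_equal(out@values[1, 1], mean(c(1, 3, 10, 11, 12)))
  expect_equal(out@values[2, 2], mean(c(1, 2, 3, 10, 11, 12)))
  # no matching layers
  expect_error(seasonalMean(list(mk(1)), month = 5, year = 2004,
                            season = "summer"), class = "sdmSelectionError")
})

test_that("point extraction agrees with a per-point scan of all cells", {
  set.seed(11)
  st <- tinyStack(nRows = 8, nCols = 9, nodataCells = cbind(3, 4))
  g <- gridOf(st)
  e <- gridExtent(g)
  lon <- runif(100, e["lonMin"] - 0.3, e["lonMax"] + 0.3)
  lat <- runif(100, e["latMin"] - 0.3, e["latMax"] + 0.3)
  tab <- extractAtPoints(st, lon, lat)
  for (i in seq_len(100)) {
    found <- NA_real_
    for (r in seq_len(g@nRows)) for (c in seq_len(g@nCols)) {
      if (lon[i] >= g@originLon + (c - 1) * g@res &&
          lon[i] < g@originLon + c * g@res &&
          lat[i] > g@originLat - r * g@res &&
          lat[i] <= g@originLat - (r - 1) * g@res)
        found <- st@layers$a@values[r, c]
    }
    expect_identical(tab$a[i], found)
  }
  expect_identical(tab$inExtent, !is.na(cellFromLonLat(g, lon, lat)$cell))
})

test_that("a point at a centre reads that cell; edge points go east/south", {
  st <- tinyStack(nRows = 3, nCols = 3, res = 1, originLon = 0,
                  originLat = 3)
  v <- envValues(st@layers$a)
  expect_equal(extractAtPoints(st, 1.5, 1.5)$a, v[2, 2])
  # vertical shared edge -> east cell; horizontal -> south cell
  expect_equal(extractAtPoints(st, 2, 1.5)$a, v[2, 3])
  expect_equal(extractAtPoints(st, 1.5, 1)$a, v[3, 2])
})

test_that("VIF matches the closed form 1/(1-r^2) for two variables", {
  # engineered sample correlation of 0.9
  n <- 200
  set.seed(3)
  x <- rnorm(n)
  yr <- rnorm(n)
  y <- 0.9 * scale(x)[, 1] + sqrt(1 - 0.81) *
    scale(stats::residuals(lm(yr ~ x)))[, 1]
  tab <- data.frame(a = x, b = y)
  r2 <- cor(tab$a, tab$b)^2
  rep <- vifScreen(tab, threshold = 3)
  expect_equal(unname(rep$vif["a"]), 1 / (1 - r2), tolerance = 1e-12)
  expect_equal(unname(rep$vif["b"]), 1 / (1 - r2), tolerance = 1e-12)
  expect_equal(abs(cor(tab$a, tab$b)), 0.9, tolerance = 1e-12)
  expect_true(all(rep$vif > 3))
  expect_identical(rep$retained, character(0))

  # property: random two-variable instances match the closed form to 1e-9
  for (seed in 1:10) {
    set.seed(seed)
    a <- rnorm(50); b <- 0.3 * a + rnorm(50)
    rep <- vifScreen(data.frame(a = a, b = b))
    expect_equal(unname(rep$vif["a"]), 1 / (1 - cor(a, b)^2),
                 tolerance = 1e-9)
  }
})

test_that("orthogonal predictors all score VIF 1 and are retained", {
  set.seed(2)
  # columns orthogonal to each other AND to the intercept -> VIF exactly 1
  x <- qr.Q(qr(cbind(1, matrix(rnorm(64), 16, 4))))[, 2:5]
  tab <- as.data.frame(x)
  rep <- vifScreen(tab)
  expect_equal(unname(rep$vif), rep(1, 4), tolerance = 1e-9)
  expect_identical(rep$retained, names(tab))
})

test_that("weakly correlated eight-predictor sets pass the screen at 3", {
  set.seed(21)
  n <- 300
  # independent noise plus a weak shared factor: pairwise r around 0.2
  x <- matrix(rnorm(n * 8), n, 8) + 0.5 * rnorm(n)
  tab <- as.data.frame(x)
  names(tab) <- c("bathymetry", "slope", "dist_shore", "chl_a", "sst",
                  "salinity", "uo", "vo")
  cors <- cor(tab)
  expect_true(all(abs(cors[upper.tri(cors)]) < 0.4))
  rep <- vifScreen(tab, threshold = 3)
  expect_identical(rep$retained, names(tab))
  expect_length(rep$dropped, 0)
})

test_that("a perfectly collinear column reports infinite VIF and is dropped", {
  set.seed(5)
  a <- rnorm(40); b <- rnorm(40)
  rep <- vifScreen(data.frame(a = a, b = b, c = a + b))
  expect_true(all(is.infinite(rep$vif)))
  expect_identical(rep$retained, character(0))
})

test_that("VIF agrees with the car package on a shared fixture", {
  set.seed(9)
  d <- as.data.frame(matrix(rnorm(300), 100, 3))
  d <- transform(d, V4 = 0.6 * V1 + 0.4 * V2 + rnorm(100, sd = 0.5))
  y <- rnorm(100)
  ours <- vifScreen(d)$vif
  theirs <- car::vif(lm(y ~ ., data = d))
  expect_equal(unname(ours), unname(theirs[names(ours)]), tolerance = 1e-8)
})
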