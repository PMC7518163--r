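# Virtual species and synthetic environments.
#
# Generates multi-layer predictor stacks on a regular lat/lon grid with a
# land mask and spatial autocorrelation, plus presence-only samples drawn
# from a known parametric niche -- the ground truth against which the whole
# modelling workflow is validated.

#' Synthetic environment configuration
#'
#' The default configuration mirrors the eight-predictor marine roster
#' (bathymetry, slope, dist_shore, chl_a, sst, salinity, uo, vo) on a
#' 120 x 100 cell grid at 0.083 degrees with a western land band, so that
#' run configurations transfer verbatim between synthetic and real inputs.
#'
#' Layer recipe types: `latgrad` (north-to-south gradient, optional
#' autocorrelated noise), `grf` (kernel-smoothed Gaussian random field with
#' a correlation length in cells), `distEdge` (distance to the land mask in
#' km), `constNoise` (constant plus white noise).
#'
#' @param grid a [GridSpec].
#' @param recipes named list of layer recipes.
#' @param landMask land-mask recipe, e.g. `list(type = "westBand", k = 12)`.
#' @param seed integer seed; generation is deterministic given it.
#' @return list of class `SyntheticEnvConfig`.
#' @export
synthEnvConfig <- function(
    grid = gridSpec(15, -24, 0.083, 120, 100),
    recipes = list(
      bathymetry = list(type = "grf", corLength = 8, mean = -2500, sd = 1200),
      slope = list(type = "grf", corLength = 4, mean = 3, sd = 2),
      dist_shore = list(type = "distEdge"),
      chl_a = list(type = "grf", corLength = 6, mean = 0.7, sd = 0.35,
                   min = 0.02),
      sst = list(type = "latgrad", from = 26, to = 12, noiseSd = 0.8,
                 corLength = 6),
      salinity = list(type = "grf", corLength = 8, mean = 35, sd = 0.4),
      uo = list(type = "grf", corLength = 6, mean = 0, sd = 0.15),
      vo = list(type = "grf", corLength = 6, mean = 0, sd = 0.15)),
    landMask = list(type = "westBand", k = 12L),
    seed = 1L) {
  for (nm in names(recipes)) {
    r <- recipes[[nm]]
    if (!r$type %in% c("latgrad", "grf", "distEdge", "constNoise"))
      sdmStop("sdmConfigError", "unknown recipe type '%s' for layer %s",
              r$type, nm)
    if (!is.null(r$corLength) && r$corLength <= 0)
      sdmStop("sdmConfigError", "corLength must be > 0 (layer %s)", nm)
  }
  structure(list(grid = grid, recipes = recipes, landMask = landMask,
                 seed = as.integer(seed)),
            class = "SyntheticEnvConfig")
}

# separable Gaussian kernel smoothing with edge renormalisation
smoothField <- function(m, corLength) {
  gauss <- function(n) {
    S <- outer(seq_len(n), seq_len(n),
               function(i, j) exp(-0.5 * ((i - j) / corLength)^2))
    S / rowSums(S)
  }
  gauss(nrow(m)) %*% m %*% t(gauss(ncol(m)))
}

# two-pass chamfer distance transform (cell units) to the land mask
distToLand <- function(land) {
  nr <- nrow(land); nc <- ncol(land)
  if (!any(land)) {
    # no land: fall back to distance to the western grid edge
    return(matrix(rep(seq_len(nc) - 0.5, each = nr), nr, nc))
  }
  D <- matrix(Inf, nr, nc)
  D[land] <- 0
  s2 <- sqrt(2)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (r > 1) D[r, c] <- min(D[r, c], D[r - 1, c] + 1)
    if (c > 1) D[r, c] <- min(D[r, c], D[r, c - 1] + 1)
    if (r > 1 && c > 1) D[r, c] <- min(D[r, c], D[r - 1, c - 1] + s2)
    if (r > 1 && c < nc) D[r, c] <- min(D[r, c], D[r - 1, c + 1] + s2)
  }
  for (r in rev(seq_len(nr))) for (c in rev(seq_len(nc))) {
    if (r < nr) D[r, c] <- min(D[r, c], D[r + 1, c] + 1)
    if (c < nc) D[r, c] <- min(D[r, c], D[r, c + 1] + 1)
    if (r < nr && c < nc) D[r, c] <- min(D[r, c], D[r + 1, c + 1] + s2)
    if (r < nr && c > 1) D[r, c] <- min(D[r, c], D[r + 1, c - 1] + s2)
  }
  D
}

#' Generate a synthetic environmental stack
#'
#' Builds every configured layer, applies the land mask (land cells are
#' nodata in all layers), and returns an aligned [EnvStack]. Deterministic
#' under the configured seed. Autocorrelated layers are built by
#' kernel-smoothing white noise and rescaling to the requested mean/sd.
#'
#' @param config a [synthEnvConfig()].
#' @return an [EnvStack].
#' @export
synthEnvStack <- function(config) {
  stopifnot(inherits(config, "SyntheticEnvConfig"))
  g <- config$grid
  nr <- g@nRows; nc <- g@nCols
  land <- switch(config$landMask$type,
    westBand = {
      m <- matrix(FALSE, nr, nc)
      m[, seq_len(min(config$landMask$k, nc))] <- TRUE
      m
    },
    none = matrix(FALSE, nr, nc),
    sdmStop("sdmConfigError", "unknown land-mask type '%s'",
            config$landMask$type))
  set.seed(config$seed)
  kmPerCell <- g@res * 111.32
  layers <- vector("list", length(config$recipes))
  names(layers) <- names(config$recipes)
  for (nm in names(config$recipes)) {
    r <- config$recipes[[nm]]
    m <- switch(r$type,
      latgrad = {
        base <- matrix(rep(seq(r$from, r$to, length.out = nr), nc), nr, nc)
        if (!is.null(r$noiseSd) && r$noiseSd > 0) {
          z <- smoothField(matrix(stats::rnorm(nr * nc), nr, nc),
                           r$corLength)
          base <- base + r$noiseSd * (z - mean(z)) / stats::sd(z)
        }
        base
      },
      grf = {
        z <- smoothField(matrix(stats::rnorm(nr * nc), nr, nc), r$corLength)
        z <- r$mean + r$sd * (z - mean(z)) / stats::sd(z)
        if (!is.null(r$min)) z <- pmax(z, r$min)
        if (!is.null(r$max)) z <- pmin(z, r$max)
        z
      },
      distEdge = distToLand(land) * kmPerCell,
      constNoise = r$value + matrix(stats::rnorm(nr * nc, sd = r$sd), nr, nc))
    m[land] <- NA
    layers[[nm]] <- envLayer(nm, g, m)
  }
  envStack(layers)
}

#' Define a virtual species
#'
#' A parametric niche over a subset of predictors (the drivers); the other
#' layers have no effect on suitability. Per-driver responses are Gaussian
#' (optimum `mu`, breadth `sd`) or logistic (midpoint, slope).
#'
#' @param drivers named list of responses, e.g.
#'   `list(sst = list(type = "gaussian", mu = 20, sd = 2.5))`.
#' @param nPresences number of presence records to sample.
#' @param bias `NULL` (uniform effort) or `list(lambda = <km>)` for
#'   coast-biased effort decaying as `exp(-dist / lambda)`.
#' @param seed sampling seed.
#' @return list of class `VirtualSpecies`.
#' @export
virtualSpecies <- function(
    drivers = list(sst = list(type = "gaussian", mu = 20, sd = 1.2),
                   chl_a = list(type = "gaussian", mu = 0.8, sd = 0.15)),
    nPresences = 300L, bias = NULL, seed = 1L) {
  for (nm in names(drivers))
    if (!drivers[[nm]]$type %in% c("gaussian", "logistic"))
      sdmStop("sdmConfigError", "unknown response type for driver %s", nm)
  structure(list(drivers = drivers, nPresences = as.integer(nPresences),
                 bias = bias, seed = as.integer(seed)),
            class = "VirtualSpecies")
}

#' True suitability surface of a virtual species
#'
#' Cellwise product of the per-driver responses, rescaled so the maximum
#' over valid cells is 1.
#'
#' @param stack an [EnvStack] containing every driver layer.
#' @param species a [virtualSpecies()].
#' @return a suitability [EnvLayer] in `[0, 1]`.
#' @export
virtualSpeciesSuitability <- function(stack, species) {
  miss <- setdiff(names(species$drivers), layerNames(stack))
  if (length(miss))
    sdmStop("sdmConfigError", "driver layer(s) missing from stack: %s",
            paste(miss, collapse = ", "))
  g <- gridOf(stack)
  s <- matrix(1, g@nRows, g@nCols)
  for (nm in names(species$drivers)) {
    d <- species$drivers[[nm]]
    x <- stack@layers[[nm]]@values
    resp <- switch(d$type,
      gaussian = exp(-0.5 * ((x - d$mu) / d$sd)^2),
      logistic = stats::plogis(d$slope * (x - d$mid)))
    s <- s * resp
  }
  s[!envMask(stack)] <- NA
  mx <- max(s, na.rm = TRUE)
  if (mx <= 0) sdmStop("sdmConfigError", "suitability is zero everywhere")
  envLayer("true_suitability", g, s / mx, units = "probability")
}

#' Sample presence-only records from a suitability surface
#'
#' Cells are drawn (with replacement -- repeat sightings of good habitat
#' are the norm in opportunistic data) with probability proportional to
#' suitability times the effort weight; each record is placed uniformly
#' within its cell. Dates are uniform over the season window's months in
#' `yearRange`; the source label is `"synthetic"`.
#'
#' @param suitability a suitability [EnvLayer] (e.g. from
#'   [virtualSpeciesSuitability()]).
#' @param n number of records.
#' @param bias `NULL` or `list(lambda = <km>)`; requires `distLayer`.
#' @param distLayer [EnvLayer] of distances to the coast in km (used only
#'   with `bias`).
#' @param seed sampling seed.
#' @param species species label for the records.
#' @param season `"summer"` or `"winter"` sampling window.
#' @param yearRange two-element integer vector of sampling years.
#' @return an [OccurrenceSet] (unthinned).
#' @export
samplePresences <- function(suitability, n, bias = NULL, distLayer = NULL,
                            seed = 1L, species = "virtual species",
                            season = "summer", yearRange = c(2010L, 2016L)) {
  g <- suitability@grid
  s <- suitability@values
  w <- s
  if (!is.null(bias)) {
    if (is.null(distLayer))
      sdmStop("sdmConfigError", "coastal bias needs a distance layer")
    w <- w * exp(-distLayer@values / bias$lambda)
  }
  ok <- which(!is.na(w) & w > 0)
  if (n > 0 && !length(ok))
    sdmStop("sdmSamplingError", "suitability is zero on every valid cell")
  set.seed(seed)
  if (n > 0) {
    cells <- sample(ok, n, replace = TRUE, prob = w[ok])
    row <- (cells - 1L) %% g@nRows + 1L    # `which` on a matrix: col-major
    col <- (cells - 1L) %/% g@nRows + 1L
    lon <- g@originLon + (col - 1 + stats::runif(n)) * g@res
    lat <- g@originLat - (row - 1 + stats::runif(n)) * g@res
    months <- if (season == "summer") c(10:12, 1:3) else 4:9
    date <- as.Date(sprintf("%d-%02d-%02d",
                            sample(yearRange[1]:yearRange[2], n, TRUE),
                            sample(months, n, TRUE),
                            sample(28, n, TRUE)))
    rec <- data.frame(species = species, lon = lon, lat = lat, date = date,
                      source = "synthetic", stringsAsFactors = FALSE)
  } else {
    rec <- data.frame(species = character(), lon = numeric(),
                      lat = numeric(), date = as.Date(character()),
                      source = character(), stringsAsFactors = FALSE)
  }
  occurrenceSet(species, rec, season = season)
}
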