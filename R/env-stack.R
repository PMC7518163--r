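# Predictor preparation: alignment, clipping, seasonal averaging, point
# extraction and collinearity screening.

#' Nearest-neighbour resampling
#'
#' Resamples a layer onto a target grid: each target cell takes the value of
#' the source cell that contains the target cell's centre (half-open cell
#' convention). Target centres falling outside the source extent, or inside
#' source nodata cells, become nodata. Resampling a layer onto its own grid
#' is the identity.
#'
#' @param layer source [EnvLayer].
#' @param target target [GridSpec].
#' @return an [EnvLayer] on `target`.
#' @export
resampleNearest <- function(layer, target) {
  stopifnot(is(layer, "EnvLayer"), is(target, "GridSpec"))
  es <- gridExtent(layer@grid); et <- gridExtent(target)
  if (es["lonMin"] >= et["lonMax"] || et["lonMin"] >= es["lonMax"] ||
      es["latMin"] >= et["latMax"] || et["latMin"] >= es["latMax"])
    sdmStop("sdmExtentError", "source and target grids do not overlap")
  ctr <- allCellCenters(target)
  idx <- cellFromLonLat(layer@grid, ctr$lon, ctr$lat)
  vals <- rep(NA_real_, nrow(ctr))
  ok <- !is.na(idx$row)
  vals[ok] <- layer@values[cbind(idx$row[ok], idx$col[ok])]
  m <- matrix(vals, nrow = target@nRows, ncol = target@nCols, byrow = TRUE)
  envLayer(layer@name, target, m, units = layer@units)
}

#' Clip a stack to a bounding box
#'
#' Keeps exactly the cells whose centres fall inside the (closed) box; all
#' layers are clipped identically so the result is a valid aligned stack.
#'
#' @param stack an [EnvStack].
#' @param lonMin,lonMax,latMin,latMax box edges in decimal degrees.
#' @return the clipped [EnvStack].
#' @export
clipToExtent <- function(stack, lonMin, lonMax, latMin, latMax) {
  stopifnot(is(stack, "EnvStack"))
  g <- gridOf(stack)
  rows <- seq_len(g@nRows); cols <- seq_len(g@nCols)
  cLon <- g@originLon + (cols - 0.5) * g@res
  cLat <- g@originLat - (rows - 0.5) * g@res
  keepC <- which(cLon >= lonMin & cLon <= lonMax)
  keepR <- which(cLat >= latMin & cLat <= latMax)
  if (!length(keepC) || !length(keepR))
    sdmStop("sdmExtentError", "clip box contains no cell centres")
  ng <- gridSpec(g@originLon + (min(keepC) - 1) * g@res,
                 g@originLat - (min(keepR) - 1) * g@res,
                 g@res, length(keepR), length(keepC))
  envStack(lapply(stack@layers, function(l)
    envLayer(l@name, ng, l@values[keepR, keepC, drop = FALSE],
             units = l@units)))
}

#' Seasonal climatology of monthly layers
#'
#' Cellwise arithmetic mean over the monthly layers whose month falls in the
#' season and whose year falls in `years`. Nodata months are ignored per
#' cell; a cell is nodata only when every contributing month is nodata.
#'
#' @param layers list of [EnvLayer], all on one grid.
#' @param month,year integer vectors tagging each layer.
#' @param season `"summer"` (Oct-Mar) or `"winter"` (Apr-Sep); see
#'   [seasonOfMonth()].
#' @param years years to include (default: all present).
#' @return an [EnvLayer] named after the first input layer.
#' @export
seasonalMean <- function(layers, month, year, season,
                         years = sort(unique(year))) {
  stopifnot(length(layers) == length(month), length(month) == length(year))
  g <- layers[[1]]@grid
  for (l in layers)
    if (!sameGrid(l@grid, g))
      sdmStop("sdmExtentError", "monthly layers are not on one grid")
  sel <- seasonOfMonth(month) == season & year %in% years
  if (!any(sel))
    sdmStop("sdmSelectionError",
            "no layer matches season '%s' in the given years", season)
  arr <- layerArray(lapply(layers[sel], function(l) l@values))
  n <- apply(!is.na(arr), c(1, 2), sum)
  s <- apply(arr, c(1, 2), function(v) sum(v, na.rm = TRUE))
  m <- ifelse(n > 0, s / n, NA_real_)
  envLayer(layers[[which(sel)[1]]]@name, g, m,
           units = layers[[which(sel)[1]]]@units)
}

#' Extract predictor values at points
#'
#' Reads, for each point, the values of every stack layer from the cell
#' containing the point (half-open convention: a point on a shared edge
#' belongs to the east/south cell). Points outside the grid extent or on
#' invalid (nodata) cells are flagged, not dropped.
#'
#' @param stack an [EnvStack].
#' @param lon,lat point coordinates.
#' @return data.frame with columns `lon`, `lat`, one column per layer
#'   (`NA` outside/invalid), plus logicals `inExtent` and `valid`.
#' @export
extractAtPoints <- function(stack, lon, lat) {
  stopifnot(is(stack, "EnvStack"), length(lon) == length(lat))
  g <- gridOf(stack)
  idx <- cellFromLonLat(g, lon, lat)
  out <- data.frame(lon = lon, lat = lat)
  ok <- !is.na(idx$row)
  for (l in stack@layers) {
    v <- rep(NA_real_, length(lon))
    v[ok] <- l@values[cbind(idx$row[ok], idx$col[ok])]
    out[[l@name]] <- v
  }
  msk <- envMask(stack)
  valid <- rep(FALSE, length(lon))
  valid[ok] <- msk[cbind(idx$row[ok], idx$col[ok])]
  out$inExtent <- ok
  out$valid <- valid
  out
}

#' Variance-inflation-factor collinearity screen
#'
#' Computes, for every variable j, `VIF_j = 1 / (1 - R_j^2)` where `R_j^2`
#' comes from the linear regression of variable j on all the others, and
#' retains the variables whose VIF is strictly below the threshold
#' (default 3). A perfectly collinear variable (R^2 = 1) is reported as
#' infinite and dropped.
#'
#' @param table data.frame of predictor columns (any `lon`/`lat`/flag
#'   columns are ignored); rows with missing values are dropped.
#' @param threshold retention threshold; strict comparison.
#' @return list of class `VifReport`: `vif` (named numeric), `threshold`,
#'   `retained`, `dropped`, `nRows` used.
#' @export
vifScreen <- function(table, threshold = 3) {
  vars <- setdiff(names(table), c("lon", "lat", "inExtent", "valid"))
  x <- table[vars]
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (length(vars) < 2)
    sdmStop("sdmConfigError", "vifScreen needs at least two variables")
  if (nrow(x) < length(vars) + 2)
    sdmStop("sdmConfigError",
            "vifScreen needs at least n_vars + 2 complete rows")
  vif <- vapply(vars, function(v) {
    fit <- stats::lm(stats::reformulate(setdiff(vars, v), response = v),
                     data = x)
    r2 <- suppressWarnings(summary(fit)$r.squared)  # perfect-fit chatter
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  structure(list(vif = vif, threshold = threshold,
                 retained = vars[vif < threshold],
                 dropped = vars[!(vif < threshold)],
                 nRows = nrow(x)),
            class = "VifReport")
}

#' @export
print.VifReport <- function(x, ...) {
  cat(sprintf("VIF screen (threshold %g, %d rows):\n", x$threshold, x$nRows))
  for (v in names(x$vif))
    cat(sprintf("  %-12s %8.3f  %s\n", v, x$vif[[v]],
                if (v %in% x$retained) "retained" else "dropped"))
  invisible(x)
}

#' Select a subset of layers
#'
#' @param stack an [EnvStack].
#' @param names layer names to keep, in the given order.
#' @return an [EnvStack].
#' @export
subsetStack <- function(stack, names) {
  missing <- setdiff(names, layerNames(stack))
  if (length(missing))
    sdmStop("sdmConfigError", "no such layer(s): %s",
            paste(missing, collapse = ", "))
  envStack(stack@layers[names])
}

#' Read a directory of rasters as a stack
#'
#' Reads every `.tif`/`.tiff`/`.asc` file in a directory as one layer
#' (named after the filename stem) and assembles them into an [EnvStack].
#'
#' @param dir directory path.
#' @param units optional named character vector of unit labels.
#' @return an [EnvStack].
#' @export
readEnvStack <- function(dir, units = character()) {
  files <- list.files(dir, pattern = "\\.(tif|tiff|asc)$", full.names = TRUE,
                      ignore.case = TRUE)
  if (!length(files))
    sdmStop("sdmFormatError", "no raster files found in %s", dir)
  layers <- lapply(files, function(f) {
    nm <- sub("\\.[^.]*$", "", basename(f))
    u <- if (nm %in% names(units)) units[[nm]] else ""
    readRasterLayer(f, name = nm, units = u)
  })
  envStack(layers)
}

#' Export a predictor table as CSV
#'
#' Writes `lon, lat` followed by one column per predictor.
#'
#' @param table a predictor table from [extractAtPoints()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePredictorTable <- function(table, path) {
  drop <- intersect(c("inExtent", "valid"), names(table))
  utils::write.csv(table[setdiff(names(table), drop)], path,
                   row.names = FALSE)
  invisible(path)
}
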