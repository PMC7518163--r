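# Grid geometry: constructors, accessors and the half-open cell convention.

#' Construct a GridSpec
#'
#' @param originLon,originLat west edge / north edge in decimal degrees.
#' @param res cell size in decimal degrees.
#' @param nRows,nCols grid dimensions.
#' @param datum datum label (geographic WGS84 assumed).
#' @return a [GridSpec].
#' @examples
#' gridSpec(0, 0, res = 1, nRows = 10, nCols = 20)
#' @export
gridSpec <- function(originLon, originLat, res, nRows, nCols,
                     datum = "WGS84") {
  new("GridSpec", originLon = as.numeric(originLon),
      originLat = as.numeric(originLat), res = as.numeric(res),
      nRows = as.integer(nRows), nCols = as.integer(nCols), datum = datum)
}

# numeric fingerprint used to test grid identity
gridKey <- function(g) {
  c(g@originLon, g@originLat, g@res, g@nRows, g@nCols)
}

sameGrid <- function(a, b) identical(unname(gridKey(a)), unname(gridKey(b)))

#' Construct an EnvLayer
#'
#' @param name layer name.
#' @param grid a [GridSpec].
#' @param values numeric matrix (`nRows x nCols`), `NA` = nodata.
#' @param units unit label.
#' @return an [EnvLayer].
#' @export
envLayer <- function(name, grid, values, units = "") {
  storage.mode(values) <- "double"
  new("EnvLayer", name = name, units = units, grid = grid, values = values)
}

#' Construct an EnvStack
#'
#' @param ... [EnvLayer] objects, or a single list of them.
#' @return an [EnvStack].
#' @export
envStack <- function(...) {
  ls <- list(...)
  if (length(ls) == 1L && is.list(ls[[1]]) && !is(ls[[1]], "EnvLayer"))
    ls <- ls[[1]]
  names(ls) <- vapply(ls, function(l) l@name, character(1))
  new("EnvStack", layers = ls)
}

#' @rdname gridOf
#' @export
setGeneric("gridOf", function(x) standardGeneric("gridOf"))

#' Grid of a raster object
#'
#' @param x an [EnvLayer] or [EnvStack].
#' @return the shared [GridSpec].
#' @export
setMethod("gridOf", "EnvLayer", function(x) x@grid)

#' @rdname gridOf
#' @export
setMethod("gridOf", "EnvStack", function(x) x@layers[[1]]@grid)

#' @rdname layerNames
#' @export
setGeneric("layerNames", function(x) standardGeneric("layerNames"))

#' Layer names of a stack
#'
#' @param x an [EnvStack].
#' @return character vector of layer names, in stack order.
#' @export
setMethod("layerNames", "EnvStack", function(x) names(x@layers))

#' @rdname envValues
#' @export
setGeneric("envValues", function(x) standardGeneric("envValues"))

#' Raw value matrix of a layer
#'
#' @param x an [EnvLayer].
#' @return the numeric value matrix (`NA` = nodata).
#' @export
setMethod("envValues", "EnvLayer", function(x) x@values)

#' @rdname envMask
#' @export
setGeneric("envMask", function(x) standardGeneric("envMask"))

#' Validity mask
#'
#' For a layer, `TRUE` where the cell is finite; for a stack, the
#' conjunction over all layers (a cell is valid iff no layer is nodata
#' there).
#'
#' @param x an [EnvLayer] or [EnvStack].
#' @return logical matrix of dimension `nRows x nCols`.
#' @export
setMethod("envMask", "EnvLayer", function(x) !is.na(x@values))

#' @rdname envMask
#' @export
setMethod("envMask", "EnvStack", function(x) {
  Reduce(`&`, lapply(x@layers, function(l) !is.na(l@values)))
})

#' Extent of a grid
#'
#' @param g a [GridSpec].
#' @return named vector `lonMin, lonMax, latMin, latMax` (outer cell edges).
#' @export
gridExtent <- function(g) {
  c(lonMin = g@originLon, lonMax = g@originLon + g@nCols * g@res,
    latMin = g@originLat - g@nRows * g@res, latMax = g@originLat)
}

#' Map points to grid cells (half-open convention)
#'
#' Returns the 1-based row/column of the cell containing each point. A point
#' on a shared cell edge belongs to the cell to its east/south; points on
#' the far east/south outer edge (or anywhere outside) get `NA`.
#'
#' @param g a [GridSpec].
#' @param lon,lat point coordinates, decimal degrees.
#' @return data.frame with columns `row`, `col`, `cell` (row-major linear
#'   index by row then column: `(row-1)*nCols + col`), `NA` when outside.
#' @export
cellFromLonLat <- function(g, lon, lat) {
  stopifnot(length(lon) == length(lat))
  col <- floor((lon - g@originLon) / g@res) + 1
  row <- floor((g@originLat - lat) / g@res) + 1
  # the north edge of row 1 belongs to row 1 (half-open south-inclusive)
  row[lat == g@originLat] <- 1
  bad <- !is.finite(lon) | !is.finite(lat) |
    col < 1 | col > g@nCols | row < 1 | row > g@nRows
  row[bad] <- NA_integer_
  col[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col),
             cell = as.integer((row - 1) * g@nCols + col))
}

#' Cell centre coordinates
#'
#' @param g a [GridSpec].
#' @param row,col 1-based cell indices (vectors).
#' @return data.frame with columns `lon`, `lat` of the cell centres.
#' @export
cellCenter <- function(g, row, col) {
  data.frame(lon = g@originLon + (col - 0.5) * g@res,
             lat = g@originLat - (row - 0.5) * g@res)
}

# all cell centres of a grid, row-major (row 1 first)
allCellCenters <- function(g) {
  idx <- expand.grid(col = seq_len(g@nCols), row = seq_len(g@nRows))
  cbind(cellCenter(g, idx$row, idx$col), row = idx$row, col = idx$col)
}

#' @export
setMethod("show", "GridSpec", function(object) {
  e <- gridExtent(object)
  cat(sprintf("GridSpec: %d x %d cells @ %g deg (%s)\n",
              object@nRows, object@nCols, object@res, object@datum))
  cat(sprintf("  lon [%g, %g]  lat [%g, %g]\n",
              e["lonMin"], e["lonMax"], e["latMin"], e["latMax"]))
})

#' @export
setMethod("show", "EnvLayer", function(object) {
  v <- object@values
  cat(sprintf("EnvLayer '%s'%s: %d x %d, %d nodata cells\n", object@name,
              if (nzchar(object@units)) sprintf(" [%s]", object@units) else "",
              nrow(v), ncol(v), sum(is.na(v))))
  if (any(!is.na(v)))
    cat(sprintf("  range [%g, %g]\n", min(v, na.rm = TRUE),
                max(v, na.rm = TRUE)))
})

#' @export
setMethod("show", "EnvStack", function(object) {
  g <- gridOf(object)
  cat(sprintf("EnvStack: %d layers on %d x %d grid @ %g deg; %d valid cells\n",
              length(object@layers), g@nRows, g@nCols, g@res,
              sum(envMask(object))))
  cat(" ", paste(layerNames(object), collapse = ", "), "\n")
})

# classed error helper so callers/tests can match on condition class
sdmStop <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "sdmError")))
}
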