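# Raster file IO.
#
# Two on-disk encodings are supported, both in geographic (lon/lat) WGS84:
#   * ESRI ASCII grid (.asc)
#   * single-band uncompressed GeoTIFF (.tif/.tiff), float64 samples when
#     written by this package; float32/float64 and common integer sample
#     formats when read.
# No GDAL-style library is used: the GeoTIFF codec here handles exactly the
# single-band, strip-organised, uncompressed case with
# ModelPixelScale/ModelTiepoint georeferencing and the GDAL_NODATA tag, which
# is what practitioners exchange for gridded environmental predictors.
# Round-trips are bit-exact for double data.

.TIFF_TYPE_SIZE <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L,
                     `11` = 4L, `12` = 8L)
.NODATA_DEFAULT <- -3.4e38

#' Read a raster layer from disk
#'
#' Reads a single-band GeoTIFF or ESRI ASCII grid into an [EnvLayer].
#' The format is chosen by file extension unless `format` is given. The
#' layer name defaults to the filename stem; units come from the caller
#' (raster files do not carry them).
#'
#' @param path file path.
#' @param name layer name; default: filename without extension.
#' @param units unit label to attach.
#' @param format `"auto"`, `"geotiff"` or `"ascii"`.
#' @return an [EnvLayer].
#' @seealso [writeRasterLayer()]
#' @export
readRasterLayer <- function(path, name = NULL, units = "",
                            format = c("auto", "geotiff", "ascii")) {
  format <- match.arg(format)
  if (!file.exists(path))
    sdmStop("sdmFormatError", "raster file not found: %s", path)
  if (format == "auto") format <- .guessFormat(path)
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  out <- switch(format,
    geotiff = .readGeoTiff(path),
    ascii = .readAsciiGrid(path))
  envLayer(name, out$grid, out$values, units = units)
}

#' Write a raster layer to disk
#'
#' @param layer an [EnvLayer].
#' @param path output path.
#' @param format `"auto"` (by extension), `"geotiff"` or `"ascii"`.
#' @param nodata sentinel written for `NA` cells.
#' @return `path`, invisibly.
#' @export
writeRasterLayer <- function(layer, path,
                             format = c("auto", "geotiff", "ascii"),
                             nodata = .NODATA_DEFAULT) {
  stopifnot(is(layer, "EnvLayer"))
  format <- match.arg(format)
  if (format == "auto") format <- .guessFormat(path)
  switch(format,
    geotiff = .writeGeoTiff(layer, path, nodata),
    ascii = .writeAsciiGrid(layer, path, nodata))
  invisible(path)
}

.guessFormat <- function(path) {
  ext <- tolower(sub(".*\\.", "", basename(path)))
  if (ext %in% c("tif", "tiff")) return("geotiff")
  if (ext %in% c("asc", "agr", "txt")) return("ascii")
  sdmStop("sdmFormatError",
          "cannot infer raster format from extension of %s", path)
}

## --- ESRI ASCII grid ------------------------------------------------------

.readAsciiGrid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2 && grepl("^[A-Za-z_]+$", parts[1]) &&
        !is.na(suppressWarnings(as.numeric(parts[2])))) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      i <- i + 1L
    } else break
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)) ||
      !(("xllcorner" %in% names(hdr) || "xllcenter" %in% names(hdr)) &&
        ("yllcorner" %in% names(hdr) || "yllcenter" %in% names(hdr))))
    sdmStop("sdmFormatError", "garbled ASCII grid header in %s", path)
  res <- hdr$cellsize
  ncols <- as.integer(hdr$ncols); nrows <- as.integer(hdr$nrows)
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else hdr$xllcenter - res / 2
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else hdr$yllcenter - res / 2
  vals <- scan(text = paste(lines[-seq_len(i)], collapse = "\n"),
               what = double(), quiet = TRUE)
  if (length(vals) != nrows * ncols)
    sdmStop("sdmFormatError", "expected %d values, found %d in %s",
            nrows * ncols, length(vals), path)
  m <- matrix(vals, nrow = nrows, ncol = ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  g <- gridSpec(xll, yll + nrows * res, res, nrows, ncols)
  list(grid = g, values = m)
}

.writeAsciiGrid <- function(layer, path, nodata) {
  g <- layer@grid
  m <- layer@values
  m[is.na(m)] <- nodata
  hdr <- c(
    sprintf("ncols %d", g@nCols),
    sprintf("nrows %d", g@nRows),
    sprintf("xllcorner %.17g", g@originLon),
    sprintf("yllcorner %.17g", g@originLat - g@nRows * g@res),
    sprintf("cellsize %.17g", g@res),
    sprintf("NODATA_value %.17g", nodata))
  body <- apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, body), path)
}

## --- GeoTIFF --------------------------------------------------------------

.readGeoTiff <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8) sdmStop("sdmFormatError", "truncated TIFF: %s", path)
  endian <- if (rawToChar(raw[1:2]) == "II") "little"
            else if (rawToChar(raw[1:2]) == "MM") "big"
            else sdmStop("sdmFormatError", "not a TIFF file: %s", path)
  rd <- function(off, what, n, size)
    readBin(raw[(off + 1):length(raw)], what, n = n, size = size,
            endian = endian, signed = (size > 2))
  if (rd(2, "integer", 1, 2) != 42L)
    sdmStop("sdmFormatError", "not a TIFF file: %s", path)
  ifdOff <- rd(4, "integer", 1, 4)
  nEntries <- rd(ifdOff, "integer", 1, 2)
  tags <- list()
  for (k in seq_len(nEntries)) {
    e <- ifdOff + 2 + (k - 1) * 12
    tag <- rd(e, "integer", 1, 2)
    type <- rd(e + 2, "integer", 1, 2)
    count <- rd(e + 4, "integer", 1, 4)
    sz <- .TIFF_TYPE_SIZE[as.character(type)]
    if (is.na(sz)) next
    nbytes <- sz * count
    voff <- if (nbytes > 4) rd(e + 8, "integer", 1, 4) else e + 8
    vals <- switch(as.character(type),
      `1` = rd(voff, "integer", count, 1),
      `2` = {
        b <- raw[(voff + 1):(voff + count)]
        rawToChar(b[b != as.raw(0)])
      },
      `3` = rd(voff, "integer", count, 2),
      `4` = rd(voff, "integer", count, 4),
      `11` = readBin(raw[(voff + 1):length(raw)], "double", n = count,
                     size = 4, endian = endian),
      `12` = readBin(raw[(voff + 1):length(raw)], "double", n = count,
                     size = 8, endian = endian))
    tags[[as.character(tag)]] <- vals
  }
  tg <- function(t, default = NULL)
    if (!is.null(tags[[as.character(t)]])) tags[[as.character(t)]] else default
  width <- tg(256); height <- tg(257)
  if (is.null(width) || is.null(height))
    sdmStop("sdmFormatError", "TIFF missing image dimensions: %s", path)
  if (tg(259, 1L)[1] != 1L)
    sdmStop("sdmFormatError", "compressed TIFF not supported: %s", path)
  if (tg(277, 1L)[1] != 1L)
    sdmStop("sdmFormatError", "multi-band TIFF not supported: %s", path)
  bits <- tg(258, 1L)[1]
  sfmt <- tg(339, 1L)[1]    # 1 unsigned int, 2 signed int, 3 IEEE float
  stripOff <- tg(273); stripCnt <- tg(279)
  if (is.null(stripOff) || is.null(stripCnt))
    sdmStop("sdmFormatError", "TIFF missing strip layout: %s", path)
  if (any(stripOff < 0) || any(stripOff + stripCnt > length(raw)))
    sdmStop("sdmFormatError", "strip data out of bounds in %s", path)
  bytes <- raw(0)
  for (s in seq_along(stripOff))
    bytes <- c(bytes, raw[(stripOff[s] + 1):(stripOff[s] + stripCnt[s])])
  n <- width * height
  vals <- if (sfmt == 3L && bits == 64L) {
    readBin(bytes, "double", n = n, size = 8, endian = endian)
  } else if (sfmt == 3L && bits == 32L) {
    readBin(bytes, "double", n = n, size = 4, endian = endian)
  } else if (sfmt %in% c(1L, 2L) && bits %in% c(8L, 16L, 32L)) {
    readBin(bytes, "integer", n = n, size = bits / 8, endian = endian,
            signed = (sfmt == 2L || bits == 32L))
  } else {
    sdmStop("sdmFormatError",
            "unsupported TIFF sample format (%d bits, format %d): %s",
            bits, sfmt, path)
  }
  m <- matrix(as.double(vals), nrow = height, ncol = width, byrow = TRUE)
  # georeference: pixel scale + a (0,0) tiepoint
  scale <- tg(33550); tie <- tg(33922)
  if (is.null(scale) || is.null(tie) || length(tie) < 6 ||
      any(tie[1:2] != 0) || scale[1] <= 0 || scale[2] <= 0)
    sdmStop("sdmFormatError", "missing or garbled georeferencing in %s", path)
  if (abs(scale[1] - scale[2]) > 1e-9 * scale[1])
    sdmStop("sdmFormatError", "non-square pixels not supported: %s", path)
  nod <- tg(42113)
  if (!is.null(nod)) {
    nodv <- suppressWarnings(as.numeric(trimws(nod)))
    if (!is.na(nodv)) m[m == nodv] <- NA
  }
  m[is.nan(m)] <- NA
  g <- gridSpec(tie[4], tie[5], scale[1], height, width)
  list(grid = g, values = m)
}

.writeGeoTiff <- function(layer, path, nodata) {
  g <- layer@grid
  m <- layer@values
  m[is.na(m)] <- nodata
  data <- writeBin(as.double(t(m)), raw(), size = 8, endian = "little")
  dataOff <- 8L
  ifdOff <- dataOff + length(data)
  if (ifdOff %% 2L == 1L) { data <- c(data, as.raw(0)); ifdOff <- ifdOff + 1L }

  nodStr <- sprintf("%.17g", nodata)
  nodRaw <- c(charToRaw(nodStr), as.raw(0))
  geoKeys <- as.integer(c(1, 1, 0, 3,        # version, n keys
                          1024, 0, 1, 2,     # model type: geographic
                          1025, 0, 1, 1,     # raster type: pixel-is-area
                          2048, 0, 1, 4326)) # geographic CRS: WGS84
  pixScale <- c(g@res, g@res, 0)
  tiepoint <- c(0, 0, 0, g@originLon, g@originLat, 0)

  # entries: list(tag, type, count, value) -- value either inline or raw blob
  entries <- list(
    list(256L, 4L, 1L, g@nCols),
    list(257L, 4L, 1L, g@nRows),
    list(258L, 3L, 1L, 64L),
    list(259L, 3L, 1L, 1L),
    list(262L, 3L, 1L, 1L),
    list(273L, 4L, 1L, dataOff),
    list(277L, 3L, 1L, 1L),
    list(278L, 4L, 1L, g@nRows),
    list(279L, 4L, 1L, g@nRows * g@nCols * 8L),
    list(284L, 3L, 1L, 1L),
    list(339L, 3L, 1L, 3L),
    list(33550L, 12L, 3L, pixScale),
    list(33922L, 12L, 6L, tiepoint),
    list(34735L, 3L, 16L, geoKeys),
    list(42113L, 2L, length(nodRaw), nodRaw))

  encVal <- function(type, val) {
    switch(as.character(type),
      `2` = as.raw(val),
      `3` = writeBin(as.integer(val), raw(), size = 2, endian = "little"),
      `4` = writeBin(as.integer(val), raw(), size = 4, endian = "little"),
      `12` = writeBin(as.double(val), raw(), size = 8, endian = "little"))
  }
  extOff <- ifdOff + 2L + 12L * length(entries) + 4L
  ext <- raw(0)
  ifd <- writeBin(length(entries), raw(), size = 2, endian = "little")
  for (en in entries) {
    blob <- encVal(en[[2]], en[[4]])
    ifd <- c(ifd,
             writeBin(en[[1]], raw(), size = 2, endian = "little"),
             writeBin(en[[2]], raw(), size = 2, endian = "little"),
             writeBin(en[[3]], raw(), size = 4, endian = "little"))
    if (length(blob) <= 4L) {
      ifd <- c(ifd, blob, raw(4L - length(blob)))
    } else {
      off <- extOff + length(ext)
      ifd <- c(ifd, writeBin(off, raw(), size = 4, endian = "little"))
      ext <- c(ext, blob)
      if (length(ext) %% 2L == 1L) ext <- c(ext, as.raw(0))
    }
  }
  ifd <- c(ifd, writeBin(0L, raw(), size = 4, endian = "little"))
  header <- c(charToRaw("II"),
              writeBin(42L, raw(), size = 2, endian = "little"),
              writeBin(dataOff + length(data), raw(), size = 4,
                       endian = "little"))
  # recompute IFD offset: header is 8 bytes, then data
  writeBin(c(header, data, ifd, ext), path)
}
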