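# Occurrence ingest, seasonal splitting and grid-cell spatial thinning.

#' Season of a calendar month
#'
#' Austral convention used throughout: October-March is summer,
#' April-September is winter. The mapping is total over months 1-12.
#'
#' @param month integer vector in 1..12.
#' @return character vector, `"summer"` or `"winter"`.
#' @examples
#' seasonOfMonth(c(11, 4, 3))
#' @export
seasonOfMonth <- function(month) {
  stopifnot(all(month %in% 1:12 | is.na(month)))
  ifelse(is.na(month), NA_character_,
         ifelse(month >= 10 | month <= 3, "summer", "winter"))
}

#' Construct an OccurrenceSet
#'
#' @param species species label.
#' @param records data.frame with columns
#'   `species, lon, lat, date, source` (`date` as `Date`).
#' @param season `"summer"`, `"winter"` or `"all"`.
#' @param thinned has spatial thinning been applied.
#' @return an [OccurrenceSet].
#' @export
occurrenceSet <- function(species, records, season = "all",
                          thinned = FALSE) {
  new("OccurrenceSet", species = species, season = season,
      records = records, thinned = thinned)
}

#' @rdname nRecords
#' @export
setGeneric("nRecords", function(x) standardGeneric("nRecords"))

#' Number of records in a set
#' @param x an [OccurrenceSet].
#' @return integer count.
#' @export
setMethod("nRecords", "OccurrenceSet", function(x) nrow(x@records))

#' @rdname occRecords
#' @export
setGeneric("occRecords", function(x) standardGeneric("occRecords"))

#' Records of a set
#' @param x an [OccurrenceSet].
#' @return the records data.frame.
#' @export
setMethod("occRecords", "OccurrenceSet", function(x) x@records)

#' @export
setMethod("show", "OccurrenceSet", function(object) {
  cat(sprintf("OccurrenceSet: %s, %s season, %d records%s\n",
              object@species, object@season, nrow(object@records),
              if (object@thinned) " (thinned)" else ""))
})

#' Read presence records from CSV
#'
#' Expects a header naming species, date, longitude, latitude and source
#' columns; the exact header words are configurable through `aliases`.
#' Rows with unparseable dates or out-of-range coordinates are rejected,
#' counted and returned in the rejection attribute -- never silently
#' dropped.
#'
#' @param path CSV path.
#' @param aliases named list mapping the canonical fields
#'   `species, date, lon, lat, source` to acceptable header names.
#' @param dateFormats candidate date formats, tried in order per row.
#' @return data.frame of clean records (`species, lon, lat, date, source`)
#'   with attributes `nRejected` (count) and `rejected` (the bad rows and
#'   a reason column).
#' @export
readOccurrences <- function(path,
    aliases = list(species = c("species", "sp"),
                   date = c("date", "eventdate", "sighting_date"),
                   lon = c("longitude", "lon", "long", "x"),
                   lat = c("latitude", "lat", "y"),
                   source = c("source", "provider", "platform")),
    dateFormats = c("%Y-%m-%d", "%d/%m/%Y")) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  hdr <- tolower(trimws(names(raw)))
  pick <- function(field) {
    hit <- which(hdr %in% tolower(aliases[[field]]))
    if (!length(hit))
      sdmStop("sdmSchemaError",
              "missing column for '%s'; accepted names: %s", field,
              paste(aliases[[field]], collapse = ", "))
    hit[1]
  }
  cols <- vapply(c("species", "date", "lon", "lat", "source"), pick,
                 integer(1))
  df <- data.frame(species = trimws(as.character(raw[[cols["species"]]])),
                   lon = suppressWarnings(as.numeric(raw[[cols["lon"]]])),
                   lat = suppressWarnings(as.numeric(raw[[cols["lat"]]])),
                   date = as.Date(NA),
                   source = as.character(raw[[cols["source"]]]),
                   stringsAsFactors = FALSE)
  dateStr <- as.character(raw[[cols["date"]]])
  for (fmt in dateFormats) {
    todo <- is.na(df$date)
    if (!any(todo)) break
    df$date[todo] <- as.Date(dateStr[todo], format = fmt)
  }
  reason <- rep(NA_character_, nrow(df))
  reason[is.na(df$lon) | is.na(df$lat)] <- "unparseable coordinates"
  reason[!is.na(df$lon) & !is.na(df$lat) &
         (abs(df$lon) > 180 | abs(df$lat) > 90)] <- "coordinates out of range"
  reason[is.na(reason) & is.na(df$date) & !is.na(dateStr) &
         nzchar(dateStr)] <- "unparseable date"
  bad <- !is.na(reason)
  if (any(bad))
    message(sprintf("readOccurrences: rejected %d of %d rows (%s)",
                    sum(bad), nrow(df),
                    paste(unique(reason[bad]), collapse = "; ")))
  out <- df[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "nRejected") <- sum(bad)
  attr(out, "rejected") <- cbind(df[bad, , drop = FALSE],
                                 reason = reason[bad])
  out
}

#' Split records into seasonal occurrence sets
#'
#' Partitions records by the season of their calendar month (summer =
#' Oct-Mar, winter = Apr-Sep). Every dated record lands in exactly one
#' season; dateless records are excluded and counted.
#'
#' @param records data.frame as returned by [readOccurrences()].
#' @param species species label for the resulting sets; defaults to the
#'   single species present in `records`.
#' @return named list with [OccurrenceSet] elements `summer` and `winter`
#'   and an integer `nUndated`.
#' @export
assignSeason <- function(records, species = NULL) {
  if (is.null(species)) {
    sp <- unique(records$species)
    if (length(sp) != 1)
      sdmStop("sdmConfigError",
              "records hold %d species; pass `species` explicitly",
              length(sp))
    species <- sp
  } else {
    records <- records[normSpecies(records$species) == normSpecies(species), ,
                       drop = FALSE]
  }
  dated <- !is.na(records$date)
  season <- rep(NA_character_, nrow(records))
  season[dated] <- seasonOfMonth(as.integer(format(records$date[dated],
                                                   "%m")))
  mk <- function(s) occurrenceSet(
    species, records[!is.na(season) & season == s, , drop = FALSE],
    season = s)
  list(summer = mk("summer"), winter = mk("winter"),
       nUndated = sum(!dated))
}

normSpecies <- function(x) tolower(gsub("\\s+", " ", trimws(x)))

#' Spatially thin occurrences to one record per grid cell
#'
#' Keeps at most one record per grid cell, the first record in input order;
#' records falling outside the grid are excluded and counted separately
#' from thinning removals.
#'
#' @param set an [OccurrenceSet].
#' @param grid a [GridSpec] (typically the predictor grid).
#' @return the thinned [OccurrenceSet], flagged `thinned`, with attributes
#'   `originalN`, `thinnedN`, `outOfExtentN`, `removedN`.
#' @export
thinToGrid <- function(set, grid) {
  stopifnot(is(set, "OccurrenceSet"), is(grid, "GridSpec"))
  r <- set@records
  idx <- cellFromLonLat(grid, r$lon, r$lat)
  inside <- !is.na(idx$cell)
  kept <- inside & !duplicated(idx$cell)
  out <- occurrenceSet(set@species, r[kept, , drop = FALSE],
                       season = set@season, thinned = TRUE)
  attr(out, "originalN") <- nrow(r)
  attr(out, "outOfExtentN") <- sum(!inside)
  attr(out, "thinnedN") <- sum(kept)
  attr(out, "removedN") <- sum(inside) - sum(kept)
  out
}

#' Per-source contribution percentages
#'
#' @param set an [OccurrenceSet].
#' @return data.frame (source, n, percent) with integer-rounded percentages
#'   that sum to 100 up to rounding.
#' @export
sourceBreakdown <- function(set) {
  tab <- table(set@records$source)
  data.frame(source = names(tab), n = as.integer(tab),
             percent = as.integer(round(100 * as.integer(tab) / sum(tab))),
             stringsAsFactors = FALSE)
}

#' Write an occurrence set as CSV
#'
#' @param set an [OccurrenceSet].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeOccurrences <- function(set, path) {
  utils::write.csv(set@records, path, row.names = FALSE)
  invisible(path)
}
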