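writeOccCsv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

test_that("clean CSV rows ingest one-to-one", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeOccCsv(data.frame(species = "sp", date = c("2015-11-03", "2016-01-10",
                                                  "2014-06-30"),
                         longitude = c(20, 21, 22), latitude = c(-30, -31, -32),
                         source = "MRI"), p)
  recs <- readOccurrences(p)
  expect_equal(nrow(recs), 3L)
  expect_equal(attr(recs, "nRejected"), 0L)
  expect_s3_class(recs$date, "Date")
})

test_that("out-of-range coordinates are rejected and counted, not dropped silently", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeOccCsv(data.frame(species = "sp", date = "2015-01-01",
                         longitude = c(20, 21), latitude = c(95, -30),
                         source = "OBIS"), p)
  expect_message(recs <- readOccurrences(p), "rejected 1")
  expect_equal(nrow(recs), 1L)
  expect_equal(attr(recs, "nRejected"), 1L)
  expect_equal(attr(recs, "rejected")$reason, "coordinates out of range")
})

test_that("mixed configured date formats parse to one calendar representation", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeOccCsv(data.frame(species = "sp", date = c("2015-11-03", "03/11/2015"),
                         longitude = c(20, 21), latitude = c(-30, -30),
                         source = "x"), p)
  recs <- readOccurrences(p)
  expect_equal(recs$date, rep(as.Date("2015-11-03"), 2))
  # round-trip: write the parsed records, read again, identical dates
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeOccurrences(occurrenceSet("sp", recs), p2)
  expect_equal(readOccurrences(p2)$date, recs$date)
})

test_that("a missing mandatory column is a schema error listing expected names", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeOccCsv(data.frame(species = "sp", longitude = 1, latitude = 2,
                         source = "x"), p)
  err <- tryCatch(readOccurrences(p), error = identity)
  expect_s3_class(err, "sdmSchemaError")
  expect_match(conditionMessage(err), "date")
})

test_that("season assignment is the austral Oct-Mar / Apr-Sep partition", {
  expect_equal(seasonOfMonth(11), "summer")   # e.g. 2015-11-03
  expect_equal(seasonOfMonth(4), "winter")    # 2015-04-01
  expect_equal(seasonOfMonth(3), "summer")    # 2015-03-31
  expect_equal(sum(seasonOfMonth(1:12) == "summer"), 6L)

  recs <- makeRecords(lon = 1:12, lat = rep(-30, 12),
                      date = as.Date(sprintf("2015-%02d-15", 1:12)))
  split <- assignSeason(recs)
  expect_equal(nRecords(split$summer), 6L)
  expect_equal(nRecords(split$winter), 6L)
  expect_equal(split$nUndated, 0L)
  # partition totality with an undated record
  recs$date[5] <- NA
  split <- assignSeason(recs)
  expect_equal(nRecords(split$summer) + nRecords(split$winter) +
                 split$nUndated, 12L)
})

test_that("grid thinning keeps the first record per occupied cell", {
  g <- gridSpec(0, 5, 1, 5, 5)
  # records 2 and 4 share cell (1,1); record 5 outside the grid
  set <- makeOccSet(lon = c(2.5, 0.2, 3.5, 0.8, 9.0),
                    lat = c(-1.5 + 4, 4.9, 1.5, 4.3, 4.0))
  th <- thinToGrid(set, g)
  expect_equal(nRecords(th), 3L)
  expect_true(th@thinned)
  expect_equal(attr(th, "originalN"), 5L)
  expect_equal(attr(th, "outOfExtentN"), 1L)
  expect_equal(attr(th, "removedN"), 1L)
  # the FIRST of the two sharing records survives
  expect_true(0.2 %in% occRecords(th)$lon)
  expect_false(0.8 %in% occRecords(th)$lon)
})

test_that("thinning is idempotent and counts equal distinct occupied cells", {
  g <- gridSpec(0, 10, 0.5, 20, 20)
  for (seed in 1:5) {
    set.seed(seed)
    n <- 80
    set <- makeOccSet(lon = runif(n, 0, 10), lat = runif(n, 0, 10))
    th <- thinToGrid(set, g)
    cells <- cellFromLonLat(g, occRecords(set)$lon, occRecords(set)$lat)$cell
    expect_equal(nRecords(th), length(unique(cells[!is.na(cells)])))
    th2 <- thinToGrid(th, g)
    expect_identical(occRecords(th2), occRecords(th))
    expect_equal(attr(th2, "removedN"), 0L)
  }
})

test_that("records already in distinct cells pass thinning unchanged", {
  g <- gridSpec(0, 5, 1, 5, 5)
  set <- makeOccSet(lon = c(0.5, 1.5, 2.5), lat = c(4.5, 3.5, 2.5))
  th <- thinToGrid(set, g)
  expect_equal(occRecords(th)$lon, occRecords(set)$lon)
})

test_that("source percentages are integer-rounded and sum to ~100", {
  one <- makeOccSet(lon = 1:3 / 10, lat = rep(-1, 3))
  expect_equal(sourceBreakdown(one)$percent, 100L)

  two <- makeOccSet(lon = 1:4 / 10, lat = rep(-1, 4),
                    source = c("A", "B", "B", "B"))
  bd <- sourceBreakdown(two)
  expect_equal(bd$percent[bd$source == "A"], 25L)
  expect_equal(bd$percent[bd$source == "B"], 75L)

  four <- makeOccSet(lon = seq_len(100) / 100, lat = rep(-1, 100),
                     source = rep(c("MRI", "OBIS", "CS", "PASA"),
                                  c(54, 1, 38, 7)))
  bd <- sourceBreakdown(four)
  expect_equal(bd$percent[match(c("MRI", "OBIS", "CS", "PASA"), bd$source)],
               c(54L, 1L, 38L, 7L))
  expect_equal(sum(bd$percent), 100L)
})
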