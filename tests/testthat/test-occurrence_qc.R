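test_that("coordinate validation drops out-of-range, null-island and malformed points", {
  df <- occ_df(c("a", "a", "a", "a", "a", "a"),
               c(91, 0, -33.90, NA, 45, -91),
               c(10, 0, 18.42, 10, 181, 5))
  df$decimalLatitude[5] <- 45  # lon out of range row
  out <- validate_coordinates(df)
  expect_equal(out$status, c("dropped", "dropped", "retained", "dropped",
                             "dropped", "dropped"))
  expect_true(all(out$drop_reason[out$status == "dropped"] ==
                    "invalid_coordinate"))
  expect_equal(out$drop_reason[3], "none")
  # non-numeric text coordinates are treated as missing
  txt <- data.frame(taxon = "a", decimalLatitude = "12,3",
                    decimalLongitude = "4.0", stringsAsFactors = FALSE)
  expect_equal(suppressWarnings(validate_coordinates(txt))$drop_reason,
               "invalid_coordinate")
  # empty input passes through
  expect_equal(nrow(validate_coordinates(occ_df(character(0), numeric(0),
                                                numeric(0)))), 0)
})

test_that("land-mask filter honors the half-open cell convention", {
  ok <- filter_landmass(occ_df("a", 5.5, 5.5), toy_mask(TRUE))
  expect_equal(ok$status, "retained")
  expect_warning(bad <- filter_landmass(occ_df("a", 5.5, 5.5),
                                        toy_mask(FALSE)),
                 "zero land cells")
  expect_equal(bad$drop_reason, "off_land")
  # 0.01 degrees beyond the northern mask edge is off-extent, hence dropped
  edge <- filter_landmass(occ_df("a", 10.01, 5), toy_mask(TRUE))
  expect_equal(edge$drop_reason, "off_land")
  # the northern grid edge itself belongs to the top row
  on_edge <- filter_landmass(occ_df("a", 10, 5), toy_mask(TRUE))
  expect_equal(on_edge$status, "retained")
  expect_warning(filter_landmass(occ_df("a", 5, 5), toy_mask(FALSE)),
                 "zero land cells")
})

test_that("institution-proximity filter uses great-circle distance", {
  hq <- c(55.6761, 12.5683)
  at_hq <- filter_institution_proximity(occ_df("a", hq[1], hq[2]))
  expect_equal(at_hq$drop_reason, "institution_proximity")
  antipode <- filter_institution_proximity(occ_df("a", -hq[1], hq[2] - 180))
  expect_equal(antipode$status, "retained")
  # independent oracle: spherical law of cosines
  slc_km <- function(lat1, lon1, lat2, lon2) {
    r <- pi / 180
    6371 * acos(pmin(1, sin(lat1 * r) * sin(lat2 * r) +
                       cos(lat1 * r) * cos(lat2 * r) * cos((lon2 - lon1) * r)))
  }
  pts <- occ_df(c("a", "a"), hq[1] + c(0.4487, 0.46), hq[2])
  d <- slc_km(pts$decimalLatitude, pts$decimalLongitude, hq[1], hq[2])
  expect_lt(d[1], 50); expect_gt(d[2], 50)
  expect_equal(haversine_km(pts$decimalLatitude, pts$decimalLongitude,
                            hq[1], hq[2]), d, tolerance = 1e-9)
  out <- filter_institution_proximity(pts, radius_km = 50)
  expect_equal(out$status, c("dropped", "retained"))
})

test_that("deduplication keys on taxon and 2-decimal rounded coordinates", {
  df <- occ_df(c("A", "A", "B"), c(1.004, 1.001, 1.001), c(2.004, 2.001, 2.001))
  out <- deduplicate(df)
  expect_equal(out$status, c("retained", "dropped", "retained"))
  expect_equal(out$drop_reason[2], "duplicate")
  expect_equal(out$decimalLatitude[1], 1.00)   # rounded in place
  expect_equal(out$decimalLongitude[1], 2.00)
  # identical coordinates under two taxa are both kept
  expect_equal(sum(out$status == "retained" &
                     out$decimalLatitude == 1.00), 2)
  # half-away-from-zero, not banker's rounding
  neg <- deduplicate(occ_df("A", -1.005, 2.005))
  expect_equal(neg$decimalLatitude, -1.01)
  expect_equal(neg$decimalLongitude, 2.01)
  # brute-force key grouping on a random table
  set.seed(42)
  r <- occ_df(sample(c("x", "y"), 30, TRUE),
              round(runif(30, 0, 0.05), 3), round(runif(30, 0, 0.05), 3))
  out <- deduplicate(r)
  keys <- unique(paste(r$taxon, round(r$decimalLatitude, 2),
                       round(r$decimalLongitude, 2)))
  expect_equal(sum(out$status == "retained"), length(keys))
})

test_that("clean_occurrences composes the filters in order and is idempotent", {
  mask <- toy_mask(TRUE, nrow = 90, ncol = 180, west = -180, north = 90,
                   cellsize = 2)
  df <- occ_df(c("a", "a", "a", "a", "a"),
               c(95, 55.6761, 5.123, 5.134, 40),
               c(10, 12.5683, 5.456, 5.456, 20))
  df$decimalLatitude[4] <- 5.123  # duplicate of row 3 after rounding
  qc <- clean_occurrences(df, mask = mask)
  expect_s3_class(qc, "qc_result")
  expect_equal(qc$report$totals$input, 5)
  expect_equal(qc$report$totals$retained, 2)
  expect_equal(qc$report$totals$invalid_coordinate, 1)
  expect_equal(qc$report$totals$institution_proximity, 1)
  expect_equal(qc$report$totals$duplicate, 1)
  # partition: every record retained or dropped with exactly one reason
  expect_equal(sum(qc$records$status == "retained") +
                 sum(qc$records$status == "dropped"), nrow(df))
  expect_true(all(qc$records$drop_reason[qc$records$status == "dropped"] !=
                    "none"))
  # idempotence on the retained set
  again <- clean_occurrences(qc$retained, mask = mask)
  expect_equal(again$retained$decimalLatitude, qc$retained$decimalLatitude)
  expect_equal(again$retained$decimalLongitude, qc$retained$decimalLongitude)
  expect_equal(again$report$totals$retained, qc$report$totals$retained)
})

test_that("permuting input order preserves the retained key set", {
  set.seed(7)
  df <- occ_df(sample(c("x", "y"), 40, TRUE),
               round(runif(40, 0, 0.04), 3), round(runif(40, 0, 0.04), 3))
  key_set <- function(d) {
    r <- clean_occurrences(d)$retained
    sort(paste(r$taxon, r$decimalLatitude, r$decimalLongitude))
  }
  expect_equal(key_set(df), key_set(df[sample(nrow(df)), ]))
})

test_that("occurrence CSVs round-trip bit-exactly", {
  set.seed(3)
  df <- occ_df(c("a", "b"), runif(2, -90, 90), runif(2, -180, 180))
  path <- withr::local_tempfile(fileext = ".csv")
  write_occurrences(df, path)
  back <- read_occurrences(path)
  expect_identical(back$decimalLatitude, df$decimalLatitude)
  expect_identical(back$decimalLongitude, df$decimalLongitude)
})
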