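# Occurrence-record quality control.
#
# Four filters, applied in a fixed order: coordinate validation, land-mask
# overlay, institution-proximity exclusion, and deduplication at two-decimal
# coordinate resolution.  Every record keeps an auditable status and a single
# drop reason; proximity and land tests run on the original (pre-rounding)
# coordinates.

DROP_REASONS <- c("none", "invalid_coordinate", "off_land",
                  "institution_proximity", "duplicate")

# Default institution filter: GBIF headquarters, Copenhagen.
GBIF_HQ <- c(lat = 55.6761, lon = 12.5683)

qc_init <- function(records) {
  need <- c("taxon", "decimalLatitude", "decimalLongitude")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols))
    stop("occurrence table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  if (is.null(records$status))
    records$status <- rep("retained", nrow(records))
  if (is.null(records$drop_reason))
    records$drop_reason <- rep("none", nrow(records))
  records
}

is_active <- function(records) records$status == "retained"

#' Flag anomalous coordinates
#'
#' Marks records whose latitude/longitude are missing, non-finite, outside
#' \eqn{[-90, 90] \times [-180, 180]}, or exactly (0, 0) ("null island", a
#' common geocoding artifact) as dropped with reason `invalid_coordinate`.
#'
#' @param records Data frame with columns `taxon`, `decimalLatitude`,
#'   `decimalLongitude`; extra columns pass through untouched.  Coordinate
#'   columns may be character (non-numeric entries are treated as missing).
#' @return `records` with `status` and `drop_reason` columns updated.
#' @examples
#' validate_coordinates(data.frame(taxon = "a", decimalLatitude = 91,
#'                                 decimalLongitude = 10))
#' @export
validate_coordinates <- function(records) {
  records <- qc_init(records)
  if (nrow(records) == 0L) return(records)
  lat <- suppressWarnings(as.numeric(records$decimalLatitude))
  lon <- suppressWarnings(as.numeric(records$decimalLongitude))
  records$decimalLatitude <- lat
  records$decimalLongitude <- lon
  bad <- !is.finite(lat) | !is.finite(lon) |
    lat < -90 | lat > 90 | lon < -180 | lon > 180 |
    (lat == 0 & lon == 0)
  hit <- is_active(records) & bad
  records$status[hit] <- "dropped"
  records$drop_reason[hit] <- "invalid_coordinate"
  records
}

#' Drop records falling off land
#'
#' A record is dropped with reason `off_land` when the cell containing its
#' original coordinates is water (`FALSE`) in the mask, or when the point
#' lies outside the mask extent.
#'
#' @param records Coordinate-validated occurrence table.
#' @param mask A [land_mask()].
#' @return Updated `records`.
#' @export
filter_landmass <- function(records, mask) {
  stopifnot(inherits(mask, "land_mask"))
  records <- qc_init(records)
  if (!any(mask$land))
    warning("land mask has zero land cells; all records will be dropped")
  act <- which(is_active(records))
  if (!length(act)) return(records)
  idx <- cell_index(mask$spec, records$decimalLatitude[act],
                    records$decimalLongitude[act])
  on_land <- rep(FALSE, length(act))
  ok <- !is.na(idx$row)
  on_land[ok] <- mask$land[cbind(idx$row[ok], idx$col[ok])]
  records$status[act[!on_land]] <- "dropped"
  records$drop_reason[act[!on_land]] <- "off_land"
  records
}

#' Great-circle distance (haversine)
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (vectorized).
#' @param radius_earth_km Earth radius, default 6371 km.
#' @return Distances in km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2, radius_earth_km = 6371) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * radius_earth_km * asin(pmin(1, sqrt(a)))
}

#' Drop records near a collection institution
#'
#' Occurrence archives accumulate records geocoded to the coordinates of the
#' archiving institution.  Records within `radius_km` great-circle distance
#' of `center` are dropped with reason `institution_proximity`.  The default
#' center is GBIF headquarters in Copenhagen and the default radius 50 km.
#'
#' @param records Coordinate-validated occurrence table.
#' @param center `c(lat, lon)` of the institution.
#' @param radius_km Positive exclusion radius in km.
#' @return Updated `records`.
#' @export
filter_institution_proximity <- function(records, center = GBIF_HQ,
                                         radius_km = 50) {
  stopifnot(radius_km > 0, length(center) == 2)
  records <- qc_init(records)
  act <- which(is_active(records))
  if (!length(act)) return(records)
  d <- haversine_km(records$decimalLatitude[act],
                    records$decimalLongitude[act],
                    center[[1]], center[[2]])
  hit <- act[d <= radius_km]
  records$status[hit] <- "dropped"
  records$drop_reason[hit] <- "institution_proximity"
  records
}

# round-half-away-from-zero at `digits` decimals (base round() is banker's);
# the 1e-9 nudge absorbs the binary representation error of decimal inputs
# (e.g. 1.005 * 100 = 100.49999...), far above double rounding noise and far
# below any real coordinate resolution
round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Remove repeated occurrences at two-decimal resolution
#'
#' Coordinates are rounded to `digits` decimal places (half away from zero);
#' within each taxon, only the first record of each rounded coordinate pair
#' (in input order) is retained, and its coordinates are replaced by the
#' rounded values.  Later records with the same key are dropped with reason
#' `duplicate`.
#'
#' @param records Coordinate-validated occurrence table.
#' @param digits Rounding resolution in decimal places (default 2).
#' @return Updated `records`.
#' @export
deduplicate <- function(records, digits = 2) {
  records <- qc_init(records)
  act <- which(is_active(records))
  if (!length(act)) return(records)
  rlat <- round_half_away(records$decimalLatitude[act], digits)
  rlon <- round_half_away(records$decimalLongitude[act], digits)
  key <- paste(records$taxon[act], format(rlat, nsmall = digits),
               format(rlon, nsmall = digits), sep = "\r")
  dup <- duplicated(key)
  records$status[act[dup]] <- "dropped"
  records$drop_reason[act[dup]] <- "duplicate"
  keep <- act[!dup]
  records$decimalLatitude[keep] <- rlat[!dup]
  records$decimalLongitude[keep] <- rlon[!dup]
  records
}

#' Run the full occurrence-cleaning sequence
#'
#' Applies, in order: [validate_coordinates()], [filter_landmass()] (when a
#' mask is supplied), [filter_institution_proximity()], [deduplicate()].
#' Proximity and land tests use the original coordinates; retained records
#' end up with rounded coordinates.  The composition is idempotent.
#'
#' @param records Raw occurrence table (`taxon`, `decimalLatitude`,
#'   `decimalLongitude`, extra columns pass through).
#' @param mask Optional [land_mask()]; `NULL` skips the land filter.
#' @param center,radius_km Institution filter parameters, see
#'   [filter_institution_proximity()].
#' @param digits Deduplication resolution (decimal places, default 2).
#' @param verbose Emit one message per filter.
#' @return A list of class `qc_result`:
#'   \describe{
#'     \item{retained}{data frame of retained records (rounded coordinates)}
#'     \item{records}{all input records with `status` and `drop_reason`}
#'     \item{report}{list with `totals` (named counts per drop reason plus
#'       `retained`) and `per_taxon` (data frame of the same counts by taxon)}
#'   }
#' @export
clean_occurrences <- function(records, mask = NULL, center = GBIF_HQ,
                              radius_km = 50, digits = 2, verbose = FALSE) {
  records <- qc_init(records)
  n0 <- sum(is_active(records))
  records <- validate_coordinates(records)
  if (verbose) message("validate_coordinates: ",
                       n0 - sum(is_active(records)), " dropped")
  if (!is.null(mask)) records <- filter_landmass(records, mask)
  records <- filter_institution_proximity(records, center, radius_km)
  records <- deduplicate(records, digits)
  reason_counts <- function(x) {
    out <- vapply(DROP_REASONS[-1],
                  function(r) sum(x$drop_reason == r), integer(1))
    c(input = nrow(x), retained = sum(x$status == "retained"), out)
  }
  totals <- reason_counts(records)
  taxa <- sort(unique(records$taxon))
  per_taxon <- do.call(rbind, lapply(taxa, function(tx) {
    as.data.frame(as.list(reason_counts(records[records$taxon == tx, ])))
  }))
  if (length(taxa)) per_taxon <- cbind(taxon = taxa, per_taxon)
  if (verbose)
    message("clean: ", totals[["retained"]], "/", totals[["input"]],
            " records retained")
  structure(list(retained = records[records$status == "retained", ,
                                    drop = FALSE],
                 records = records,
                 report = list(totals = as.list(totals),
                               per_taxon = per_taxon)),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  t <- x$report$totals
  cat(sprintf("<qc_result> %d/%d retained (%d invalid, %d off land, %d near institution, %d duplicate)\n",
              t$retained, t$input, t$invalid_coordinate, t$off_land,
              t$institution_proximity, t$duplicate))
  invisible(x)
}

#' Read and write occurrence CSV files
#'
#' Occurrence tables use Darwin-Core-like column names (`taxon`,
#' `decimalLatitude`, `decimalLongitude`; extra columns pass through).
#' Coordinates are written with 17 significant digits so that a write/read
#' cycle reproduces the doubles bit-exactly.
#'
#' @param records Occurrence data frame.
#' @param path CSV path.
#' @return `read_occurrences`: the occurrence data frame;
#'   `write_occurrences`: `path`, invisibly.
#' @export
write_occurrences <- function(records, path) {
  out <- records
  for (col in c("decimalLatitude", "decimalLongitude"))
    if (is.numeric(out[[col]]))
      out[[col]] <- vapply(out[[col]], function(v)
        if (is.na(v)) "" else formatC(v, digits = 17, format = "g"),
        character(1))
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_occurrences
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  qc_init(df)
}

#' Write a QC report to disk
#'
#' @param qc A `qc_result` from [clean_occurrences()].
#' @param csv_path Per-taxon counts as CSV (`NULL` to skip).
#' @param json_path Totals as JSON (`NULL` to skip).
#' @return Invisibly, the report list.
#' @export
write_qc_report <- function(qc, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(qc, "qc_result"))
  if (!is.null(csv_path))
    utils::write.csv(qc$report$per_taxon, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(qc$report$totals, json_path, auto_unbox = TRUE)
  invisible(qc$report)
}
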