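# Bioclimatic summaries derived from monthly stacks, and assembly of the
# occurrence-by-variable environment matrix.

# quarter = any 3 consecutive months with December-January wrap-around;
# 12 candidate quarters, indexed by their starting month.
quarter_members <- function(start) ((start - 1L) + 0:2) %% 12L + 1L

#' Derive bioclimatic variables from monthly stacks
#'
#' From a monthly mean-temperature stack and a monthly precipitation stack
#' (and optionally a monthly minimum-temperature stack), computes per cell:
#' \describe{
#'   \item{MAT}{mean of the 12 monthly mean temperatures (deg C)}
#'   \item{MAP}{sum of monthly precipitation (mm)}
#'   \item{growth_season_temp}{mean temperature of the wettest quarter, a
#'     quarter being any 3 consecutive months with December-January
#'     wrap-around; ties broken toward the earliest calendar start month}
#'   \item{min_temp}{minimum over months of the minimum-temperature stack
#'     (falls back to the mean-temperature stack when `tmin` is absent)}
#'   \item{min_precip}{precipitation of the driest month (mm)}
#' }
#'
#' @param temps [monthly_stack()] of monthly mean temperature.
#' @param precs [monthly_stack()] of monthly precipitation totals.
#' @param tmins Optional [monthly_stack()] of monthly minimum temperature.
#' @return Named list of five [env_grid()] objects.
#' @export
derive_bioclim <- function(temps, precs, tmins = NULL) {
  stopifnot(inherits(temps, "monthly_stack"), inherits(precs, "monthly_stack"))
  if (!same_spec(temps$spec, precs$spec))
    stop("temperature and precipitation stacks are on different grids")
  if (!is.null(tmins) && !same_spec(tmins$spec, temps$spec))
    stop("tmin stack is on a different grid")
  spec <- temps$spec
  tm <- simplify2array(temps$layers)       # nrow x ncol x 12
  pm <- simplify2array(precs$layers)
  mat <- apply(tm, c(1, 2), mean)
  map <- apply(pm, c(1, 2), sum)
  # quarterly precipitation sums and temperature means for all 12 starts
  qsum <- array(0, dim = c(spec$nrow, spec$ncol, 12))
  qtmp <- array(0, dim = c(spec$nrow, spec$ncol, 12))
  for (s in 1:12) {
    ms <- quarter_members(s)
    qsum[, , s] <- pm[, , ms[1]] + pm[, , ms[2]] + pm[, , ms[3]]
    qtmp[, , s] <- (tm[, , ms[1]] + tm[, , ms[2]] + tm[, , ms[3]]) / 3
  }
  # earliest start month wins ties: which.max scans in order 1..12
  wq <- apply(qsum, c(1, 2), function(v) {
    if (anyNA(v)) NA_integer_ else which.max(v)
  })
  gst <- matrix(NA_real_, spec$nrow, spec$ncol)
  ok <- which(!is.na(wq))
  gst[ok] <- qtmp[cbind(arrayInd(ok, dim(wq)), wq[ok])]
  tmin_arr <- if (is.null(tmins)) tm else simplify2array(tmins$layers)
  mint <- apply(tmin_arr, c(1, 2), min)
  minp <- apply(pm, c(1, 2), min)
  list(
    MAT = env_grid(spec, mat, "MAT"),
    MAP = env_grid(spec, map, "MAP"),
    growth_season_temp = env_grid(spec, gst, "growth_season_temp"),
    min_temp = env_grid(spec, mint, "min_temp"),
    min_precip = env_grid(spec, minp, "min_precip")
  )
}

#' Rainfall seasonality index
#'
#' An absolute-deviation index of how concentrated annual rainfall is:
#' \deqn{SI = 100 \cdot \frac{\sum_m |x_m - R/12| / R}{11/6}}
#' where \eqn{x_m} is month-\eqn{m} precipitation and \eqn{R} the annual
#' total.  The normalisation \eqn{11/6} is the deviation sum attained when
#' all rain falls in a single month, so the index is 0 for perfectly even
#' rainfall and exactly 100 when one month carries the whole year.  Cells
#' with \eqn{R = 0} are assigned 0 by convention.
#'
#' @param precs [monthly_stack()] of monthly precipitation totals.
#' @return An [env_grid()] with variable `rainfall_seasonality`.
#' @export
rainfall_seasonality <- function(precs) {
  stopifnot(inherits(precs, "monthly_stack"))
  pm <- simplify2array(precs$layers)
  if (any(pm < 0, na.rm = TRUE))
    stop("negative monthly precipitation encountered")
  R <- apply(pm, c(1, 2), sum)
  dev <- apply(pm, c(1, 2), function(v) sum(abs(v - sum(v) / 12)))
  si <- matrix(0, nrow(R), ncol(R))
  pos <- !is.na(R) & R > 0
  si[pos] <- 100 * (dev[pos] / R[pos]) / (11 / 6)
  si[is.na(R)] <- NA_real_
  env_grid(precs$spec, si, "rainfall_seasonality")
}

#' Assemble the occurrence-by-variable environment matrix
#'
#' Overlays the (cleaned) occurrence coordinates on each supplied raster and
#' returns one row per record with one column per variable, in registry
#' order (see [env_variables()]).  Cells that are nodata or off-extent give
#' `NA` for that record/variable.
#'
#' @param records Cleaned occurrence table (`taxon`, `decimalLatitude`,
#'   `decimalLongitude`).
#' @param layers Named list of [env_grid()] objects; names must belong to
#'   the registry.
#' @return Data frame `taxon`, `decimalLatitude`, `decimalLongitude`, then
#'   one numeric column per supplied variable in registry order.
#' @export
assemble_env_matrix <- function(records, layers) {
  if (is.null(names(layers)) || any(names(layers) == ""))
    stop("layers must be a named list")
  unknown <- setdiff(names(layers), env_variables())
  if (length(unknown))
    stop("unknown variable name(s): ", paste(unknown, collapse = ", "))
  vars <- intersect(env_variables(), names(layers))
  out <- data.frame(taxon = records$taxon,
                    decimalLatitude = records$decimalLatitude,
                    decimalLongitude = records$decimalLongitude,
                    stringsAsFactors = FALSE)
  for (v in vars) {
    out[[v]] <- extract_at_points(layers[[v]], records$decimalLatitude,
                                  records$decimalLongitude)
  }
  out
}

#' Write an environment matrix as CSV
#'
#' Missing values are serialized as empty fields; column order is stable.
#'
#' @param env_matrix Output of [assemble_env_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_env_matrix <- function(env_matrix, path) {
  utils::write.csv(env_matrix, path, row.names = FALSE, na = "")
  invisible(path)
}
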