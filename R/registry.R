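# Variable registry shared by extraction, aggregation and the test suite.

.registry <- data.frame(
  variable = c("MAT", "MAP", "growth_season_temp", "min_temp", "frost_days",
               "min_precip", "wet_days", "sunshine", "rainfall_seasonality",
               "FRI", "OC", "TEB", "CEC", "pH", "altitude"),
  unit = c("deg C", "mm", "deg C", "deg C", "days/yr", "mm", "days/yr",
           "% of maximum", "index 0-100", "index", "% weight", "cmol/kg",
           "cmol/kg", "-log[H+]", "m"),
  class = c("climate", "climate", "climate", "climate", "climate", "climate",
            "climate", "climate", "climate", "climate", "soil", "soil",
            "soil", "soil", "geography"),
  stringsAsFactors = FALSE
)

#' Environmental variable registry
#'
#' The fixed roster of environmental variables known to the pipeline:
#' mean annual temperature (`MAT`, deg C), mean annual precipitation (`MAP`,
#' mm), growing-season temperature (`growth_season_temp`, mean temperature of
#' the wettest quarter, deg C), minimum temperature of the coldest month
#' (`min_temp`, deg C), annual frost days (`frost_days`), precipitation of
#' the driest month (`min_precip`, mm), annual wet days (`wet_days`),
#' sunshine (`sunshine`, % of maximum), rainfall seasonality
#' (`rainfall_seasonality`, 0-100), fire return interval (`FRI`, index),
#' topsoil organic carbon (`OC`, % weight), total exchangeable bases (`TEB`,
#' cmol/kg), cation exchange capacity (`CEC`, cmol/kg), topsoil `pH`, and
#' `altitude` (m).  Matrix columns, PCA variable pools and report ordering
#' all follow this registry order.
#'
#' @param class Optional filter: `"climate"`, `"soil"` or `"geography"`.
#' @return Character vector of variable names in registry order.
#' @examples
#' env_variables("soil")
#' @export
env_variables <- function(class = NULL) {
  if (is.null(class)) return(.registry$variable)
  class <- match.arg(class, unique(.registry$class))
  .registry$variable[.registry$class == class]
}

#' The eight variables entering the contrast tests
#'
#' Two ordination axes (climate and soil PC1) plus six individual variables:
#' growing-season temperature, minimum temperature, minimum precipitation,
#' rainfall seasonality, topsoil organic carbon and total exchangeable
#' bases.  The multiple-testing correction divides alpha by the length of
#' this vector (0.05 / 8 = 0.00625).
#'
#' @return Character vector of length 8.
#' @export
test_variables <- function() {
  c("climate_PC1", "soil_PC1", "growth_season_temp", "min_temp",
    "min_precip", "rainfall_seasonality", "OC", "TEB")
}

#' Photosynthetic type labels
#' @return `c("C3", "C3-C4", "C4")`.
#' @export
photosynthetic_types <- function() c("C3", "C3-C4", "C4")
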