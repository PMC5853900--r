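# Whittaker-style biome classification in MAT-MAP space.
#
# The polygon boundaries shipped with the package are a hand-constructed,
# simplified stand-in for the published Whittaker diagram (the original
# boundary coordinates are not redistributable here); the file is labelled
# `_synthetic` accordingly.  Classification is descriptive output only and
# feeds no test statistic.

biome_env <- new.env(parent = emptyenv())

biome_polygons <- function() {
  if (is.null(biome_env$polys)) {
    path <- system.file("extdata", "whittaker_biomes_synthetic.csv",
                        package = "nichecontrast", mustWork = TRUE)
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    biome_env$polys <- split(df[c("mat", "map")], factor(df$label,
                                                         unique(df$label)))
  }
  biome_env$polys
}

# even-odd ray casting; boundary points may fall either side, the nearest-
# polygon fallback below makes classification total regardless
point_in_poly <- function(px, py, vx, vy) {
  n <- length(vx)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    if ((vy[i] > py) != (vy[j] > py)) {
      xint <- vx[i] + (py - vy[i]) / (vy[j] - vy[i]) * (vx[j] - vx[i])
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# distance from a point to a polygon boundary in scaled space
# (1 deg C ~ 50 mm, so both axes contribute comparably)
poly_distance <- function(px, py, vx, vy, map_scale = 50) {
  px2 <- px; py2 <- py / map_scale
  x <- vx; y <- vy / map_scale
  n <- length(x)
  j <- n
  dmin <- Inf
  for (i in seq_len(n)) {
    ax <- x[j]; ay <- y[j]; bx <- x[i]; by <- y[i]
    t <- ((px2 - ax) * (bx - ax) + (py2 - ay) * (by - ay)) /
      max((bx - ax)^2 + (by - ay)^2, .Machine$double.eps)
    t <- min(1, max(0, t))
    d <- sqrt((px2 - (ax + t * (bx - ax)))^2 + (py2 - (ay + t * (by - ay)))^2)
    if (d < dmin) dmin <- d
    j <- i
  }
  dmin
}

#' Classify points into Whittaker-style biomes
#'
#' Assigns each (MAT, MAP) pair the label of the temperature-precipitation
#' polygon containing it; points outside every polygon take the label of
#' the nearest polygon (distance measured with MAP scaled by 1/50 so both
#' axes contribute comparably), making the classification total over finite
#' inputs.  Labels: tropical rainforest (`TrRF`), temperate rainforest
#' (`TeRF`), temperate forest (`TF`), tropical seasonal forest (`TSF`),
#' woodland/grassland/shrubland (`WGS`), savanna (`S`), desert (`D`), taiga
#' (`Ta`), tundra (`Tu`).
#'
#' @param mat Mean annual temperature (deg C), vectorized.
#' @param map Mean annual precipitation (mm), vectorized.
#' @return Character vector of biome labels (`NA` for non-finite input).
#' @examples
#' classify_biome(26, 4000)   # "TrRF"
#' classify_biome(-12, 150)   # "Tu"
#' @export
classify_biome <- function(mat, map) {
  stopifnot(length(mat) == length(map))
  polys <- biome_polygons()
  labels <- names(polys)
  vapply(seq_along(mat), function(i) {
    if (!is.finite(mat[i]) || !is.finite(map[i])) return(NA_character_)
    for (lb in labels) {
      p <- polys[[lb]]
      if (point_in_poly(mat[i], map[i], p$mat, p$map)) return(lb)
    }
    d <- vapply(labels, function(lb) {
      p <- polys[[lb]]
      poly_distance(mat[i], map[i], p$mat, p$map)
    }, numeric(1))
    labels[which.min(d)]
  }, character(1))
}
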