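# Shared fixtures: tiny grids, occurrence tables and lineage worlds built
# in code at test time.

# constant-valued grid over [0, 10] x [0, 10] with 1-degree cells
toy_grid <- function(value = 7, variable = "MAT", nrow = 10, ncol = 10,
                     west = 0, north = 10, cellsize = 1) {
  spec <- grid_spec(west, north, cellsize, nrow, ncol)
  env_grid(spec, matrix(value, nrow, ncol), variable)
}

toy_mask <- function(land = TRUE, nrow = 10, ncol = 10, west = 0,
                     north = 10, cellsize = 1) {
  spec <- grid_spec(west, north, cellsize, nrow, ncol)
  land_mask(spec, matrix(land, nrow, ncol))
}

# monthly stack with every cell carrying the same 12-vector
toy_stack <- function(values12, what, nrow = 2, ncol = 2) {
  spec <- grid_spec(0, 10, 1, nrow, ncol)
  monthly_stack(spec, lapply(values12, function(v) matrix(v, nrow, ncol)),
                what)
}

occ_df <- function(taxon, lat, lon) {
  data.frame(taxon = taxon, decimalLatitude = lat, decimalLongitude = lon,
             stringsAsFactors = FALSE)
}

# brute-force Kendall tau over all index pairs (independent oracle)
brute_tau <- function(x, y) {
  C <- 0; D <- 0; tx <- 0; ty <- 0
  n <- length(x)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sx <- sign(x[j] - x[i]); sy <- sign(y[j] - y[i])
    if (sx == 0) tx <- tx + 1
    if (sy == 0) ty <- ty + 1
    if (sx * sy > 0) C <- C + 1
    if (sx * sy < 0) D <- D + 1
  }
  n0 <- n * (n - 1) / 2
  (C - D) / sqrt((n0 - tx) * (n0 - ty))
}

# group-niche table built directly from named per-lineage values:
# values is a list type -> named numeric vector (lineage -> value)
gn_table <- function(values, variable = "growth_season_temp") {
  do.call(rbind, unlist(recursive = FALSE, lapply(names(values), function(tp) {
    v <- values[[tp]]
    lapply(names(v), function(lin)
      data.frame(lineage = lin, type = tp, variable = variable,
                 value = unname(v[lin]), n_species = 1L,
                 stringsAsFactors = FALSE))
  })))
}

# small synthetic world shared by the slower pipeline tests
small_world <- function(seed = 11) {
  make_world(world_config(seed = seed))
}
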