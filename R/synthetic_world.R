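# Synthetic data generation with full ground truth.
#
# Three layers, each deterministic under a fixed seed and separately
# seeded (substream rule below): a physical world (monthly climate grids,
# soil surfaces, elevation, land mask), a set of comparison lineages with
# controllable niche conservatism and type-specific shifts, and per-species
# occurrence records sampled by environmental suitability, optionally laced
# with the record errors the QC stage is built to catch.
#
# Substream rule: from a master seed s, stage i (world = 1, lineages = 2,
# occurrences = 3, errors = 4) uses seed (s * 7919 + i) mod 2147483629.

substream_seed <- function(seed, stage) {
  as.integer((as.double(seed) * 7919 + stage) %% 2147483629)
}

#' Configuration of a synthetic world
#'
#' Defaults describe an Earth-like stated world: a global 2.5-degree grid,
#' temperature falling from a 28 deg C equator at 0.45 deg C per degree of
#' latitude, seasonal amplitude growing to 15 deg C at the poles, a wet
#' equatorial precipitation belt (~2500 mm) decaying to ~200 mm at high
#' latitude, rainfall concentration increasing away from the equator, soil
#' surfaces spanning the published topsoil ranges (OC 0-40 % weight, TEB
#' 0-80 and CEC 0-90 cmol/kg, pH 3-10), and ~30 % ocean.
#'
#' @param west,north,cellsize,nrow,ncol Grid registration
#'   ([grid_spec()]); default global at 2.5 degrees.
#' @param equator_temp Mean annual temperature at the equator (deg C).
#' @param lapse_per_degree MAT decrease per degree of |latitude| (deg C).
#' @param seasonal_amplitude Polar monthly temperature amplitude (deg C).
#' @param tmin_offset Offset of monthly minimum below monthly mean (deg C).
#' @param equator_precip,base_precip Peak equatorial-belt and high-latitude
#'   baseline annual precipitation (mm).
#' @param precip_belt_width e-folding width of the wet belt (deg latitude).
#' @param smoothing_cells Spatial smoothing radius of the noise fields, in
#'   cells; 0 gives white noise.
#' @param temp_noise_sd,precip_noise_sd Standard deviations of the smoothed
#'   noise added to MAT (deg C) and annual precipitation (mm).
#' @param ocean_fraction Fraction of cells assigned to water, in [0, 1).
#' @param seed Integer seed; the world is bit-identical for a fixed
#'   configuration.
#' @return A list of class `world_config`.
#' @export
world_config <- function(west = -180, north = 90, cellsize = 2.5,
                         nrow = 72, ncol = 144,
                         equator_temp = 28, lapse_per_degree = 0.45,
                         seasonal_amplitude = 15, tmin_offset = 6,
                         equator_precip = 2300, base_precip = 200,
                         precip_belt_width = 20,
                         smoothing_cells = 3,
                         temp_noise_sd = 2, precip_noise_sd = 200,
                         ocean_fraction = 0.3, seed = 1L) {
  stopifnot(ocean_fraction >= 0, ocean_fraction < 1)
  structure(as.list(environment()), class = "world_config")
}

# white noise smoothed by repeated box blur (radius in cells, clamped at
# the grid edge); unit variance after smoothing
smooth_noise <- function(nrow, ncol, radius) {
  z <- matrix(stats::rnorm(nrow * ncol), nrow, ncol)
  if (radius > 0) {
    blur_1d <- function(m) {          # along rows
      out <- m
      for (i in seq_len(base::nrow(m))) {
        lo <- pmax(1, seq_len(base::ncol(m)) - radius)
        hi <- pmin(base::ncol(m), seq_len(base::ncol(m)) + radius)
        cs <- cumsum(c(0, m[i, ]))
        out[i, ] <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
      }
      out
    }
    for (pass in 1:2) z <- t(blur_1d(t(blur_1d(z))))
  }
  z / stats::sd(z)
}

logistic_field <- function(z, lo, hi) lo + (hi - lo) * stats::plogis(z)

#' Generate a synthetic world
#'
#' Builds monthly mean/minimum temperature and precipitation stacks, four
#' soil surfaces, an elevation grid and a land mask from a
#' [world_config()].  Temperature decreases with |latitude| plus smoothed
#' noise; monthly amplitude grows with |latitude| (peak month July in the
#' north, January in the south); precipitation has a wet equatorial belt
#' and a rainfall concentration that grows poleward; soils and elevation
#' are smooth random surfaces in realistic ranges.  The 3x3 cell
#' neighbourhood around the institution-filter center is always land, so
#' planted institution-proximity errors are attributable to that filter.
#'
#' @param config A [world_config()].
#' @param institution `c(lat, lon)` kept on land (default GBIF HQ).
#' @return List of class `synthetic_world`: `spec`, `temp`, `tmin`, `prec`
#'   ([monthly_stack()]s), `soil` (named [env_grid()]s: OC, TEB, CEC, pH),
#'   `elevation`, `mask` ([land_mask()]), `layers` (all single-layer grids
#'   incl. derived bioclim, keyed by registry name) and `config`.
#' @export
make_world <- function(config = world_config(), institution = GBIF_HQ) {
  stopifnot(inherits(config, "world_config"))
  set.seed(substream_seed(config$seed, 1L))
  spec <- grid_spec(config$west, config$north, config$cellsize,
                    config$nrow, config$ncol)
  lat <- matrix(row_lats(spec), spec$nrow, spec$ncol)
  rad <- config$smoothing_cells
  tbar <- config$equator_temp - config$lapse_per_degree * abs(lat) +
    config$temp_noise_sd * smooth_noise(spec$nrow, spec$ncol, rad)
  amp <- config$seasonal_amplitude * abs(lat) / 90
  peak <- ifelse(lat >= 0, 7, 1)
  temp_layers <- lapply(1:12, function(m)
    tbar + amp * cos(2 * pi * (m - peak) / 12))
  tmin_layers <- lapply(temp_layers, function(x) x - config$tmin_offset)
  R <- config$base_precip +
    config$equator_precip * exp(-(lat / config$precip_belt_width)^2) +
    config$precip_noise_sd * smooth_noise(spec$nrow, spec$ncol, rad)
  R <- pmax(R, 10)
  conc <- pmin(0.95, pmax(0, 0.25 + abs(lat) / 120 +
                            0.25 * smooth_noise(spec$nrow, spec$ncol, rad)))
  wet_peak <- ifelse(lat >= 0, 7, 1)
  weights <- lapply(1:12, function(m)
    1 + conc * cos(2 * pi * (m - wet_peak) / 12))
  wsum <- Reduce(`+`, weights)
  prec_layers <- lapply(weights, function(w) R * w / wsum)
  soil_range <- list(OC = c(0.05, 40), TEB = c(0.1, 80),
                     CEC = c(0.5, 90), pH = c(3, 10))
  soil <- lapply(names(soil_range), function(v)
    env_grid(spec, logistic_field(1.5 * smooth_noise(spec$nrow, spec$ncol,
                                                     rad),
                                  soil_range[[v]][1], soil_range[[v]][2]),
             v))
  names(soil) <- names(soil_range)
  elevation <- env_grid(
    spec, logistic_field(1.5 * smooth_noise(spec$nrow, spec$ncol, rad) - 1,
                         0, 3000), "altitude")
  land <- matrix(TRUE, spec$nrow, spec$ncol)
  if (config$ocean_fraction > 0) {
    f <- smooth_noise(spec$nrow, spec$ncol, rad)
    land <- f > stats::quantile(f, config$ocean_fraction)
  }
  inst <- cell_index(spec, institution[[1]], institution[[2]])
  if (!is.na(inst$row)) {
    rows <- pmax(1, inst$row - 1):pmin(spec$nrow, inst$row + 1)
    cols <- pmax(1, inst$col - 1):pmin(spec$ncol, inst$col + 1)
    land[rows, cols] <- TRUE
  }
  temp <- monthly_stack(spec, temp_layers, "temperature")
  tmin <- monthly_stack(spec, tmin_layers, "tmin")
  prec <- monthly_stack(spec, prec_layers, "precipitation")
  bio <- derive_bioclim(temp, prec, tmin)
  layers <- c(bio, list(rainfall_seasonality = rainfall_seasonality(prec),
                        altitude = elevation), soil)
  structure(list(spec = spec, temp = temp, tmin = tmin, prec = prec,
                 soil = soil, elevation = elevation,
                 mask = land_mask(spec, land), layers = layers,
                 config = config),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("<synthetic_world> %d x %d cells (%g deg), %.0f%% land\n",
              x$spec$nrow, x$spec$ncol, x$spec$cellsize,
              100 * mean(x$mask$land)))
  invisible(x)
}

#' Configuration of synthetic comparison lineages
#'
#' The generative model mirrors the structure the sister-group analysis
#' assumes: each lineage has a base niche
#' \eqn{b_\ell \sim N(\mathrm{center}, \sigma_L^2)} per variable, and each
#' member species an optimum
#' \eqn{b_\ell + \delta_{\mathrm{type}} + N(0, \sigma_S^2)}.  The
#' conservatism index \eqn{\rho = \sigma_L^2 / (\sigma_L^2 + \sigma_S^2)}
#' is 0 when lineage identity carries no information and 1 when species
#' within a lineage are identical.  Defaults mirror the real comparison
#' set: 19 lineages with a C3 sister, 5 of them lacking close C4
#' relatives, plus 1 lineage contributing only to the C4 vs C3-C4
#' comparison (so the three comparisons have 19, 14 and 15 lineages), 3
#' species per type, and conservatism 0.5.
#'
#' @param n_lineages Lineages with C3 and C3-C4 members (default 19).
#' @param n_without_C4 How many of those lack a C4 sister set (default 5).
#' @param n_extra_C4_only Extra lineages with C3-C4 and C4 members but no
#'   usable C3 sister (default 1).
#' @param species_per_type Species per photosynthetic type per lineage.
#' @param occurrences_per_species Clean records per species.
#' @param variables Niche variable names.
#' @param center Named niche centers; defaults to 18 deg C / 1000 mm for
#'   MAT / MAP and 0 for other variables (overridden by the land mean when
#'   a world is supplied to [simulate_lineages()]).
#' @param sigma_L,sigma_S Between-lineage and within-lineage (between
#'   species) spreads, named per variable or recycled scalars; default
#'   5 deg C / 400 mm for MAT / MAP, 1 otherwise.
#' @param delta_c3c4,delta_c4 Additive type shifts per variable (named or
#'   recycled scalars; applied to C3-C4 and C4 species respectively; C3
#'   species carry no shift).
#' @param tau Suitability-kernel breadth per variable (named or recycled;
#'   default 2 deg C / 150 mm for MAT / MAP, 1 otherwise; used only when
#'   sampling occurrences against a world).
#' @param rate_duplicate,rate_offland,rate_institution,rate_invalid
#'   Error-injection rates (per clean record).
#' @param seed Integer seed.
#' @return A list of class `lineage_config` (with `rho`, the conservatism
#'   index per variable, attached).
#' @export
lineage_config <- function(n_lineages = 19, n_without_C4 = 5,
                           n_extra_C4_only = 1, species_per_type = 3,
                           occurrences_per_species = 100,
                           variables = c("MAT", "MAP"),
                           center = NULL, sigma_L = NULL, sigma_S = NULL,
                           delta_c3c4 = 0, delta_c4 = 0, tau = NULL,
                           rate_duplicate = 0.05, rate_offland = 0.02,
                           rate_institution = 0.01, rate_invalid = 0.01,
                           seed = 1L) {
  # per-variable fallbacks in natural units (deg C / mm); unlisted
  # variables default to unit scales
  fallback <- function(per_var, other) {
    out <- stats::setNames(rep(other, length(variables)), variables)
    known <- intersect(variables, names(per_var))
    out[known] <- per_var[known]
    out
  }
  recycle <- function(x, default) {
    if (is.null(x)) return(default)
    if (is.null(names(x))) {
      x <- rep_len(x, length(variables))
      names(x) <- variables
    }
    unknown <- setdiff(names(x), variables)
    if (length(unknown))
      stop("parameter names not in variables: ",
           paste(unknown, collapse = ", "))
    absent <- setdiff(variables, names(x))
    x[absent] <- default[absent]
    x[variables]
  }
  stopifnot(n_without_C4 <= n_lineages, species_per_type >= 1)
  center <- recycle(center, fallback(c(MAT = 18, MAP = 1000), 0))
  sigma_L <- recycle(sigma_L, fallback(c(MAT = 5, MAP = 400), 1))
  sigma_S <- recycle(sigma_S, fallback(c(MAT = 5, MAP = 400), 1))
  delta_c3c4 <- recycle(delta_c3c4, stats::setNames(rep(0, length(variables)),
                                                    variables))
  delta_c4 <- recycle(delta_c4, stats::setNames(rep(0, length(variables)),
                                                variables))
  tau <- recycle(tau, fallback(c(MAT = 2, MAP = 150), 1))
  if (any(sigma_L < 0) || any(sigma_S < 0)) stop("spreads must be >= 0")
  cfg <- list(n_lineages = n_lineages, n_without_C4 = n_without_C4,
              n_extra_C4_only = n_extra_C4_only,
              species_per_type = species_per_type,
              occurrences_per_species = occurrences_per_species,
              variables = variables, center = center, sigma_L = sigma_L,
              sigma_S = sigma_S, delta_c3c4 = delta_c3c4,
              delta_c4 = delta_c4, tau = tau,
              rate_duplicate = rate_duplicate, rate_offland = rate_offland,
              rate_institution = rate_institution,
              rate_invalid = rate_invalid, seed = seed,
              rho = sigma_L^2 / (sigma_L^2 + sigma_S^2))
  structure(cfg, class = "lineage_config")
}

#' Simulate comparison lineages with ground truth
#'
#' Draws lineage base niches and species optima under a
#' [lineage_config()].  Without a world, optima live in an abstract
#' variable space centered on `config$center`.  When a `world` is
#' supplied, every niche is anchored to actual land-cell environments (the
#' world's variables covary, so independently drawn per-variable values
#' need not co-occur anywhere): a lineage's base niche is the environment
#' of a uniformly drawn land cell, and each species optimum is the
#' environment of a land cell drawn with Gaussian weight `sigma_S` around
#' base + delta -- realizable and locally typical by construction.
#' `sigma_L` is not used in world mode; the between-lineage spread is the
#' world's own environmental spread.
#'
#' @param config A [lineage_config()].
#' @param world Optional [make_world()] output.
#' @return List of class `synthetic_lineages`: `membership` (lineage /
#'   species / photosynthetic_type data frame), `groups`
#'   ([comparison_groups()]), `truth` (list: `base` lineage-by-variable
#'   matrix, `optima` long data frame with per-species true (realizable)
#'   optima, `delta`, `rho`, `config`).
#' @export
simulate_lineages <- function(config = lineage_config(), world = NULL) {
  stopifnot(inherits(config, "lineage_config"))
  set.seed(substream_seed(config$seed, 2L))
  vars <- config$variables
  center <- config$center
  env_cells <- NULL
  if (!is.null(world)) {
    absent <- setdiff(vars, names(world$layers))
    if (length(absent))
      stop("world has no layer for variable(s): ",
           paste(absent, collapse = ", "))
    land <- which(world$mask$land)
    env_cells <- sapply(vars, function(v) world$layers[[v]]$values[land])
    env_cells <- matrix(env_cells, ncol = length(vars),
                        dimnames = list(NULL, vars))
  }
  # a *typical* realizable environment near `target`: a land cell drawn
  # with Gaussian weight at the given scales.  (A nearest-point projection
  # would systematically pick locally extreme environments -- hull points
  # of the env cloud -- and bias downstream median recovery.)
  realize_draw <- function(target, scales) {
    scales <- pmax(scales, 1e-9)   # zero width degenerates to nearest cell
    z <- sweep(sweep(env_cells, 2, target), 2, scales, "/")
    logw <- -0.5 * rowSums(z^2)
    env_cells[sample.int(nrow(env_cells), 1,
                         prob = exp(logw - max(logw))), ]
  }
  n_total <- config$n_lineages + config$n_extra_C4_only
  lineages <- sprintf("L%02d", seq_len(n_total))
  has_C3 <- c(rep(TRUE, config$n_lineages),
              rep(FALSE, config$n_extra_C4_only))
  has_C4 <- c(rep(c(FALSE, TRUE),
                  c(config$n_without_C4,
                    config$n_lineages - config$n_without_C4)),
              rep(TRUE, config$n_extra_C4_only))
  if (is.null(env_cells)) {
    base <- sapply(vars, function(v)
      stats::rnorm(n_total, center[[v]], config$sigma_L[[v]]))
    base <- matrix(base, nrow = n_total,
                   dimnames = list(lineages, vars))
  } else {
    # lineage bases are the environments of uniformly drawn land cells:
    # realizable and typical; between-lineage spread is then the world's
    # own environmental spread (sigma_L is not used in world mode)
    base <- env_cells[sample.int(nrow(env_cells), n_total,
                                 replace = TRUE), , drop = FALSE]
    dimnames(base) <- list(lineages, vars)
  }
  delta <- list(C3 = stats::setNames(rep(0, length(vars)), vars),
                `C3-C4` = config$delta_c3c4, C4 = config$delta_c4)
  rows <- list()
  opt_rows <- list()
  for (i in seq_len(n_total)) {
    types <- c(if (has_C3[i]) "C3", "C3-C4", if (has_C4[i]) "C4")
    for (tp in types) {
      for (s in seq_len(config$species_per_type)) {
        sp <- sprintf("%s_%s_sp%d", lineages[i], gsub("-", "", tp), s)
        if (is.null(env_cells)) {
          opt <- base[i, ] + delta[[tp]] +
            stats::rnorm(length(vars), 0, config$sigma_S)
        } else {
          opt <- realize_draw(base[i, ] + delta[[tp]], config$sigma_S[vars])
        }
        rows[[length(rows) + 1L]] <- data.frame(
          lineage = lineages[i], species = sp, photosynthetic_type = tp,
          stringsAsFactors = FALSE)
        opt_rows[[length(opt_rows) + 1L]] <- data.frame(
          lineage = lineages[i], species = sp, type = tp, variable = vars,
          optimum = unname(opt), row.names = NULL, stringsAsFactors = FALSE)
      }
    }
  }
  membership <- do.call(rbind, rows)
  truth <- list(base = base, optima = do.call(rbind, opt_rows),
                delta = delta, rho = config$rho, has_C4 = has_C4,
                config = config)
  structure(list(membership = membership,
                 groups = comparison_groups(membership), truth = truth),
            class = "synthetic_lineages")
}

#' Group niches implied by the simulation ground truth
#'
#' Mean of member-species true optima per lineage, type and variable --
#' the noiseless analogue of [group_niche_table()], used for calibration
#' experiments that bypass occurrence sampling.
#'
#' @param lineages Output of [simulate_lineages()].
#' @return Data frame `lineage`, `type`, `variable`, `value`, `n_species`.
#' @export
truth_group_niches <- function(lineages) {
  opt <- lineages$truth$optima
  agg <- stats::aggregate(optimum ~ lineage + type + variable, data = opt,
                          FUN = mean)
  cnt <- stats::aggregate(optimum ~ lineage + type + variable, data = opt,
                          FUN = length)
  out <- data.frame(lineage = agg$lineage, type = agg$type,
                    variable = agg$variable, value = agg$optimum,
                    n_species = cnt$optimum, stringsAsFactors = FALSE)
  out[order(out$lineage, out$type, out$variable), ]
}

#' Sample occurrence records from a synthetic world
#'
#' For each species, land cells are sampled with probability proportional
#' to the Gaussian suitability
#' \eqn{\exp(-\tfrac12 \sum_v ((e_v - o_v)/\tau_v)^2)} of their
#' environment, and a uniform jitter places each record inside its cell.
#' Jitter is resampled so that clean records (a) have a unique
#' two-decimal rounded coordinate key within their taxon, (b) lie more
#' than `radius_km + 2` km from the institution center, and (c) are not
#' exactly (0, 0) -- i.e. the stated world contains no accidental
#' QC casualties.  Error records are then injected at the configured
#' per-record rates (binomially drawn counts): exact coordinate
#' duplicates of existing records, points in water cells, points within
#' the institution radius, and invalid coordinates.
#'
#' @param lineages Output of [simulate_lineages()] (with a `world`).
#' @param world Output of [make_world()].
#' @param center,radius_km Institution filter geometry (defaults match
#'   [clean_occurrences()]).
#' @return List of class `synthetic_occurrences`: `records` (occurrence
#'   data frame: `taxon`, `decimalLatitude`, `decimalLongitude`), `truth`
#'   (the lineage truth extended with `injected`, a data frame describing
#'   every planted error record, and `n_clean`).
#' @export
simulate_occurrences <- function(lineages, world, center = GBIF_HQ,
                                 radius_km = 50) {
  stopifnot(inherits(lineages, "synthetic_lineages"),
            inherits(world, "synthetic_world"))
  config <- lineages$truth$config
  set.seed(substream_seed(config$seed, 3L))
  spec <- world$spec
  vars <- config$variables
  land_idx <- which(world$mask$land)
  if (!length(land_idx)) stop("world has no land cells")
  env_cells <- sapply(vars, function(v) world$layers[[v]]$values[land_idx])
  env_cells <- matrix(env_cells, ncol = length(vars),
                      dimnames = list(NULL, vars))
  cell_rc <- arrayInd(land_idx, c(spec$nrow, spec$ncol))
  cell_north <- spec$north - (cell_rc[, 1] - 1) * spec$cellsize
  cell_west <- spec$west + (cell_rc[, 2] - 1) * spec$cellsize
  opt <- lineages$truth$optima
  species <- unique(opt$species)
  n_occ <- config$occurrences_per_species
  recs <- vector("list", length(species))
  for (si in seq_along(species)) {
    sp <- species[si]
    o <- opt$optimum[opt$species == sp][match(vars,
                                              opt$variable[opt$species == sp])]
    z <- sweep(sweep(env_cells, 2, o), 2, config$tau[vars], "/")
    logw <- -0.5 * rowSums(z^2)
    logw[is.na(logw)] <- -Inf
    w <- exp(logw - max(logw))
    if (!any(is.finite(logw)))
      stop("species '", sp, "' has zero positive-suitability cells")
    cells <- sample.int(length(land_idx), n_occ, replace = TRUE, prob = w)
    seen <- character(0)
    lat <- numeric(n_occ); lon <- numeric(n_occ)
    for (j in seq_len(n_occ)) {
      repeat {
        la <- cell_north[cells[j]] - stats::runif(1) * spec$cellsize
        lo <- cell_west[cells[j]] + stats::runif(1) * spec$cellsize
        key <- paste(round_half_away(la, 2), round_half_away(lo, 2))
        far <- haversine_km(la, lo, center[[1]], center[[2]]) >
          radius_km + 2
        if (!(key %in% seen) && far && !(la == 0 && lo == 0)) {
          seen <- c(seen, key)
          lat[j] <- la; lon[j] <- lo
          break
        }
        cells[j] <- sample.int(length(land_idx), 1, prob = w)
      }
    }
    recs[[si]] <- data.frame(taxon = sp, decimalLatitude = lat,
                             decimalLongitude = lon,
                             stringsAsFactors = FALSE)
  }
  clean <- do.call(rbind, recs)
  n_clean <- nrow(clean)
  set.seed(substream_seed(config$seed, 4L))
  water_idx <- which(!world$mask$land)
  inj <- list()
  add_error <- function(df, type) {
    if (!is.null(df) && nrow(df)) {
      df$error_type <- type
      inj[[length(inj) + 1L]] <<- df
    }
  }
  n_dup <- stats::rbinom(1, n_clean, config$rate_duplicate)
  if (n_dup > 0) {
    src <- clean[sample.int(n_clean, n_dup, replace = FALSE), , drop = FALSE]
    add_error(src, "duplicate")
  }
  n_off <- stats::rbinom(1, n_clean, config$rate_offland)
  if (n_off > 0 && length(water_idx)) {
    wc <- arrayInd(sample(water_idx, n_off, replace = TRUE),
                   c(spec$nrow, spec$ncol))
    add_error(data.frame(
      taxon = sample(species, n_off, replace = TRUE),
      decimalLatitude = spec$north - (wc[, 1] - 0.5) * spec$cellsize,
      decimalLongitude = spec$west + (wc[, 2] - 0.5) * spec$cellsize,
      stringsAsFactors = FALSE), "off_land")
  }
  n_inst <- stats::rbinom(1, n_clean, config$rate_institution)
  if (n_inst > 0) {
    repeat {
      la <- center[[1]] + stats::runif(n_inst, -0.3, 0.3)
      lo <- center[[2]] + stats::runif(n_inst, -0.5, 0.5)
      if (all(haversine_km(la, lo, center[[1]], center[[2]]) < radius_km))
        break
    }
    add_error(data.frame(taxon = sample(species, n_inst, replace = TRUE),
                         decimalLatitude = la, decimalLongitude = lo,
                         stringsAsFactors = FALSE), "institution_proximity")
  }
  n_inv <- stats::rbinom(1, n_clean, config$rate_invalid)
  if (n_inv > 0) {
    kind <- sample(1:3, n_inv, replace = TRUE)
    la <- c(91, 0, NA_real_)[kind] + ifelse(kind == 1,
                                            stats::runif(n_inv, 0, 30), 0)
    lo <- c(10, 0, 10)[kind]
    add_error(data.frame(taxon = sample(species, n_inv, replace = TRUE),
                         decimalLatitude = la, decimalLongitude = lo,
                         stringsAsFactors = FALSE), "invalid_coordinate")
  }
  injected <- if (length(inj)) do.call(rbind, inj) else
    data.frame(taxon = character(0), decimalLatitude = numeric(0),
               decimalLongitude = numeric(0), error_type = character(0))
  records <- rbind(clean, injected[names(clean)])
  records$record_id <- seq_len(nrow(records))
  truth <- lineages$truth
  truth$injected <- injected
  truth$injected$record_id <- if (nrow(injected))
    n_clean + seq_len(nrow(injected)) else integer(0)
  truth$n_clean <- n_clean
  structure(list(records = records, truth = truth),
            class = "synthetic_occurrences")
}

#' Compare pipeline output with simulation ground truth
#'
#' Reports, per species and kernel variable, the absolute difference
#' between the recovered niche median and the true optimum in units of the
#' suitability breadth \eqn{\tau_v}; the realized conservatism (share of
#' optimum variance between lineages) against the configured \eqn{\rho};
#' and, when a contrast-suite report is supplied, which variables were
#' flagged versus planted.
#'
#' @param niches Species medians ([species_medians()]) from a pipeline run
#'   on the synthetic records.
#' @param truth The `truth` element of [simulate_occurrences()] (or
#'   [simulate_lineages()]) output.
#' @param suite Optional [run_contrast_suite()] report.
#' @return List with `median_error` (per species/variable data frame with
#'   `abs_error` and `error_in_tau`), `frac_within_half_tau`,
#'   `realized_rho` (per variable), and `detection` (flagged variables per
#'   comparison, or `NULL`).
#' @export
recover_parameters <- function(niches, truth, suite = NULL) {
  config <- truth$config
  opt <- truth$optima
  merged <- merge(opt, niches[c("taxon", "variable", "median")],
                  by.x = c("species", "variable"),
                  by.y = c("taxon", "variable"))
  merged$abs_error <- abs(merged$median - merged$optimum)
  merged$error_in_tau <- merged$abs_error / config$tau[merged$variable]
  realized_rho <- vapply(config$variables, function(v) {
    o <- opt[opt$variable == v, ]
    lin_means <- tapply(o$optimum, o$lineage, mean)
    vb <- stats::var(as.numeric(lin_means))
    vw <- mean(tapply(o$optimum, o$lineage, stats::var), na.rm = TRUE)
    vb / (vb + vw)
  }, numeric(1))
  detection <- NULL
  if (!is.null(suite)) {
    flagged <- suite[suite$test == "sign" & suite$significant, ]
    detection <- split(flagged$variable, flagged$comparison)
  }
  list(median_error = merged,
       frac_within_half_tau = mean(merged$error_in_tau <= 0.5),
       realized_rho = realized_rho, detection = detection)
}
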