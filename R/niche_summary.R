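# Species-level and group-level niche aggregation.
#
# The occurrence-level environment matrix is summarized per species by the
# median (robust to residual bad records), then per comparison group by the
# arithmetic mean of its member-species medians ("mean of medians").

#' Read and validate a group-membership table
#'
#' @param x Path to a CSV with columns `lineage`, `species`,
#'   `photosynthetic_type`, or an equivalent data frame.
#' @return Validated data frame with those three character columns.
#' @export
read_membership <- function(x) {
  m <- if (is.character(x)) utils::read.csv(x, stringsAsFactors = FALSE) else x
  need <- c("lineage", "species", "photosynthetic_type")
  missing_cols <- setdiff(need, names(m))
  if (length(missing_cols))
    stop("membership table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  bad <- setdiff(unique(m$photosynthetic_type), photosynthetic_types())
  if (length(bad))
    stop("unknown photosynthetic type(s): ", paste(bad, collapse = ", "))
  dup <- duplicated(m[c("lineage", "species")])
  if (any(dup)) m <- m[!dup, , drop = FALSE]
  m[need]
}

#' Build comparison groups from a membership table
#'
#' Each lineage becomes a comparison group holding disjoint C3, C3-C4 and
#' (optionally empty) C4 species sets.  Lineages without a C3-C4 member are
#' rejected; `has_C4_sister` records whether a C4 sister set exists.
#'
#' @param membership Membership table, see [read_membership()].
#' @return Named list of `comparison_group` objects (one per lineage), each
#'   with elements `lineage`, `C3`, `C3-C4`, `C4`, `has_C4_sister`.
#' @export
comparison_groups <- function(membership) {
  membership <- read_membership(membership)
  split_by <- split(membership, membership$lineage)
  out <- lapply(split_by, function(m) {
    sets <- lapply(photosynthetic_types(),
                   function(tp) m$species[m$photosynthetic_type == tp])
    names(sets) <- photosynthetic_types()
    if (!length(sets[["C3-C4"]]))
      stop("lineage '", m$lineage[1], "' has no C3-C4 member")
    structure(list(lineage = m$lineage[1], C3 = sets[["C3"]],
                   `C3-C4` = sets[["C3-C4"]], C4 = sets[["C4"]],
                   has_C4_sister = length(sets[["C4"]]) > 0),
              class = "comparison_group")
  })
  out[order(names(out))]
}

# sample median: even count -> mean of the two central order statistics
sample_median <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  stats::median(x)
}

#' Per-species, per-variable niche medians
#'
#' For each species and each variable, the median over non-missing occurrence
#' values.  The median is preferred over the mean to blunt the influence of
#' residual misidentifications or bad geocodes.
#'
#' @param env_matrix Occurrence-by-variable matrix
#'   ([assemble_env_matrix()]), possibly augmented with PC scores.
#' @param taxa Optional subset of taxa; default all taxa present.
#' @param warn_singletons Warn for species represented by one occurrence
#'   (they are retained).
#' @return Long data frame `taxon`, `variable`, `median`, `n` (count of
#'   non-missing values behind each median; variables with no data for a
#'   species are flagged by `n = 0` and `median = NA`).
#' @export
species_medians <- function(env_matrix, taxa = NULL, warn_singletons = FALSE) {
  vars <- intersect(c(env_variables(), pc_score_names()), names(env_matrix))
  if (is.null(taxa)) taxa <- sort(unique(env_matrix$taxon))
  missing_taxa <- setdiff(taxa, env_matrix$taxon)
  if (length(missing_taxa))
    stop("no occurrences for taxon/taxa: ",
         paste(missing_taxa, collapse = ", "))
  out <- do.call(rbind, lapply(taxa, function(tx) {
    rows <- env_matrix[env_matrix$taxon == tx, , drop = FALSE]
    if (warn_singletons && nrow(rows) == 1L)
      warning("taxon '", tx, "' has a single occurrence", call. = FALSE)
    data.frame(taxon = tx, variable = vars,
               median = vapply(vars, function(v) sample_median(rows[[v]]),
                               numeric(1)),
               n = vapply(vars, function(v) sum(!is.na(rows[[v]])),
                          integer(1)),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  out
}

#' Niche median profile of one species
#'
#' @inheritParams species_medians
#' @param taxon A single taxon name present in `env_matrix`.
#' @return One row per variable, see [species_medians()].
#' @export
species_median <- function(env_matrix, taxon) {
  stopifnot(length(taxon) == 1L)
  species_medians(env_matrix, taxa = taxon)
}

#' Mean of member-species medians for one group and type
#'
#' @param niches Output of [species_medians()].
#' @param group A `comparison_group` (see [comparison_groups()]).
#' @param type One of `"C3"`, `"C3-C4"`, `"C4"`.
#' @param allow_missing Return `NULL` instead of erroring when the type
#'   set is empty (a lineage can lack a usable C3 or C4 sister set; the
#'   C3-C4 set is always required).
#' @return Data frame `lineage`, `type`, `variable`, `value`, `n_species`
#'   (species contributing per variable), or `NULL` for an absent sister
#'   set (the C4 type of a group without a C4 sister, or an empty C3 set
#'   under `allow_missing`).
#' @export
group_mean_of_medians <- function(niches, group, type,
                                  allow_missing = FALSE) {
  stopifnot(inherits(group, "comparison_group"))
  type <- match.arg(type, photosynthetic_types())
  members <- group[[type]]
  if (!length(members)) {
    if (type == "C4" && !group$has_C4_sister) return(NULL)
    if (allow_missing && type != "C3-C4") return(NULL)
    stop("lineage '", group$lineage, "' has no members of type ", type)
  }
  absent <- setdiff(members, niches$taxon)
  if (length(absent))
    stop("no niche medians for species: ", paste(absent, collapse = ", "))
  sub <- niches[niches$taxon %in% members & niches$n > 0, , drop = FALSE]
  vars <- unique(niches$variable)
  agg <- lapply(vars, function(v) {
    vals <- sub$median[sub$variable == v]
    data.frame(lineage = group$lineage, type = type, variable = v,
               value = if (length(vals)) mean(vals) else NA_real_,
               n_species = length(vals), stringsAsFactors = FALSE)
  })
  do.call(rbind, agg)
}

#' Group-level niche table for all lineages and types
#'
#' @param niches Output of [species_medians()].
#' @param groups Output of [comparison_groups()].
#' @return Long data frame `lineage`, `type`, `variable`, `value`,
#'   `n_species` covering every lineage and every available type.
#' @export
group_niche_table <- function(niches, groups) {
  out <- do.call(rbind, unlist(recursive = FALSE, lapply(groups, function(g) {
    lapply(photosynthetic_types(),
           function(tp) group_mean_of_medians(niches, g, tp,
                                              allow_missing = TRUE))
  })))
  rownames(out) <- NULL
  out
}

#' Per-lineage occurrence ranges of the C3-C4 members
#'
#' Pools the occurrences of each lineage's C3-C4 member species and reports
#' the occurrence count and min-max range of latitude and of each requested
#' variable.  Lineages without any pooled occurrence are omitted with a
#' warning.
#'
#' @param env_matrix Occurrence-by-variable matrix.
#' @param membership Membership table, see [read_membership()].
#' @param variables Variables to range over; defaults to those of
#'   `altitude`, `MAT`, `MAP`, `OC`, `TEB`, `CEC`, `pH` present in
#'   `env_matrix`.
#' @return Data frame with `lineage`, `n`, `lat_min`, `lat_max`, then
#'   `<var>_min`/`<var>_max` per variable.
#' @export
range_table <- function(env_matrix, membership,
                        variables = NULL) {
  membership <- read_membership(membership)
  if (is.null(variables))
    variables <- intersect(c("altitude", "MAT", "MAP", "OC", "TEB", "CEC",
                             "pH"), names(env_matrix))
  focal <- membership[membership$photosynthetic_type == "C3-C4", ,
                      drop = FALSE]
  rows <- lapply(sort(unique(focal$lineage)), function(lin) {
    sp <- focal$species[focal$lineage == lin]
    sub <- env_matrix[env_matrix$taxon %in% sp, , drop = FALSE]
    if (!nrow(sub)) {
      warning("lineage '", lin, "' has no retained C3-C4 occurrences; ",
              "omitted from range table", call. = FALSE)
      return(NULL)
    }
    row <- data.frame(lineage = lin, n = nrow(sub),
                      lat_min = min(sub$decimalLatitude),
                      lat_max = max(sub$decimalLatitude),
                      stringsAsFactors = FALSE)
    for (v in variables) {
      vals <- sub[[v]][!is.na(sub[[v]])]
      row[[paste0(v, "_min")]] <- if (length(vals)) min(vals) else NA_real_
      row[[paste0(v, "_max")]] <- if (length(vals)) max(vals) else NA_real_
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
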