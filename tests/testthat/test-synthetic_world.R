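test_that("the synthetic world is deterministic and physically sensible", {
  w1 <- make_world(world_config(seed = 5))
  w2 <- make_world(world_config(seed = 5))
  expect_identical(w1$layers$MAT$values, w2$layers$MAT$values)
  expect_identical(w1$mask$land, w2$mask$land)
  w3 <- make_world(world_config(seed = 6))
  expect_false(identical(w1$layers$MAT$values, w3$layers$MAT$values))
  # equator warmer than 60 degrees latitude
  lats <- row_lats_of <- w1$spec$north -
    (seq_len(w1$spec$nrow) - 0.5) * w1$spec$cellsize
  eq_row <- which.min(abs(lats))
  cold_row <- which.min(abs(lats - 60))
  expect_gt(mean(w1$layers$MAT$values[eq_row, ]),
            mean(w1$layers$MAT$values[cold_row, ]))
  # precipitation belt: equator wetter than 60N
  expect_gt(mean(w1$layers$MAP$values[eq_row, ]),
            mean(w1$layers$MAP$values[cold_row, ]))
  # the institution neighbourhood is forced to land
  idx <- nichecontrast:::cell_index(w1$spec, 55.6761, 12.5683)
  expect_true(w1$mask$land[idx$row, idx$col])
  # roughly the configured ocean fraction
  expect_lt(abs(mean(!w1$mask$land) - 0.3), 0.05)
})

test_that("spatial smoothing increases neighbour correlation", {
  neigh_cor <- function(m) cor(as.vector(m[, -ncol(m)]),
                               as.vector(m[, -1]))
  rough <- make_world(world_config(seed = 7, smoothing_cells = 0))
  smooth <- make_world(world_config(seed = 7, smoothing_cells = 4))
  # soil surfaces are pure (transformed) noise fields
  expect_gt(neigh_cor(smooth$soil$OC$values),
            neigh_cor(rough$soil$OC$values) + 0.3)
})

test_that("lineage simulation honors its variance structure and defaults", {
  cfg <- lineage_config(seed = 9)
  expect_equal(unname(cfg$rho), c(0.5, 0.5))  # sigma_L = sigma_S defaults
  lin <- simulate_lineages(cfg)
  # default comparison set mirrors the published design: 19/14/15
  gn <- truth_group_niches(lin)
  p_all <- build_contrasts(gn, "C3C4_vs_C3_all", "MAT")
  p_c4 <- build_contrasts(gn, "C3C4_vs_C3_withC4", "MAT")
  p_vs <- build_contrasts(gn, "C4_vs_C3C4", "MAT")
  expect_equal(c(nrow(p_all), nrow(p_c4), nrow(p_vs)), c(19, 14, 15))
  # sigma_S = 0 and delta = 0: all species of a lineage share an optimum
  frozen <- simulate_lineages(lineage_config(sigma_S = 0, seed = 3))
  opt <- frozen$truth$optima
  spread <- tapply(opt$optimum, paste(opt$lineage, opt$variable),
                   function(v) max(v) - min(v))
  expect_true(all(spread == 0))
  # delta shifts the C3-C4 type additively
  shifted <- simulate_lineages(lineage_config(
    sigma_S = 0, delta_c3c4 = c(MAT = 3), seed = 3))
  so <- shifted$truth$optima
  base <- shifted$truth$base
  mat34 <- so[so$type == "C3-C4" & so$variable == "MAT", ]
  expect_equal(mat34$optimum, unname(base[mat34$lineage, "MAT"]) + 3)
  expect_error(lineage_config(delta_c3c4 = c(bogus = 1)),
               "not in variables")
})

test_that("high conservatism produces positive sister correlations", {
  # rho = 0.9: tau between C3 and C3-C4 lineage values should be positive
  # in nearly every replicate
  hits <- 0
  for (s in 1:200) {
    cfg <- lineage_config(n_lineages = 15, n_without_C4 = 0,
                          n_extra_C4_only = 0, species_per_type = 2,
                          variables = "MAT", center = c(MAT = 15),
                          sigma_L = c(MAT = 3), sigma_S = c(MAT = 1),
                          seed = 1000 + s)
    gn <- truth_group_niches(simulate_lineages(cfg))
    pairs <- build_contrasts(gn, "C3C4_vs_C3_all", "MAT")
    if (kendall_tau(pairs$reference, pairs$focal)$tau > 0) hits <- hits + 1
  }
  expect_gt(hits / 200, 0.95)
})

test_that("occurrence sampling concentrates where suitability peaks", {
  w <- small_world(seed = 31)
  cfg <- lineage_config(n_lineages = 2, n_without_C4 = 0,
                        n_extra_C4_only = 0, species_per_type = 1,
                        occurrences_per_species = 150,
                        sigma_L = c(MAT = 3, MAP = 200),
                        sigma_S = c(MAT = 0, MAP = 0),
                        tau = c(MAT = 1, MAP = 50), seed = 31)
  lin <- simulate_lineages(cfg, w)
  occ <- simulate_occurrences(lin, w)
  m <- assemble_env_matrix(occ$records[seq_len(occ$truth$n_clean), ],
                           list(MAT = w$layers$MAT, MAP = w$layers$MAP))
  sm <- species_medians(m)
  merged <- merge(sm, lin$truth$optima,
                  by.x = c("taxon", "variable"),
                  by.y = c("species", "variable"))
  err_tau <- abs(merged$median - merged$optimum) /
    cfg$tau[merged$variable]
  expect_lt(stats::median(err_tau), 1)
  # same seed gives identical records
  occ2 <- simulate_occurrences(simulate_lineages(cfg, w), w)
  expect_identical(occ$records, occ2$records)
})

test_that("error injection is fully book-kept and recovered by QC", {
  w <- small_world(seed = 41)
  cfg <- lineage_config(n_lineages = 4, n_without_C4 = 1,
                        n_extra_C4_only = 0, species_per_type = 2,
                        occurrences_per_species = 40,
                        rate_duplicate = 0.1, rate_offland = 0.05,
                        rate_institution = 0.02, rate_invalid = 0.02,
                        seed = 41)
  lin <- simulate_lineages(cfg, w)
  occ <- simulate_occurrences(lin, w)
  truth <- occ$truth
  expect_equal(nrow(occ$records), truth$n_clean + nrow(truth$injected))
  qc <- clean_occurrences(occ$records, mask = w$mask)
  dropped <- qc$records[qc$records$status == "dropped", ]
  # every dropped record is a planted one and vice versa, with the
  # matching reason
  expect_setequal(dropped$record_id, truth$injected$record_id)
  merged <- merge(dropped[c("record_id", "drop_reason")],
                  truth$injected[c("record_id", "error_type")])
  expect_equal(merged$drop_reason, merged$error_type)
  # injection counts are binomial draws around rate * n_clean
  expect_gt(nrow(truth$injected), 0)
  expect_lt(abs(sum(truth$injected$error_type == "duplicate") -
                  0.1 * truth$n_clean), 4 * sqrt(0.1 * truth$n_clean))
})

test_that("median recovery improves with more occurrences per species", {
  w <- small_world(seed = 51)
  err_at <- function(n_occ) {
    errs <- numeric(3)
    for (s in 1:3) {
      cfg <- lineage_config(n_lineages = 2, n_without_C4 = 0,
                            n_extra_C4_only = 0, species_per_type = 1,
                            occurrences_per_species = n_occ,
                            sigma_L = c(MAT = 2, MAP = 100),
                            sigma_S = c(MAT = 0, MAP = 0),
                            tau = c(MAT = 1.5, MAP = 80), seed = 60 + s)
      lin <- simulate_lineages(cfg, w)
      occ <- simulate_occurrences(lin, w)
      m <- assemble_env_matrix(occ$records[seq_len(occ$truth$n_clean), ],
                               list(MAT = w$layers$MAT))
      sm <- species_medians(m)
      merged <- merge(sm[sm$variable == "MAT", ], lin$truth$optima[
        lin$truth$optima$variable == "MAT", ],
        by.x = "taxon", by.y = "species")
      errs[s] <- mean(abs(merged$median - merged$optimum))
    }
    mean(errs)
  }
  expect_lt(err_at(160), err_at(10))
})
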