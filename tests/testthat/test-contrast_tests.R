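test_that("kendall tau-b matches the brute-force pair enumeration", {
  expect_equal(kendall_tau(1:4, c(1, 2, 4, 3))$tau, (5 - 1) / 6)
  expect_equal(kendall_tau(1:5, (1:5)^3)$tau, 1)       # monotone
  expect_equal(kendall_tau(1:5, rev(1:5))$tau, -1)     # reversed
  set.seed(13)
  for (n in 3:8) {
    for (rep in 1:20) {
      x <- rnorm(n); y <- rnorm(n)
      expect_equal(kendall_tau(x, y)$tau, brute_tau(x, y),
                   tolerance = 1e-12)
    }
    # with ties
    xt <- sample(1:3, n, TRUE); yt <- sample(1:3, n, TRUE)
    if (length(unique(xt)) > 1 && length(unique(yt)) > 1)
      expect_equal(kendall_tau(xt, yt)$tau, brute_tau(xt, yt),
                   tolerance = 1e-12)
  }
  expect_error(kendall_tau(c(1, 1, 1), 1:3), "constant")
  expect_error(kendall_tau(1:2, 1:2), "at least 3")
})

test_that("kendall p-values agree with cor.test", {
  set.seed(17)
  for (rep in 1:20) {
    n <- sample(4:9, 1)
    x <- rnorm(n); y <- rnorm(n)
    got <- kendall_tau(x, y)
    want <- cor.test(x, y, method = "kendall")
    expect_equal(got$method, "exact")
    expect_equal(got$p, want$p.value, tolerance = 1e-12)
  }
  # large-n path: normal approximation with continuity correction
  set.seed(18)
  x <- rnorm(40); y <- x + rnorm(40, 0, 2)
  got <- kendall_tau(x, y)
  want <- cor.test(x, y, method = "kendall", exact = FALSE,
                   continuity = TRUE)
  expect_equal(got$method, "normal")
  expect_equal(got$p, want$p.value, tolerance = 1e-10)
  expect_equal(got$tau, unname(want$estimate), tolerance = 1e-12)
})

test_that("sign test reproduces its tail conventions exactly", {
  # frozen exact-integer expectations
  expect_equal(sign_test(13, 14), 2 / 2^14)
  expect_equal(sign_test(12, 14), 2 * 15 / 2^14)
  expect_equal(sign_test(7, 15), 1)
  # k = n/2 with even n: the asymmetric paper convention leaves the point
  # mass at n/2 in the lower tail only; the symmetric convention gives 1
  expect_equal(sign_test(7, 14), 2 * pbinom(7, 14, 0.5, lower.tail = FALSE))
  expect_equal(sign_test(7, 14, "symmetric"), 1)
  # symmetric convention differs when the observed count is extreme
  expect_equal(sign_test(12, 14, "symmetric"), 2 * 106 / 2^14)
  expect_equal(signif(sign_test(12, 14, "symmetric"), 3), 0.0129)
  # at k = n the (empty) upper tail falls back to P(X >= n)
  expect_equal(sign_test(14, 14), 2 / 2^14)
  # both code paths (exact integers vs pbinom) agree to 1e-12
  for (n in c(5, 14, 19, 30)) for (k in 0:n) {
    upper <- if (k == n) dbinom(n, n, 0.5) else
      pbinom(k, n, 0.5, lower.tail = FALSE)
    p_ref <- min(1, 2 * min(pbinom(k, n, 0.5), upper))
    expect_equal(sign_test(k, n), p_ref, tolerance = 1e-12)
    expect_gt(sign_test(k, n), 0)
    expect_lte(sign_test(k, n), 1)
  }
  expect_error(sign_test(3.5, 10), "integers")
  expect_error(sign_test(5, 0), "n must be")
  expect_error(sign_test(11, 10), "0 <= k <= n")
})

test_that("corrected threshold is alpha over m", {
  expect_equal(corrected_threshold(0.05, 8), 0.00625)
  expect_equal(corrected_threshold(0.05, 1), 0.05)
  expect_equal(corrected_threshold(0.04, 5), 0.008)
  expect_error(corrected_threshold(1.2, 8))
})

test_that("contrast construction respects comparison eligibility", {
  gn <- gn_table(list(
    C3 = c(L1 = 1, L2 = 2, L3 = 3),
    `C3-C4` = c(L1 = 2, L2 = 1, L3 = 5, L4 = 4),
    C4 = c(L1 = 3, L3 = 2)))
  all_pairs <- build_contrasts(gn, "C3C4_vs_C3_all", "growth_season_temp")
  expect_equal(all_pairs$lineage, c("L1", "L2", "L3"))  # L4 has no C3
  withc4 <- build_contrasts(gn, "C3C4_vs_C3_withC4", "growth_season_temp")
  expect_equal(withc4$lineage, c("L1", "L3"))
  c4 <- build_contrasts(gn, "C4_vs_C3C4", "growth_season_temp")
  expect_equal(c4$focal, c(3, 2))
  expect_equal(c4$reference, c(2, 5))
  expect_error(build_contrasts(gn, "C4_vs_C3C4", "min_precip"),
               "no eligible")
  # single lineage input yields one pair
  one <- gn_table(list(C3 = c(L9 = 0), `C3-C4` = c(L9 = 1)))
  expect_equal(nrow(build_contrasts(one, "C3C4_vs_C3_all",
                                    "growth_season_temp")), 1)
})

test_that("shift counting matches a brute-force loop and reports ties", {
  pairs <- data.frame(lineage = c("a", "b", "c"), variable = "v",
                      focal = c(2, 1, 5), reference = c(1, 3, 4))
  sc <- count_shifts(pairs)
  expect_equal(sc$k, 2); expect_equal(sc$n, 3); expect_equal(sc$ties, 0)
  tied <- data.frame(lineage = "a", variable = "v", focal = 1,
                     reference = 1)
  sct <- count_shifts(tied)
  expect_equal(sct$n, 0); expect_equal(sct$ties, 1)
  expect_error(sign_test(sct$k, sct$n), "n must be")
  set.seed(23)
  rp <- data.frame(lineage = letters[1:15], variable = "v",
                   focal = sample(1:5, 15, TRUE),
                   reference = sample(1:5, 15, TRUE))
  brute_k <- 0; brute_n <- 0
  for (i in 1:15) {
    if (rp$focal[i] != rp$reference[i]) brute_n <- brute_n + 1
    if (rp$focal[i] > rp$reference[i]) brute_k <- brute_k + 1
  }
  sc2 <- count_shifts(rp)
  expect_equal(sc2$k, brute_k); expect_equal(sc2$n, brute_n)
})

test_that("the suite flags a planted uniform shift and nothing else", {
  set.seed(29)
  base <- seq(10, 75, length.out = 14)   # well separated so tau stays 1
  eps <- runif(14, 0.1, 0.2) * rep(c(1, -1), 7)
  gn <- rbind(
    gn_table(list(C3 = setNames(base, paste0("L", 1:14)),
                  `C3-C4` = setNames(base + 2, paste0("L", 1:14)),
                  C4 = setNames(base + 2 + eps, paste0("L", 1:14))),
             "growth_season_temp"),
    gn_table(list(C3 = setNames(base, paste0("L", 1:14)),
                  `C3-C4` = setNames(base + eps, paste0("L", 1:14)),
                  C4 = setNames(base + 2 * eps, paste0("L", 1:14))),
             "min_precip"))
  suite <- run_contrast_suite(gn, variables = c("growth_season_temp",
                                                "min_precip"), m = 8)
  expect_equal(attr(suite, "threshold"), 0.00625)
  planted <- suite[suite$test == "sign" &
                     suite$variable == "growth_season_temp" &
                     suite$comparison == "C3C4_vs_C3_withC4", ]
  expect_equal(planted$k, 14)
  expect_equal(planted$p, 2 / 2^14)
  expect_true(planted$significant)
  balanced <- suite[suite$test == "sign" & suite$variable == "min_precip" &
                      suite$comparison == "C3C4_vs_C3_all", ]
  expect_equal(balanced$k, 7)                 # eps alternates sign
  expect_false(balanced$significant)
  # strongly conserved niches give tau = 1
  taus <- suite$tau[suite$test == "kendall"]
  expect_true(all(taus == 1))
})
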