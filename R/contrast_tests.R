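# Sister-group inference: Kendall rank correlation between paired lineage
# values (phylogenetic effect) and a two-tailed binomial sign test of
# directional niche shifts, evaluated against a multiple-testing-corrected
# threshold.

#' Kendall rank correlation (tau-b) with a two-tailed p-value
#'
#' The statistic is the tie-corrected tau-b.  For n <= `exact_limit` (9)
#' without ties the two-tailed p-value is exact, from the full permutation
#' null distribution of the concordant-minus-discordant statistic (computed
#' by the inversion-count recursion, so no permutations are enumerated
#' explicitly); otherwise a normal approximation with continuity correction
#' and the standard tie-corrected variance is used.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param exact_limit Largest n for the exact null (default 9).
#' @return List with `tau`, `p`, `n`, and `method` (`"exact"` or
#'   `"normal"`).
#' @examples
#' kendall_tau(1:4, c(1, 2, 4, 3))  # tau = 2/3
#' @export
kendall_tau <- function(x, y, exact_limit = 9) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("tau undefined for a constant sequence")
  dx <- sign(outer(x, x, "-"))
  dy <- sign(outer(y, y, "-"))
  up <- upper.tri(dx)
  S <- sum(dx[up] * dy[up])
  n0 <- n * (n - 1) / 2
  tie_sum <- function(v) {
    t <- table(v)
    sum(t * (t - 1) / 2)
  }
  n1 <- tie_sum(x)
  n2 <- tie_sum(y)
  tau <- S / sqrt((n0 - n1) * (n0 - n2))
  has_ties <- n1 > 0 || n2 > 0
  if (n <= exact_limit && !has_ties) {
    p <- kendall_exact_p(S, n)
    method <- "exact"
  } else {
    p <- kendall_normal_p(S, x, y)
    method <- "normal"
  }
  list(tau = tau, p = p, n = n, method = method)
}

# Exact two-tailed P(|S*| >= |S|) under the permutation null (no ties).
# The null distribution of the discordant-pair count d is the Mahonian
# (inversion-count) distribution: T(m, d) = sum_{j=0..m-1} T(m-1, d-j).
kendall_exact_p <- function(S, n) {
  counts <- 1
  for (m in 2:n) {                   # insert item m: adds 0..m-1 inversions
    nc <- numeric(length(counts) + m - 1)
    for (j in 0:(m - 1)) {
      idx <- seq_along(counts) + j
      nc[idx] <- nc[idx] + counts
    }
    counts <- nc
  }                                  # counts[d+1], d = 0..choose(n,2)
  N <- n * (n - 1) / 2
  d_obs <- (N - S) / 2               # S = N - 2d
  dmin <- min(d_obs, N - d_obs)
  if (d_obs == N - d_obs) return(1)
  min(1, 2 * sum(counts[seq_len(dmin + 1)]) / factorial(n))
}

# Normal approximation with continuity correction; tie-corrected variance.
kendall_normal_p <- function(S, x, y) {
  n <- length(x)
  tx <- as.numeric(table(x)); ty <- as.numeric(table(y))
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(tx * (tx - 1) * (2 * tx + 5))
  vu <- sum(ty * (ty - 1) * (2 * ty + 5))
  v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
  v2 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
    (9 * n * (n - 1) * (n - 2))
  var_s <- (v0 - vt - vu) / 18 + v1 + v2
  if (var_s <= 0) return(1)
  z <- (S - sign(S)) / sqrt(var_s)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Two-tailed binomial sign test
#'
#' Tests whether `k` successes out of `n` independent 0.5-probability trials
#' are compatible with chance.  With `F` the cumulative distribution of
#' Binomial(n, 1/2), the default (`"paper"`) convention is
#' \deqn{p = \min(1,\; 2 \min(F(k),\, 1 - F(k)))}
#' i.e. the observed count is included in the lower tail and excluded from
#' the upper (at `k = n`, where that upper tail is empty, `P(X >= n)` is
#' used instead so the p-value stays positive).  The textbook symmetric
#' convention
#' \eqn{p = \min(1, 2\min(P(X \le k), P(X \ge k)))} is available as method
#' `"symmetric"`.  For n <= 30 tail masses are accumulated by exact integer
#' arithmetic (binomial coefficients over a power of two); larger n uses
#' [stats::pbinom()].
#'
#' @param k Number of successes (integer, `0 <= k <= n`).
#' @param n Number of trials (integer >= 1).
#' @param method `"paper"` (default) or `"symmetric"`.
#' @return Two-tailed p-value in (0, 1].
#' @examples
#' sign_test(13, 14)  # 2 * P(X > 13) = 2/2^14 ~ 0.00012
#' sign_test(7, 15)   # 1
#' @export
sign_test <- function(k, n, method = c("paper", "symmetric")) {
  method <- match.arg(method)
  if (length(k) != 1 || length(n) != 1 || is.na(k) || is.na(n) ||
      k != round(k) || n != round(n))
    stop("k and n must be single integers")
  if (n < 1) stop("n must be >= 1")
  if (k < 0 || k > n) stop("k must satisfy 0 <= k <= n")
  F_lower <- binom_cdf_half(k, n)           # P(X <= k)
  F_upper <- 1 - F_lower                    # P(X > k)
  # at k = n the upper tail above the observation is empty; fall back to
  # P(X >= n) so the p-value stays in (0, 1]
  if (k == n) F_upper <- 1 - binom_cdf_half(n - 1, n)
  if (method == "paper") {
    p <- 2 * min(F_lower, F_upper)
  } else {
    p_ge <- 1 - binom_cdf_half(k - 1, n)    # P(X >= k)
    p <- 2 * min(F_lower, p_ge)
  }
  min(1, p)
}

# P(X <= k) for X ~ Binomial(n, 1/2); exact integer arithmetic for n <= 30
# (choose() is exact there and 2^n fits a double exactly), pbinom beyond.
binom_cdf_half <- function(k, n) {
  if (k < 0) return(0)
  if (k >= n) return(1)
  if (n <= 30) sum(choose(n, 0:k)) / 2^n
  else stats::pbinom(k, n, 0.5)
}

#' Multiple-testing-corrected significance threshold
#'
#' Bonferroni division of the family-wise level by the number of tests;
#' with the default eight test variables, 0.05 / 8 = 0.00625.
#'
#' @param alpha Family-wise level in (0, 1), default 0.05.
#' @param m Number of comparisons (>= 1), default 8.
#' @return `alpha / m`.
#' @export
corrected_threshold <- function(alpha = 0.05, m = 8) {
  stopifnot(alpha > 0, alpha < 1, m >= 1)
  alpha / m
}

#' Build sister-group contrast pairs for one variable
#'
#' @param group_niches Long table from [group_niche_table()].
#' @param comparison One of `"C3C4_vs_C3_all"` (focal C3-C4 vs C3 over all
#'   lineages), `"C3C4_vs_C3_withC4"` (same, restricted to lineages with a
#'   C4 sister set), `"C4_vs_C3C4"` (focal C4 vs C3-C4).
#' @param variable Variable name present in `group_niches`.
#' @return Data frame `lineage`, `variable`, `focal`, `reference` with one
#'   row per eligible lineage; lineages missing the variable in either type
#'   are skipped with a message.
#' @export
build_contrasts <- function(group_niches,
                            comparison = c("C3C4_vs_C3_all",
                                           "C3C4_vs_C3_withC4",
                                           "C4_vs_C3C4"),
                            variable) {
  comparison <- match.arg(comparison)
  focal_type <- if (comparison == "C4_vs_C3C4") "C4" else "C3-C4"
  ref_type <- if (comparison == "C4_vs_C3C4") "C3-C4" else "C3"
  with_c4 <- unique(group_niches$lineage[group_niches$type == "C4" &
                                           group_niches$n_species > 0])
  lineages <- sort(unique(group_niches$lineage))
  if (comparison != "C3C4_vs_C3_all")
    lineages <- intersect(lineages, with_c4)
  pick <- function(lin, tp) {
    v <- group_niches$value[group_niches$lineage == lin &
                              group_niches$type == tp &
                              group_niches$variable == variable]
    if (length(v) != 1L || !is.finite(v)) NA_real_ else v
  }
  rows <- lapply(lineages, function(lin) {
    f <- pick(lin, focal_type)
    r <- pick(lin, ref_type)
    if (is.na(f) || is.na(r)) {
      message("build_contrasts: lineage '", lin, "' missing '", variable,
              "' for ", comparison, "; skipped")
      return(NULL)
    }
    data.frame(lineage = lin, variable = variable, focal = f,
               reference = r, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || !nrow(out))
    stop("no eligible lineages for ", comparison, " on ", variable)
  rownames(out) <- NULL
  out
}

#' Count directional shifts across lineages
#'
#' @param pairs Contrast pairs from [build_contrasts()].
#' @return List with `k` (lineages where focal > reference), `n` (non-tied
#'   lineages) and `ties`.
#' @export
count_shifts <- function(pairs) {
  stopifnot(nrow(pairs) >= 1)
  tied <- pairs$focal == pairs$reference
  list(k = sum(pairs$focal > pairs$reference), n = sum(!tied),
       ties = sum(tied))
}

#' Run the full contrast-test suite
#'
#' For each test variable: Kendall correlations between sister values
#' (C3-C4 vs C3 over all lineages; C4 vs C3-C4 over lineages with a C4
#' sister) and sign tests of directional shifts for the three comparisons.
#' Each p-value is flagged against the Bonferroni-corrected threshold
#' `alpha / m`.
#'
#' @param group_niches Long table from [group_niche_table()].
#' @param variables Variables to test; default [test_variables()].
#' @param alpha Family-wise level (default 0.05).
#' @param m Number of corrections (default `length(variables)`).
#' @param sign_method Tail convention for [sign_test()].
#' @return Data frame with one row per variable x test: columns `variable`,
#'   `comparison`, `test`, `tau`, `k`, `n`, `p`, `significant`; the applied
#'   threshold is attached as attribute `"threshold"`.
#' @export
run_contrast_suite <- function(group_niches, variables = test_variables(),
                               alpha = 0.05, m = length(variables),
                               sign_method = c("paper", "symmetric")) {
  sign_method <- match.arg(sign_method)
  thr <- corrected_threshold(alpha, m)
  variables <- intersect(variables, unique(group_niches$variable))
  if (!length(variables)) stop("none of the requested variables present")
  rows <- list()
  for (v in variables) {
    for (cmp in c("C3C4_vs_C3_all", "C4_vs_C3C4")) {
      pairs <- build_contrasts(group_niches, cmp, v)
      kt <- kendall_tau(pairs$reference, pairs$focal)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, comparison = cmp, test = "kendall", tau = kt$tau,
        k = NA_integer_, n = kt$n, p = kt$p, stringsAsFactors = FALSE)
    }
    for (cmp in c("C3C4_vs_C3_all", "C3C4_vs_C3_withC4", "C4_vs_C3C4")) {
      pairs <- build_contrasts(group_niches, cmp, v)
      sc <- count_shifts(pairs)
      if (sc$n == 0) stop("all lineages tied for ", v, " (", cmp, ")")
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, comparison = cmp, test = "sign", tau = NA_real_,
        k = sc$k, n = sc$n, p = sign_test(sc$k, sc$n, sign_method),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$significant <- out$p < thr
  attr(out, "threshold") <- thr
  out
}

#' Write a contrast-suite report
#'
#' @param report Output of [run_contrast_suite()].
#' @param csv_path,json_path Output paths (`NULL` to skip either).
#' @return Invisibly, the report.
#' @export
write_contrast_report <- function(report, csv_path = NULL,
                                  json_path = NULL) {
  ord <- order(report$variable, report$comparison, report$test)
  out <- report[ord, , drop = FALSE]
  if (!is.null(csv_path)) {
    fmt <- out
    for (col in c("tau", "p"))
      fmt[[col]] <- ifelse(is.na(out[[col]]), "",
                           format(out[[col]], digits = 12, trim = TRUE))
    utils::write.csv(fmt, csv_path, row.names = FALSE, na = "")
  }
  if (!is.null(json_path))
    jsonlite::write_json(out, json_path, digits = NA, na = "null")
  invisible(report)
}
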