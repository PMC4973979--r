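fw <- function(cf, cc, kf, kc) {
  structure(list(n_cancer_functional = cf, n_cancer_control = cc,
                 n_1kg_functional = kf, n_1kg_control = kc),
            class = "four_way_counts")
}

# Hypergeometric enumeration oracle for the two-sided Fisher p of a 2x2
# table with fixed margins (sum of probabilities <= the observed one).
fisher_2x2_oracle <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  x <- max(0, k - n):min(k, m)
  probs <- dhyper(x, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

test_that("the double ratio follows its definition and invariances", {
  r <- double_ratio(fw(10, 10, 10, 10))
  expect_equal(r$double_ratio, 1)
  r2 <- double_ratio(fw(40, 20, 30, 30))
  expect_equal(r2$double_ratio, 2)
  expect_equal(r2$fisher_p, fisher_2x2_oracle(40, 20, 30, 30), tolerance = 1e-9)
  # scaling all four counts leaves the ratio unchanged
  expect_equal(double_ratio(fw(400, 200, 300, 300))$double_ratio, 2)
  # swapping functional/control labels inverts the ratio
  expect_equal(double_ratio(fw(20, 40, 30, 30))$double_ratio, 1 / 2)
  # zero denominators: flagged undefined, Fisher still computed
  r0 <- double_ratio(fw(5, 0, 3, 3))
  expect_false(r0$defined)
  expect_true(is.na(r0$double_ratio))
  expect_true(is.finite(r0$fisher_p))
})

test_that("rate chi-squared matches hand computation with Yates correction", {
  # equal rates: statistic 0, p = 1
  r <- rate_chisq(100, 10000, 100, 10000)
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p_value, 1)
  # hand-sized table 30/1000 vs 10/1000 with Yates continuity correction
  m <- matrix(c(30, 970, 10, 990), 2, byrow = TRUE)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  stat_hand <- sum((abs(m - expected) - 0.5)^2 / expected)
  r2 <- rate_chisq(30, 1000, 10, 1000, yates = TRUE)
  expect_equal(unname(r2$statistic), stat_hand, tolerance = 1e-9)
  # doubling all cells increases the statistic
  r4 <- rate_chisq(60, 2000, 20, 2000, yates = TRUE)
  expect_gt(r4$statistic, r2$statistic)
})

test_that("the simulated profile shape test agrees with the exact 2x2 Fisher", {
  # identical profiles: no shape difference
  r <- position_profile_test(c(5, 5, 5), c(5, 5, 5), n_sim = 2000, seed = 1)
  expect_gt(r$shape_p, 0.5)
  # 2-position profiles: the simulated p converges to the exact 2x2 p
  exact <- fisher.test(cbind(c(18, 4), c(6, 15)))$p.value
  r2 <- position_profile_test(c(18, 4), c(6, 15), n_sim = 20000, seed = 2)
  mc_se <- sqrt(exact * (1 - exact) / 20000)
  expect_lt(abs(r2$shape_p - exact), 3 * mc_se + 1 / 20000)
  # all-zero profile: undefined and flagged
  r0 <- position_profile_test(c(0, 0), c(0, 0), n_sim = 100, seed = 3)
  expect_false(r0$defined)
  expect_true(is.na(r0$shape_p))
})

test_that("the shape test matches fisher.test's own simulation on an RxC table", {
  m <- matrix(c(20, 5, 9, 4, 18, 12), nrow = 3)
  r <- position_profile_test(m[, 1], m[, 2], n_sim = 2e4, seed = 5)
  set.seed(99)
  ref <- stats::fisher.test(m, simulate.p.value = TRUE, B = 2e4)$p.value
  mc_se <- sqrt(ref * (1 - ref) / 2e4)
  expect_lt(abs(r$shape_p - ref), 4 * mc_se + 2e-4)
})

test_that("a planted position hotspot is detected by the shape test", {
  L <- 19
  set.seed(7)
  base <- rpois(L, 8)
  cancer <- base + c(rep(0, 8), 60, rep(0, 10))  # hotspot at position 9
  kg <- rpois(L, 8)
  r <- position_profile_test(cancer, kg, n_sim = 1e4, seed = 4)
  expect_lt(r$shape_p, 1e-3)
})

# Assemble a site_mutation_table directly from per-motif counts, so panel
# behaviour can be tested across many motifs without a genome scan.
synthetic_tbl <- function(counts) {
  rows <- list()
  for (i in seq_len(nrow(counts))) {
    for (cell in c("cancer_functional", "cancer_control",
                   "1kg_functional", "1kg_control")) {
      n <- counts[[cell]][i]
      if (n == 0) next
      grp <- if (startsWith(cell, "cancer")) "cancer" else "1KG"
      cls <- sub(".*_", "", cell)
      rows[[length(rows) + 1L]] <- data.frame(
        site_id = sprintf("%s_%s", counts$motif_id[i], cls),
        motif_id = counts$motif_id[i], site_class = cls,
        cohort = ifelse(grp == "1KG", "1KG", "tumourA"), cohort_group = grp,
        sample_id = "s", chrom = "chr1", pos = 0L, motif_position = 1L,
        ref_m = "C", alt_m = "T",
        event_key = sprintf("%s_%s_%s_%d", counts$motif_id[i], cell,
                            grp, seq_len(n)),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(assignments = do.call(rbind, rows), variants = NULL,
                 motif_length = stats::setNames(rep(10L, nrow(counts)),
                                                counts$motif_id)),
            class = "site_mutation_table")
}

test_that("per-motif panels detect a planted global excess and stay quiet under the null", {
  set.seed(11)
  n_motifs <- 100
  mk <- function(fold) data.frame(
    motif_id = sprintf("M%03d", seq_len(n_motifs)),
    cancer_functional = rpois(n_motifs, 60 * fold),
    cancer_control = rpois(n_motifs, 60),
    `1kg_functional` = rpois(n_motifs, 40),
    `1kg_control` = rpois(n_motifs, 40), check.names = FALSE)
  planted <- per_motif_panels(synthetic_tbl(mk(1.4)))
  expect_lt(planted$tests$ratio_cancer_vs_1kg_p, 0.01)
  expect_gt(median(planted$table$double_ratio, na.rm = TRUE), 1.2)
  null <- per_motif_panels(synthetic_tbl(mk(1)))
  expect_gt(null$tests$ratio_cancer_vs_1kg_p, 0.01)
  # BH column is emitted alongside the uncorrected p-values
  expect_true(all(planted$table$fisher_p_bh >= planted$table$fisher_p - 1e-12))
})

test_that("Fisher power simulation is calibrated and monotone", {
  # equal rates: power approximately alpha
  p0 <- fisher_power(5000, 5000, 0.01, 0.01, n_sim = 400, seed = 1)
  expect_lt(abs(p0$power - 0.05), 0.05)
  # large n with a 3x rate difference: power at least 0.8
  p1 <- fisher_power(5000, 20000, 0.009, 0.003, n_sim = 200, seed = 2)
  expect_gte(p1$power, 0.8)
  # monotone non-decreasing in n (within Monte-Carlo error)
  sizes <- c(500, 2000, 8000)
  pw <- vapply(sizes, function(n) {
    fisher_power(n, 4 * n, 0.009, 0.003, n_sim = 200, seed = 3)$power
  }, numeric(1))
  expect_true(all(diff(pw) > -0.1))
})

test_that("null four-way simulations keep the per-motif false-positive rate near alpha", {
  nulls <- simulate_null_fourway(n_motifs = 200, seed = 9)
  ps <- vapply(nulls, function(x) double_ratio(x)$fisher_p, numeric(1))
  frac <- mean(ps < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 200))
})
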