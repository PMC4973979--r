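# Exhaustive enumeration oracle: scores and probabilities of every word of
# length L under the background, on the same discretized grid as the DP.
enumerate_tail <- function(pwm) {
  L <- pwm$length
  words <- as.matrix(expand.grid(rep(list(1:4), L)))
  scores <- numeric(nrow(words))
  probs <- numeric(nrow(words))
  for (i in seq_len(nrow(words))) {
    idx <- cbind(words[i, ], seq_len(L))
    scores[i] <- sum(pwm$disc[idx])
    probs[i] <- prod(pwm$background[words[i, ]])
  }
  list(scores = scores, probs = probs,
       tail = function(s) sum(probs[scores >= s]))
}

test_that("window scores follow the log-odds definition", {
  # uniform frequencies equal to background: every window scores 0
  unif <- pwm(matrix(25, 4, 5), "UNIF", pseudocount = 0)
  expect_equal(score_window(unif, "ACGTA"), 0)
  expect_equal(score_window(unif, "TTTTT", "-"), 0)
  # hand-computed case: two informative columns plus two uniform columns
  # (which contribute exactly zero bits)
  p2 <- pwm(matrix(c(97, 1, 1, 1, 97, 1, 1, 1, rep(25, 8)), 4, 4),
            "P2", pseudocount = 0)
  expect_equal(score_window(p2, "AACG"), 2 * log2(0.97 / 0.25))
  # minus strand scores the reverse complement: revcomp("CGTT") is "AACG"
  expect_equal(score_window(p2, "CGTT", "-"), 2 * log2(0.97 / 0.25))
  # consensus attains the per-column maximum
  p <- toy_pwm("ACGTT", dominance = 0.8)
  expect_equal(score_window(p, "ACGTT"),
               sum(apply(p$log_odds, 2, max)))
  # N windows are unscorable; length mismatch is a contract violation
  expect_true(is.na(score_window(p, "ACGNT")))
  expect_error(score_window(p, "ACGT"), "length")
})

test_that("DP score distribution is exact: sums to one and matches enumeration", {
  set.seed(1)
  for (L in 4:8) {
    counts <- matrix(stats::rgamma(4 * L, 2, 1) * 20, 4, L)
    p <- pwm(counts, sprintf("R%d", L))
    d <- pwm_score_distribution(p)
    expect_equal(sum(d$prob), 1, tolerance = 1e-9)
    oracle <- enumerate_tail(p)
    grid_scores <- d$min_score + seq_along(d$prob) - 1
    # check the full tail function on every occupied grid point
    occupied <- grid_scores[d$prob > 0]
    for (s in occupied) {
      expect_equal(d$tail[s - d$min_score + 1], oracle$tail(s),
                   tolerance = 1e-9)
    }
  }
})

test_that("p-value thresholds bound the background tail", {
  # length 8: the single best word has background probability 0.25^8 = 1.5e-5,
  # so the default match threshold of 4.4e-5 is attainable
  p <- toy_pwm("ACGTACGT", dominance = 0.85)
  d <- pwm_score_distribution(p)
  # p_max = 1 admits everything: threshold is the minimum attainable score
  thr1 <- score_threshold_for_pvalue(p, 1)
  expect_equal(thr1$min_score_grid, d$min_score)
  # a stringent threshold agrees with enumeration
  oracle <- enumerate_tail(p)
  thr <- score_threshold_for_pvalue(p, 4.4e-5)
  expect_lte(oracle$tail(thr$min_score_grid), 4.4e-5)
  expect_gt(oracle$tail(thr$min_score_grid - 1), 4.4e-5)
  # p_max below the best word's probability flags unattainability
  thr0 <- score_threshold_for_pvalue(p, 1e-12)
  expect_false(thr0$attainable)
})

test_that("scanning finds a planted consensus and only high-scoring windows", {
  p <- toy_pwm("ACGTACGTTG", id = "PLANT", dominance = 0.95)
  set.seed(5)
  bg <- sample(c("A", "C", "G", "T"), 3000, replace = TRUE)
  bg[1001:1010] <- strsplit("ACGTACGTTG", "")[[1]]
  genome <- genome_ref(c(chr1 = paste(bg, collapse = "")))
  hits <- scan_genome(p, genome, p_max = 4.4e-5)
  expect_true(any(hits$start == 1000 & hits$strand == "+"))
  # every reported hit satisfies the p-value bound, and p-values are in (0,1]
  expect_true(all(hits$p_value <= 4.4e-5))
  expect_true(all(hits$p_value > 0))
  # monotonicity: a smaller p_max never adds hits
  hits_tight <- scan_genome(p, genome, p_max = 1e-6)
  key <- function(h) paste(h$chrom, h$start, h$strand)
  expect_true(all(key(hits_tight) %in% key(hits)))
  # determinism: identical inputs give identical hit lists
  expect_identical(hits, scan_genome(p, genome, p_max = 4.4e-5))
})

test_that("all-N sequence yields no hits and excluded regions are masked out", {
  p <- toy_pwm("ACGTAC")
  genome_n <- genome_ref(c(chr1 = strrep("N", 500)))
  expect_equal(nrow(scan_genome(p, genome_n, p_max = 1)), 0L)
  # a hit overlapping an excluded region is dropped
  set.seed(2)
  bg <- sample(c("A", "C", "G", "T"), 1000, replace = TRUE)
  bg[501:506] <- strsplit("ACGTAC", "")[[1]]
  g1 <- genome_ref(c(chr1 = paste(bg, collapse = "")))
  g2 <- genome_ref(c(chr1 = paste(bg, collapse = "")),
                   excluded = data.frame(chrom = "chr1", start = 503L, end = 504L))
  expect_true(any(scan_genome(p, g1, 4.4e-5)$start == 500))
  expect_false(any(scan_genome(p, g2, 4.4e-5)$start == 500))
})

test_that("reverse-complementing the genome swaps strands and mirrors coordinates", {
  p <- toy_pwm("ACGGTACCGAT", dominance = 0.9)
  set.seed(9)
  bg <- sample(c("A", "C", "G", "T"), 4000, replace = TRUE)
  bg[601:611] <- strsplit("ACGGTACCGAT", "")[[1]]
  bg[2001:2011] <- strsplit(revcomp("ACGGTACCGAT"), "")[[1]]
  genome <- genome_ref(c(chr1 = paste(bg, collapse = "")))
  hits <- scan_genome(p, genome, p_max = 1e-4)
  expect_gte(nrow(hits), 2L)
  rc <- genome_ref(c(chr1 = revcomp(genome_seq(genome, "chr1", 0, 4000))))
  hits_rc <- scan_genome(p, rc, p_max = 1e-4)
  len <- 4000
  mirrored <- data.frame(start = len - hits$end,
                         strand = ifelse(hits$strand == "+", "-", "+"),
                         score = hits$score)
  o1 <- mirrored[order(mirrored$start, mirrored$strand), ]
  o2 <- hits_rc[order(hits_rc$start, hits_rc$strand), c("start", "strand", "score")]
  expect_equal(o1$start, o2$start)
  expect_equal(o1$strand, o2$strand)
  expect_equal(o1$score, o2$score)
})

test_that("hit capping keeps the smallest p-values with deterministic ties", {
  h <- data.frame(motif_id = "M", chrom = "chr1",
                  start = c(10L, 20L, 30L, 40L), end = c(16L, 26L, 36L, 46L),
                  strand = "+", score = c(5, 8, 7, 8),
                  p_value = c(1e-3, 1e-6, 1e-5, 1e-6),
                  site_class = "unassigned", stringsAsFactors = FALSE)
  expect_identical(cap_hits(h, 10L)$start, h$start)  # under cap: unchanged
  capped <- cap_hits(h, 2L)
  expect_setequal(capped$start, c(20L, 40L))  # the two 1e-6 hits
  capped3 <- cap_hits(h, 3L)
  expect_setequal(capped3$start, c(20L, 30L, 40L))
  expect_identical(cap_hits(h, 3L), capped3)  # deterministic
})
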