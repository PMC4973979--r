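iv <- function(chrom, start, end, ...) {
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             ..., stringsAsFactors = FALSE)
}

test_that("constitutive regions apply the support thresholds and merge", {
  master <- iv("chr1", c(0, 200, 500), c(100, 300, 600),
               support_count = c(113L, 112L, 125L))
  foot <- iv("chr1", c(300, 1000), c(400, 1100), support_count = c(39L, 38L))
  cr <- constitutive_regions(master, foot, 113L, 39L)
  # support 112 and 38 dropped; [200,300) out, [300,400) footprint in
  expect_equal(cr$start, c(0L, 300L, 500L))
  expect_equal(cr$end, c(100L, 400L, 600L))
  # adjacent retained intervals merge
  cr2 <- constitutive_regions(iv("chr1", c(100, 200), c(200, 300),
                                 support_count = c(120L, 120L)),
                              foot[0, ], 113L, 39L)
  expect_equal(cr2, iv("chr1", 100, 300))
  expect_error(constitutive_regions(iv("chr1", 0, 10), foot[0, ]),
               "support_count")
})

test_that("functional classification requires full containment", {
  hits <- data.frame(motif_id = "M", chrom = "chr1",
                     start = c(150L, 95L, 700L), end = c(169L, 114L, 719L),
                     strand = "+", score = 10, p_value = 1e-6,
                     site_class = "unassigned", stringsAsFactors = FALSE)
  const <- iv("chr1", 100, 300)
  out <- classify_functional(hits, const)
  expect_equal(out$site_class, c("functional", "unassigned", "unassigned"))
  # any-overlap mode admits the straddling hit
  out2 <- classify_functional(hits, const, containment = "any")
  expect_equal(out2$site_class, c("functional", "functional", "unassigned"))
})

test_that("control pool excludes open chromatin, genes, upstream margins and excluded", {
  mk_hit <- function(start) {
    data.frame(motif_id = "M", chrom = "chr1", start = start, end = start + 10L,
               strand = "+", score = 10, p_value = 1e-6,
               site_class = "unassigned", stringsAsFactors = FALSE)
  }
  genes <- iv("chr1", 10000, 12000, strand = "+")
  open <- iv("chr1", 3000, 3200)     # single-tissue DNase peak
  excl <- iv("chr1", 5000, 5100)
  # 1500 bp upstream of the + gene start (TSS 10000): inside the 2 kb margin
  expect_equal(nrow(select_controls(mk_hit(8500L), open, genes, excl)), 0L)
  # 2500 bp upstream: eligible
  expect_equal(nrow(select_controls(mk_hit(7500L), open, genes, excl)), 1L)
  # overlapping any-tissue open chromatin: excluded
  expect_equal(nrow(select_controls(mk_hit(3100L), open, genes, excl)), 0L)
  # inside the gene body or the excluded region: excluded
  expect_equal(nrow(select_controls(mk_hit(11000L), open, genes, excl)), 0L)
  expect_equal(nrow(select_controls(mk_hit(5050L), open, genes, excl)), 0L)
  # minus-strand gene: upstream margin sits beyond the gene end
  genes_m <- iv("chr1", 10000, 12000, strand = "-")
  expect_equal(nrow(select_controls(mk_hit(12500L), open, genes_m, excl)), 0L)
  expect_equal(nrow(select_controls(mk_hit(8500L), open, genes_m, excl)), 1L)
})

test_that("nearest matching is greedy in genome order with deterministic ties", {
  mk <- function(starts, class = "unassigned") {
    data.frame(motif_id = "M", chrom = "chr1", start = as.integer(starts),
               end = as.integer(starts) + 10L, strand = "+", score = 10,
               p_value = 1e-6, site_class = class, stringsAsFactors = FALSE)
  }
  # one functional site, controls at 5 kb and 40 kb: nearest wins
  cat1 <- match_nearest(mk(100L, "functional"), mk(c(5100L, 40100L)))
  expect_equal(cat1$start[cat1$site_class == "control"], 5100L)
  # two functional sites competing for one nearest control: first in genome
  # order takes it, the second takes its next-nearest
  fun <- mk(c(1000L, 2000L), "functional")
  pool <- mk(c(1600L, 9000L))
  cat2 <- match_nearest(fun, pool)
  ctl <- cat2[cat2$site_class == "control", ]
  fun_rows <- cat2[cat2$site_class == "functional", ]
  expect_equal(ctl$start[match(fun_rows$pair_id[fun_rows$start == 1000L],
                               ctl$pair_id)], 1600L)
  expect_equal(ctl$start[match(fun_rows$pair_id[fun_rows$start == 2000L],
                               ctl$pair_id)], 9000L)
  # equidistant controls: tie broken toward the smaller coordinate
  cat3 <- match_nearest(mk(5000L, "functional"), mk(c(3000L, 7000L)))
  expect_equal(cat3$start[cat3$site_class == "control"], 3000L)
  # no same-chromosome control: functional dropped, counts stay equal
  pool_other <- mk(8000L); pool_other$chrom <- "chr2"
  expect_message(cat4 <- match_nearest(mk(100L, "functional"), pool_other),
                 "dropped")
  expect_equal(nrow(cat4), 0L)
  expect_warning(match_nearest(mk(100L, "functional"), mk(1L)[0, ]),
                 "empty control pool")
})

test_that("the assembled catalog satisfies its invariants on synthetic data", {
  sim <- small_sim(seed = 21)
  catalog <- suppressMessages(catalog_from_sim(sim))
  s <- catalog$sites
  # per-motif equality of functional and control counts
  tab <- table(s$motif_id, s$site_class)
  expect_equal(unname(tab[, "functional"]), unname(tab[, "control"]))
  # matching is injective: every pair id occurs exactly twice, once per class
  expect_true(all(table(s$pair_id) == 2))
  # no control overlaps open chromatin, genes, upstream margins or excluded
  ctl <- s[s$site_class == "control", ]
  open_any <- rbind(sim$tracks$dnase_master[, c("chrom", "start", "end")],
                    sim$tracks$footprints[, c("chrom", "start", "end")])
  expect_false(any(overlaps_any(ctl, open_any)))
  expect_false(any(overlaps_any(ctl, sim$tracks$genes)))
  expect_false(any(overlaps_any(ctl, sim$tracks$excluded)))
  g <- sim$tracks$genes
  upstream <- data.frame(
    chrom = g$chrom,
    start = ifelse(g$strand == "+", pmax(0L, g$start - 2000L), g$end),
    end = ifelse(g$strand == "+", g$start, g$end + 2000L))
  expect_false(any(overlaps_any(ctl, upstream)))
  # matched distance recovers the planted ~10 kb spacing
  expect_lt(abs(matched_distance_median(catalog) - 10000), 500)
  # determinism given identical inputs
  catalog2 <- suppressMessages(catalog_from_sim(sim))
  expect_identical(catalog$sites, catalog2$sites)
})
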