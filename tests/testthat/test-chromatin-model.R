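test_that("anchor flags match a brute-force midpoint scan", {
  set.seed(3)
  sites <- data.frame(chrom = "chr1", start = sample(0:5000, 50),
                      stringsAsFactors = FALSE)
  sites$end <- sites$start + 19L
  anchors <- data.frame(chrom = "chr1", start = c(100L, 2000L, 4000L),
                        end = c(600L, 2400L, 4800L))
  got <- anchor_flag(sites, anchors)
  mid <- floor((sites$start + sites$end) / 2)
  oracle <- vapply(mid, function(m) {
    any(anchors$start <= m & m < anchors$end)
  }, logical(1))
  expect_equal(got, oracle)
})

test_that("anchor profiles conserve totals and peak at planted enrichment", {
  anchors <- data.frame(chrom = "chr1", start = c(50000L, 150000L),
                        end = c(50400L, 150400L))
  set.seed(9)
  # sites planted tightly around the anchor midpoints plus a uniform background
  amid <- floor((anchors$start + anchors$end) / 2)
  near <- data.frame(chrom = "chr1",
                     start = c(amid[1] - 9L + sample(-300:300, 40, TRUE),
                               amid[2] - 9L + sample(-300:300, 40, TRUE)))
  bg <- data.frame(chrom = "chr1", start = sample(0:200000, 50))
  sites <- rbind(near, bg)
  sites$end <- sites$start + 19L
  v <- make_variants("chr1", sample(0:200000, 200), "A", "G",
                     sample_id = "s1")
  prof <- anchor_profiles(sites, v, anchors, window_bp = 1000L,
                          span_bp = 20000L)
  expect_equal(prof$offset, seq(-19500, 19500, by = 1000))
  # enrichment peaks in the windows flanking offset zero
  expect_lte(abs(prof$offset[which.max(prof$motif_count)]), 500)
  # conservation: window totals equal direct in-span counts
  smid <- floor((sites$start + sites$end) / 2)
  direct <- sum(vapply(smid, function(m) {
    sum((m - amid) >= -20000 & (m - amid) < 20000)
  }, numeric(1)))
  expect_equal(sum(prof$motif_count), direct)
})

test_that("anchor burden and focal-position fractions detect a planted anchor effect", {
  cfg <- sim_config(seed = 101, pwms = default_sim_pwms()["CTCF_like"],
                    n_pairs = c(CTCF_like = 60L),
                    functional_fold = c(CTCF_like = 3.31),
                    anchor_fold = 8,
                    hotspot = list(motif_id = "CTCF_like", position = 9L,
                                   fold = 1),
                    cohorts = list(liver_like = list(n_samples = 10L,
                                                     rate_per_bp = 5e-4,
                                                     signature = "T>C",
                                                     hotspot = FALSE)),
                    germline_density = 0, selection_strength = 0)
  sim <- simulate_genome_and_tracks(cfg)
  catalog <- suppressMessages(catalog_from_sim(sim))
  muts <- simulate_mutations(sim)
  tbl <- intersect_variants(catalog, muts$somatic)
  ab <- anchor_burden_test(tbl, catalog, sim$tracks$anchors, "CTCF_like")
  # mutated-site fraction is higher inside anchors
  frac_in <- ab$n_mutated[["inside"]] / ab$n_sites[["inside"]]
  frac_out <- ab$n_mutated[["outside"]] / ab$n_sites[["outside"]]
  expect_gt(frac_in, frac_out)
  expect_lt(ab$fisher_p, 0.05)
})

test_that("published-count arithmetic for focal fractions matches the convention", {
  expect_equal(position_fraction_pct(204, 792), 26)
  expect_equal(position_fraction_pct(83, 539), 15)
})

test_that("the chromatin-state screen flags planted insulator excess in all cell lines", {
  # direct construction: 200 sites per motif, insulator sites mutate more
  # for the flagged motif only
  set.seed(11)
  mk_sites <- function(motif, n = 240L) {
    data.frame(motif_id = motif, chrom = "chr1",
               start = seq(0L, by = 1000L, length.out = n),
               end = seq(0L, by = 1000L, length.out = n) + 19L,
               strand = "+", site_class = "functional",
               stringsAsFactors = FALSE)
  }
  sites <- rbind(mk_sites("HOT"), mk_sites("COLD"))
  sites$start <- seq(0L, by = 1000L, length.out = nrow(sites))
  sites$end <- sites$start + 19L
  catalog <- manual_catalog(sites)
  colors <- rep(tfbsburden:::CHROMATIN_COLORS, length.out = nrow(sites))
  states <- data.frame(chrom = "chr1", start = sites$start - 100L,
                       end = sites$end + 100L, state_color = colors,
                       stringsAsFactors = FALSE)
  states$start <- pmax(states$start, 0L)
  p_mut <- ifelse(sites$motif_id == "HOT" & colors == "insulator", 0.7, 0.12)
  mutated <- stats::runif(nrow(sites)) < p_mut
  asg <- data.frame(site_id = catalog$sites$site_id[mutated],
                    motif_id = sites$motif_id[mutated],
                    site_class = "functional", cohort = "tumourA",
                    cohort_group = "cancer", sample_id = "s1",
                    chrom = "chr1", pos = sites$start[mutated],
                    motif_position = 1L, ref_m = "C", alt_m = "T",
                    event_key = paste0("e", which(mutated)),
                    stringsAsFactors = FALSE)
  tbl <- structure(list(assignments = asg, variants = NULL,
                        motif_length = c(HOT = 19L, COLD = 19L)),
                   class = "site_mutation_table")
  tracks <- list(cl1 = states, cl2 = states, cl3 = states)
  scr <- chromhmm_screen(catalog, tbl, tracks)
  expect_true("HOT" %in% scr$significant)
  expect_false("COLD" %in% scr$significant)
  # conjunction monotonicity: one cell line never flags fewer motifs than three
  scr1 <- chromhmm_screen(catalog, tbl, tracks["cl1"])
  expect_true(all(scr$significant %in% scr1$significant))
})

test_that("the logistic model recovers planted coefficients and rejects nulls", {
  st <- simulate_site_table(n_sites = 20000L, seed = 5)
  truth <- attr(st, "truth")
  fit <- fit_mutation_model(st)
  co <- fit$coefficients
  for (nm in c("timing", "functionality", "anchor")) {
    row <- co[co$term == nm, ]
    expect_lt(abs(row$estimate - truth[[nm]]) / row$se, 2.5)
  }
  # predicted fractions at constant timing are higher inside anchors
  pred <- fit$predicted
  expect_true(all(pred$predicted_fraction[pred$anchor == 1] >
                    pred$predicted_fraction[pred$anchor == 0]))
  # outcome independent of predictors: coefficients near zero
  st0 <- simulate_site_table(n_sites = 20000L, beta_timing = 0,
                             beta_functionality = 0, beta_anchor = 0,
                             motif_spread = 0, seed = 6)
  fit0 <- fit_mutation_model(st0)
  co0 <- fit0$coefficients
  for (nm in c("timing", "functionality", "anchor")) {
    expect_lt(abs(co0$estimate[co0$term == nm] / co0$se[co0$term == nm]), 3)
  }
})

test_that("correcting for replication timing deflates a timing-confounded anchor effect", {
  # anchors concentrated in late-replicating sequence; mutation rate driven
  # by timing only
  set.seed(8)
  n <- 30000L
  timing <- stats::rnorm(n)
  anchor <- stats::rbinom(n, 1, stats::plogis(1.5 * timing))
  eta <- -2.5 + 0.8 * timing  # no true anchor effect
  st <- data.frame(mutated = stats::rbinom(n, 1, stats::plogis(eta)),
                   timing = timing, motif_id = factor("M1"),
                   functionality = stats::rbinom(n, 1, 0.5), anchor = anchor)
  with_t <- fit_mutation_model(st)
  no_t <- stats::glm(mutated ~ functionality + anchor, binomial(), st)
  coef_with <- with_t$coefficients$estimate[with_t$coefficients$term == "anchor"]
  coef_without <- unname(coef(no_t)["anchor"])
  expect_gt(coef_without, 0.3)           # confounded: inflated anchor effect
  expect_lt(abs(coef_with), coef_without)  # timing correction deflates it
})

test_that("timing summaries by anchor status behave under null and planted shifts", {
  sites <- data.frame(chrom = "chr1", start = seq(0L, 99000L, by = 1000L))
  sites$end <- sites$start + 19L
  anchors <- data.frame(chrom = "chr1", start = 0L, end = 50000L)
  flat <- data.frame(chrom = "chr1", start = 0L, end = 100000L,
                     timing_value = 0.5)
  r_null <- timing_by_anchor(sites, flat, anchors)
  expect_equal(r_null$p_value, 1)
  gradient <- data.frame(chrom = "chr1", start = seq(0L, 99000L, by = 1000L),
                         end = seq(1000L, 100000L, by = 1000L),
                         timing_value = seq(0, 0.99, by = 0.01))
  r_grad <- timing_by_anchor(sites, gradient, anchors)
  expect_lt(r_grad$p_value, 1e-6)
  expect_lt(r_grad$median_inside, r_grad$median_outside)
})
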