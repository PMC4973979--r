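test_that("simulation is deterministic given a seed", {
  s1 <- small_sim(seed = 5)
  s2 <- small_sim(seed = 5)
  expect_identical(as.character(s1$genome$seq), as.character(s2$genome$seq))
  expect_identical(s1$truth, s2$truth)
  m1 <- simulate_mutations(s1)
  m2 <- simulate_mutations(s2)
  expect_identical(m1$somatic, m2$somatic)
  expect_identical(m1$germline, m2$germline)
  # a different seed changes the genome
  s3 <- small_sim(seed = 6)
  expect_false(identical(as.character(s1$genome$seq),
                         as.character(s3$genome$seq)))
})

test_that("the seed is mandatory and geometry is validated", {
  expect_error(sim_config(), "seed")
  expect_error(sim_config(seed = 1, tile_bp = 5000L) |>
                 simulate_genome_and_tracks(), "infeasible")
})

test_that("planted sites verify against the genome sequence and truth table", {
  sim <- small_sim(seed = 15)
  tr <- sim$truth[sim$truth$class %in% c("functional", "control"), ]
  p_ok <- vapply(seq_len(nrow(tr)), function(i) {
    s <- genome_seq(sim$genome, tr$chrom[i], tr$start[i], tr$end[i])
    if (tr$strand[i] == "-") s <- revcomp(s)
    score_window(sim$pwms[[tr$motif_id[i]]], s) > 0
  }, logical(1))
  expect_true(all(p_ok))
  # anchors only on functional sites of the anchor motif
  expect_true(all(tr$motif_id[tr$anchor] == "CTCF_like"))
  expect_true(all(tr$class[tr$anchor] == "functional"))
})

test_that("every somatic call carries a generating stratum consistent with the truth", {
  sim <- small_sim(seed = 25)
  muts <- simulate_mutations(sim)
  expect_true(all(muts$somatic$stratum %in% c("background", "functional",
                                              "hotspot")))
  fun <- sim$truth[sim$truth$class == "functional", c("chrom", "start", "end")]
  in_fun <- overlaps_any(muts$somatic, fun)
  expect_true(all(muts$somatic$stratum[!in_fun] == "background"))
  expect_true(all(muts$somatic$stratum[in_fun] != "background"))
  # references always agree with the genome
  chk <- suppressMessages(
    tfbsburden:::validate_variants(muts$somatic[, 1:7], sim$genome))
  expect_equal(nrow(chk), nrow(muts$somatic))
})

test_that("per-cohort empirical spectra recover the configured mixture", {
  cfg <- sim_config(seed = 35, pwms = default_sim_pwms()["CTCF_like"],
                    n_pairs = c(CTCF_like = 20L),
                    functional_fold = c(CTCF_like = 1), anchor_fold = 1,
                    hotspot = list(motif_id = "CTCF_like", position = 9L,
                                   fold = 1),
                    cohorts = list(big = list(n_samples = 5L,
                                              rate_per_bp = 4e-2,
                                              signature = "C>T",
                                              hotspot = FALSE)),
                    timing_beta = 0, germline_density = 0,
                    selection_strength = 0)
  sim <- simulate_genome_and_tracks(cfg)
  muts <- simulate_mutations(sim)
  expect_gt(nrow(muts$somatic), 50000)
  pooled <- muts$somatic
  pooled$sample_id <- "pooled"
  sp <- suppressMessages(sample_spectrum(pooled, sim$genome))
  target <- signature_preset("C>T")
  tvd <- sum(abs(sp$channels - target)) / 2
  expect_lt(tvd, 0.05)
})

test_that("germline selection thins PWM-lowering alleles at functional sites", {
  base <- list(seed = 45, pwms = default_sim_pwms()["CTCF_like"],
               n_pairs = c(CTCF_like = 60L),
               functional_fold = c(CTCF_like = 1), anchor_fold = 1,
               hotspot = list(motif_id = "CTCF_like", position = 9L, fold = 1),
               germline_density = 3e-2)
  sim_sel <- simulate_genome_and_tracks(
    do.call(sim_config, c(base, selection_strength = 0.9)))
  sim_neu <- simulate_genome_and_tracks(
    do.call(sim_config, c(base, selection_strength = 0)))
  fun <- sim_sel$truth[sim_sel$truth$class == "functional",
                       c("chrom", "start", "end")]
  n_fun_sel <- sum(overlaps_any(simulate_mutations(sim_sel)$germline, fun))
  n_fun_neu <- sum(overlaps_any(simulate_mutations(sim_neu)$germline, fun))
  # identical seeds: the same draws, thinned only under selection
  expect_lt(n_fun_sel, n_fun_neu)
})

test_that("a zero-pair motif yields an empty catalog", {
  cfg <- sim_config(seed = 55, pwms = default_sim_pwms()["MOTIF_D"],
                    n_pairs = c(MOTIF_D = 2L),
                    functional_fold = c(MOTIF_D = 1))
  sim <- simulate_genome_and_tracks(cfg)
  # remove the open-chromatin tracks: nothing can be classified functional
  sim$tracks$dnase_master <- sim$tracks$dnase_master[0, ]
  sim$tracks$footprints <- sim$tracks$footprints[0, ]
  catalog <- suppressMessages(catalog_from_sim(sim))
  expect_equal(nrow(catalog$sites), 0L)
})

test_that("the emitted dataset round-trips through the format readers", {
  sim <- small_sim(seed = 65)
  muts <- simulate_mutations(sim)
  dir <- withr::local_tempdir()
  write_sim_dataset(sim, muts, dir)
  # genome FASTA
  seqs <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  expect_identical(as.character(seqs), as.character(sim$genome$seq))
  # somatic MAF round-trip preserves every record
  g2 <- genome_ref(as.character(seqs),
                   excluded = read_intervals(file.path(dir, "excluded.bed")))
  som <- suppressMessages(
    read_variants(file.path(dir, "somatic.maf"), g2, cohort = "pooled"))
  expect_equal(nrow(som), nrow(muts$somatic))
  expect_equal(som$pos, muts$somatic$pos)
  # germline VCF round-trip preserves positions and frequencies
  kg <- suppressMessages(
    read_variants(file.path(dir, "germline.vcf"), g2, cohort = "1KG"))
  expect_equal(sort(kg$pos), sort(muts$germline$pos))
  expect_equal(sum(kg$allele_frequency > 0.05),
               sum(muts$germline$allele_frequency > 0.05))
  # support-count tracks keep their payloads
  master <- read_intervals(file.path(dir, "dnase_master.bed"), "support_bed")
  expect_setequal(master$support_count, sim$tracks$dnase_master$support_count)
  # PWM set round-trips to the same frequencies
  pwms2 <- read_pwm_set(file.path(dir, "motifs.pfm"), pseudocount = 0)
  expect_equal(pwms2$CTCF_like$freq, sim$pwms$CTCF_like$freq, tolerance = 1e-4)
})
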