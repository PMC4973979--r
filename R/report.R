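# Pipeline orchestration helpers and cohort-level reporting.

#' Default analysis thresholds
#'
#' The numeric defaults used across the pipeline, collected in one place so
#' drivers can echo them into output provenance blocks.
#'
#' @return named list: `p_max` (motif-match p-value ceiling, 4.4e-5),
#'   `cap` (per-motif hit cap, 300000), `master_min` / `master_total`
#'   (113/125), `footprint_min` / `footprint_total` (39/41),
#'   `upstream_margin` (2000 bp), `maf_min` (0.05), `flank_bp` (100),
#'   `min_mutations` (7000), `k_groups` (5), `alpha` (0.05),
#'   `chromhmm_p` (1e-3), `n_sim_shape` (1e6).
#' @export
run_defaults <- function() {
  list(p_max = 4.4e-5, cap = 300000L,
       master_min = 113L, master_total = 125L,
       footprint_min = 39L, footprint_total = 41L,
       upstream_margin = 2000L, maf_min = 0.05, flank_bp = 100L,
       min_mutations = 7000L, k_groups = 5L, alpha = 0.05,
       chromhmm_p = 1e-3, n_sim_shape = 1e6)
}

#' Scan a synthetic dataset and build its site catalog
#'
#' Convenience wrapper running the scanning and catalog stages over the
#' output of [simulate_genome_and_tracks()].
#'
#' @param sim output of [simulate_genome_and_tracks()].
#' @param p_max motif-match p-value ceiling.
#' @param cap per-motif hit cap.
#' @return a `site_catalog`.
#' @export
catalog_from_sim <- function(sim, p_max = 4.4e-5, cap = 300000L) {
  hits <- scan_genome_set(sim$pwms, sim$genome, p_max = p_max, cap = cap)
  const <- constitutive_regions(sim$tracks$dnase_master, sim$tracks$footprints)
  any_open <- rbind(sim$tracks$dnase_master[, c("chrom", "start", "end")],
                    sim$tracks$footprints[, c("chrom", "start", "end")])
  build_site_catalog(hits, const, any_open, sim$tracks$genes,
                     sim$tracks$excluded)
}

#' Fraction of planted sites recovered with the correct class
#'
#' @param catalog a `site_catalog`.
#' @param truth planted-site truth table from the simulator.
#' @return list with per-class recovery fractions and the overall fraction.
#' @export
catalog_recovery <- function(catalog, truth) {
  s <- catalog$sites
  truth <- truth[truth$class %in% c("functional", "control"), , drop = FALSE]
  key_cat <- paste(s$chrom, s$start, s$end, s$site_class)
  rec <- function(cls) {
    tt <- truth[truth$class == cls, , drop = FALSE]
    mean(paste(tt$chrom, tt$start, tt$end, cls) %in% key_cat)
  }
  out <- list(functional = rec("functional"), control = rec("control"))
  out$overall <- mean(
    paste(truth$chrom, truth$start, truth$end, truth$class) %in% key_cat)
  out
}

#' Planted-fold recovery study
#'
#' Runs the end-to-end pipeline (simulate, scan, catalog, intersect, count)
#' on a CTCF-like-only synthetic study with a planted functional fold and no
#' other planted effect (no hotspot, no anchor fold, no germline selection),
#' pooling the four-way counts across seeds, and returns the pooled double
#' ratio. The germline density is set high enough that the polymorphism
#' denominators carry adequate counts at desk scale.
#'
#' @param seeds integer vector of simulation seeds (one pipeline run each).
#' @param fold planted functional fold at the CTCF-like motif (default 3.3).
#' @param n_pairs planted site pairs (default 60).
#' @return list with `double_ratio` (pooled), `per_seed` (ratios per seed),
#'   `counts` (pooled `four_way_counts`).
#' @export
planted_fold_recovery <- function(seeds, fold = 3.3, n_pairs = 60L) {
  pooled <- list(n_cancer_functional = 0, n_cancer_control = 0,
                 n_1kg_functional = 0, n_1kg_control = 0)
  per_seed <- numeric(0)
  for (sd in seeds) {
    cfg <- sim_config(seed = sd,
                      pwms = default_sim_pwms()["CTCF_like"],
                      n_pairs = c(CTCF_like = n_pairs),
                      functional_fold = c(CTCF_like = fold),
                      anchor_fold = 1,
                      hotspot = list(motif_id = "CTCF_like", position = 9L,
                                     fold = 1),
                      selection_strength = 0,
                      germline_density = 4.5e-2)
    sim <- simulate_genome_and_tracks(cfg)
    catl <- catalog_from_sim(sim)
    muts <- simulate_mutations(sim)
    kg <- muts$germline[muts$germline$allele_frequency > 0.05, , drop = FALSE]
    vars <- rbind(muts$somatic[, names(kg)], kg)
    tbl <- intersect_variants(catl, vars)
    fw <- four_way_counts(tbl, motif_id = "CTCF_like")
    for (nm in names(pooled)) pooled[[nm]] <- pooled[[nm]] + fw[[nm]]
    per_seed <- c(per_seed, double_ratio(fw)$double_ratio)
  }
  class(pooled) <- "four_way_counts"
  list(double_ratio = double_ratio(pooled)$double_ratio,
       per_seed = per_seed, counts = pooled)
}

#' Cohort-level mutation summary
#'
#' Per cohort: number of samples, total substitutions, substitutions per
#' individual (rounded to the nearest integer) and deduplicated
#' substitutions inside functional TFBSs, plus grand totals.
#'
#' @param counts data frame with columns `cohort`, `n_individuals`,
#'   `n_mutations`, `n_tfbs_mutations` (deduplicated).
#' @return the data frame with `mutations_per_individual` added and a
#'   `"TOTAL"` row appended (whose per-individual cell is the grand-total
#'   ratio, rounded).
#' @export
summarize_cohort_counts <- function(counts) {
  stopifnot(all(c("cohort", "n_individuals", "n_mutations",
                  "n_tfbs_mutations") %in% names(counts)))
  empty <- counts$n_individuals == 0
  if (any(empty)) {
    warning(sum(empty), " empty cohort(s) excluded")
    counts <- counts[!empty, , drop = FALSE]
  }
  counts$mutations_per_individual <- round(counts$n_mutations / counts$n_individuals)
  total <- data.frame(cohort = "TOTAL",
                      n_individuals = sum(counts$n_individuals),
                      n_mutations = sum(counts$n_mutations),
                      n_tfbs_mutations = sum(counts$n_tfbs_mutations),
                      mutations_per_individual =
                        round(sum(counts$n_mutations) / sum(counts$n_individuals)),
                      stringsAsFactors = FALSE)
  rbind(counts, total)
}

#' Cohort summary table from variants and a site mutation table
#'
#' @param variants somatic variant data frame (cohort- and sample-labelled).
#' @param tbl a `site_mutation_table` built from the same variants.
#' @return summary data frame from [summarize_cohort_counts()].
#' @export
report_cohort_table <- function(variants, tbl) {
  v <- variants[variants$cohort != "1KG", , drop = FALSE]
  cohorts <- sort(unique(v$cohort))
  counts <- do.call(rbind, lapply(cohorts, function(co) {
    vv <- v[v$cohort == co, , drop = FALSE]
    data.frame(cohort = co,
               n_individuals = length(unique(vv$sample_id)),
               n_mutations = length(unique(variant_key(vv))),
               n_tfbs_mutations = dedup_total(tbl, site_class = "functional",
                                              cohort = co),
               stringsAsFactors = FALSE)
  }))
  summarize_cohort_counts(counts)
}
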