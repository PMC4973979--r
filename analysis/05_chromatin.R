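#!/usr/bin/env Rscript
# Stage 5: chromatin context and the site-level logistic mutation model.
#
# Loop-anchor profiles of CTCF motif and mutation density, the
# inside/outside-anchor burden and position-9 fractions, the chromatin-state
# screen across cell lines (p < 1e-3 in every cell line), replication timing
# by anchor status, and the logistic regression of mutated/not-mutated on
# timing, matrix, functionality and anchor membership.

library(tfbsburden)

defaults <- run_defaults()
genome <- genome_ref(
  as.character(Biostrings::readDNAStringSet("results/sim/genome.fa")),
  excluded = read_intervals("results/sim/excluded.bed"))
catalog <- read_catalog_bed("results/site_catalog.bed")
somatic <- local({
  samples <- read.table("results/sim/samples.tsv", header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
  v <- read_variants("results/sim/somatic.maf", genome, cohort = "pooled")
  v$cohort <- samples$cohort[match(v$sample_id, samples$sample_id)]
  v
})
anchors_pe <- read_intervals("results/sim/anchors.bedpe", "bedpe")
anchors <- unique(anchors_pe[, c("chrom", "start", "end")])
timing <- read_intervals("results/sim/timing.bedgraph", "bedgraph")
state_files <- list.files("results/sim", pattern = "^states_.*\\.bed$",
                          full.names = TRUE)
states <- lapply(state_files, read_intervals, kind = "state_bed")
names(states) <- sub("^states_(.*)\\.bed$", "\\1", basename(state_files))

tbl <- intersect_variants(catalog, somatic)
fun_ctcf <- catalog$sites[catalog$sites$motif_id == "CTCF_like" &
                            catalog$sites$site_class == "functional", ]

prof <- anchor_profiles(fun_ctcf, somatic, anchors,
                        window_bp = 1000L, span_bp = 20000L)
write.table(prof, "results/anchor_profiles.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

ab <- anchor_burden_test(tbl, catalog, anchors, "CTCF_like")
cat(sprintf("CTCF sites mutated inside anchors: %d/%d; outside: %d/%d (Fisher p = %.3g)\n",
            ab$n_mutated[["inside"]], ab$n_sites[["inside"]],
            ab$n_mutated[["outside"]], ab$n_sites[["outside"]], ab$fisher_p))
cat(sprintf("position-9 share of substitutions: %d%% inside vs %d%% outside anchors\n",
            ab$focal_inside$percent, ab$focal_outside$percent))

scr <- suppressWarnings(
  chromhmm_screen(catalog, tbl, states, p_threshold = defaults$chromhmm_p))
write.table(scr$per_cell_line, "results/chromhmm_screen.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("state-screen significant in all cell lines:",
    if (length(scr$significant)) paste(scr$significant, collapse = ", ")
    else "(none)", "\n")

tba <- timing_by_anchor(fun_ctcf, timing, anchors)
cat(sprintf("replication timing, median inside %.3f vs outside %.3f (rank p = %.3g)\n",
            tba$median_inside, tba$median_outside, tba$p_value))

site_tab <- regression_table(catalog, tbl, timing, anchors)
fit <- fit_mutation_model(site_tab)
write.table(fit$coefficients, "results/logistic_model.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("logistic model (Wald tests):\n")
print(fit$coefficients[fit$coefficients$term %in%
                         c("timing", "functionality", "anchor"), ],
      row.names = FALSE)
write.table(fit$predicted, "results/logistic_predicted_fractions.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
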