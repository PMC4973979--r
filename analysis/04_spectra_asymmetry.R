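#!/usr/bin/env Rscript
# Stage 4: mutational spectra and transcriptional strand asymmetry.
#
# Per-sample 96-channel spectra normalized by the genome's trinucleotide
# composition, Manhattan-distance hierarchical clustering into spectral
# groups, burden restratified by group (the hotspot should be confined to
# the T>C-signature group), and the A:T>G:C strand asymmetry genome-wide
# and at functional CTCF sites.

library(tfbsburden)

defaults <- run_defaults()
genome <- genome_ref(
  as.character(Biostrings::readDNAStringSet("results/sim/genome.fa")),
  excluded = read_intervals("results/sim/excluded.bed"))
catalog <- read_catalog_bed("results/site_catalog.bed")
samples <- read.table("results/sim/samples.tsv", header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
somatic <- read_variants("results/sim/somatic.maf", genome, cohort = "pooled")
somatic$cohort <- samples$cohort[match(somatic$sample_id, samples$sample_id)]
genes <- read_intervals("results/sim/genes.bed", "bed")

spectra <- spectra_by_sample(somatic, genome)
write_spectra_tsv(spectra, "results/spectra.tsv")

# the desk-scale study has fewer mutations per sample than a whole cancer
# genome; the retention threshold is scaled accordingly
retain <- min(defaults$min_mutations,
              stats::quantile(vapply(spectra, `[[`, numeric(1), "raw_count"),
                              0.1))
grouping <- cluster_spectra(spectra, min_mutations = retain, k = 2L)
print(grouping)
write_tree_newick(grouping, "results/spectra_tree.nwk")
write.table(data.frame(sample_id = names(grouping$groups),
                       group = grouping$groups),
            "results/spectra_groups.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

tbl <- intersect_variants(catalog, somatic)
strat <- stratified_burden(grouping, tbl, motif_id = "CTCF_like")
for (g in names(strat)) {
  cat(sprintf("group %s (%d samples): position-9 count %d (%.2f per individual)\n",
              g, strat[[g]]$n_samples, strat[[g]]$profile[9],
              strat[[g]]$profile_per_individual[9]))
}

# strand asymmetry of A:T>G:C mutations
uni <- unidirectional_regions(genes, genome)
asym_all <- asymmetry(uni, somatic, genome)
cat("genome-wide ")
print(asym_all)
fun_ctcf <- catalog$sites[catalog$sites$motif_id == "CTCF_like" &
                            catalog$sites$site_class == "functional",
                          c("chrom", "start", "end")]
asym_ctcf <- asymmetry(uni, somatic, genome, restrict_to = fun_ctcf)
cat("functional CTCF sites in transcribed regions ")
print(asym_ctcf)
asym_tab <- data.frame(
  stratum = c("genome_ntx", "genome_tx", "ctcf_ntx", "ctcf_tx"),
  bp_at_risk = c(asym_all$bp_at_risk_ntx, asym_all$bp_at_risk_tx,
                 asym_ctcf$bp_at_risk_ntx, asym_ctcf$bp_at_risk_tx),
  observed = c(asym_all$count_ntx, asym_all$count_tx,
               asym_ctcf$count_ntx, asym_ctcf$count_tx),
  asymmetry = c(asym_all$asymmetry, NA, asym_ctcf$asymmetry, NA))
write.table(asym_tab, "results/strand_asymmetry.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
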