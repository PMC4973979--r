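#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study.
#
# Builds the default study conditions — four planted motifs (one CTCF-like,
# 3.31-fold functional excess, anchors with a 3-fold effect and a position-9
# hotspot restricted to the T>C-signature cohort; 1.43-fold at the other
# motifs), two tumour cohorts, and a 1KG-like polymorphism panel under
# purifying selection — and writes the dataset in standard formats under
# results/sim/.

library(tfbsburden)

seed <- 20260923L
cfg <- sim_config(seed = seed,
                  n_pairs = c(CTCF_like = 60L, MOTIF_B = 30L,
                              MOTIF_C = 30L, MOTIF_D = 30L))
sim <- simulate_genome_and_tracks(cfg)
muts <- simulate_mutations(sim)

dir.create("results", showWarnings = FALSE)
write_sim_dataset(sim, muts, "results/sim")

cat("genome:", sum(sim$genome$chrom_lengths), "bp over",
    length(sim$genome$seq), "chromosomes\n")
cat("planted sites:", sum(sim$truth$class == "functional"), "functional,",
    sum(sim$truth$class == "control"), "control\n")
cat("somatic substitutions:", nrow(muts$somatic), "across",
    length(unique(muts$somatic$sample_id)), "samples\n")
cat("germline polymorphisms:", nrow(muts$germline),
    sprintf("(%d above 5%% frequency)\n",
            sum(muts$germline$allele_frequency > 0.05)))
cat("dataset written to results/sim/\n")
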