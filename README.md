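# tfbsburden

Genome-wide analysis of somatic mutation burden and binding disruption at
transcription factor binding sites (TFBSs), for researchers studying
regulatory mutation in cancer genomes.

Short motif matches (10–20 bp) mutate under strong compositional and
regional biases, so the package is built around a matched-control design:
PWM motif matches inside *constitutively* open chromatin (DNase-accessible
in nearly all cell types) are labelled putatively functional, and each is
position-matched to the nearest motif match of the same matrix in closed,
intergenic, mappable sequence. Somatic substitutions and common (>5%)
germline polymorphisms are intersected with both site classes, and the
central statistic per motif is the double ratio

```
(cancer_functional / cancer_control) / (1KG_functional / 1KG_control)
```

— above 1 when functional sites carry a somatic excess beyond what the
population tolerates at the same sequences. Around it the package
implements:

* PWM scanning with **exact** p-value calibration (dynamic programming over
  a discretized score grid; default match threshold p < 4.4e-5, 300,000-hit
  cap per motif),
* four-way Fisher contingency tests, per-bp rate chi-squared tests, and
  fixed-margin Monte-Carlo tests of per-position profile shape,
* binding-disruption scores PWM-score(ALT)/PWM-score(REF) with
  Price–Bonett distribution-free confidence intervals for ratios of group
  medians,
* 96-channel trinucleotide mutational spectra, expected-count normalized,
  with Manhattan-distance hierarchical clustering and group-stratified
  burden,
* transcriptional strand asymmetry of A:T>G:C mutations in
  unidirectionally transcribed regions,
* chromatin context: loop-anchor profiles and burden, a chromatin-state
  (six-colour) chi-squared screen across cell lines, and a site-level
  logistic model of mutation status on replication timing, matrix,
  functionality and anchor membership,
* a synthetic-data generator that plants all of these effects with known
  sizes, so every stage has a ground-truth recovery test.

## Worked example

A complete synthetic study, end to end:

```r
library(tfbsburden)

cfg <- sim_config(seed = 20260923L,
                  n_pairs = c(CTCF_like = 60L, MOTIF_B = 30L,
                              MOTIF_C = 30L, MOTIF_D = 30L))
sim  <- simulate_genome_and_tracks(cfg)   # 2.1 Mb genome, 150 site pairs
muts <- simulate_mutations(sim)           # 54,878 somatic calls, 20 samples

catalog <- catalog_from_sim(sim)          # scan + classify + match
matched_distance_median(catalog)
#> [1] 10000

kg   <- muts$germline[muts$germline$allele_frequency > 0.05, ]
tbl  <- intersect_variants(catalog, rbind(muts$somatic[, names(kg)], kg))
double_ratio(four_way_counts(tbl, motif_id = "CTCF_like"))$double_ratio
```

The catalog recovers the planted 10 kb functional–control spacing exactly,
and the CTCF-like double ratio lands near the planted 3.31-fold excess
(compounded by the planted anchor effect). The per-position profile of
functional CTCF-like sites makes the planted position-9 hotspot obvious —
from the driver run:

```
CTCF functional profile (cancer): 8 8 13 9 12 14 5 12 68 9 9 8 8 5 8 10 7 11 7
```

and restratifying by spectral group confines it to the T>C-signature
cohort (position-9 count 67 in that group versus 1 elsewhere).

The numbered drivers under `analysis/` run the same workflow through the
on-disk formats (FASTA, JASPAR pfm, BED/bedGraph/BEDPE, MAF-like, VCF) and
write tables under `results/`:

```sh
Rscript analysis/01_simulate.R        # genome, tracks, cohorts -> results/sim/
Rscript analysis/02_scan_catalog.R    # scan, classify, match   -> site_catalog.bed
Rscript analysis/03_burden_impact.R   # burden + disruption tables
Rscript analysis/04_spectra_asymmetry.R
Rscript analysis/05_chromatin.R
Rscript analysis/06_report.R          # cohort summary tables
```

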