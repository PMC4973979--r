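---
title: "Quantifying somatic mutation burden and disruption at transcription factor binding sites"
author: "tfbsburden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying somatic mutation burden and disruption at transcription factor binding sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfbsburden)
```

## The question and the design

Whole-genome sequencing of tumours shows that most somatic substitutions fall
outside coding sequence, and regulatory sites — short transcription factor
binding sites (TFBSs), typically 10–20 bp — are candidates both for driver
mutations and for unusual mutational mechanics. Measuring a rate excess at
such short elements is delicate: mutation rates vary with trinucleotide
context, chromatin accessibility and replication timing, so a naive
comparison of binding sites against arbitrary background conflates
composition with biology.

This package implements a matched-control design. Motif matches are found by
scanning the genome with position weight matrices (PWMs) under an exact
p-value threshold. Matches fully inside *constitutively* open chromatin —
DNase-accessible in nearly all assayed cell types, or inside near-universal
DNase footprints — are called **putatively functional**: open chromatin
across essentially all tissues is a strong proxy for occupancy without
needing per-factor ChIP data. For each matrix, an equal number of **control**
sites is drawn from motif matches in fully closed, intergenic, mappable
sequence, each functional site being matched to its *nearest* eligible
control so the pair shares regional mutation rate. Because functional and
control sites match the same matrix, they share sequence composition by
construction; the burden contrast is then internally controlled.

Two variant sets flow through the same catalog: somatic substitutions from
tumour cohorts, and common germline polymorphisms (allele frequency above
5%), which stand in for variation tolerated by purifying selection. The core
statistic is the **double ratio**

$$\frac{\text{cancer}_{\text{functional}} / \text{cancer}_{\text{control}}}
       {\text{1KG}_{\text{functional}} / \text{1KG}_{\text{control}}},$$

which is greater than 1 when functional sites carry a somatic excess beyond
what the population tolerates at the same sites. Disruption is quantified
per observed substitution as PWM-score(ALT)/PWM-score(REF) on the summed
log-odds score, with Price–Bonett distribution-free confidence intervals for
ratios of group medians.

## Motif scanning with exact p-values

Scores are summed log2 odds of the site sequence under the motif versus a
background (uniform by default; a genome-composition background can be
supplied — which one an external scanner used is rarely documented, so both
are supported). The null distribution of the score is computed exactly by
dynamic programming: per-column score distributions, discretized on a
1/1000-bit grid, are convolved across columns assuming independence under
the background. The scan threshold is the smallest grid score whose tail
probability is at most the match ceiling (default `p < 4.4e-5`), and every
reported hit carries its tail p-value from the same distribution — the
discretized window score is compared against the discretized threshold, so
scanning and calibration cannot disagree. Unit tests require the DP tail to
equal exhaustive enumeration over all $4^L$ words for every length up to 8.

Per motif, at most 300,000 instances are kept (worst p-values dropped, ties
broken by coordinate so results are reproducible). Windows containing N and
hits intersecting the excluded-region track are discarded. Overlapping hits,
including opposite-strand hits at one locus, are all retained; the
double-counting question is resolved downstream, where dataset-level totals
count each substitution event once no matter how many sites it touches.

## Catalog construction choices

Three points were genuinely open and are fixed as follows:

* **"Inside" open chromatin** means full containment of the motif interval,
  not mere overlap (an `any`-overlap mode exists as an option). A motif
  half-out of a DNase site is not convincingly bound.
* **Nearest matching is greedy in genome order**, each control used at most
  once, ties broken toward the smaller coordinate. Functional sites left
  without a same-chromosome control are dropped (with a logged count) rather
  than matched across chromosomes — cross-chromosome pairs would defeat the
  purpose of sharing regional rate.
* Controls may overlap each other across matrices, as functional sites may;
  only the exclusion tracks (any-tissue open chromatin, gene bodies, a 2 kb
  strand-aware upstream margin, excluded regions) are enforced.

## Burden and disruption statistics

Per motif, the four substitution counts (cancer/1KG × functional/control)
feed a two-sided Fisher exact test and the double ratio; all primary
p-values are uncorrected across the motif panel, with a Benjamini–Hochberg
column emitted alongside and clearly labelled. Motifs with a zero cell keep
their counts but are flagged ratio-undefined. Per-bp rate contrasts between
region sets use the 2×2 chi-squared with optional Yates correction.

The **shape test** compares per-position substitution profiles (cancer
versus 1KG) on the $L \times 2$ table by fixed-margin Monte-Carlo
simulation: tables are drawn with `r2dtable`, and the p-value is the
fraction of simulated tables whose conditional probability does not exceed
the observed one, with the $(1+k)/(1+B)$ correction; the default is
$10^6$ draws, configurable downward. The generic simulated Fisher test in
base R silently reverts to the exact test on 2×2 tables, so the simulation
is implemented in the package and cross-checked in tests against both the
exact 2×2 p-value and base R's own simulation on larger tables.

For disruption, records with non-positive reference scores are excluded
from median summaries (with a count) rather than clamped — a ratio of
signed scores has no interpretation. The Price–Bonett interval for the
ratio of medians uses the order-statistic standard error of each sample
median (the distribution-free binomial CI for the median, converted to a
standard error), combined on the log scale; coverage is verified by
simulation at roughly nominal level. A motif is called differently
disruptive in cancer when its cancer and 1KG intervals are disjoint —
deliberately conservative — and the direction is recorded, since an
increase of relative score in cancer (candidate binding gain) is as
interesting as a loss.

## Spectra, strand asymmetry, chromatin context

Per-sample mutational spectra use the standard 96 channels (six
pyrimidine-centred substitution classes × 16 flanking contexts). Observed
channel counts are divided by expected counts proportional to the
analyzable genome's trinucleotide abundance under an any-to-any equal-rate
assumption, then scaled to sum one; the absolute scale of the expectation
cancels, so only relative trinucleotide abundances matter. Samples with at
least 7,000 mutations are clustered on Manhattan distances; the linkage is
configurable (complete by default, recorded in output metadata) and the
tree is cut into a configurable number of groups (default 5) — a published
dendrogram cut is inherently visual, so the cut count is a parameter, not a
constant. Burden tables can be recomputed within each spectral group, with
per-individual normalization.

Transcriptional strand asymmetry of A:T>G:C mutations is computed in
unidirectionally transcribed regions (bidirectional overlap excluded): a
reference A in a region transcribed from the reference strand lies on the
non-transcribed strand, and symmetrically for reference T. The statistic is
the ratio of per-base-at-risk rates (non-transcribed over transcribed) with
a rate-ratio confidence interval; the raw counts and exposures are always
emitted so any alternative transform can be applied.

Chromatin context enters three ways: sliding-window profiles of motif and
mutation density around loop-anchor midpoints (1 kb windows over ±50 kb by
default — published profile figures rarely state their windows, so these
are explicit parameters); a per-motif chi-squared screen of mutated versus
intact sites across six chromatin-state colours, a motif passing only when
p is below the threshold (default $10^{-3}$) in *every* supplied cell
line; and a site-level logistic regression of mutated/not-mutated on
standardized replication timing (larger = later), the motif matrix as a
factor, functionality and anchor membership, with Wald tests and predicted
mutated fractions at fixed timing. Sites are assigned to anchors and states
by midpoint containment, which avoids double assignment at boundaries.
Anchor sets from different cell lines are analysed one at a time, never
merged.

## The synthetic-data generator

Every stage is testable against ground truth because the generator plants
its own effects. The genome is laid out in 14 kb tiles, one
functional/control pair per tile: the functional site (sequence drawn from
the PWM) sits inside a constitutive open-chromatin region whose support
count straddles the 113/125 master or 39/41 footprint threshold; the
control copy is planted 10 kb away in closed sequence — the catalog should
recover that spacing as its median matched distance; each tile carries a
gene (every third tile transcribing across its functional site, so strand
asymmetry has in-gene sites), a low-support tissue-variable open region,
and periodically an excluded block. A low-support accessibility blanket
covers the remainder of each tile except a small carve-out around the
planted control: control sites must sit in genuinely closed chromatin, and
the carve-out keeps the eligible pool from being flooded by background
motif matches. Spare "nursery" motif instances in an eligible margin at
each chromosome end give the control pool slack, so background functional
matches cannot exhaust it and cascade planted sites out of the catalog.

Somatic mutations are drawn per sample with per-base weights proportional
to the cohort's 96-channel signature over trinucleotide contexts,
multiplied by the functional fold inside planted functional sites (defaults:
3.31 for the CTCF-like matrix, 1.43 elsewhere), by the anchor fold (3) at
functional CTCF-like sites inside loop anchors, by the hotspot fold (8) at
motif position 9 of CTCF-like sites for samples of hotspot-carrying
cohorts, and log-linearly by replication timing. Every emitted call records
its generating stratum (background / functional / hotspot), enabling exact
decomposition tests. Germline polymorphisms are uniform with frequencies
from a site-frequency-shaped (log-uniform) distribution so the >5% filter
is exercised; purifying selection acts by *thinning* PWM-lowering alleles
at functional sites — the simplest mechanism that reproduces the
population-level contrast in which common variants at functional sites are
depleted and less disruptive.

What the generator does **not** emulate: megabase-scale rate domains,
sample-to-sample burden heterogeneity beyond Poisson, clustered mutations
(kataegis), indels and rearrangements, linkage between polymorphisms, and
realistic chromosome lengths. Passing tests therefore show that the
pipeline's statistics recover effects of the stated kind and size from data
with the stated structure — not that real cancer genomes contain them.

## Problem sizes, calibrations, degenerate inputs

The test and acceptance workloads run at desk scale by design: synthetic
genomes of one to a few megabases, tens of planted sites per motif, tens of
samples. Per-sample somatic rates (about $10^{-3}$ per bp) and the
germline density (1.5×10⁻², of which roughly a third exceeds the 5%
frequency cut) are deliberately denser than human reality: at a few
megabases, realistic densities would leave single-digit counts inside the
~2 kb of catalog site sequence and make every ratio denominator degenerate.
These are scaled-down study conditions, chosen once; the planted-fold
recovery study additionally switches off the hotspot, anchor fold and
germline selection, because each of those processes moves the pooled double
ratio away from the planted functional fold by construction, and raises the
germline density threefold so the 1KG denominators carry adequate counts.
The recovered pooled ratio runs slightly below the planted fold, because a
minority of catalog functional sites are background motif matches inside
open chromatin that carry no planted excess — the same dilution a real
catalog has, since a motif match in open chromatin is not a guarantee of
binding.

Numeric edge rules, collected: score grid 1/1000 bit; PWM pseudocount 0.01
per cell before column normalization; windows with N unscorable; variants
at contig edges skipped from spectra with a logged count; zero-width region
sets are an error for rate denominators; all-zero profiles and zero-count
ratio cells return flagged NA rather than numbers; ties in nearest matching
break toward the smaller coordinate; hit-cap ties break by coordinate;
Monte-Carlo seeds are mandatory arguments recorded in outputs.

## Limitations

The catalog inherits every limitation of motif scanning: a match is not
occupancy, and constitutive accessibility underrepresents tissue-specific
binding by design. The shape test has little power when one column of the
profile table is sparse — at desk scale the 1KG profile often is, and the
driver output shows exactly that. The chromatin-state screen needs
unsaturated per-site mutation probabilities to resolve colour differences;
at aggressive synthetic rates most sites are hit and the screen reports
nothing, which is correct behaviour, not a bug. Real-data concerns —
caller artefacts, mappability beyond the supplied exclusion list, tumour
purity — are out of scope for the synthetic validation.
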