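# Transcriptional strand asymmetry of A:T>G:C mutations.
#
# Within unidirectionally transcribed regions, a reference 'A' lies on the
# non-transcribed (coding) strand when the region is transcribed from the
# reference strand, and on the transcribed (template) strand when the region
# is transcribed from the complement strand; the logic is mirrored for
# reference 'T' (whose complementary 'A' sits on the other strand). The
# asymmetry statistic is the ratio of per-base-at-risk rates,
# non-transcribed over transcribed; raw counts are always emitted so other
# transforms can be applied.

#' Partition the genome by transcription direction
#'
#' @param genes stranded gene intervals.
#' @param genome optional `genome_ref` to bound intervals by chromosome ends.
#' @return list with `plus_only` (regions transcribed from the reference
#'   strand only), `minus_only` (complement strand only) and `bidirectional`
#'   (excluded from asymmetry analysis).
#' @export
unidirectional_regions <- function(genes, genome = NULL) {
  plus <- merge_intervals(genes[genes$strand == "+", , drop = FALSE])
  minus <- merge_intervals(genes[genes$strand == "-", , drop = FALSE])
  gr_p <- as_granges(plus); gr_m <- as_granges(minus)
  both <- GenomicRanges::intersect(gr_p, gr_m, ignore.strand = TRUE)
  p_only <- GenomicRanges::setdiff(gr_p, gr_m, ignore.strand = TRUE)
  m_only <- GenomicRanges::setdiff(gr_m, gr_p, ignore.strand = TRUE)
  strip <- function(gr) {
    df <- granges_to_df(gr); df$strand <- NULL; df
  }
  list(plus_only = strip(p_only), minus_only = strip(m_only),
       bidirectional = strip(both))
}

# Count A and T reference bases of a genome within an interval set.
count_at_bases <- function(genome, regions) {
  if (nrow(regions) == 0) return(c(A = 0, T = 0))
  a <- 0; t <- 0
  for (i in seq_len(nrow(regions))) {
    s <- genome_seq(genome, regions$chrom[i], regions$start[i], regions$end[i])
    f <- Biostrings::letterFrequency(Biostrings::DNAString(s), c("A", "T"))
    a <- a + f[["A"]]; t <- t + f[["T"]]
  }
  c(A = a, T = t)
}

#' Transcriptional strand asymmetry of A:T>G:C mutations
#'
#' @param regions list from [unidirectional_regions()].
#' @param variants variant data frame (typically one cohort's somatic
#'   mutations).
#' @param genome a `genome_ref`.
#' @param restrict_to optional interval data frame (e.g. functional CTCF
#'   sites) intersected with the unidirectional regions before counting.
#' @param conf_level confidence level of the rate-ratio interval
#'   (default 0.95).
#' @return list of class `asymmetry_result`: base pairs at risk and observed
#'   A:T>G:C counts per strand stratum (`ntx` = reference A on the
#'   non-transcribed strand), per-bp rates, the `asymmetry` ratio
#'   (ntx / tx) and its confidence interval.
#' @export
asymmetry <- function(regions, variants, genome, restrict_to = NULL,
                      conf_level = 0.95) {
  scope <- function(df) {
    if (is.null(restrict_to) || nrow(df) == 0) return(df)
    gr <- GenomicRanges::intersect(as_granges(df),
                                   as_granges(merge_intervals(restrict_to)),
                                   ignore.strand = TRUE)
    out <- granges_to_df(gr); out$strand <- NULL; out
  }
  plus <- scope(regions$plus_only)
  minus <- scope(regions$minus_only)
  at_plus <- count_at_bases(genome, plus)
  at_minus <- count_at_bases(genome, minus)
  # bases at risk: reference A on the non-transcribed strand happens for A in
  # plus-transcribed regions and (via the complementary A) for T in
  # minus-transcribed regions.
  bp_ntx <- at_plus[["A"]] + at_minus[["T"]]
  bp_tx <- at_minus[["A"]] + at_plus[["T"]]
  v <- variants[(variants$ref == "A" & variants$alt == "G") |
                  (variants$ref == "T" & variants$alt == "C"), , drop = FALSE]
  in_plus <- overlaps_any(v, plus)
  in_minus <- overlaps_any(v, minus)
  n_ntx <- sum(in_plus & v$ref == "A") + sum(in_minus & v$ref == "T")
  n_tx <- sum(in_minus & v$ref == "A") + sum(in_plus & v$ref == "T")
  if (bp_ntx == 0 || bp_tx == 0) {
    warning("zero at-risk bp in a stratum; asymmetry undefined")
    ratio <- NA_real_; ci <- c(NA_real_, NA_real_)
  } else {
    ratio <- (n_ntx / bp_ntx) / (n_tx / bp_tx)
    pt <- stats::poisson.test(c(n_ntx, n_tx), c(bp_ntx, bp_tx),
                              conf.level = conf_level)
    ci <- unname(pt$conf.int)
  }
  structure(list(bp_at_risk_ntx = bp_ntx, bp_at_risk_tx = bp_tx,
                 count_ntx = n_ntx, count_tx = n_tx,
                 rate_ntx = n_ntx / bp_ntx, rate_tx = n_tx / bp_tx,
                 asymmetry = ratio, conf_int = ci, conf_level = conf_level),
            class = "asymmetry_result")
}

#' @export
print.asymmetry_result <- function(x, ...) {
  cat(sprintf("A:T>G:C strand asymmetry (ntx/tx): %.3f [%.3f, %.3f]\n",
              x$asymmetry, x$conf_int[1], x$conf_int[2]))
  cat(sprintf("  ntx: %d / %d bp; tx: %d / %d bp\n",
              x$count_ntx, x$bp_at_risk_ntx, x$count_tx, x$bp_at_risk_tx))
  invisible(x)
}
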