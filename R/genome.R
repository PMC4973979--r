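# Reference-genome container: sequences, excluded (unmappable) regions and
# pyrimidine-centred trinucleotide counts over the analyzable genome.

PYRIMIDINE_TRINUCS <- local({
  b <- c("A", "C", "G", "T")
  ctx <- expand.grid(left = b, centre = c("C", "T"), right = b,
                     stringsAsFactors = FALSE)
  sort(paste0(ctx$left, ctx$centre, ctx$right))
})

#' Build a reference genome object
#'
#' Wraps a set of chromosome sequences together with the excluded-region
#' (unmappable) track and the trinucleotide composition of the analyzable
#' genome. "Analyzable" means outside excluded regions and free of N bases;
#' trinucleotide counts are collapsed to the 32 pyrimidine-centred contexts by
#' reverse complementing purine-centred windows, the standard 96-channel
#' convention.
#'
#' @param seqs named character vector of chromosome sequences, or a
#'   `Biostrings::DNAStringSet`.
#' @param excluded optional interval data frame (`chrom`, `start`, `end`,
#'   0-based half-open) of regions to exclude from all rate denominators.
#' @return an object of class `genome_ref` with elements `seq`
#'   (`DNAStringSet`), `excluded`, `trinuc` (named counts over
#'   the 32 pyrimidine-centred trinucleotides) and `chrom_lengths`.
#' @export
genome_ref <- function(seqs, excluded = NULL) {
  if (is.character(seqs)) {
    stopifnot(!is.null(names(seqs)))
    seqs <- Biostrings::DNAStringSet(toupper(seqs))
  }
  stopifnot(methods::is(seqs, "DNAStringSet"), !is.null(names(seqs)))
  letters_ok <- Biostrings::uniqueLetters(seqs)
  if (!all(letters_ok %in% c("A", "C", "G", "T", "N"))) {
    stop("genome sequences may contain only A, C, G, T, N")
  }
  if (is.null(excluded)) {
    excluded <- data.frame(chrom = character(), start = integer(),
                           end = integer(), stringsAsFactors = FALSE)
  }
  g <- structure(
    list(seq = seqs,
         excluded = merge_intervals(excluded),
         chrom_lengths = stats::setNames(Biostrings::width(seqs), names(seqs))),
    class = "genome_ref"
  )
  g$trinuc <- trinucleotide_counts(g)
  g
}

#' @export
print.genome_ref <- function(x, ...) {
  cat(sprintf("genome_ref: %d chromosome(s), %s bp total, %d excluded region(s)\n",
              length(x$seq), format(sum(x$chrom_lengths), big.mark = ","),
              nrow(x$excluded)))
  invisible(x)
}

#' Chromosome names of a genome
#' @param genome a `genome_ref`.
#' @return character vector of chromosome identifiers.
#' @export
chrom_names <- function(genome) names(genome$seq)

#' Extract genome sequence
#'
#' @param genome a `genome_ref`.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open coordinates.
#' @return uppercase DNA string.
#' @export
genome_seq <- function(genome, chrom, start, end) {
  stopifnot(chrom %in% names(genome$seq), start >= 0,
            end <= genome$chrom_lengths[[chrom]], start < end)
  as.character(Biostrings::subseq(genome$seq[[chrom]], start + 1L, end))
}

# Sequences with excluded regions hard-masked to N (DNAStringSet).
masked_seqs <- function(genome) {
  seqs <- genome$seq
  if (nrow(genome$excluded) > 0) {
    for (cc in unique(genome$excluded$chrom)) {
      ex <- genome$excluded[genome$excluded$chrom == cc, , drop = FALSE]
      at <- IRanges::IRanges(ex$start + 1L, ex$end)
      value <- Biostrings::DNAStringSet(strrep("N", IRanges::width(at)))
      seqs[[cc]] <- Biostrings::replaceAt(seqs[[cc]], at, value)
    }
  }
  seqs
}

#' Trinucleotide counts over the analyzable genome
#'
#' Counts every 3-bp window (step 1) that contains no N and does not intersect
#' an excluded region, collapsed onto the 32 pyrimidine-centred trinucleotides.
#'
#' @param genome a `genome_ref`.
#' @return named integer vector over the 32 pyrimidine-centred trinucleotides.
#' @export
trinucleotide_counts <- function(genome) {
  seqs <- masked_seqs(genome)
  counts64 <- colSums(Biostrings::trinucleotideFrequency(seqs, step = 1))
  out <- stats::setNames(numeric(length(PYRIMIDINE_TRINUCS)), PYRIMIDINE_TRINUCS)
  for (tn in names(counts64)) {
    centre <- substr(tn, 2, 2)
    key <- if (centre %in% c("C", "T")) tn else revcomp(tn)
    out[key] <- out[key] + counts64[[tn]]
  }
  out
}

# Vectorized trinucleotide context lookup. `pos` is the 0-based position of
# the centre base; returns NA at contig edges or when any base is N/excluded
# is NOT applied here (callers decide whether to use masked sequence).
variant_context <- function(genome, chrom, pos) {
  stopifnot(length(chrom) == length(pos))
  out <- rep(NA_character_, length(pos))
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    len <- genome$chrom_lengths[[cc]]
    s <- as.character(genome$seq[[cc]])
    p <- pos[idx]
    ok <- p >= 1 & p <= len - 2
    ctx <- rep(NA_character_, length(p))
    ctx[ok] <- substring(s, p[ok], p[ok] + 2L)  # 1-based start = pos0 - 1 + 1
    ctx[grepl("N", ctx)] <- NA_character_
    out[idx] <- ctx
  }
  out
}
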