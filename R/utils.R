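# Shared low-level helpers. All genomic coordinates in this package are
# 0-based half-open [start, end); conversion to the 1-based closed convention
# of GRanges / VCF happens only at the boundaries defined here.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA character strings
#'
#' @param x character vector of DNA strings (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Complement single bases
#'
#' @param x character vector of single bases.
#' @return complemented bases.
#' @export
complement_base <- function(x) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  unname(map[x])
}

#' Convert a 0-based half-open interval data frame to GRanges
#'
#' @param df data frame with columns `chrom`, `start`, `end` and optionally
#'   `strand` (0-based half-open coordinates).
#' @return a `GRanges` (1-based closed).
#' @export
as_granges <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  strand <- if ("strand" %in% names(df)) {
    s <- as.character(df$strand)
    s[!s %in% c("+", "-")] <- "*"
    s
  } else rep("*", nrow(df))
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand
  )
}

#' Convert GRanges back to a 0-based half-open interval data frame
#'
#' @param gr a `GRanges`.
#' @return data frame with `chrom`, `start`, `end`, `strand`.
#' @export
granges_to_df <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}

#' Merge (union) a set of intervals
#'
#' Overlapping or book-ended intervals are merged; payload columns are dropped.
#'
#' @param df interval data frame (0-based half-open).
#' @return merged interval data frame sorted by (chrom, start).
#' @export
merge_intervals <- function(df) {
  if (nrow(df) == 0) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  gr <- GenomicRanges::reduce(as_granges(df[, c("chrom", "start", "end")]))
  out <- granges_to_df(gr)
  out$strand <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Total width of a merged interval set
#'
#' @param df interval data frame.
#' @return total number of base pairs covered.
#' @export
interval_bp <- function(df) {
  m <- merge_intervals(df)
  sum(m$end - m$start)
}

# Indices of rows of `query` (interval df or variant df with `pos`) that
# overlap any interval in `subject`.
overlaps_any <- function(query, subject) {
  if (nrow(query) == 0) return(logical(0))
  if (nrow(subject) == 0) return(rep(FALSE, nrow(query)))
  qgr <- if ("pos" %in% names(query) && !"start" %in% names(query)) {
    GenomicRanges::GRanges(query$chrom, IRanges::IRanges(query$pos + 1L, width = 1L))
  } else {
    as_granges(query)
  }
  IRanges::overlapsAny(qgr, as_granges(subject), ignore.strand = TRUE)
}

# Named empty variant table (shared by parsers and the simulator).
empty_variants <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), sample_id = character(), cohort = character(),
             allele_frequency = numeric(), stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
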