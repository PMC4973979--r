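# Readers and writers for external formats. VCF and the MAF-like table are
# 1-based on disk and converted to the internal 0-based half-open convention
# at parse time; BED/bedGraph/BEDPE are already 0-based half-open.

#' Read single-base substitutions from VCF or a MAF-like table
#'
#' VCF (`*.vcf`) rows are parsed via the vcfR package; multi-allelic rows are
#' split into one record per alternate base and the allele frequency is taken
#' from the `AF` INFO field (per alternate for multi-allelic rows). The
#' MAF-like dialect is a tab-separated table with header columns `chrom`,
#' `pos_1based`, `ref`, `alt`, `sample_id`. Non-SNV rows, records whose
#' reference base disagrees with the genome, and records on unknown
#' chromosomes are dropped with a logged count.
#'
#' @param path input file.
#' @param genome a `genome_ref` used to validate reference bases.
#' @param cohort cohort label attached to every record (e.g. a tumour type or
#'   `"1KG"`).
#' @param min_frequency if set, records with allele frequency <= this value
#'   are dropped (the "> 5 percent" polymorphism filter with
#'   `min_frequency = 0.05`).
#' @param format `"auto"` (by extension), `"vcf"` or `"maf"`.
#' @return variant data frame with columns `chrom`, `pos` (0-based), `ref`,
#'   `alt`, `sample_id`, `cohort`, `allele_frequency` (NA for somatic
#'   records without one).
#' @export
read_variants <- function(path, genome, cohort, min_frequency = NULL,
                          format = c("auto", "vcf", "maf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "maf"
  }
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    info <- vcfR::getINFO(v)
    af_str <- vapply(strsplit(info %||% character(0), ";"), function(fields) {
      hit <- fields[startsWith(fields, "AF=")]
      if (length(hit)) sub("^AF=", "", hit[1]) else NA_character_
    }, character(1))
    alts <- strsplit(ifelse(is.na(fix$ALT), "", fix$ALT), ",")
    afs <- lapply(seq_len(nrow(fix)), function(i) {
      n <- length(alts[[i]])
      if (is.na(af_str[i])) return(rep(NA_real_, n))
      a <- suppressWarnings(as.numeric(strsplit(af_str[i], ",")[[1]]))
      if (length(a) != n) rep(a[1], n) else a
    })
    idx <- rep(seq_len(nrow(fix)), lengths(alts))
    df <- if (length(idx)) data.frame(
      chrom = fix$CHROM[idx], pos = as.integer(fix$POS[idx]) - 1L,
      ref = fix$REF[idx], alt = unlist(alts), sample_id = cohort,
      cohort = cohort, allele_frequency = unlist(afs),
      stringsAsFactors = FALSE) else empty_variants()
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, comment.char = "#")
    need <- c("chrom", "pos_1based", "ref", "alt", "sample_id")
    if (!all(need %in% names(tab))) {
      stop("MAF-like table must have columns: ", paste(need, collapse = ", "))
    }
    df <- data.frame(chrom = as.character(tab$chrom),
                     pos = as.integer(tab$pos_1based) - 1L,
                     ref = toupper(tab$ref), alt = toupper(tab$alt),
                     sample_id = as.character(tab$sample_id), cohort = cohort,
                     allele_frequency = NA_real_, stringsAsFactors = FALSE)
  }
  validate_variants(df, genome, min_frequency = min_frequency)
}

# Shared validation: SNVs only, known chrom, ref agreement, frequency filter.
validate_variants <- function(df, genome, min_frequency = NULL) {
  n0 <- nrow(df)
  snv <- nchar(df$ref) == 1 & nchar(df$alt) == 1 &
    df$ref %in% DNA_BASES & df$alt %in% DNA_BASES & df$ref != df$alt
  if (any(!snv)) message(sum(!snv), " non-SNV record(s) dropped")
  df <- df[snv, , drop = FALSE]
  known <- df$chrom %in% chrom_names(genome)
  if (any(!known)) message(sum(!known), " record(s) on unknown chromosomes rejected")
  df <- df[known, , drop = FALSE]
  if (nrow(df) > 0) {
    obs <- character(nrow(df))
    for (cc in unique(df$chrom)) {
      idx <- which(df$chrom == cc)
      s <- as.character(genome$seq[[cc]])
      obs[idx] <- substring(s, df$pos[idx] + 1L, df$pos[idx] + 1L)
    }
    agree <- obs == df$ref
    if (any(!agree)) message(sum(!agree), " record(s) with reference mismatch rejected")
    df <- df[agree, , drop = FALSE]
  }
  if (!is.null(min_frequency)) {
    keep <- !is.na(df$allele_frequency) & df$allele_frequency > min_frequency
    message(sum(!keep), " record(s) at or below frequency ", min_frequency, " dropped")
    df <- df[keep, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Read an interval track
#'
#' @param path BED / bedGraph / BEDPE file (0-based half-open, no header;
#'   `#`-prefixed comment lines allowed).
#' @param kind one of `"bed"` (BED3/BED6), `"support_bed"` (BED3 + integer
#'   support-count column), `"state_bed"` (BED3 + chromatin-state colour
#'   column), `"bedgraph"` (BED3 + numeric value column) or `"bedpe"` (two
#'   end intervals per row).
#' @return for `"bedpe"`, a data frame of anchor-end intervals with an
#'   `anchor_id` (one id per input row) and `side` column; otherwise an
#'   interval data frame with the payload column named `support_count`,
#'   `state_color` or `timing_value`, sorted by (chrom, start). Rows with
#'   `start >= end` are rejected with a logged count.
#' @export
read_intervals <- function(path, kind = c("bed", "support_bed", "state_bed",
                                          "bedgraph", "bedpe")) {
  kind <- match.arg(kind)
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
  if (kind == "bedpe") {
    stopifnot(ncol(tab) >= 6)
    ends <- rbind(
      data.frame(chrom = tab[[1]], start = as.integer(tab[[2]]),
                 end = as.integer(tab[[3]]), anchor_id = seq_len(nrow(tab)),
                 side = "left", stringsAsFactors = FALSE),
      data.frame(chrom = tab[[4]], start = as.integer(tab[[5]]),
                 end = as.integer(tab[[6]]), anchor_id = seq_len(nrow(tab)),
                 side = "right", stringsAsFactors = FALSE))
    bad <- ends$start >= ends$end
    if (any(bad)) message(sum(bad), " BEDPE end(s) with start >= end rejected")
    ends <- ends[!bad, , drop = FALSE]
    ends <- ends[order(ends$chrom, ends$start), , drop = FALSE]
    rownames(ends) <- NULL
    return(ends)
  }
  df <- data.frame(chrom = as.character(tab[[1]]), start = as.integer(tab[[2]]),
                   end = as.integer(tab[[3]]), stringsAsFactors = FALSE)
  if (kind == "support_bed") df$support_count <- as.integer(tab[[4]])
  if (kind == "state_bed") df$state_color <- as.character(tab[[4]])
  if (kind == "bedgraph") df$timing_value <- as.numeric(tab[[4]])
  if (kind == "bed" && ncol(tab) >= 6) {
    df$name <- as.character(tab[[4]])
    df$score <- tab[[5]]
    df$strand <- as.character(tab[[6]])
  }
  bad <- df$start >= df$end
  if (any(bad)) message(sum(bad), " interval(s) with start >= end rejected")
  df <- df[!bad, , drop = FALSE]
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Point query on a value track
#'
#' @param track bedGraph-style interval data frame with a `timing_value`
#'   column.
#' @param chrom,pos vectors of query points (0-based).
#' @return numeric values (`NA` where uncovered).
#' @export
track_value_at <- function(track, chrom, pos) {
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1L, width = 1L))
  s <- as_granges(track)
  hit <- GenomicRanges::findOverlaps(q, s, select = "first")
  track$timing_value[hit]
}

#' Write intervals as BED
#'
#' Coordinates are written 0-based half-open as read; extra columns beyond
#' chrom/start/end are appended in the given order.
#'
#' @param df interval data frame.
#' @param path output file.
#' @param extra_cols character vector of payload column names to append.
#' @export
write_bed <- function(df, path, extra_cols = setdiff(names(df), c("chrom", "start", "end"))) {
  out <- df[, c("chrom", "start", "end", extra_cols), drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write variants as a minimal VCF
#'
#' @param df variant data frame (0-based `pos`); the allele frequency, when
#'   present, is written as an `AF` INFO field.
#' @param path output file.
#' @export
write_vcf <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele Frequency\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  info <- ifelse(is.na(df$allele_frequency), ".",
                 sprintf("AF=%.6f", df$allele_frequency))
  writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t%s",
                     df$chrom, df$pos + 1L, df$ref, df$alt, info), con)
  invisible(path)
}

#' Write somatic variants as a MAF-like table
#'
#' @param df variant data frame (0-based `pos`).
#' @param path output file.
#' @export
write_maf <- function(df, path) {
  out <- data.frame(chrom = df$chrom, pos_1based = df$pos + 1L, ref = df$ref,
                    alt = df$alt, sample_id = df$sample_id,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a genome as FASTA
#'
#' @param genome a `genome_ref`.
#' @param path output file.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome$seq, path)
  invisible(path)
}
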