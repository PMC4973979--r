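# Intersection of variants with the site catalog: per-site, per-motif-position
# and flank counts, with dataset-level deduplication (a substitution hitting
# several overlapping sites is counted once at the dataset level).

# Cohort group: germline polymorphism panel ("1KG") versus everything else
# ("cancer").
cohort_group <- function(cohort) ifelse(cohort == "1KG", "1KG", "cancer")

# Unique substitution-event key (sample x genomic change).
variant_key <- function(df) {
  paste(df$sample_id, df$chrom, df$pos, df$alt, sep = ":")
}

#' Intersect variants with a site catalog
#'
#' Each variant is assigned to every overlapping catalog site. The
#' motif-relative position is 1-based from the motif's 5' end on the hit
#' strand; for minus-strand hits ref and alt are complemented so that
#' per-position profiles are motif-centric.
#'
#' @param catalog a `site_catalog`.
#' @param variants variant data frame (somatic and/or germline records,
#'   cohort-labelled; the 1KG frequency filter is assumed already applied).
#' @return object of class `site_mutation_table`: list with `assignments`
#'   (one row per variant x site overlap, with `site_id`, `motif_id`,
#'   `site_class`, `cohort`, `cohort_group`, `sample_id`, `motif_position`,
#'   `ref_m`, `alt_m`, `event_key`), `variants` (the input), and
#'   `motif_length` (per-motif lengths).
#' @export
intersect_variants <- function(catalog, variants) {
  s <- catalog$sites
  vgr <- GenomicRanges::GRanges(variants$chrom,
                                IRanges::IRanges(variants$pos + 1L, width = 1L))
  sgr <- as_granges(s)
  ov <- GenomicRanges::findOverlaps(vgr, sgr, ignore.strand = TRUE)
  vi <- S4Vectors::queryHits(ov)
  si <- S4Vectors::subjectHits(ov)
  minus <- s$strand[si] == "-"
  motif_position <- ifelse(minus,
                           s$end[si] - variants$pos[vi],
                           variants$pos[vi] - s$start[si] + 1L)
  asg <- data.frame(
    site_id = s$site_id[si], motif_id = s$motif_id[si],
    site_class = s$site_class[si], cohort = variants$cohort[vi],
    cohort_group = cohort_group(variants$cohort[vi]),
    sample_id = variants$sample_id[vi],
    chrom = variants$chrom[vi], pos = variants$pos[vi],
    motif_position = as.integer(motif_position),
    ref_m = ifelse(minus, complement_base(variants$ref[vi]), variants$ref[vi]),
    alt_m = ifelse(minus, complement_base(variants$alt[vi]), variants$alt[vi]),
    event_key = variant_key(variants)[vi],
    stringsAsFactors = FALSE)
  ml <- tapply(s$end - s$start, s$motif_id, function(x) x[1])
  structure(list(assignments = asg, variants = variants,
                 motif_length = ml),
            class = "site_mutation_table")
}

#' @export
print.site_mutation_table <- function(x, ...) {
  cat(sprintf("site_mutation_table: %d variant-site assignment(s), %d unique event(s)\n",
              nrow(x$assignments), length(unique(x$assignments$event_key))))
  invisible(x)
}

#' Per (motif, class, cohort-group) substitution totals
#'
#' Within each cell, a substitution event overlapping several sites of that
#' motif/class is counted once.
#'
#' @param tbl a `site_mutation_table`.
#' @param dedup count each event once per cell (default TRUE).
#' @return data frame with `motif_id`, `site_class`, `cohort_group`, `n`.
#' @export
site_totals <- function(tbl, dedup = TRUE) {
  a <- tbl$assignments
  if (dedup) {
    a <- a[!duplicated(a[, c("motif_id", "site_class", "cohort_group", "event_key")]), ,
           drop = FALSE]
  }
  agg <- stats::aggregate(list(n = rep(1L, nrow(a))),
                          a[, c("motif_id", "site_class", "cohort_group")], sum)
  agg
}

#' Dataset-level deduplicated totals
#'
#' @param tbl a `site_mutation_table`.
#' @param site_class optional restriction (e.g. `"functional"`).
#' @param cohort optional restriction to one cohort label.
#' @return number of unique substitution events assigned to any catalog site
#'   in scope.
#' @export
dedup_total <- function(tbl, site_class = NULL, cohort = NULL) {
  a <- tbl$assignments
  if (!is.null(site_class)) a <- a[a$site_class %in% site_class, , drop = FALSE]
  if (!is.null(cohort)) a <- a[a$cohort %in% cohort, , drop = FALSE]
  length(unique(a$event_key))
}

#' Share of substitutions affecting more than one binding site
#'
#' @param tbl a `site_mutation_table`.
#' @param site_class site classes in scope (default functional).
#' @return list with `n_multi`, `n_total` (unique events) and `share`.
#' @export
multi_site_share <- function(tbl, site_class = "functional") {
  a <- tbl$assignments[tbl$assignments$site_class %in% site_class, , drop = FALSE]
  per_event <- table(unique(a[, c("event_key", "site_id")])$event_key)
  n_total <- length(per_event)
  n_multi <- sum(per_event > 1)
  list(n_multi = n_multi, n_total = n_total,
       share = if (n_total > 0) n_multi / n_total else NA_real_)
}

#' Per-motif-position substitution counts
#'
#' @param tbl a `site_mutation_table`.
#' @param motif_id motif to profile.
#' @param site_class site class (default `"functional"`).
#' @param cohort_group `"cancer"` or `"1KG"` (default `"cancer"`).
#' @param samples optional restriction to a set of sample ids.
#' @param by_alteration if TRUE, return counts split by (ref_m, alt_m).
#' @return integer vector of counts per motif position 1..L, or a data frame
#'   when `by_alteration` is TRUE.
#' @export
position_counts <- function(tbl, motif_id, site_class = "functional",
                            cohort_group = "cancer", samples = NULL,
                            by_alteration = FALSE) {
  L <- tbl$motif_length[[motif_id]]
  a <- tbl$assignments
  a <- a[a$motif_id == motif_id & a$site_class == site_class &
           a$cohort_group == cohort_group, , drop = FALSE]
  if (!is.null(samples)) a <- a[a$sample_id %in% samples, , drop = FALSE]
  if (by_alteration) {
    if (nrow(a) == 0) {
      return(data.frame(position = integer(), ref = character(),
                        alt = character(), count = integer()))
    }
    agg <- stats::aggregate(list(count = rep(1L, nrow(a))),
                            list(position = a$motif_position, ref = a$ref_m,
                                 alt = a$alt_m), sum)
    return(agg[order(agg$position, agg$ref, agg$alt), , drop = FALSE])
  }
  counts <- tabulate(a$motif_position, nbins = L)
  stats::setNames(counts, as.character(seq_len(L)))
}

#' Flank substitution counts
#'
#' Counts substitution events in the `flank_bp` windows on either side of
#' each catalog site, excluding flank bases that fall inside any same-motif
#' site of the same class.
#'
#' @param catalog a `site_catalog`.
#' @param variants variant data frame.
#' @param flank_bp flank width (default 100).
#' @return data frame per (motif_id, site_class): `n_flank` (unique events in
#'   flanks) and `flank_bp_total` (merged flank base pairs after exclusion).
#' @export
flank_counts <- function(catalog, variants, flank_bp = 100L) {
  s <- catalog$sites
  out <- list()
  for (key in unique(paste(s$motif_id, s$site_class))) {
    parts <- strsplit(key, " ")[[1]]
    ss <- s[s$motif_id == parts[1] & s$site_class == parts[2], , drop = FALSE]
    fl <- rbind(
      data.frame(chrom = ss$chrom, start = pmax(0L, ss$start - flank_bp),
                 end = ss$start, stringsAsFactors = FALSE),
      data.frame(chrom = ss$chrom, start = ss$end, end = ss$end + flank_bp,
                 stringsAsFactors = FALSE))
    fl <- merge_intervals(fl)
    # remove bases inside any same-motif site of this class
    flgr <- GenomicRanges::setdiff(as_granges(fl),
                                   as_granges(ss[, c("chrom", "start", "end")]),
                                   ignore.strand = TRUE)
    fl <- granges_to_df(flgr)[, c("chrom", "start", "end")]
    infl <- overlaps_any(variants, fl)
    ev <- unique(variant_key(variants[infl, , drop = FALSE]))
    out[[key]] <- data.frame(motif_id = parts[1], site_class = parts[2],
                             n_flank = length(ev),
                             flank_bp_total = sum(fl$end - fl$start),
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Substitutions per base pair over a region set
#'
#' @param regions interval data frame (merged internally).
#' @param variants variant data frame; events are deduplicated by
#'   (sample, position, alt).
#' @param label optional label attached to the result.
#' @return list with `label`, `n` (unique events overlapping the regions),
#'   `bp` (merged width) and `rate` (substitutions per bp).
#' @export
per_bp_rates <- function(regions, variants, label = "") {
  m <- merge_intervals(regions)
  bp <- sum(m$end - m$start)
  if (bp == 0) stop("zero-width region set: rate undefined")
  inr <- overlaps_any(variants, m)
  n <- length(unique(variant_key(variants[inr, , drop = FALSE])))
  list(label = label, n = n, bp = bp, rate = n / bp)
}
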