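# Functional versus position-matched control site catalog.
#
# Functional sites are motif hits fully contained in constitutively open
# chromatin (DNase master regions accessible in nearly all cell types, or
# footprints present in nearly all tissues). Control sites for a motif are
# hits outside any open chromatin, outside gene bodies and their
# promoter-proximal upstream margin, and outside excluded regions; each
# functional site is matched to its nearest available control on the same
# chromosome so that per-motif functional and control counts are equal and
# regional mutation rates are shared.

#' Constitutive open-chromatin regions
#'
#' Union of DNase master regions supported by at least `master_min` cell
#' types and footprints supported by at least `footprint_min` tissues,
#' merged where overlapping.
#'
#' @param dnase_master interval data frame with a `support_count` column.
#' @param footprints interval data frame with a `support_count` column.
#' @param master_min minimum master-region support (default 113, of 125).
#' @param footprint_min minimum footprint support (default 39, of 41).
#' @return merged interval data frame.
#' @export
constitutive_regions <- function(dnase_master, footprints,
                                 master_min = 113L, footprint_min = 39L) {
  for (df in list(dnase_master, footprints)) {
    if (nrow(df) > 0 && !"support_count" %in% names(df)) {
      stop("support_count column required")
    }
  }
  keep <- rbind(
    dnase_master[dnase_master$support_count >= master_min,
                 c("chrom", "start", "end"), drop = FALSE],
    footprints[footprints$support_count >= footprint_min,
               c("chrom", "start", "end"), drop = FALSE])
  merge_intervals(keep)
}

#' Label motif hits inside constitutive open chromatin as functional
#'
#' A hit is functional when its interval is fully contained within one
#' constitutive region; all other hits keep `site_class = "unassigned"`.
#'
#' @param hits motif hit data frame.
#' @param constitutive merged constitutive-region intervals.
#' @param containment `"within"` (default; full containment) or `"any"`
#'   (any overlap).
#' @return the hit data frame with `site_class` updated.
#' @export
classify_functional <- function(hits, constitutive, containment = c("within", "any")) {
  containment <- match.arg(containment)
  if (nrow(hits) == 0) return(hits)
  ov <- GenomicRanges::findOverlaps(
    as_granges(hits), as_granges(constitutive),
    type = if (containment == "within") "within" else "any",
    ignore.strand = TRUE)
  hits$site_class <- "unassigned"
  hits$site_class[unique(S4Vectors::queryHits(ov))] <- "functional"
  hits
}

#' Eligible control-site pool
#'
#' Controls must overlap none of: open chromatin in any tissue (master
#' regions or footprints at any support), gene bodies, the strand-aware
#' upstream margin of each gene's transcription start, or excluded regions.
#'
#' @param hits motif hit data frame.
#' @param any_open_chromatin intervals of open chromatin in any tissue.
#' @param genes stranded gene intervals.
#' @param excluded excluded-region intervals.
#' @param upstream_margin bp upstream of each gene start to avoid
#'   (default 2000).
#' @return the subset of `hits` eligible as controls.
#' @export
select_controls <- function(hits, any_open_chromatin, genes, excluded,
                            upstream_margin = 2000L) {
  if (nrow(hits) == 0) return(hits)
  upstream <- if (nrow(genes) > 0) {
    plus <- genes$strand == "+"
    data.frame(
      chrom = genes$chrom,
      start = ifelse(plus, pmax(0L, genes$start - upstream_margin), genes$end),
      end = ifelse(plus, genes$start, genes$end + upstream_margin),
      stringsAsFactors = FALSE)
  } else genes
  upstream <- upstream[upstream$start < upstream$end, , drop = FALSE]
  bad <- rep(FALSE, nrow(hits))
  for (track in list(any_open_chromatin, genes, upstream, excluded)) {
    if (!is.null(track) && nrow(track) > 0) {
      bad <- bad | overlaps_any(hits, track[, c("chrom", "start", "end"), drop = FALSE])
    }
  }
  out <- hits[!bad, , drop = FALSE]
  out$site_class <- rep("control_pool", nrow(out))
  rownames(out) <- NULL
  out
}

#' Match functional sites to nearest controls
#'
#' Greedy nearest matching by midpoint distance on the same chromosome,
#' processing functional sites in genome order; each control is used at most
#' once, ties are broken toward the smaller coordinate, and functional sites
#' with no available same-chromosome control are dropped (logged) so
#' per-motif counts stay equal.
#'
#' @param functional functional hits for one motif.
#' @param control_pool eligible control hits for the same motif.
#' @return data frame of catalog sites: the retained functional hits
#'   (`site_class = "functional"`) and their matched controls
#'   (`site_class = "control"`), with a shared `pair_id` and a unique
#'   `site_id`.
#' @export
match_nearest <- function(functional, control_pool) {
  stopifnot(length(unique(c(functional$motif_id, control_pool$motif_id))) <= 1)
  if (nrow(control_pool) == 0) {
    warning("empty control pool for motif ",
            paste(unique(functional$motif_id), collapse = ","))
    return(functional[0, , drop = FALSE])
  }
  functional <- functional[order(functional$chrom, functional$start, functional$strand), ,
                           drop = FALSE]
  fm <- (functional$start + functional$end) / 2
  cm <- (control_pool$start + control_pool$end) / 2
  used <- rep(FALSE, nrow(control_pool))
  match_idx <- rep(NA_integer_, nrow(functional))
  n_dropped <- 0L
  for (i in seq_len(nrow(functional))) {
    cand <- which(!used & control_pool$chrom == functional$chrom[i])
    if (length(cand) == 0) { n_dropped <- n_dropped + 1L; next }
    d <- abs(cm[cand] - fm[i])
    best <- cand[d == min(d)]
    if (length(best) > 1) best <- best[which.min(cm[best])]
    match_idx[i] <- best[1]
    used[best[1]] <- TRUE
  }
  if (n_dropped > 0) {
    message(n_dropped, " functional site(s) without a same-chromosome control dropped")
  }
  keep <- !is.na(match_idx)
  fun <- functional[keep, , drop = FALSE]
  ctl <- control_pool[match_idx[keep], , drop = FALSE]
  if (nrow(fun) == 0) return(functional[0, , drop = FALSE])
  fun$site_class <- "functional"
  ctl$site_class <- "control"
  fun$pair_id <- ctl$pair_id <- sprintf("%s_p%04d", fun$motif_id, seq_len(nrow(fun)))
  out <- rbind(fun, ctl)
  out$site_id <- sprintf("%s_%s", out$pair_id,
                         ifelse(out$site_class == "functional", "F", "C"))
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the full site catalog
#'
#' Runs [classify_functional()], [select_controls()] and [match_nearest()]
#' per motif and assembles the catalog.
#'
#' @param hits combined motif hits for all motifs.
#' @param constitutive constitutive open-chromatin intervals.
#' @param any_open_chromatin any-tissue open-chromatin intervals.
#' @param genes stranded gene intervals.
#' @param excluded excluded-region intervals.
#' @param upstream_margin bp upstream of gene starts to avoid (default 2000).
#' @param containment passed to [classify_functional()].
#' @return object of class `site_catalog`: list with `sites` (catalog data
#'   frame), and `n_sites` (per-motif functional-site counts).
#' @export
build_site_catalog <- function(hits, constitutive, any_open_chromatin, genes,
                               excluded, upstream_margin = 2000L,
                               containment = "within") {
  hits <- classify_functional(hits, constitutive, containment = containment)
  pieces <- lapply(split(hits, hits$motif_id), function(h) {
    fun <- h[h$site_class == "functional", , drop = FALSE]
    pool <- select_controls(h[h$site_class == "unassigned", , drop = FALSE],
                            any_open_chromatin, genes, excluded, upstream_margin)
    if (nrow(fun) == 0) return(NULL)
    match_nearest(fun, pool)
  })
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  pieces <- pieces[vapply(pieces, nrow, integer(1)) > 0]
  sites <- if (length(pieces)) do.call(rbind, pieces) else {
    out <- hits[0, , drop = FALSE]
    out$pair_id <- character(0)
    out$site_id <- character(0)
    out
  }
  rownames(sites) <- NULL
  n_sites <- table(sites$motif_id[sites$site_class == "functional"])
  structure(list(sites = sites, n_sites = n_sites), class = "site_catalog")
}

#' @export
print.site_catalog <- function(x, ...) {
  cat(sprintf("site_catalog: %d motif(s), %d functional + %d control sites\n",
              length(x$n_sites), sum(x$sites$site_class == "functional"),
              sum(x$sites$site_class == "control")))
  invisible(x)
}

#' Read a site catalog serialized by [write_catalog_bed()]
#'
#' @param path BED file written by [write_catalog_bed()].
#' @return a `site_catalog`.
#' @export
read_catalog_bed <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  sites <- data.frame(motif_id = tab[[9]], chrom = tab[[1]],
                      start = as.integer(tab[[2]]), end = as.integer(tab[[3]]),
                      strand = tab[[6]], score = as.numeric(tab[[5]]),
                      p_value = NA_real_, site_class = tab[[7]],
                      pair_id = tab[[8]], site_id = tab[[4]],
                      stringsAsFactors = FALSE)
  n_sites <- table(sites$motif_id[sites$site_class == "functional"])
  structure(list(sites = sites, n_sites = n_sites), class = "site_catalog")
}

#' Median functional-control matched distance
#'
#' @param catalog a `site_catalog`.
#' @return median midpoint distance (bp) between matched pairs.
#' @export
matched_distance_median <- function(catalog) {
  s <- catalog$sites
  mid <- (s$start + s$end) / 2
  fun <- s$site_class == "functional"
  m <- match(s$pair_id[fun], s$pair_id[s$site_class == "control"])
  stats::median(abs(mid[fun] - mid[which(s$site_class == "control")][m]))
}

#' Serialize a site catalog as BED
#'
#' @param catalog a `site_catalog`.
#' @param path output file.
#' @export
write_catalog_bed <- function(catalog, path) {
  s <- catalog$sites
  out <- data.frame(chrom = s$chrom, start = s$start, end = s$end,
                    name = s$site_id, score = s$score, strand = s$strand,
                    site_class = s$site_class, pair_id = s$pair_id,
                    motif_id = s$motif_id, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
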