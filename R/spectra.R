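# 96-channel trinucleotide mutational spectra, expected-count normalization
# against genome composition, and Manhattan-distance hierarchical clustering
# into spectral groups.

SUBSTITUTION_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' The 96 spectrum channels
#'
#' Channel order is fixed: substitution class major (C>A, C>G, C>T, T>A,
#' T>C, T>G), then 5' flank, then 3' flank, each in A, C, G, T order — the
#' standard COSMIC-style layout. Channel names look like `A[C>A]A`.
#'
#' @return data frame with `name`, `class`, `ref`, `alt`, `left`, `right`,
#'   `context` (the pyrimidine-centred trinucleotide).
#' @export
spectrum_channels <- function() {
  grid <- expand.grid(right = DNA_BASES, left = DNA_BASES,
                      class = SUBSTITUTION_CLASSES, stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$class, SUBSTITUTION_CLASSES), grid$left, grid$right), ]
  ref <- substr(grid$class, 1, 1)
  alt <- substr(grid$class, 3, 3)
  data.frame(name = sprintf("%s[%s]%s", grid$left, grid$class, grid$right),
             class = grid$class, ref = ref, alt = alt,
             left = grid$left, right = grid$right,
             context = paste0(grid$left, ref, grid$right),
             stringsAsFactors = FALSE)
}

# Map variants to channel indices (1..96); NA when the context is
# unavailable (contig edge / N). Purine-site substitutions are collapsed to
# the complementary pyrimidine channel.
variant_channels <- function(variants, genome) {
  ch <- spectrum_channels()
  ctx <- variant_context(genome, variants$chrom, variants$pos)
  ref <- variants$ref
  alt <- variants$alt
  pur <- ref %in% c("A", "G")
  ctx[pur & !is.na(ctx)] <- revcomp(ctx[pur & !is.na(ctx)])
  ref[pur] <- complement_base(ref[pur])
  alt[pur] <- complement_base(alt[pur])
  match(sprintf("%s[%s>%s]%s", substr(ctx, 1, 1), ref, alt, substr(ctx, 3, 3)),
        ch$name)
}

#' Mutational spectrum of one sample
#'
#' Counts the 96 substitution types, divides each channel by its expected
#' count — proportional to the genome's analyzable trinucleotide abundance
#' under the assumption that any base substitutes to any other with equal
#' probability — and scales the result to sum 1. Variants without a full
#' trinucleotide context (contig edges, N) are skipped with a logged count.
#'
#' @param variants variant data frame for one sample.
#' @param genome a `genome_ref`.
#' @param sample_id label (default taken from the variants).
#' @return object of class `spectrum_vector`: list with `sample_id`,
#'   `channels` (named 96-vector summing to 1), `raw` (raw channel counts)
#'   and `raw_count`.
#' @export
sample_spectrum <- function(variants, genome, sample_id = NULL) {
  ch <- spectrum_channels()
  sample_id <- sample_id %||% (if (nrow(variants) > 0) variants$sample_id[1] else "")
  idx <- variant_channels(variants, genome)
  if (anyNA(idx)) message(sum(is.na(idx)), " variant(s) without trinucleotide context skipped")
  idx <- idx[!is.na(idx)]
  raw <- tabulate(idx, nbins = 96)
  expected <- genome$trinuc[ch$context] / 3
  norm <- raw / expected
  norm[!is.finite(norm)] <- 0
  total <- sum(norm)
  channels <- if (total > 0) norm / total else norm
  structure(list(sample_id = sample_id,
                 channels = stats::setNames(channels, ch$name),
                 raw = stats::setNames(raw, ch$name),
                 raw_count = length(idx)),
            class = "spectrum_vector")
}

#' Spectra for all samples in a variant table
#'
#' @param variants variant data frame (multiple samples).
#' @param genome a `genome_ref`.
#' @return list of `spectrum_vector`, one per sample.
#' @export
spectra_by_sample <- function(variants, genome) {
  lapply(split(variants, variants$sample_id), sample_spectrum, genome = genome)
}

#' Cluster sample spectra into spectral groups
#'
#' Manhattan distances between sum-one spectra, agglomerative hierarchical
#' clustering, and a k-group cut of the tree. Only samples with at least
#' `min_mutations` context-resolved mutations are retained.
#'
#' @param spectra list of `spectrum_vector`.
#' @param min_mutations retention threshold on raw mutation count
#'   (default 7000).
#' @param k number of groups (default 5).
#' @param method linkage method for [stats::hclust()] (default
#'   `"complete"`; `"average"` and `"ward.D2"` are sensible alternatives).
#' @return object of class `spectrum_grouping`: list with `groups` (named
#'   integer vector sample -> group), `tree` (`hclust`), `dist`, `retained`,
#'   `method`, `k`.
#' @export
cluster_spectra <- function(spectra, min_mutations = 7000L, k = 5L,
                            method = "complete") {
  counts <- vapply(spectra, `[[`, numeric(1), "raw_count")
  keep <- counts >= min_mutations
  if (sum(keep) < k) {
    stop(sprintf("only %d sample(s) with >= %d mutations; cannot form %d groups",
                 sum(keep), min_mutations, k))
  }
  mat <- do.call(rbind, lapply(spectra[keep], `[[`, "channels"))
  rownames(mat) <- vapply(spectra[keep], `[[`, character(1), "sample_id")
  d <- stats::dist(mat, method = "manhattan")
  tree <- stats::hclust(d, method = method)
  groups <- stats::cutree(tree, k = k)
  structure(list(groups = groups, tree = tree, dist = d,
                 retained = rownames(mat), method = method, k = k),
            class = "spectrum_grouping")
}

#' @export
print.spectrum_grouping <- function(x, ...) {
  cat(sprintf("spectrum_grouping: %d sample(s) in %d group(s) (%s linkage)\n",
              length(x$groups), x$k, x$method))
  print(table(x$groups))
  invisible(x)
}

#' Burden statistics stratified by spectral group
#'
#' Recomputes the four-way counts and per-position profiles within each
#' spectral group, with per-individual normalization (count divided by group
#' size) alongside.
#'
#' @param grouping a `spectrum_grouping`.
#' @param tbl a `site_mutation_table`.
#' @param motif_id motif for the per-position profiles (default: motif with
#'   the most assignments).
#' @return list per group label: `n_samples`, `four_way`, `profile`
#'   (per-position counts for `motif_id` functional sites in cancer) and
#'   `profile_per_individual`.
#' @export
stratified_burden <- function(grouping, tbl, motif_id = NULL) {
  if (is.null(motif_id)) {
    a <- tbl$assignments
    motif_id <- names(sort(table(a$motif_id), decreasing = TRUE))[1]
  }
  out <- list()
  for (g in sort(unique(grouping$groups))) {
    samples <- names(grouping$groups)[grouping$groups == g]
    prof <- position_counts(tbl, motif_id, samples = samples)
    out[[as.character(g)]] <- list(
      n_samples = length(samples),
      four_way = four_way_counts(tbl, samples = samples),
      profile = prof,
      profile_per_individual = prof / length(samples))
  }
  out
}

#' Write spectra as a sample-by-channel TSV
#'
#' @param spectra list of `spectrum_vector`.
#' @param path output file.
#' @export
write_spectra_tsv <- function(spectra, path) {
  mat <- do.call(rbind, lapply(spectra, `[[`, "channels"))
  df <- data.frame(sample_id = vapply(spectra, `[[`, character(1), "sample_id"),
                   raw_count = vapply(spectra, `[[`, numeric(1), "raw_count"),
                   mat, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a clustering tree in Newick format
#'
#' @param grouping a `spectrum_grouping`.
#' @param path output file.
#' @export
write_tree_newick <- function(grouping, path) {
  # stats::hclust -> newick via a simple recursive writer
  tr <- grouping$tree
  lab <- tr$labels
  rec <- function(i) {
    if (i < 0) return(lab[-i])
    sprintf("(%s,%s):%f", rec(tr$merge[i, 1]), rec(tr$merge[i, 2]), tr$height[i])
  }
  writeLines(paste0(rec(nrow(tr$merge)), ";"), path)
  invisible(path)
}
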