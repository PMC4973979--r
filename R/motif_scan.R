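# Genome scanning with exact p-value calibration.
#
# The null distribution of the discretized log-odds score under the background
# model (independence across positions) is computed by dynamic programming:
# the exact convolution of the per-column score distributions on the
# milli-bit grid. Scan thresholds compare the *discretized* score of each
# window against the DP-derived threshold, so the per-hit p-values and the
# threshold come from one distribution.

#' Exact null score distribution of a PWM
#'
#' @param pwm a `pwm`.
#' @return list with `prob` (probabilities per grid score), `min_score`
#'   (grid score of `prob[1]`, in grid units) and `tail`
#'   (`tail[i] = P(score >= min_score + i - 1)`).
#' @export
pwm_score_distribution <- function(pwm) {
  p <- 1
  off <- 0L
  bg <- pwm$background
  for (j in seq_len(pwm$length)) {
    dj <- pwm$disc[, j]
    mn <- min(dj)
    mx <- max(dj)
    np <- numeric(length(p) + mx - mn)
    for (b in 1:4) {
      k <- dj[b] - mn
      idx <- (1L + k):(length(p) + k)
      np[idx] <- np[idx] + p * bg[b]
    }
    p <- np
    off <- off + mn
  }
  list(prob = p, min_score = off, tail = rev(cumsum(rev(p))))
}

#' Score threshold for a target p-value
#'
#' Returns the smallest discretized score s such that
#' P_background(score >= s) <= p_max.
#'
#' @param pwm a `pwm`.
#' @param p_max maximum match p-value, in (0, 1].
#' @param dist optional precomputed [pwm_score_distribution()].
#' @return list with `min_score` (bits), `min_score_grid` (grid units),
#'   `p_at_threshold` and `attainable` (FALSE when not even the best word
#'   reaches `p_max`).
#' @export
score_threshold_for_pvalue <- function(pwm, p_max, dist = NULL) {
  stopifnot(p_max > 0, p_max <= 1)
  if (is.null(dist)) dist <- pwm_score_distribution(pwm)
  ok <- which(dist$tail <= p_max)
  if (length(ok) == 0) {
    # even the single best word is more probable than p_max
    i <- length(dist$tail)
    return(list(min_score = (dist$min_score + i - 1) * pwm$grid,
                min_score_grid = dist$min_score + i - 1L,
                p_at_threshold = dist$tail[i], attainable = FALSE))
  }
  i <- min(ok)
  list(min_score = (dist$min_score + i - 1) * pwm$grid,
       min_score_grid = dist$min_score + i - 1L,
       p_at_threshold = dist$tail[i], attainable = TRUE)
}

# Encode a chromosome string as integer base codes (A=1,C=2,G=3,T=4, else NA).
encode_seq <- function(s) {
  codes <- utf8ToInt(s)
  map <- rep(NA_integer_, 128)
  map[utf8ToInt("A")] <- 1L; map[utf8ToInt("C")] <- 2L
  map[utf8ToInt("G")] <- 3L; map[utf8ToInt("T")] <- 4L
  map[codes]
}

# Discretized scores of all windows of length L (grid units); NA where the
# window contains a non-ACGT base.
window_scores_disc <- function(disc, code) {
  L <- ncol(disc)
  n <- length(code) - L + 1L
  if (n < 1) return(numeric(0))
  s <- numeric(n)
  for (j in seq_len(L)) {
    s <- s + disc[, j][code[j:(j + n - 1L)]]
  }
  s
}

#' Scan a genome for motif matches
#'
#' Both strands are scanned; windows whose background p-value is at most
#' `p_max` (by the exact DP distribution on the discretized score grid) are
#' reported. Hits containing N bases or overlapping an excluded region are
#' discarded. Overlapping hits, including opposite-strand hits at one locus,
#' are all retained.
#'
#' @param pwm a `pwm`.
#' @param genome a `genome_ref`.
#' @param p_max maximum match p-value (default 4.4e-5).
#' @param excluded optional interval data frame overriding `genome$excluded`.
#' @return data frame of motif hits with columns `motif_id`, `chrom`,
#'   `start`, `end` (0-based half-open), `strand`, `score` (bits, on the
#'   discretized grid), `p_value`, `site_class` (all `"unassigned"`), sorted
#'   by (chrom, start, strand).
#' @export
scan_genome <- function(pwm, genome, p_max = 4.4e-5, excluded = NULL) {
  excluded <- excluded %||% genome$excluded
  dist_fwd <- pwm_score_distribution(pwm)
  thr_fwd <- score_threshold_for_pvalue(pwm, p_max, dist_fwd)
  rcp <- pwm_revcomp(pwm)
  dist_rev <- pwm_score_distribution(rcp)
  thr_rev <- score_threshold_for_pvalue(rcp, p_max, dist_rev)
  L <- pwm$length
  res <- list()
  for (cc in chrom_names(genome)) {
    code <- encode_seq(as.character(genome$seq[[cc]]))
    for (st in c("+", "-")) {
      disc <- if (st == "+") pwm$disc else rcp$disc
      dist <- if (st == "+") dist_fwd else dist_rev
      thr <- if (st == "+") thr_fwd else thr_rev
      s <- window_scores_disc(disc, code)
      keep <- which(!is.na(s) & s >= thr$min_score_grid)
      if (length(keep) == 0) next
      pv <- dist$tail[s[keep] - dist$min_score + 1L]
      res[[length(res) + 1L]] <- data.frame(
        motif_id = pwm$motif_id, chrom = cc,
        start = keep - 1L, end = keep - 1L + L, strand = st,
        score = s[keep] * pwm$grid, p_value = pv,
        site_class = "unassigned", stringsAsFactors = FALSE
      )
    }
  }
  hits <- if (length(res)) do.call(rbind, res) else
    data.frame(motif_id = character(), chrom = character(), start = integer(),
               end = integer(), strand = character(), score = numeric(),
               p_value = numeric(), site_class = character(),
               stringsAsFactors = FALSE)
  if (nrow(hits) > 0 && nrow(excluded) > 0) {
    hits <- hits[!overlaps_any(hits, excluded), , drop = FALSE]
  }
  hits <- hits[order(hits$chrom, hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Cap the number of hits per motif
#'
#' When more than `cap` instances are found for one motif, those with the
#' largest p-values are dropped; ties at the boundary are broken by
#' (chrom, start, strand) lexicographic order so the result is deterministic.
#'
#' @param hits hit data frame for a single motif.
#' @param cap maximum number of instances (default 300000).
#' @return hit data frame sorted by (chrom, start, strand).
#' @export
cap_hits <- function(hits, cap = 300000L) {
  stopifnot(length(unique(hits$motif_id)) <= 1)
  if (nrow(hits) > cap) {
    o <- order(hits$p_value, hits$chrom, hits$start, hits$strand)
    hits <- hits[o[seq_len(cap)], , drop = FALSE]
  }
  hits <- hits[order(hits$chrom, hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Scan a genome with a set of PWMs, capping each motif's hit count
#'
#' @param pwms named list of `pwm` objects.
#' @inheritParams scan_genome
#' @inheritParams cap_hits
#' @return combined hit data frame.
#' @export
scan_genome_set <- function(pwms, genome, p_max = 4.4e-5, cap = 300000L,
                            excluded = NULL) {
  do.call(rbind, lapply(pwms, function(p) {
    cap_hits(scan_genome(p, genome, p_max = p_max, excluded = excluded), cap)
  })) -> hits
  rownames(hits) <- NULL
  hits
}
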