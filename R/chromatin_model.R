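# Chromatin-context integration: loop-anchor profiles and burden, chromatin
# state (chromHMM colour) screening, replication timing, and the site-level
# logistic mutation model.

CHROMATIN_COLORS <- c("promoter", "enhancer", "insulator", "transcription",
                      "repressed", "low_signal")

#' Flag sites whose midpoint lies inside a loop anchor
#'
#' Midpoint containment avoids double assignment at anchor boundaries.
#'
#' @param sites site/hit data frame.
#' @param anchors anchor interval data frame.
#' @return logical vector per site.
#' @export
anchor_flag <- function(sites, anchors) {
  if (nrow(sites) == 0) return(logical(0))
  mid <- floor((sites$start + sites$end) / 2)
  overlaps_any(data.frame(chrom = sites$chrom, pos = mid), anchors)
}

#' Chromatin state colour at each site midpoint
#'
#' @param sites site data frame.
#' @param states interval data frame with a `state_color` column.
#' @return character vector of colours (`NA` where uncovered).
#' @export
state_at_sites <- function(sites, states) {
  mid <- floor((sites$start + sites$end) / 2)
  q <- GenomicRanges::GRanges(sites$chrom, IRanges::IRanges(mid + 1L, width = 1L))
  hit <- GenomicRanges::findOverlaps(q, as_granges(states), select = "first")
  states$state_color[hit]
}

#' Motif and mutation density around anchor midpoints
#'
#' Sliding-window profile: counts of site midpoints and of substitutions per
#' fixed offset window across all anchor midpoints.
#'
#' @param sites site/hit data frame.
#' @param variants variant data frame.
#' @param anchors anchor interval data frame.
#' @param window_bp window width (default 1000).
#' @param span_bp half-span around anchor midpoints (default 50000).
#' @return data frame with `offset` (window centre, bp), `motif_count`,
#'   `mutation_count`.
#' @export
anchor_profiles <- function(sites, variants, anchors, window_bp = 1000L,
                            span_bp = 50000L) {
  stopifnot(nrow(anchors) > 0)
  breaks <- seq(-span_bp, span_bp, by = window_bp)
  centres <- breaks[-length(breaks)] + window_bp / 2
  amid <- floor((anchors$start + anchors$end) / 2)
  bin_counts <- function(chrom, pos) {
    total <- numeric(length(centres))
    for (i in seq_along(amid)) {
      same <- chrom == anchors$chrom[i]
      off <- pos[same] - amid[i]
      off <- off[off >= -span_bp & off < span_bp]
      if (length(off)) {
        total <- total + tabulate(findInterval(off, breaks), nbins = length(centres))
      }
    }
    total
  }
  smid <- floor((sites$start + sites$end) / 2)
  data.frame(offset = centres,
             motif_count = bin_counts(sites$chrom, smid),
             mutation_count = bin_counts(variants$chrom, variants$pos))
}

#' Mutation burden of sites inside versus outside loop anchors
#'
#' Fisher test on (mutated sites, intact sites) x (inside, outside anchors),
#' plus the fraction of substitutions falling at a focal motif position
#' inside and outside anchors.
#'
#' @param tbl a `site_mutation_table`.
#' @param catalog the matching `site_catalog`.
#' @param anchors anchor interval data frame.
#' @param motif_id motif to analyse.
#' @param focal_position motif position for the substitution fraction
#'   (e.g. the CTCF hotspot position 9).
#' @param site_class site class in scope (default functional).
#' @return list with per-stratum site and substitution counts, `fisher_p`,
#'   and `focal_fraction_inside` / `focal_fraction_outside` (per cent,
#'   rounded to integers as conventionally printed, plus raw fractions).
#' @export
anchor_burden_test <- function(tbl, catalog, anchors, motif_id,
                               focal_position = 9L, site_class = "functional") {
  s <- catalog$sites[catalog$sites$motif_id == motif_id &
                       catalog$sites$site_class == site_class, , drop = FALSE]
  s$inside <- anchor_flag(s, anchors)
  a <- tbl$assignments[tbl$assignments$motif_id == motif_id &
                         tbl$assignments$site_class == site_class &
                         tbl$assignments$cohort_group == "cancer", , drop = FALSE]
  a$inside <- s$inside[match(a$site_id, s$site_id)]
  mutated_sites <- unique(a$site_id)
  n_sites <- c(inside = sum(s$inside), outside = sum(!s$inside))
  n_mutated <- c(inside = sum(s$inside & s$site_id %in% mutated_sites),
                 outside = sum(!s$inside & s$site_id %in% mutated_sites))
  m <- rbind(mutated = n_mutated, intact = n_sites - n_mutated)
  fisher_p <- stats::fisher.test(m)$p.value
  frac <- function(inside) {
    sub <- a[a$inside == inside, , drop = FALSE]
    n_total <- nrow(sub)
    n_focal <- sum(sub$motif_position == focal_position)
    list(n_focal = n_focal, n_total = n_total,
         fraction = if (n_total > 0) n_focal / n_total else NA_real_,
         percent = if (n_total > 0) position_fraction_pct(n_focal, n_total) else NA_real_)
  }
  list(n_sites = n_sites, n_mutated = n_mutated, table = m, fisher_p = fisher_p,
       focal_inside = frac(TRUE), focal_outside = frac(FALSE))
}

#' Percent of substitutions at a motif position, as conventionally printed
#'
#' @param n_at_position substitutions at the position.
#' @param n_total total substitutions.
#' @return percentage rounded to the nearest integer.
#' @export
position_fraction_pct <- function(n_at_position, n_total) {
  round(100 * n_at_position / n_total)
}

#' Chromatin-state screen of per-motif mutation load
#'
#' For each motif and cell line, a chi-squared test of mutated versus intact
#' functional sites across the six chromatin colours (colours with zero
#' sites are collapsed out with a warning); a motif passes the screen when
#' p < `p_threshold` in every supplied cell line.
#'
#' @param catalog a `site_catalog`.
#' @param tbl a `site_mutation_table`.
#' @param state_tracks named list of state interval data frames, one per
#'   cell line.
#' @param p_threshold significance threshold (default 1e-3).
#' @param site_class site class in scope (default functional).
#' @return list with `per_cell_line` (data frame motif x cell line with
#'   `chisq`, `p`) and `significant` (motifs with p < threshold in all cell
#'   lines).
#' @export
chromhmm_screen <- function(catalog, tbl, state_tracks, p_threshold = 1e-3,
                            site_class = "functional") {
  s <- catalog$sites[catalog$sites$site_class == site_class, , drop = FALSE]
  mutated_sites <- unique(tbl$assignments$site_id[
    tbl$assignments$cohort_group == "cancer"])
  rows <- list()
  for (cl in names(state_tracks)) {
    col <- state_at_sites(s, state_tracks[[cl]])
    for (m in sort(unique(s$motif_id))) {
      sel <- s$motif_id == m & !is.na(col)
      if (!any(sel)) next
      mut <- s$site_id[sel] %in% mutated_sites
      tab <- table(factor(col[sel], levels = CHROMATIN_COLORS),
                   factor(mut, levels = c(TRUE, FALSE)))
      empty <- rowSums(tab) == 0
      if (any(empty)) {
        warning(sprintf("motif %s / %s: %d colour(s) with zero sites collapsed",
                        m, cl, sum(empty)))
        tab <- tab[!empty, , drop = FALSE]
      }
      res <- if (nrow(tab) < 2 || any(colSums(tab) == 0)) {
        list(statistic = NA_real_, p.value = NA_real_)
      } else suppressWarnings(stats::chisq.test(tab))
      rows[[length(rows) + 1L]] <- data.frame(
        motif_id = m, cell_line = cl,
        chisq = unname(res$statistic), p = res$p.value,
        stringsAsFactors = FALSE)
    }
  }
  per <- do.call(rbind, rows)
  sig <- if (is.null(per)) character(0) else {
    ok <- stats::aggregate(list(all_sig = !is.na(per$p) & per$p < p_threshold),
                           list(motif_id = per$motif_id), all)
    ok$motif_id[ok$all_sig]
  }
  list(per_cell_line = per, significant = sig, p_threshold = p_threshold)
}

#' Build the site-level regression table
#'
#' One observation per catalog site: mutated in any cancer sample or not,
#' with replication timing (standardized), motif matrix, functionality and
#' loop-anchor membership as predictors.
#'
#' @param catalog a `site_catalog`.
#' @param tbl a `site_mutation_table`.
#' @param timing_track bedGraph-style data frame with `timing_value` (larger
#'   values = later replication).
#' @param anchors anchor interval data frame.
#' @return data frame with `site_id`, `motif_id` (factor), `mutated` (0/1),
#'   `timing` (standardized), `functionality` (0/1), `anchor` (0/1). Sites
#'   without timing coverage are excluded with a message.
#' @export
regression_table <- function(catalog, tbl, timing_track, anchors) {
  s <- catalog$sites
  mutated_sites <- unique(tbl$assignments$site_id[
    tbl$assignments$cohort_group == "cancer"])
  mid <- floor((s$start + s$end) / 2)
  timing <- track_value_at(timing_track, s$chrom, mid)
  drop <- is.na(timing)
  if (any(drop)) message(sum(drop), " site(s) without timing coverage excluded")
  out <- data.frame(site_id = s$site_id, motif_id = factor(s$motif_id),
                    mutated = as.integer(s$site_id %in% mutated_sites),
                    timing = timing,
                    functionality = as.integer(s$site_class == "functional"),
                    anchor = as.integer(anchor_flag(s, anchors)),
                    stringsAsFactors = FALSE)
  out <- out[!drop, , drop = FALSE]
  out$timing <- as.numeric(scale(out$timing))
  out
}

#' Logistic model of site mutation status
#'
#' Maximum-likelihood logistic regression of mutated/not-mutated on
#' replication timing, motif matrix, functionality and loop-anchor
#' membership, with per-coefficient Wald tests and predicted mutated
#' fractions per (matrix, anchor status) at a fixed replication time.
#'
#' @param site_table data frame from [regression_table()] (or a synthetic
#'   equivalent with the same columns).
#' @param timing_at timing value at which predicted fractions are evaluated
#'   (default 0, i.e. the standardized mean).
#' @return list with `fit` (`glm`), `coefficients` (term, estimate, se,
#'   wald_z, p), `separation` flag, and `predicted` (per matrix x anchor,
#'   functional sites, at `timing_at`).
#' @export
fit_mutation_model <- function(site_table, timing_at = 0) {
  single_matrix <- length(unique(site_table$motif_id)) < 2
  form <- if (single_matrix) {
    mutated ~ timing + functionality + anchor
  } else {
    mutated ~ timing + motif_id + functionality + anchor
  }
  fit <- stats::glm(form, family = stats::binomial(), data = site_table)
  sm <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                      wald_z = sm[, 3], p = sm[, 4], row.names = NULL,
                      stringsAsFactors = FALSE)
  separation <- !fit$converged || any(abs(coefs$estimate) > 15)
  if (separation) {
    warning("possible separation: ",
            paste(coefs$term[abs(coefs$estimate) > 15], collapse = ", "))
  }
  grid <- expand.grid(motif_id = levels(factor(site_table$motif_id)),
                      anchor = c(0L, 1L), stringsAsFactors = FALSE)
  grid$functionality <- 1L
  grid$timing <- timing_at
  grid$predicted_fraction <- stats::predict(fit, newdata = grid, type = "response")
  list(fit = fit, coefficients = coefs, separation = separation,
       predicted = grid)
}

#' Replication timing inside versus outside loop anchors
#'
#' @param sites site data frame.
#' @param timing_track bedGraph-style data frame with `timing_value`.
#' @param anchors anchor interval data frame.
#' @return list with per-group summaries, `n_uncovered`, and the two-sided
#'   Wilcoxon rank-test p-value.
#' @export
timing_by_anchor <- function(sites, timing_track, anchors) {
  mid <- floor((sites$start + sites$end) / 2)
  timing <- track_value_at(timing_track, sites$chrom, mid)
  inside <- anchor_flag(sites, anchors)
  ok <- !is.na(timing)
  x <- timing[ok & inside]; y <- timing[ok & !inside]
  p <- if (length(x) > 0 && length(y) > 0) {
    if (length(unique(c(x, y))) == 1) 1 else
      stats::wilcox.test(x, y, exact = FALSE)$p.value
  } else NA_real_
  list(inside = summary(x), outside = summary(y),
       median_inside = stats::median(x), median_outside = stats::median(y),
       n_uncovered = sum(!ok), p_value = p)
}
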