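# Binding-disruption statistics: relative PWM score of observed variants and
# distribution-free confidence intervals for ratios of group medians
# (Price-Bonett order-statistic approach).

#' Relative PWM score of a substitution
#'
#' Ratio of the summed log-odds score of the alternate site sequence to that
#' of the reference site sequence (the same log-odds score the scanner
#' thresholds). Records with non-positive reference scores are flagged
#' unstable and excluded from median summaries downstream: ratios of signed
#' scores are not interpretable.
#'
#' @param pwm a `pwm`.
#' @param site_seq reference site sequence oriented to the motif strand
#'   (length `pwm$length`).
#' @param motif_position 1-based position of the substitution within the
#'   motif (motif-strand orientation).
#' @param alt_base alternate base, motif-strand orientation.
#' @return list with `pwm_ratio`, `score_ref`, `score_alt`, `unstable`.
#' @export
pwm_ratio <- function(pwm, site_seq, motif_position, alt_base) {
  site_seq <- toupper(site_seq)
  stopifnot(nchar(site_seq) == pwm$length,
            motif_position >= 1, motif_position <= pwm$length)
  score_ref <- score_window(pwm, site_seq, "+")
  alt_seq <- site_seq
  substr(alt_seq, motif_position, motif_position) <- alt_base
  score_alt <- score_window(pwm, alt_seq, "+")
  unstable <- is.na(score_ref) || score_ref <= 0
  list(pwm_ratio = if (unstable) NA_real_ else score_alt / score_ref,
       score_ref = score_ref, score_alt = score_alt, unstable = unstable)
}

#' Relative PWM scores for every variant-site assignment
#'
#' @param tbl a `site_mutation_table`.
#' @param catalog the `site_catalog` the table was built from.
#' @param genome a `genome_ref`.
#' @param pwms named list of `pwm` objects.
#' @return data frame of impact records: `motif_id`, `site_class`,
#'   `cohort_group`, `event_key`, `pwm_ratio`, `unstable`. The count of
#'   unstable (excluded) records is reported via a message.
#' @export
impact_records <- function(tbl, catalog, genome, pwms) {
  a <- tbl$assignments
  s <- catalog$sites
  si <- match(a$site_id, s$site_id)
  out <- data.frame(motif_id = a$motif_id, site_class = a$site_class,
                    cohort_group = a$cohort_group, event_key = a$event_key,
                    pwm_ratio = NA_real_, unstable = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(a))) {
    st <- s[si[i], ]
    ref_seq <- genome_seq(genome, st$chrom, st$start, st$end)
    if (st$strand == "-") ref_seq <- revcomp(ref_seq)
    r <- pwm_ratio(pwms[[a$motif_id[i]]], ref_seq, a$motif_position[i], a$alt_m[i])
    out$pwm_ratio[i] <- r$pwm_ratio
    out$unstable[i] <- r$unstable
  }
  if (any(out$unstable)) {
    message(sum(out$unstable), " impact record(s) with non-positive reference score excluded")
  }
  out
}

# Order-statistic standard error of a sample median (the distribution-free
# estimator used by the Price-Bonett ratio-of-medians interval): the exact
# binomial CI order statistics (X_(l), X_(u)) for the median at the target
# confidence give SE = (X_(u) - X_(l)) / (2 z).
median_se <- function(x, confidence = 0.95) {
  x <- sort(x)
  n <- length(x)
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  l <- max(1L, stats::qbinom((1 - confidence) / 2, n, 0.5))
  u <- min(n, n - l + 1L)
  se <- (x[u] - x[l]) / (2 * z)
  list(se = se, degenerate = se == 0)
}

#' Confidence interval for a ratio of medians (Price-Bonett)
#'
#' Distribution-free CI for `median(x) / median(y)` of two independent
#' samples: the log ratio of sample medians plus/minus z times the combined
#' order-statistic standard error of the log medians.
#'
#' @param x,y numeric samples (e.g. functional and control `pwm_ratio`
#'   values); NAs dropped.
#' @param confidence confidence level (default 0.95).
#' @param min_n minimum group size for a CI (default 5; smaller groups are
#'   flagged and get no CI).
#' @return list with `median_x`, `median_y`, `ratio`, `ci` (length-2 or NULL),
#'   `confidence`, `testable`, `degenerate_ties`.
#' @export
median_ratio_ci <- function(x, y, confidence = 0.95, min_n = 5L) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  mx <- stats::median(x); my <- stats::median(y)
  out <- list(median_x = mx, median_y = my, ratio = mx / my, ci = NULL,
              confidence = confidence, testable = FALSE, degenerate_ties = FALSE)
  if (length(x) < min_n || length(y) < min_n) return(out)
  if (mx <= 0 || my <= 0) return(out)
  sx <- median_se(x, confidence); sy <- median_se(y, confidence)
  vlog <- (sx$se / mx)^2 + (sy$se / my)^2
  if (sx$degenerate || sy$degenerate) {
    # ties collapsed the order-statistic spread; widen using the sample IQRs
    out$degenerate_ties <- TRUE
    vlog <- vlog + (stats::IQR(x) / (sqrt(length(x)) * max(mx, .Machine$double.eps)))^2 +
      (stats::IQR(y) / (sqrt(length(y)) * max(my, .Machine$double.eps)))^2
  }
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  lr <- log(mx / my)
  out$ci <- exp(c(lr - z * sqrt(vlog), lr + z * sqrt(vlog)))
  out$testable <- TRUE
  out
}

#' Per-motif comparison of binding disruption: cancer versus 1KG
#'
#' Computes the Price-Bonett ratio-of-medians CI of functional versus
#' control relative PWM scores separately in cancer and in 1KG, and declares
#' a motif's disruption significantly different when the two intervals are
#' disjoint; the direction records whether functional-site changes are more
#' or less disruptive in cancer than in the population.
#'
#' @param records impact record data frame from [impact_records()].
#' @param confidence confidence level (default 0.95).
#' @param min_n minimum per-group record count (default 5).
#' @return data frame per motif: medians per group, ratios and CIs, a
#'   `testable` flag (`FALSE` when any group is under `min_n`), `significant`
#'   and `direction` (`"more_disruptive_in_cancer"`,
#'   `"less_disruptive_in_cancer"`, or `"none"`).
#' @export
compare_cancer_vs_1kg <- function(records, confidence = 0.95, min_n = 5L) {
  records <- records[!records$unstable & !is.na(records$pwm_ratio), , drop = FALSE]
  rows <- lapply(sort(unique(records$motif_id)), function(m) {
    r <- records[records$motif_id == m, , drop = FALSE]
    grab <- function(grp, cls) r$pwm_ratio[r$cohort_group == grp & r$site_class == cls]
    ci_cancer <- median_ratio_ci(grab("cancer", "functional"),
                                 grab("cancer", "control"), confidence, min_n)
    ci_kg <- median_ratio_ci(grab("1KG", "functional"),
                             grab("1KG", "control"), confidence, min_n)
    testable <- ci_cancer$testable && ci_kg$testable
    sig <- FALSE; dir <- "none"
    if (testable) {
      sig <- ci_cancer$ci[2] < ci_kg$ci[1] || ci_kg$ci[2] < ci_cancer$ci[1]
      if (sig) {
        dir <- if (ci_cancer$ratio < ci_kg$ratio) "more_disruptive_in_cancer"
               else "less_disruptive_in_cancer"
      }
    }
    data.frame(motif_id = m,
               ratio_cancer = ci_cancer$ratio, ratio_1kg = ci_kg$ratio,
               ci_cancer_lo = ci_cancer$ci[1] %||% NA_real_,
               ci_cancer_hi = ci_cancer$ci[2] %||% NA_real_,
               ci_1kg_lo = ci_kg$ci[1] %||% NA_real_,
               ci_1kg_hi = ci_kg$ci[2] %||% NA_real_,
               testable = testable, significant = sig, direction = dir,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
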