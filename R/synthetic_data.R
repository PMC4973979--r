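# Synthetic genomes, tracks and mutation cohorts with planted effects.
#
# The generator lays the genome out in fixed-width tiles, one matched
# functional/control site pair per tile: the functional site sits inside a
# constitutive open-chromatin region, its control is planted 10 kb away in
# closed, intergenic, mappable sequence (the catalog should recover that
# spacing), and each tile also carries a gene, a low-support (tissue
# variable) open region straddling the constitutive threshold, and
# occasionally an excluded block. Somatic mutations are drawn per sample
# from a cohort signature over trinucleotide contexts, with the per-base
# rate multiplied inside planted functional sites (functional fold), inside
# loop-anchor CTCF-like sites (anchor fold), at the designated hotspot motif
# position for hotspot cohorts, and log-linearly by replication timing.
# Germline polymorphisms are uniform, frequency-tagged from a site-frequency
# shaped distribution, and thinned at functional sites when the alternate
# lowers the PWM score (purifying selection).

# Fixed within-tile geometry (bp offsets from the tile start).
TILE_GEOMETRY <- list(open = c(500L, 1100L), func_centre = 800L,
                      anchor = c(600L, 1000L), boundary = c(0L, 400L),
                      gene = c(2000L, 5000L), var_open = c(6000L, 6400L),
                      excluded = c(8000L, 8500L), control_offset = 10000L)

#' Default planted motif set
#'
#' Deterministic motif set: one CTCF-like 19-bp matrix whose consensus has T
#' at position 9 (the hotspot position), plus three shorter matrices of
#' lengths 12, 14 and 16.
#'
#' @param dominance frequency of the consensus base at each position.
#' @param pseudocount passed to [pwm()].
#' @return named list of `pwm` objects.
#' @export
default_sim_pwms <- function(dominance = 0.95, pseudocount = 0.01) {
  consensi <- c(CTCF_like = "CCACTAGATGGCAGCACTG",
                MOTIF_B = "ACGGAAGTGCCA",
                MOTIF_C = "TGACGTCATTCGAA",
                MOTIF_D = "GATTACAGGCATGCTC")
  out <- lapply(names(consensi), function(id) {
    bases <- strsplit(consensi[[id]], "")[[1]]
    counts <- matrix((1 - dominance) / 3 * 100, nrow = 4, ncol = length(bases),
                     dimnames = list(DNA_BASES, NULL))
    counts[cbind(match(bases, DNA_BASES), seq_along(bases))] <- dominance * 100
    pwm(counts, id, pseudocount = pseudocount)
  })
  stats::setNames(out, names(consensi))
}

#' Preset 96-channel signature mixture
#'
#' One dominant substitution class carrying `weight` of the mass (spread
#' evenly over its 16 contexts), the rest spread evenly over the other 80
#' channels.
#'
#' @param dominant_class one of `"C>A"`, `"C>G"`, `"C>T"`, `"T>A"`, `"T>C"`,
#'   `"T>G"`.
#' @param weight mass on the dominant class (default 0.7).
#' @return named 96-vector summing to 1.
#' @export
signature_preset <- function(dominant_class, weight = 0.7) {
  ch <- spectrum_channels()
  w <- rep((1 - weight) / (96 - 16), 96)
  w[ch$class == dominant_class] <- weight / 16
  stats::setNames(w, ch$name)
}

#' Synthetic-study configuration
#'
#' Defaults encode the study conditions the pipeline is designed to detect:
#' a 3.31-fold somatic excess at functional CTCF-like sites and 1.43-fold at
#' the other motifs, a position-9 hotspot restricted to T>C-signature
#' cohorts, a three-fold anchor effect, purifying selection thinning
#' PWM-lowering common polymorphisms at functional sites, and a replication
#' timing gradient.
#'
#' @param seed RNG seed (mandatory).
#' @param pwms named list of planted `pwm` objects.
#' @param n_pairs named vector: functional/control pairs per motif.
#' @param functional_fold named vector: somatic rate multiplier inside
#'   functional sites.
#' @param n_chrom number of chromosomes.
#' @param tile_bp tile width (bp); one site pair per tile.
#' @param base_comp background base composition (A, C, G, T).
#' @param anchor_motif motif whose tiles can carry loop anchors.
#' @param anchor_frac fraction of anchor-motif tiles with an anchor.
#' @param anchor_fold somatic rate multiplier at functional anchor-motif
#'   sites inside anchors.
#' @param boundary_frac fraction of anchor-motif tiles marked as domain
#'   boundaries.
#' @param cohorts list per cohort: `n_samples`, `rate_per_bp` (expected
#'   somatic substitutions per sample per bp), `signature` (96-vector or a
#'   dominant-class name like `"T>C"`), `hotspot` (logical: carries the
#'   hotspot process).
#' @param hotspot list `motif_id`, `position` (1-based, motif strand),
#'   `fold` (1 disables).
#' @param timing_beta log-linear replication-timing effect on the somatic
#'   rate (0 disables).
#' @param germline_density expected polymorphisms per bp.
#' @param selection_strength probability that a PWM-lowering germline allele
#'   at a functional site is removed.
#' @param excluded_every every n-th tile carries an excluded block.
#' @param n_state_tracks number of chromatin-state cell lines to emit.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       pwms = default_sim_pwms(),
                       n_pairs = c(CTCF_like = 100L, MOTIF_B = 50L,
                                   MOTIF_C = 50L, MOTIF_D = 50L),
                       functional_fold = c(CTCF_like = 3.31, MOTIF_B = 1.43,
                                           MOTIF_C = 1.43, MOTIF_D = 1.43),
                       n_chrom = 2L,
                       tile_bp = 14000L,
                       base_comp = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3),
                       anchor_motif = "CTCF_like",
                       anchor_frac = 0.5,
                       anchor_fold = 3,
                       boundary_frac = 0.2,
                       cohorts = list(
                         liver_like = list(n_samples = 12L, rate_per_bp = 1.5e-3,
                                           signature = "T>C", hotspot = TRUE),
                         breast_like = list(n_samples = 8L, rate_per_bp = 1.0e-3,
                                            signature = "C>T", hotspot = FALSE)),
                       hotspot = list(motif_id = "CTCF_like", position = 9L,
                                      fold = 8),
                       timing_beta = 0.5,
                       germline_density = 1.5e-2,
                       selection_strength = 0.3,
                       excluded_every = 10L,
                       n_state_tracks = 3L) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(all(names(n_pairs) %in% names(pwms)),
            all(functional_fold > 0), germline_density >= 0,
            selection_strength >= 0, selection_strength <= 1)
  for (co in cohorts) {
    if (is.character(co$signature) && !co$signature %in% SUBSTITUTION_CLASSES) {
      stop("unknown signature preset: ", co$signature)
    }
    stopifnot(co$rate_per_bp >= 0)
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a genome with planted sites and all interval tracks
#'
#' @param config a `sim_config`.
#' @return list with `genome` (`genome_ref`), `pwms`, `tracks` (list:
#'   `dnase_master`, `footprints`, `genes`, `excluded`, `anchors`,
#'   `boundaries`, `states` (list per cell line), `timing`), `truth`
#'   (planted-site table with `motif_id`, `class`, `chrom`, `start`, `end`,
#'   `strand`, `anchor`, `tile`) and `config`.
#' @export
simulate_genome_and_tracks <- function(config) {
  set.seed(config$seed)
  geom <- TILE_GEOMETRY
  total_tiles <- sum(config$n_pairs)
  tiles_per_chrom <- ceiling(total_tiles / config$n_chrom)
  # spare motif instances per motif and chromosome, planted in an eligible
  # closed-chromatin margin at each chromosome end; they give the control
  # pool slack so spurious functional matches cannot exhaust it
  n_nursery <- pmax(ceiling(config$n_pairs * 0.15), 3L)
  nursery_spacing <- 300L
  margin <- 600L + sum(n_nursery) * nursery_spacing
  chrom_len <- tiles_per_chrom * config$tile_bp + margin
  if (geom$control_offset + max(vapply(config$pwms, `[[`, numeric(1), "length")) >=
      config$tile_bp) {
    stop("infeasible geometry: control offset exceeds tile width")
  }
  chroms <- sprintf("chr%d", seq_len(config$n_chrom))
  # random tile-to-motif assignment
  motif_of_tile <- sample(rep(names(config$n_pairs), config$n_pairs))
  tile_chrom <- chroms[(seq_len(total_tiles) - 1L) %% config$n_chrom + 1L]
  tile_rank <- stats::ave(seq_len(total_tiles), tile_chrom, FUN = seq_along)
  tile_start <- (tile_rank - 1L) * config$tile_bp
  # background sequence
  seq_chars <- lapply(chroms, function(cc) {
    sample(DNA_BASES, chrom_len, replace = TRUE, prob = config$base_comp)
  })
  names(seq_chars) <- chroms
  truth <- list(); master <- list(); foot <- list(); genes <- list()
  excl <- list(); anchors <- list(); bounds <- list(); states0 <- list()
  is_anchor_motif <- motif_of_tile == config$anchor_motif
  anchor_tile <- is_anchor_motif & stats::runif(total_tiles) < config$anchor_frac
  boundary_tile <- is_anchor_motif & stats::runif(total_tiles) < config$boundary_frac
  for (i in seq_len(total_tiles)) {
    m <- motif_of_tile[i]
    p <- config$pwms[[m]]
    cc <- tile_chrom[i]
    t0 <- tile_start[i]
    L <- p$length
    fstart <- t0 + geom$func_centre - (L %/% 2L)
    cstart <- fstart + geom$control_offset
    for (cls in c("functional", "control")) {
      st <- sample(c("+", "-"), 1)
      inst <- vapply(seq_len(L), function(j) {
        sample(DNA_BASES, 1, prob = p$freq[, j])
      }, character(1))
      s0 <- if (cls == "functional") fstart else cstart
      planted <- if (st == "+") inst else rev(unname(vapply(inst, complement_base,
                                                            character(1))))
      seq_chars[[cc]][(s0 + 1L):(s0 + L)] <- planted
      truth[[length(truth) + 1L]] <- data.frame(
        motif_id = m, class = cls, chrom = cc, start = s0, end = s0 + L,
        strand = st, anchor = (cls == "functional") && anchor_tile[i],
        tile = i, stringsAsFactors = FALSE)
    }
    # open chromatin: constitutive region via master (80%) or footprint (20%)
    if (stats::runif(1) < 0.8) {
      master[[length(master) + 1L]] <- data.frame(
        chrom = cc, start = t0 + geom$open[1], end = t0 + geom$open[2],
        support_count = sample(113:125, 1), stringsAsFactors = FALSE)
    } else {
      foot[[length(foot) + 1L]] <- data.frame(
        chrom = cc, start = t0 + geom$open[1], end = t0 + geom$open[2],
        support_count = sample(39:41, 1), stringsAsFactors = FALSE)
    }
    # tissue-variable open region below the constitutive threshold
    master[[length(master) + 1L]] <- data.frame(
      chrom = cc, start = t0 + geom$var_open[1], end = t0 + geom$var_open[2],
      support_count = sample(1:112, 1), stringsAsFactors = FALSE)
    # low-support accessibility blanket over the rest of the tile, carved out
    # around the planted control: keeps control sites in genuinely closed
    # chromatin and confines the eligible control pool to the carve-out
    master[[length(master) + 1L]] <- data.frame(
      chrom = cc, start = t0, end = cstart - 100L,
      support_count = 1L, stringsAsFactors = FALSE)
    master[[length(master) + 1L]] <- data.frame(
      chrom = cc, start = cstart + L + 100L, end = t0 + config$tile_bp,
      support_count = 1L, stringsAsFactors = FALSE)
    # every third tile transcribes across its functional site, so the
    # strand-asymmetry analysis has sites inside transcribed regions; the
    # shifted gene never reaches the control carve-out or its margins
    gs <- if (i %% 3L == 0L) c(300L, 3300L) else geom$gene
    genes[[length(genes) + 1L]] <- data.frame(
      chrom = cc, start = t0 + gs[1], end = t0 + gs[2],
      strand = sample(c("+", "-"), 1), stringsAsFactors = FALSE)
    if (i %% config$excluded_every == 0L) {
      excl[[length(excl) + 1L]] <- data.frame(
        chrom = cc, start = t0 + geom$excluded[1], end = t0 + geom$excluded[2],
        stringsAsFactors = FALSE)
    }
    if (anchor_tile[i]) {
      anchors[[length(anchors) + 1L]] <- data.frame(
        chrom = cc, start = t0 + geom$anchor[1], end = t0 + geom$anchor[2],
        stringsAsFactors = FALSE)
    }
    if (boundary_tile[i]) {
      bounds[[length(bounds) + 1L]] <- data.frame(
        chrom = cc, start = t0 + geom$boundary[1], end = t0 + geom$boundary[2],
        stringsAsFactors = FALSE)
    }
    states0[[length(states0) + 1L]] <- data.frame(
      chrom = cc, start = t0 + 400L, end = t0 + 1200L,
      fixed = anchor_tile[i], tile = i, stringsAsFactors = FALSE)
  }
  # nursery instances at each chromosome end (beyond the last tile)
  for (cc in chroms) {
    pos <- tiles_per_chrom * config$tile_bp + 300L
    for (m in names(config$n_pairs)) {
      p <- config$pwms[[m]]
      L <- p$length
      for (j in seq_len(n_nursery[[m]])) {
        st <- sample(c("+", "-"), 1)
        inst <- vapply(seq_len(L), function(k) {
          sample(DNA_BASES, 1, prob = p$freq[, k])
        }, character(1))
        planted <- if (st == "+") inst else
          rev(unname(vapply(inst, complement_base, character(1))))
        seq_chars[[cc]][(pos + 1L):(pos + L)] <- planted
        truth[[length(truth) + 1L]] <- data.frame(
          motif_id = m, class = "nursery", chrom = cc, start = pos,
          end = pos + L, strand = st, anchor = FALSE, tile = NA_integer_,
          stringsAsFactors = FALSE)
        pos <- pos + nursery_spacing
      }
    }
  }
  bind <- function(x, empty_cols) {
    if (length(x)) do.call(rbind, x) else empty_cols
  }
  empty3 <- data.frame(chrom = character(), start = integer(), end = integer(),
                       stringsAsFactors = FALSE)
  seqs <- vapply(seq_chars, paste, character(1), collapse = "")
  excl_df <- bind(excl, empty3)
  genome <- genome_ref(seqs, excluded = excl_df)
  # chromatin-state tracks: anchor tiles are insulator in every cell line,
  # other site segments get an independent random colour per cell line
  seg <- do.call(rbind, states0)
  states <- lapply(seq_len(config$n_state_tracks), function(k) {
    col <- ifelse(seg$fixed, "insulator",
                  sample(setdiff(CHROMATIN_COLORS, "insulator"),
                         nrow(seg), replace = TRUE))
    data.frame(chrom = seg$chrom, start = seg$start, end = seg$end,
               state_color = col, stringsAsFactors = FALSE)
  })
  names(states) <- sprintf("cell_line_%d", seq_len(config$n_state_tracks))
  # replication timing: linear gradient along each chromosome, 10 kb steps
  timing <- do.call(rbind, lapply(chroms, function(cc) {
    brk <- seq(0L, chrom_len, by = 10000L)
    if (brk[length(brk)] < chrom_len) brk <- c(brk, chrom_len)
    data.frame(chrom = cc, start = brk[-length(brk)], end = brk[-1],
               timing_value = (brk[-length(brk)] + diff(brk) / 2) / chrom_len,
               stringsAsFactors = FALSE)
  }))
  truth <- do.call(rbind, truth)
  list(genome = genome, pwms = config$pwms,
       tracks = list(dnase_master = bind(master, empty3),
                     footprints = bind(foot, empty3),
                     genes = bind(genes, empty3),
                     excluded = excl_df,
                     anchors = bind(anchors, empty3),
                     boundaries = bind(bounds, empty3),
                     states = states, timing = timing),
       truth = truth, config = config)
}

# Per-base sampling weights for one cohort (shared across its samples).
# Returns list(w = weight vector over the concatenated genome, offsets,
# ctx (1..32 context index), base character vector, cls_cum 3x32 cumulative
# class probabilities, alt_lookup 3x32).
build_mutation_weights <- function(sim, signature, hotspot_on) {
  config <- sim$config
  genome <- sim$genome
  ch <- spectrum_channels()
  ctx_names <- PYRIMIDINE_TRINUCS
  # per-context class intensities from the signature
  sig_mat <- matrix(0, nrow = 3, ncol = 32, dimnames = list(NULL, ctx_names))
  alt_mat <- matrix("", nrow = 3, ncol = 32, dimnames = list(NULL, ctx_names))
  for (j in seq_along(ctx_names)) {
    sel <- which(ch$context == ctx_names[j])
    sig_mat[, j] <- signature[sel]
    alt_mat[, j] <- ch$alt[sel]
  }
  chroms <- chrom_names(genome)
  lens <- genome$chrom_lengths
  offsets <- c(0, cumsum(as.numeric(lens)))[seq_along(chroms)]
  names(offsets) <- chroms
  base_all <- character(0)
  ctx_all <- integer(0)
  w_all <- numeric(0)
  for (cc in chroms) {
    b <- strsplit(as.character(genome$seq[[cc]]), "")[[1]]
    n <- length(b)
    tri <- rep(NA_character_, n)
    tri[2:(n - 1)] <- paste0(b[1:(n - 2)], b[2:(n - 1)], b[3:n])
    pur <- b %in% c("A", "G")
    tri[pur & !is.na(tri)] <- revcomp(tri[pur & !is.na(tri)])
    ctx <- match(tri, ctx_names)
    w <- colSums(sig_mat)[ctx]
    w[is.na(w)] <- 0
    # timing gradient (log-linear)
    if (config$timing_beta != 0) {
      tpos <- (seq_len(n) - 0.5) / n
      w <- w * exp(config$timing_beta * (tpos - 0.5))
    }
    ctx[is.na(ctx)] <- 0L
    base_all <- c(base_all, b)
    ctx_all <- c(ctx_all, ctx)
    w_all <- c(w_all, w)
  }
  # planted multipliers
  tr <- sim$truth
  fun <- tr[tr$class == "functional", , drop = FALSE]
  for (i in seq_len(nrow(fun))) {
    idx <- offsets[fun$chrom[i]] + (fun$start[i] + 1L):fun$end[i]
    mult <- config$functional_fold[[fun$motif_id[i]]]
    if (fun$anchor[i]) mult <- mult * config$anchor_fold
    w_all[idx] <- w_all[idx] * mult
    if (hotspot_on && config$hotspot$fold != 1 &&
        fun$motif_id[i] == config$hotspot$motif_id) {
      hp <- if (fun$strand[i] == "+") {
        fun$start[i] + config$hotspot$position - 1L
      } else {
        fun$end[i] - config$hotspot$position
      }
      w_all[offsets[fun$chrom[i]] + hp + 1L] <-
        w_all[offsets[fun$chrom[i]] + hp + 1L] * config$hotspot$fold
    }
  }
  # excluded regions carry no calls
  ex <- genome$excluded
  for (i in seq_len(nrow(ex))) {
    w_all[offsets[ex$chrom[i]] + (ex$start[i] + 1L):ex$end[i]] <- 0
  }
  list(w = w_all, offsets = offsets, ctx = ctx_all, base = base_all,
       cls_cum = apply(sig_mat, 2, function(x) cumsum(x) / sum(x)),
       alt = alt_mat, chroms = chroms, lens = lens)
}

# Draw n positions (global indices) proportional to weights.
draw_positions <- function(w, n) {
  cw <- cumsum(w)
  findInterval(stats::runif(n) * cw[length(cw)], cw) + 1L
}

# Global index -> (chrom, 0-based pos)
global_to_chrom <- function(idx, offsets, lens) {
  ci <- findInterval(idx - 1L, c(unname(offsets), sum(lens) + 1))
  data.frame(chrom = names(offsets)[ci], pos = idx - 1L - unname(offsets)[ci],
             stringsAsFactors = FALSE)
}

#' Simulate somatic and germline variants over a synthetic genome
#'
#' @param sim output of [simulate_genome_and_tracks()].
#' @return list with `somatic` (variant data frame across all cohorts) and
#'   `germline` (variant data frame, cohort `"1KG"`, with
#'   `allele_frequency`); both carry a `stratum` column recording the
#'   generating process of each call (`background`, `functional`, `hotspot`
#'   — the highest multiplier applying at the drawn base).
#' @export
simulate_mutations <- function(sim) {
  config <- sim$config
  set.seed(config$seed + 1L)
  genome_bp <- sum(sim$genome$chrom_lengths)
  somatic <- list()
  for (cname in names(config$cohorts)) {
    co <- config$cohorts[[cname]]
    signature <- if (is.character(co$signature)) {
      signature_preset(co$signature)
    } else co$signature
    wts <- build_mutation_weights(sim, signature, isTRUE(co$hotspot))
    for (s in seq_len(co$n_samples)) {
      n <- stats::rpois(1, co$rate_per_bp * genome_bp)
      if (n == 0) next
      idx <- unique(draw_positions(wts$w, n))
      loc <- global_to_chrom(idx, wts$offsets, wts$lens)
      ctx <- wts$ctx[idx]
      u <- stats::runif(length(idx))
      cls <- 1L + (u > wts$cls_cum[1, ctx]) + (u > wts$cls_cum[2, ctx])
      alt_p <- wts$alt[cbind(cls, ctx)]
      ref <- wts$base[idx]
      alt <- ifelse(ref %in% c("A", "G"),
                    complement_base(alt_p), alt_p)
      somatic[[length(somatic) + 1L]] <- data.frame(
        chrom = loc$chrom, pos = loc$pos, ref = ref, alt = alt,
        sample_id = sprintf("%s_s%02d", cname, s), cohort = cname,
        allele_frequency = NA_real_,
        stratum = call_stratum(sim, loc, isTRUE(co$hotspot)),
        stringsAsFactors = FALSE)
    }
  }
  somatic <- if (length(somatic)) do.call(rbind, somatic) else {
    ev <- empty_variants(); ev$stratum <- character(0); ev
  }
  germline <- simulate_germline(sim)
  list(somatic = somatic, germline = germline)
}

# Generating-stratum label for drawn positions (truth-table decomposition).
call_stratum <- function(sim, loc, hotspot_on) {
  config <- sim$config
  tr <- sim$truth[sim$truth$class == "functional", , drop = FALSE]
  out <- rep("background", nrow(loc))
  infun <- overlaps_any(loc, tr[, c("chrom", "start", "end")])
  out[infun] <- "functional"
  if (hotspot_on && config$hotspot$fold != 1) {
    hs <- tr[tr$motif_id == config$hotspot$motif_id, , drop = FALSE]
    hp <- ifelse(hs$strand == "+", hs$start + config$hotspot$position - 1L,
                 hs$end - config$hotspot$position)
    key <- paste(hs$chrom, hp)
    out[paste(loc$chrom, loc$pos) %in% key] <- "hotspot"
  }
  out
}

# Germline polymorphisms: uniform over analyzable bases, SFS-shaped
# frequencies, purifying selection by thinning at functional sites.
simulate_germline <- function(sim) {
  config <- sim$config
  genome <- sim$genome
  genome_bp <- sum(genome$chrom_lengths)
  n <- stats::rpois(1, config$germline_density * genome_bp)
  chroms <- chrom_names(genome)
  lens <- genome$chrom_lengths
  offsets <- c(0, cumsum(as.numeric(lens)))[seq_along(chroms)]
  names(offsets) <- chroms
  idx <- unique(sample.int(genome_bp, min(n, genome_bp)))
  loc <- global_to_chrom(idx, offsets, lens)
  ref <- character(nrow(loc))
  for (cc in unique(loc$chrom)) {
    sel <- loc$chrom == cc
    ref[sel] <- substring(as.character(genome$seq[[cc]]),
                          loc$pos[sel] + 1L, loc$pos[sel] + 1L)
  }
  keep <- ref %in% DNA_BASES & !overlaps_any(loc, genome$excluded)
  loc <- loc[keep, , drop = FALSE]; ref <- ref[keep]
  if (nrow(loc) == 0) {
    ev <- empty_variants(); ev$stratum <- character(0)
    return(ev)
  }
  alt <- vapply(ref, function(r) sample(setdiff(DNA_BASES, r), 1), character(1))
  af <- 5e-4 * 1000^stats::runif(length(ref))
  df <- data.frame(chrom = loc$chrom, pos = loc$pos, ref = ref, alt = alt,
                   sample_id = "1KG", cohort = "1KG", allele_frequency = af,
                   stratum = "background", stringsAsFactors = FALSE)
  # purifying selection: thin PWM-lowering alleles at functional sites
  if (config$selection_strength > 0) {
    tr <- sim$truth[sim$truth$class == "functional", , drop = FALSE]
    vgr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$pos + 1L, width = 1L))
    ov <- GenomicRanges::findOverlaps(vgr, as_granges(tr), ignore.strand = TRUE)
    drop <- rep(FALSE, nrow(df))
    vi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
    for (k in seq_along(vi)) {
      row <- tr[si[k], ]
      p <- sim$pwms[[row$motif_id]]
      mpos <- if (row$strand == "+") df$pos[vi[k]] - row$start + 1L
              else row$end - df$pos[vi[k]]
      rr <- df$ref[vi[k]]; aa <- df$alt[vi[k]]
      if (row$strand == "-") { rr <- complement_base(rr); aa <- complement_base(aa) }
      delta <- p$log_odds[aa, mpos] - p$log_odds[rr, mpos]
      if (delta < 0 && stats::runif(1) < config$selection_strength) {
        drop[vi[k]] <- TRUE
      }
    }
    df$stratum[!drop & seq_len(nrow(df)) %in% vi] <- "functional"
    df <- df[!drop, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Simulate a site-level regression table with known coefficients
#'
#' Direct generator for logistic-model recovery tests: sites with standard
#' normal replication timing, a motif factor with per-level effects,
#' functionality and anchor indicators, and Bernoulli mutation outcomes from
#' the specified log-odds model.
#'
#' @param n_sites number of sites.
#' @param intercept baseline log-odds.
#' @param beta_timing,beta_functionality,beta_anchor true coefficients.
#' @param n_motifs number of motif levels (effects spaced evenly in
#'   `[-motif_spread, motif_spread]`, first level 0 as reference).
#' @param motif_spread half-range of motif effects.
#' @param seed RNG seed.
#' @return data frame with `mutated`, `timing`, `motif_id`, `functionality`,
#'   `anchor`, plus the true coefficient vector as attribute `"truth"`.
#' @export
simulate_site_table <- function(n_sites = 50000L, intercept = -3,
                                beta_timing = 0.6, beta_functionality = 0.5,
                                beta_anchor = 0.7, n_motifs = 5L,
                                motif_spread = 0.5, seed = 1L) {
  set.seed(seed)
  motif_eff <- c(0, seq(-motif_spread, motif_spread, length.out = n_motifs - 1))
  motif <- sample.int(n_motifs, n_sites, replace = TRUE)
  timing <- stats::rnorm(n_sites)
  functionality <- stats::rbinom(n_sites, 1, 0.5)
  anchor <- stats::rbinom(n_sites, 1, 0.25)
  eta <- intercept + beta_timing * timing + motif_eff[motif] +
    beta_functionality * functionality + beta_anchor * anchor
  data.frame(
    mutated = stats::rbinom(n_sites, 1, stats::plogis(eta)),
    timing = timing,
    motif_id = factor(sprintf("M%02d", motif)),
    functionality = functionality, anchor = anchor
  ) -> out
  attr(out, "truth") <- c(intercept = intercept, timing = beta_timing,
                          functionality = beta_functionality,
                          anchor = beta_anchor)
  out
}

#' Simulate per-motif four-way counts under a null of no functional excess
#'
#' Poisson counts with equal functional and control means in both the cancer
#' and the population panel, for null-calibration of the per-motif Fisher
#' tests.
#'
#' @param n_motifs number of motifs.
#' @param mu_cancer,mu_kg expected counts per cell.
#' @param seed RNG seed.
#' @return list of `four_way_counts`-shaped lists.
#' @export
simulate_null_fourway <- function(n_motifs = 200L, mu_cancer = 80,
                                  mu_kg = 40, seed = 1L) {
  set.seed(seed)
  lapply(seq_len(n_motifs), function(i) {
    structure(list(n_cancer_functional = stats::rpois(1, mu_cancer),
                   n_cancer_control = stats::rpois(1, mu_cancer),
                   n_1kg_functional = stats::rpois(1, mu_kg),
                   n_1kg_control = stats::rpois(1, mu_kg)),
              class = "four_way_counts")
  })
}

#' Write a complete synthetic dataset to disk
#'
#' Emits exactly the formats the readers consume: FASTA genome, support BEDs
#' for open chromatin, BED6 genes, BED excluded regions, BEDPE anchors, BED
#' boundaries, state BEDs, bedGraph timing, MAF-like somatic table, VCF
#' germline and the truth table TSV.
#'
#' @param sim output of [simulate_genome_and_tracks()].
#' @param muts output of [simulate_mutations()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_sim_dataset <- function(sim, muts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(dir, x)
  write_genome_fasta(sim$genome, fp("genome.fa"))
  write_pwm_set(sim$pwms, fp("motifs.pfm"))
  write_bed(sim$tracks$dnase_master, fp("dnase_master.bed"))
  write_bed(sim$tracks$footprints, fp("footprints.bed"))
  g <- sim$tracks$genes
  utils::write.table(data.frame(g$chrom, g$start, g$end, ".", 0, g$strand),
                     fp("genes.bed"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_bed(sim$tracks$excluded, fp("excluded.bed"))
  a <- sim$tracks$anchors
  if (nrow(a) > 0) {
    utils::write.table(data.frame(a$chrom, a$start, a$end,
                                  a$chrom, a$start, a$end),
                       fp("anchors.bedpe"), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  write_bed(sim$tracks$boundaries, fp("boundaries.bed"))
  for (cl in names(sim$tracks$states)) {
    write_bed(sim$tracks$states[[cl]], fp(sprintf("states_%s.bed", cl)))
  }
  write_bed(sim$tracks$timing, fp("timing.bedgraph"))
  write_maf(muts$somatic, fp("somatic.maf"))
  write_vcf(muts$germline, fp("germline.vcf"))
  utils::write.table(sim$truth, fp("truth.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(sample_id = muts$somatic$sample_id,
                                cohort = muts$somatic$cohort)[
                                  !duplicated(muts$somatic$sample_id), ],
                     fp("samples.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(dir)
}
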