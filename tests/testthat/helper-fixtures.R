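# Shared fixtures, built in code.

# Deterministic random genome with a given seed; returns a genome_ref.
random_genome <- function(len = 2000L, n_chrom = 1L, seed = 42L,
                          excluded = NULL) {
  set.seed(seed)
  seqs <- vapply(seq_len(n_chrom), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
  names(seqs) <- sprintf("chr%d", seq_len(n_chrom))
  genome_ref(seqs, excluded = excluded)
}

# Small PWM from a consensus string with fixed dominance.
toy_pwm <- function(consensus, id = "TOY", dominance = 0.9,
                    pseudocount = 0.01) {
  bases <- strsplit(consensus, "")[[1]]
  counts <- matrix((1 - dominance) / 3 * 100, nrow = 4, ncol = length(bases),
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  counts[cbind(match(bases, c("A", "C", "G", "T")), seq_along(bases))] <-
    dominance * 100
  pwm(counts, id, pseudocount = pseudocount)
}

# Variant data frame constructor with defaults.
make_variants <- function(chrom, pos, ref, alt, sample_id = "s1",
                          cohort = "tumourA", af = NA_real_) {
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             sample_id = sample_id, cohort = cohort, allele_frequency = af,
             stringsAsFactors = FALSE)
}

# A minimal hand-built site catalog (bypassing scanning) for mutation-map
# tests: intervals are taken as given, pair ids assigned 1:1 in order.
manual_catalog <- function(sites) {
  stopifnot(all(c("motif_id", "chrom", "start", "end", "strand",
                  "site_class") %in% names(sites)))
  if (is.null(sites$score)) sites$score <- 10
  if (is.null(sites$p_value)) sites$p_value <- 1e-6
  per_class <- stats::ave(seq_len(nrow(sites)),
                          sites$motif_id, sites$site_class, FUN = seq_along)
  sites$pair_id <- sprintf("%s_p%04d", sites$motif_id, per_class)
  sites$site_id <- sprintf("%s_%s", sites$pair_id,
                           ifelse(sites$site_class == "functional", "F", "C"))
  structure(list(sites = sites,
                 n_sites = table(sites$motif_id[sites$site_class == "functional"])),
            class = "site_catalog")
}

# Tiny end-to-end synthetic study shared by integration-style tests.
small_sim <- function(seed = 11L, ...) {
  cfg <- sim_config(seed = seed,
                    n_pairs = c(CTCF_like = 15L, MOTIF_B = 8L,
                                MOTIF_C = 8L, MOTIF_D = 8L), ...)
  simulate_genome_and_tracks(cfg)
}
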