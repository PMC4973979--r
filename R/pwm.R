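# Position weight matrices: construction, JASPAR parsing, log-odds scores.

#' Construct a position weight matrix object
#'
#' Columns of the input count/frequency matrix are converted to
#' column-stochastic base frequencies after adding a pseudocount to every
#' cell, and log2 odds against the background are derived. Scores are also
#' discretized on a fixed grid (milli-bits) used by the exact p-value dynamic
#' programme, so scan thresholds and reported p-values are mutually
#' consistent.
#'
#' @param counts 4 x L numeric matrix (rows A, C, G, T; counts or
#'   frequencies per position).
#' @param motif_id identifier.
#' @param pseudocount value added to each cell before column normalization
#'   (default 0.01).
#' @param background base probabilities (A, C, G, T); default uniform.
#' @param grid discretization step in bits for the score grid (default 1e-3).
#' @return object of class `pwm` with elements `motif_id`, `length`, `freq`,
#'   `background`, `log_odds` (bits) and `disc` (integer grid scores).
#' @export
pwm <- function(counts, motif_id, pseudocount = 0.01,
                background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                grid = 1e-3) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) stop(sprintf("PWM '%s': expected 4 rows, got %d",
                                      motif_id, nrow(counts)))
  if (ncol(counts) < 4) stop(sprintf("PWM '%s': length %d < 4", motif_id, ncol(counts)))
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop(sprintf("PWM '%s': counts must be finite and non-negative", motif_id))
  }
  rownames(counts) <- DNA_BASES
  background <- background / sum(background)
  names(background) <- DNA_BASES
  freq <- apply(counts + pseudocount, 2, function(cc) cc / sum(cc))
  log_odds <- log2(freq / background)
  structure(
    list(motif_id = motif_id, length = ncol(freq), freq = freq,
         background = background, log_odds = log_odds,
         grid = grid, disc = round(log_odds / grid)),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm '%s': length %d, max score %.2f bits\n",
              x$motif_id, x$length, sum(apply(x$log_odds, 2, max))))
  invisible(x)
}

#' Consensus sequence of a PWM
#' @param x a `pwm`.
#' @return character string of per-column argmax bases.
#' @export
pwm_consensus <- function(x) {
  paste(DNA_BASES[apply(x$freq, 2, which.max)], collapse = "")
}

# Reverse-complemented PWM (matches the minus strand of the original motif).
pwm_revcomp <- function(x) {
  rc <- x
  flip <- function(m) m[4:1, ncol(m):1, drop = FALSE]
  rc$freq <- flip(x$freq)
  rc$log_odds <- flip(x$log_odds)
  rc$disc <- flip(x$disc)
  rc$background <- stats::setNames(rev(unname(x$background)), DNA_BASES)
  rownames(rc$freq) <- rownames(rc$log_odds) <- rownames(rc$disc) <- DNA_BASES
  rc
}

#' Read a set of PWMs from a JASPAR-style file
#'
#' Accepts the JASPAR pfm dialect: a `>id name` header line followed by four
#' rows, either bare whitespace-separated numbers or of the form
#' `A [ 87 167 ... ]`. Rows are taken in A, C, G, T order (or by their base
#' letter when given).
#'
#' @param path file path.
#' @inheritParams pwm
#' @return named list of `pwm` objects.
#' @export
read_pwm_set <- function(path, pseudocount = 0.01,
                         background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (length(starts) == 0) stop("no '>' motif headers found in ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  out <- list()
  for (k in seq_along(starts)) {
    header <- sub("^>\\s*", "", lines[starts[k]])
    motif_id <- strsplit(header, "\\s+")[[1]][1]
    body <- lines[(starts[k] + 1L):ends[k]]
    if (length(body) != 4) {
      stop(sprintf("PWM '%s': expected 4 matrix rows, got %d", motif_id, length(body)))
    }
    parsed <- lapply(body, function(ln) {
      ln2 <- gsub("]", " ", gsub("[", " ", ln, fixed = TRUE), fixed = TRUE)
      toks <- strsplit(trimws(ln2), "\\s+")[[1]]
      base <- NA_character_
      if (length(toks) > 0 && toupper(toks[1]) %in% DNA_BASES) {
        base <- toupper(toks[1])
        toks <- toks[-1]
      }
      nums <- suppressWarnings(as.numeric(toks))
      if (any(is.na(nums)) || length(nums) == 0) {
        stop(sprintf("PWM '%s': unparseable matrix row: %s", motif_id, ln))
      }
      list(base = base, nums = nums)
    })
    lens <- vapply(parsed, function(p) length(p$nums), integer(1))
    if (length(unique(lens)) != 1) {
      stop(sprintf("PWM '%s': ragged matrix rows (lengths %s)",
                   motif_id, paste(lens, collapse = ",")))
    }
    mat <- do.call(rbind, lapply(parsed, `[[`, "nums"))
    bases <- vapply(parsed, `[[`, character(1), "base")
    if (!any(is.na(bases))) {
      if (!setequal(bases, DNA_BASES)) {
        stop(sprintf("PWM '%s': rows must cover A,C,G,T; got %s",
                     motif_id, paste(bases, collapse = ",")))
      }
      mat <- mat[match(DNA_BASES, bases), , drop = FALSE]
    }
    out[[motif_id]] <- pwm(mat, motif_id, pseudocount = pseudocount,
                           background = background)
  }
  out
}

#' Write PWMs in JASPAR-style format
#'
#' Frequencies are written on a count scale (x 100), the conventional pfm
#' form, so re-reading with the standard pseudocount reproduces the original
#' frequencies closely.
#'
#' @param pwms named list of `pwm` objects.
#' @param path output file.
#' @export
write_pwm_set <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(sprintf(">%s", p$motif_id), con)
    for (i in 1:4) {
      writeLines(sprintf("%s [ %s ]", DNA_BASES[i],
                         paste(formatC(p$freq[i, ] * 100, format = "f",
                                       digits = 4), collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Score one window of sequence against a PWM
#'
#' The score is the summed log2-odds of the window under the motif versus the
#' background. For `strand = "-"` the window is reverse-complemented before
#' scoring. Windows containing N are unscorable and return `NA`.
#'
#' @param pwm a `pwm`.
#' @param seq DNA string of length `pwm$length`.
#' @param strand `"+"` or `"-"`.
#' @return score in bits, or `NA` for unscorable windows.
#' @export
score_window <- function(pwm, seq, strand = "+") {
  seq <- toupper(seq)
  if (nchar(seq) != pwm$length) {
    stop(sprintf("sequence length %d != motif length %d", nchar(seq), pwm$length))
  }
  if (strand == "-") seq <- revcomp(seq)
  bases <- strsplit(seq, "")[[1]]
  idx <- match(bases, DNA_BASES)
  if (anyNA(idx)) return(NA_real_)
  sum(pwm$log_odds[cbind(idx, seq_len(pwm$length))])
}
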