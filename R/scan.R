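#' Score a sequence window against a motif
#'
#' Log-odds score in bits: `sum_j log2(p'_j(base_j) / bg(base_j))` over the
#' window, where `p'` is the pseudocount-adjusted column probability.
#'
#' @param motif A [motif].
#' @param window A string whose length equals the motif width.
#' @return Score in bits.
#' @examples
#' m <- new_motif(matrix(c(1, 0, 0, 0), 4, 1), pseudocount = 0)
#' log_odds_score(m, "A")  # 2 bits
#' @export
log_odds_score <- function(motif, window) {
  stopifnot(inherits(motif, "motif"))
  v <- encode_seq(window)
  if (length(v) != motif_width(motif)) {
    abort("`window` length must equal the motif width.")
  }
  if (anyNA(v)) abort("`window` contains a non-ACGT/U base.")
  lo <- log_odds_matrix(motif)
  sum(lo[cbind(v, seq_along(v))])
}

# Discretized score machinery shared by the p-value DP and the scanner.
# Scores are held on an integer grid of `granularity` bits (default 1/1000).
score_grid <- function(motif, granularity = 1e-3) {
  lo <- log_odds_matrix(motif)
  list(int = round(lo / granularity), granularity = granularity)
}

# Exact null distribution of the discretized window score under the motif's
# 0-order background, by dynamic programming over columns.
# Returns list(offset, surv): surv[k] = P(score_int >= offset + k - 1).
score_null_distribution <- function(motif, granularity = 1e-3) {
  g <- score_grid(motif, granularity)
  s <- g$int
  bg <- motif$background
  lo_min <- sum(apply(s, 2, min)); lo_max <- sum(apply(s, 2, max))
  probs <- numeric(lo_max - lo_min + 1)
  # running distribution over partial sums
  cur <- setNames(1, "0")
  cur_off <- 0L
  cur_vec <- 1
  for (j in seq_len(ncol(s))) {
    cmin <- min(s[, j]); cmax <- max(s[, j])
    new_off <- cur_off + cmin
    new_vec <- numeric(length(cur_vec) + (cmax - cmin))
    for (b in 1:4) {
      sh <- s[b, j] - cmin
      idx <- seq_along(cur_vec) + sh
      new_vec[idx] <- new_vec[idx] + cur_vec * bg[b]
    }
    cur_vec <- new_vec
    cur_off <- new_off
  }
  surv <- rev(cumsum(rev(cur_vec)))
  # guard against accumulation slightly above 1
  surv <- pmin(surv, 1)
  list(offset = cur_off, surv = surv, granularity = granularity)
}

#' Exact p-value of a motif score under the background model
#'
#' Probability that a random window drawn from the motif's 0-order background
#' scores at least `score` bits. Computed by dynamic programming over the
#' per-column score distribution, exact up to the score discretization
#' (1/1000 bit by default).
#'
#' @param motif A [motif].
#' @param score Score in bits.
#' @param granularity Discretization step in bits.
#' @return p-value in `(0, 1]`.
#' @export
score_pvalue <- function(motif, score, granularity = 1e-3) {
  nd <- score_null_distribution(motif, granularity)
  cont_max <- sum(apply(log_odds_matrix(motif), 2, max))
  max_int <- nd$offset + length(nd$surv) - 1L
  vapply(score, function(s) {
    si <- round(s / granularity)
    # a score at (or within rounding error of) the attainable maximum maps to
    # the top of the discretized grid, never past it
    if (si > max_int && s <= cont_max + 1e-9) si <- max_int
    k <- si - nd$offset + 1
    if (k <= 0) return(1)
    if (k > length(nd$surv)) return(0)
    nd$surv[[k]]
  }, numeric(1))
}

#' Scan sequences for motif occurrences
#'
#' Slides the motif over every forward-strand window of every sequence,
#' scores it in bits, attaches the exact background p-value, and reports all
#' windows with `p <= p_max` (FIMO-style; overlapping hits allowed).
#' Coordinates are 0-based half-open. Windows containing non-ACGT/U bases are
#' skipped (with a warning) by default.
#'
#' @param sequences Sequence tibble, named character vector, or DNAStringSet.
#' @param motif A [motif].
#' @param p_max Report occurrences with p-value at or below this (default 1e-4).
#' @param background Optional named A/C/G/T frequencies. By default the
#'   0-order composition of the input sequences is used.
#' @param both_strands Also scan the reverse complement (default `FALSE`:
#'   inputs are cDNA / 3' UTRs, single-stranded).
#' @param on_invalid `"skip"` (default) or `"error"` for windows containing
#'   other letters.
#' @return Tibble of occurrences: `seq_id`, `start`, `end`, `strand`,
#'   `score` (bits), `p_value`.
#' @export
scan_sequences <- function(sequences, motif, p_max = 1e-4,
                           background = NULL, both_strands = FALSE,
                           on_invalid = c("skip", "error")) {
  on_invalid <- match.arg(on_invalid)
  tbl <- as_seq_tbl(sequences)
  if (nrow(tbl) == 0) abort("`sequences` is empty.")
  stopifnot(inherits(motif, "motif"))
  check_scalar(p_max, "p_max", lower = 0, upper = 1)
  bg <- background %||% base_composition(tbl)
  bg <- pmax(bg, 1e-6); bg <- bg / sum(bg)  # guard degenerate compositions
  m <- new_motif(motif$ppm, background = bg,
                 pseudocount = motif$pseudocount, nsites = motif$nsites,
                 name = motif$name)
  nd <- score_null_distribution(m)
  g <- score_grid(m)
  w <- motif_width(m)
  n_skipped <- 0L

  scan_one <- function(seq_chr, id, strand, L) {
    v <- encode_seq(seq_chr)
    nwin <- length(v) - w + 1L
    if (nwin < 1L) return(NULL)
    # integer window scores via column-shifted lookup
    si <- matrix(0, nrow = nwin, ncol = w)
    bad <- rep(FALSE, nwin)
    for (j in seq_len(w)) {
      bj <- v[j:(j + nwin - 1L)]
      bad <- bad | is.na(bj)
      si[, j] <- ifelse(is.na(bj), 0, g$int[cbind(pmax(bj, 1L), j)])
    }
    if (any(bad)) {
      if (on_invalid == "error") abort("Window with non-ACGT/U base encountered.")
      n_skipped <<- n_skipped + sum(bad)
    }
    tot <- as.integer(round(rowSums(si)))
    k <- tot - nd$offset + 1L
    p <- ifelse(k <= 0, 1, ifelse(k > length(nd$surv), 0, nd$surv[pmax(pmin(k, length(nd$surv)), 1L)]))
    keep <- !bad & p <= p_max
    if (!any(keep)) return(NULL)
    st <- which(keep) - 1L
    if (strand == "-") {
      # map back to forward coordinates
      fst <- L - (st + w)
      tibble(seq_id = id, start = fst, end = fst + w, strand = "-",
             score = tot[keep] * g$granularity, p_value = p[keep])
    } else {
      tibble(seq_id = id, start = st, end = st + w, strand = "+",
             score = tot[keep] * g$granularity, p_value = p[keep])
    }
  }

  res <- purrr::pmap(list(tbl$seq, tbl$seq_id), function(s, id) {
    out <- scan_one(s, id, "+", nchar(s))
    if (both_strands) {
      rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
      out <- bind_rows(out, scan_one(rc, id, "-", nchar(s)))
    }
    out
  })
  if (n_skipped > 0) {
    warn(sprintf("Skipped %d window(s) containing non-ACGT/U bases.", n_skipped))
  }
  out <- bind_rows(res)
  if (nrow(out) == 0) {
    out <- tibble(seq_id = character(), start = integer(), end = integer(),
                  strand = character(), score = numeric(), p_value = numeric())
  }
  arrange(out, .data$seq_id, .data$start)
}
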