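#' Sequence motif objects
#'
#' A `motif` is a position probability matrix (PPM) over A/C/G/T together with
#' the background base frequencies and pseudocount used when converting it to
#' a log-odds position weight matrix. Columns are motif positions; each column
#' sums to 1.
#'
#' @param ppm Numeric 4 x width matrix, rows in A, C, G, T order (rownames are
#'   set if missing); each column must sum to 1 within `1e-9`.
#' @param background Named base frequency vector (A, C, G, T), summing to 1.
#'   Default uniform.
#' @param pseudocount Pseudocount mass added (proportionally to background)
#'   when forming log-odds scores; default 0.1.
#' @param nsites Number of sites supporting the motif (metadata).
#' @param name Motif name.
#' @return An object of class `motif`.
#' @examples
#' m <- new_motif(matrix(c(0.97, 0.01, 0.01, 0.01), 4, 5), name = "polyA")
#' consensus(m)
#' @export
new_motif <- function(ppm, background = NULL, pseudocount = 0.1,
                      nsites = 0L, name = "motif") {
  ppm <- as.matrix(ppm)
  if (nrow(ppm) != 4) abort("`ppm` must have 4 rows (A, C, G, T).")
  if (any(ppm < 0)) abort("`ppm` entries must be nonnegative.")
  csums <- colSums(ppm)
  if (any(abs(csums - 1) > 1e-9)) {
    if (all(csums > 0)) ppm <- sweep(ppm, 2, csums, "/")
    else abort("Each `ppm` column must sum to 1.")
  }
  dimnames(ppm) <- list(DNA_BASES, NULL)
  background <- background %||% setNames(rep(0.25, 4), DNA_BASES)
  background <- background[DNA_BASES]
  if (any(is.na(background)) || abs(sum(background) - 1) > 1e-6) {
    abort("`background` must be named A/C/G/T frequencies summing to 1.")
  }
  check_scalar(pseudocount, "pseudocount", lower = 0)
  structure(
    list(ppm = ppm, background = background, pseudocount = pseudocount,
         nsites = nsites, name = name),
    class = "motif")
}

#' @rdname new_motif
#' @param motif A `motif` object.
#' @export
motif_width <- function(motif) ncol(motif$ppm)

#' @rdname new_motif
#' @export
consensus <- function(motif) {
  stopifnot(inherits(motif, "motif"))
  paste(DNA_BASES[apply(motif$ppm, 2, which.max)], collapse = "")
}

#' @rdname new_motif
#' @details `info_content()` returns the total information content in bits,
#'   `sum_j sum_b p_bj log2(p_bj / bg_b)` (relative entropy to background).
#' @export
info_content <- function(motif) {
  stopifnot(inherits(motif, "motif"))
  p <- motif$ppm
  lg <- ifelse(p > 0, log2(p / motif$background), 0)
  sum(p * lg)
}

#' @export
print.motif <- function(x, ...) {
  cat(sprintf("<motif> %s  width %d  IC %.2f bits  consensus %s\n",
              x$name, motif_width(x), info_content(x), consensus(x)))
  invisible(x)
}

#' Tidy a motif into a long tibble
#'
#' @param x A `motif`.
#' @param ... Unused.
#' @return One row per (position, base) with the probability and the log-odds
#'   score in bits.
#' @method tidy motif
#' @export
tidy.motif <- function(x, ...) {
  w <- motif_width(x)
  lo <- log_odds_matrix(x)
  tibble(
    position = rep(seq_len(w), each = 4),
    base = rep(DNA_BASES, w),
    probability = as.vector(x$ppm),
    log_odds = as.vector(lo))
}

#' @rdname tidy.motif
#' @method glance motif
#' @export
glance.motif <- function(x, ...) {
  tibble(name = x$name, width = motif_width(x),
         information_bits = info_content(x),
         consensus = consensus(x), nsites = x$nsites)
}

# Log-odds (bits) matrix: log2(p' / bg) with the motif's pseudocount applied
# proportionally to background: p' = (p + pc * bg_b) / (1 + pc).
log_odds_matrix <- function(motif) {
  pc <- motif$pseudocount
  padj <- sweep(motif$ppm + pc * motif$background, 2,
                1 + pc, "/")
  log2(padj / motif$background)
}
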