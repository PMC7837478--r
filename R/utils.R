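#' Report a count as a rounded percentage
#'
#' Small reporting helper used throughout: percentages of sequences with a
#' motif hit are conventionally given to one decimal, proportions of sheath
#' counts to the nearest integer percent.
#'
#' @param numerator,denominator Nonnegative counts; `denominator > 0`.
#' @param digits Decimal places to round to (default 1).
#' @return A single number, `100 * numerator / denominator` rounded.
#' @examples
#' proportion_percent(18, 38, digits = 0)   # 47
#' proportion_percent(1517, 1522)           # 99.7
#' @export
proportion_percent <- function(numerator, denominator, digits = 1) {
  stopifnot(is.numeric(numerator), is.numeric(denominator))
  if (any(denominator <= 0)) abort("`denominator` must be positive.")
  if (any(numerator < 0)) abort("`numerator` must be nonnegative.")
  round(100 * numerator / denominator, digits)
}

# Derive a per-stage seed from a global seed and a stage name, so pipeline
# stages are reproducible in isolation. Stays below 2^31 - 1.
derive_seed <- function(seed, stage) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

# Validate a scalar numeric argument.
check_scalar <- function(x, name, lower = -Inf, upper = Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  ok <- if (strict) x > lower && x < upper else x >= lower && x <= upper
  if (!ok) abort(sprintf("`%s` must be in [%s, %s].", name, lower, upper))
  invisible(x)
}

DNA_BASES <- c("A", "C", "G", "T")

# Coerce sequence input (named character vector, tibble with id/seq columns,
# or Biostrings XStringSet) to a tibble with columns seq_id, seq.
# U is folded to T so RNA input scans like cDNA.
as_seq_tbl <- function(sequences) {
  if (inherits(sequences, "XStringSet")) {
    sequences <- setNames(as.character(sequences), names(sequences))
  }
  if (is.character(sequences)) {
    if (is.null(names(sequences))) {
      names(sequences) <- paste0("seq_", seq_along(sequences))
    }
    out <- tibble(seq_id = names(sequences), seq = unname(sequences))
  } else if (is.data.frame(sequences)) {
    idc <- intersect(c("seq_id", "transcript_id", "gene_id"), names(sequences))[1]
    if (is.na(idc) || !"seq" %in% names(sequences)) {
      abort("Sequence table needs an id column (seq_id/transcript_id) and a `seq` column.")
    }
    out <- tibble(seq_id = as.character(sequences[[idc]]), seq = sequences$seq)
  } else {
    abort("`sequences` must be a named character vector, data frame, or XStringSet.")
  }
  out$seq <- chartr("acgtu", "ACGTT", out$seq)
  out$seq <- chartr("U", "T", out$seq)
  if (anyDuplicated(out$seq_id)) abort("Sequence ids must be unique.")
  out
}

# Integer encoding A=1 C=2 G=3 T=4; anything else NA.
encode_seq <- function(s) {
  m <- match(strsplit(s, "", fixed = TRUE)[[1]], DNA_BASES)
  m
}

decode_seq <- function(v) paste(DNA_BASES[v], collapse = "")

# 0-order base composition of a sequence table (named frequency vector).
base_composition <- function(seq_tbl) {
  counts <- colSums(Biostrings::letterFrequency(
    Biostrings::DNAStringSet(seq_tbl$seq), DNA_BASES))
  if (sum(counts) == 0) return(setNames(rep(0.25, 4), DNA_BASES))
  setNames(as.numeric(counts / sum(counts)), DNA_BASES)
}
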