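#' Summarize motif presence over a sequence universe
#'
#' Counts occurrences, the distinct sequences with at least one hit, and the
#' percentage of the universe with a hit (one decimal), the summary format
#' used for genome-scale scan reports.
#'
#' @param occurrences Occurrence tibble from [scan_sequences()] (needs a
#'   `seq_id` column).
#' @param universe Character vector of all scanned sequence ids (the
#'   denominator). Every occurrence id must belong to it.
#' @return One-row tibble: `n_input_sequences`, `n_occurrences`,
#'   `n_unique_with_hit`, `percent_with_hit`.
#' @export
summarize_presence <- function(occurrences, universe) {
  stopifnot(is.data.frame(occurrences), "seq_id" %in% names(occurrences))
  universe <- unique(as.character(universe))
  if (length(universe) == 0) abort("`universe` is empty.")
  extra <- setdiff(unique(occurrences$seq_id), universe)
  if (length(extra)) {
    abort(sprintf("Occurrence ids outside the universe: %s",
                  paste(head(extra, 3), collapse = ", ")))
  }
  u <- length(unique(occurrences$seq_id))
  tibble(
    n_input_sequences = length(universe),
    n_occurrences = nrow(occurrences),
    n_unique_with_hit = u,
    percent_with_hit = proportion_percent(u, length(universe), 1))
}

#' @rdname summarize_presence
#' @details `presence_from_counts()` computes the same percentage column for
#'   a table that already carries the counts (e.g. a published scan-results
#'   table with columns `n_input_sequences` and `n_unique_with_hit`).
#' @param counts Data frame with columns `n_input_sequences` and
#'   `n_unique_with_hit`.
#' @export
presence_from_counts <- function(counts) {
  stopifnot(all(c("n_input_sequences", "n_unique_with_hit") %in% names(counts)))
  mutate(as_tibble(counts),
         percent_with_hit = proportion_percent(
           .data$n_unique_with_hit, .data$n_input_sequences, 1))
}

#' Classify motif occurrences by transcript region
#'
#' Labels each occurrence `utr5`, `cds`, `utr3` when its `[start, end)`
#' interval lies fully inside that region, or `other` when it straddles a
#' region boundary; then summarizes the percentage of occurrences per label
#' (one decimal).
#'
#' @param occurrences Occurrence tibble (`seq_id`, `start`, `end`).
#' @param regions Region tibble (`transcript_id`, `region`, `start`, `end`;
#'   0-based half-open intervals tiling each transcript).
#' @return List with `occurrences` (input plus `region` column) and `summary`
#'   (tibble: `region`, `n`, `percent`).
#' @export
classify_positions <- function(occurrences, regions) {
  stopifnot(is.data.frame(occurrences), is.data.frame(regions))
  if (nrow(occurrences) == 0) {
    return(list(occurrences = mutate(as_tibble(occurrences),
                                     region = character(0)),
                summary = tibble(region = character(0), n = integer(0),
                                 percent = numeric(0))))
  }
  reg_by_tx <- split(regions, regions$transcript_id)
  lab <- vapply(seq_len(nrow(occurrences)), function(i) {
    tx <- occurrences$seq_id[i]
    r <- reg_by_tx[[tx]]
    if (is.null(r)) abort(sprintf("No region annotation for transcript '%s'.", tx))
    s <- occurrences$start[i]; e <- occurrences$end[i]
    span_lo <- min(r$start); span_hi <- max(r$end)
    if (s < span_lo || e > span_hi) {
      abort(sprintf("Occurrence [%d,%d) outside annotated span of '%s'.", s, e, tx))
    }
    inside <- r$region[r$start <= s & e <= r$end]
    if (length(inside) >= 1) inside[1] else "other"
  }, character(1))
  occ <- mutate(as_tibble(occurrences), region = lab)
  summary <- occ |>
    dplyr::count(.data$region, name = "n") |>
    mutate(percent = proportion_percent(.data$n, sum(.data$n), 1))
  list(occurrences = occ, summary = summary)
}

#' @rdname classify_positions
#' @details `position_summary_from_counts()` computes the per-region
#'   percentages from a named vector or table of occurrence counts.
#' @param counts Named numeric vector of occurrence counts per region label.
#' @export
position_summary_from_counts <- function(counts) {
  stopifnot(!is.null(names(counts)), all(counts >= 0), sum(counts) > 0)
  tibble(region = names(counts), n = as.integer(counts),
         percent = proportion_percent(as.numeric(counts), sum(counts), 1))
}
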