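#' Delete motif sites from a sequence
#'
#' Removes a set of 0-based half-open intervals (overlaps merged first) and
#' concatenates the remaining segments in order — the in-silico counterpart
#' of motif-deletion reporter constructs.
#'
#' @param sequence A single sequence string.
#' @param sites Data frame (or list of length-2 vectors) of `start`, `end`
#'   intervals, 0-based half-open, all within the sequence.
#' @return The sequence with sites removed (possibly empty, with a warning).
#' @examples
#' delete_sites("ABCDEFG", data.frame(start = 2, end = 5))  # "ABFG"
#' @export
delete_sites <- function(sequence, sites) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (is.list(sites) && !is.data.frame(sites)) {
    sites <- tibble(start = vapply(sites, `[[`, numeric(1), 1),
                    end = vapply(sites, `[[`, numeric(1), 2))
  }
  n <- nchar(sequence)
  if (nrow(sites) == 0) return(sequence)
  stopifnot(all(c("start", "end") %in% names(sites)))
  if (any(sites$start < 0 | sites$end > n | sites$start >= sites$end)) {
    abort("Sites must be nonempty 0-based half-open intervals within the sequence.")
  }
  s <- arrange(as_tibble(sites), .data$start)
  # merge overlapping intervals
  merged <- Reduce(function(acc, i) {
    last <- acc[[length(acc)]]
    if (s$start[i] <= last[2]) {
      acc[[length(acc)]] <- c(last[1], max(last[2], s$end[i])); acc
    } else c(acc, list(c(s$start[i], s$end[i])))
  }, seq_len(nrow(s))[-1], init = list(c(s$start[1], s$end[1])))
  keep <- character(0)
  cur <- 0
  for (iv in merged) {
    if (iv[1] > cur) keep <- c(keep, substr(sequence, cur + 1, iv[1]))
    cur <- iv[2]
  }
  if (cur < n) keep <- c(keep, substr(sequence, cur + 1, n))
  out <- paste(keep, collapse = "")
  if (!nzchar(out)) warn("All of the sequence was deleted.")
  out
}

#' Assemble a motif-insertion construct
#'
#' Concatenates motif sequences separated by short random spacers between two
#' flanks: `flank5 + motif1 + spacer + motif2 + ... + flank3`. Spacer lengths
#' are drawn uniformly from `spacer_len` (default 3-4 nt, the convention for
#' separating tandem localization motifs in reporter 3' UTRs); spacer bases
#' are uniform ACGT, seeded.
#'
#' @param motif_seqs Character vector of motif sequences (nonempty).
#' @param flank5,flank3 Flanking sequence strings (default empty).
#' @param spacer_len Integer vector of allowed spacer lengths; use `0` for
#'   direct concatenation.
#' @param seed Integer seed.
#' @return The assembled construct string, with attribute `layout` — a tibble
#'   of each part's `part`, `start`, `end` (0-based half-open).
#' @export
build_insertion <- function(motif_seqs, flank5 = "", flank3 = "",
                            spacer_len = c(3L, 4L), seed = 1) {
  if (length(motif_seqs) == 0) abort("`motif_seqs` must be nonempty.")
  stopifnot(all(spacer_len >= 0))
  set.seed(derive_seed(seed, "insertion"))
  parts <- character(0); labels <- character(0)
  if (nzchar(flank5)) { parts <- flank5; labels <- "flank5" }
  for (i in seq_along(motif_seqs)) {
    if (i > 1) {
      len <- if (length(spacer_len) == 1) spacer_len else sample(spacer_len, 1)
      if (len > 0) {
        parts <- c(parts, paste(sample(DNA_BASES, len, replace = TRUE),
                                collapse = ""))
        labels <- c(labels, sprintf("spacer_%d", i - 1))
      }
    }
    parts <- c(parts, motif_seqs[i])
    labels <- c(labels, sprintf("motif_%d", i))
  }
  if (nzchar(flank3)) { parts <- c(parts, flank3); labels <- c(labels, "flank3") }
  lens <- nchar(parts)
  ends <- cumsum(lens)
  out <- paste(parts, collapse = "")
  attr(out, "layout") <- tibble(part = labels, start = ends - lens, end = ends)
  out
}
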