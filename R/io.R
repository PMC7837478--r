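#' Read and write transcript FASTA files
#'
#' Thin wrappers over [Biostrings::readDNAStringSet()] returning/accepting the
#' tibble sequence representation used throughout the package
#' (columns `seq_id`, `seq`).
#'
#' @param path File path.
#' @return `read_fasta()`: a tibble with columns `seq_id`, `seq`.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  # keep only the first whitespace-delimited token of each header
  names(ss) <- sub("\\s.*$", "", names(ss))
  as_seq_tbl(ss)
}

#' @rdname read_fasta
#' @param sequences Sequence tibble or named character vector.
#' @export
write_fasta <- function(sequences, path) {
  tbl <- as_seq_tbl(sequences)
  ss <- Biostrings::DNAStringSet(setNames(tbl$seq, tbl$seq_id))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read and write region tables
#'
#' Region tables assign each transcript's 5' UTR, CDS and 3' UTR as 0-based
#' half-open `[start, end)` intervals that tile the transcript. Stored as TSV
#' with columns `transcript_id`, `region`, `start`, `end`.
#'
#' @param path File path.
#' @return A tibble with columns `transcript_id`, `region`, `start`, `end`.
#' @export
read_region_table <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           transcript_id = readr::col_character(),
                           region = readr::col_character(),
                           start = readr::col_integer(),
                           end = readr::col_integer()))
  tbl
}

#' @rdname read_region_table
#' @param regions Region tibble.
#' @export
write_region_table <- function(regions, path) {
  readr::write_tsv(regions, path)
  invisible(path)
}

#' Write motifs in MEME minimal motif format
#'
#' Serializes one or more [motif] objects (version line, alphabet, background
#' frequencies, letter-probability matrix blocks), readable back with
#' [read_motif_meme()].
#'
#' @param motifs A `motif` or list of `motif` objects.
#' @param path Output path.
#' @export
write_motif_meme <- function(motifs, path) {
  if (inherits(motifs, "motif")) motifs <- list(motifs)
  bg <- motifs[[1]]$background
  lines <- c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "Background letter frequencies",
    paste(sprintf("%s %.5f", names(bg), bg), collapse = " "), "")
  for (m in motifs) {
    w <- motif_width(m)
    lines <- c(lines,
      sprintf("MOTIF %s", m$name),
      sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
              w, max(1L, round(m$nsites))),
      apply(m$ppm, 2, function(col) paste(sprintf("%.6f", col), collapse = " ")),
      "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_motif_meme
#' @return `read_motif_meme()`: a list of `motif` objects.
#' @export
read_motif_meme <- function(path) {
  lines <- readLines(path)
  bg <- setNames(rep(0.25, 4), DNA_BASES)
  bgl <- grep("^Background letter frequencies", lines)
  if (length(bgl)) {
    toks <- strsplit(trimws(lines[bgl[1] + 1]), "\\s+")[[1]]
    bg <- setNames(as.numeric(toks[c(2, 4, 6, 8)]), toks[c(1, 3, 5, 7)])[DNA_BASES]
  }
  starts <- grep("^MOTIF ", lines)
  out <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    name <- strsplit(lines[starts[k]], "\\s+")[[1]][2]
    hdr <- starts[k] + 1
    while (!grepl("^letter-probability matrix", lines[hdr])) hdr <- hdr + 1
    w <- as.integer(sub(".*w= *([0-9]+).*", "\\1", lines[hdr]))
    ns <- as.integer(sub(".*nsites= *([0-9]+).*", "\\1", lines[hdr]))
    rows <- lines[(hdr + 1):(hdr + w)]
    ppm <- t(vapply(rows, function(r) as.numeric(strsplit(trimws(r), "\\s+")[[1]]),
                    numeric(4)))
    out[[k]] <- new_motif(t(ppm), background = bg, nsites = ns, name = name)
  }
  out
}
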