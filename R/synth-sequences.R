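#' Simulate a transcript set with planted motif instances
#'
#' Generates `n_transcripts` transcripts as i.i.d. background sequence with
#' configurable GC content, split into 5' UTR / CDS / 3' UTR regions whose
#' lengths are drawn from per-region ranges (the CDS is rounded to a multiple
#' of 3 by convention). Motif instances are planted per region with the given
#' per-region probabilities at uniform positions, and every insertion is
#' recorded with exact coordinates, so downstream discovery/scanning/region
#' classification can be scored against ground truth.
#'
#' @param n_transcripts Number of transcripts.
#' @param region_length_ranges Named list of length-2 integer ranges for
#'   `utr5`, `cds`, `utr3` (defaults 50-150 / 300-900 / 200-600 nt).
#' @param gc_content Background GC fraction (default 0.45).
#' @param planted_motifs List of plant specs, each a list with `consensus`
#'   (string; or `ppm`, a 4 x w matrix sampled per instance) and `prob`, a
#'   named vector of per-region insertion probabilities
#'   (e.g. `c(utr5 = 0.02, cds = 0.05, utr3 = 0.4)`). Default: none.
#' @param n_variants_per_gene Number of splice variants per gene (default 1);
#'   variants reuse the gene's sequence truncated at random, for exercising
#'   longest-variant selection.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments.
#' @return List with `sequences` (tibble: `gene_id`, `seq_id`, `seq`),
#'   `regions` (region tibble, 0-based half-open, tiling each transcript) and
#'   `truth` (tibble of planted occurrences: `seq_id`, `motif`, `region`,
#'   `start`, `end`).
#' @export
sim_transcripts <- function(n_transcripts,
                            region_length_ranges = list(
                              utr5 = c(50L, 150L), cds = c(300L, 900L),
                              utr3 = c(200L, 600L)),
                            gc_content = 0.45,
                            planted_motifs = list(),
                            n_variants_per_gene = 1,
                            seed = 1) {
  check_scalar(n_transcripts, "n_transcripts", lower = 1)
  check_scalar(gc_content, "gc_content", lower = 0, upper = 1)
  for (pm in planted_motifs) {
    if (is.null(pm$prob) || any(pm$prob < 0 | pm$prob > 1)) {
      abort("Each planted motif needs per-region `prob` in [0, 1].")
    }
  }
  base_p <- c(A = (1 - gc_content) / 2, C = gc_content / 2,
              G = gc_content / 2, T = (1 - gc_content) / 2)
  set.seed(derive_seed(seed, "transcripts"))

  draw_len <- function(rng) if (rng[1] == rng[2]) rng[1] else
    sample(seq.int(rng[1], rng[2]), 1)

  seqs <- vector("list", n_transcripts)
  regions <- vector("list", n_transcripts)
  truth <- list()
  for (i in seq_len(n_transcripts)) {
    tid <- sprintf("tx_%04d", i)
    l5 <- as.integer(draw_len(region_length_ranges$utr5))
    lc <- as.integer(draw_len(region_length_ranges$cds))
    lc <- max(3L, 3L * as.integer(round(lc / 3)))
    l3 <- as.integer(draw_len(region_length_ranges$utr3))
    L <- l5 + lc + l3
    s <- sample(DNA_BASES, L, replace = TRUE, prob = base_p)
    reg <- tibble(transcript_id = tid,
                  region = c("utr5", "cds", "utr3"),
                  start = c(0L, l5, l5 + lc),
                  end = c(l5, l5 + lc, L))
    for (mi in seq_along(planted_motifs)) {
      pm <- planted_motifs[[mi]]
      inst_w <- if (!is.null(pm$consensus)) nchar(pm$consensus) else ncol(pm$ppm)
      for (r in seq_len(nrow(reg))) {
        rname <- reg$region[r]
        p <- if (rname %in% names(pm$prob)) pm$prob[[rname]] else 0
        rlen <- reg$end[r] - reg$start[r]
        if (inst_w > rlen && p > 0) {
          abort(sprintf("Motif width %d exceeds %s length %d.",
                        inst_w, rname, rlen))
        }
        if (p > 0 && runif(1) < p) {
          pos0 <- reg$start[r] + sample.int(rlen - inst_w + 1L, 1) - 1L
          inst <- if (!is.null(pm$consensus)) {
            strsplit(pm$consensus, "")[[1]]
          } else {
            DNA_BASES[apply(pm$ppm, 2, function(col)
              sample.int(4, 1, prob = col))]
          }
          s[(pos0 + 1):(pos0 + inst_w)] <- inst
          truth[[length(truth) + 1L]] <- tibble(
            seq_id = tid, motif = sprintf("planted_%d", mi),
            region = rname, start = pos0, end = pos0 + inst_w)
        }
      }
    }
    seqs[[i]] <- tibble(gene_id = sprintf("gene_%04d", i), seq_id = tid,
                        seq = paste(s, collapse = ""))
    regions[[i]] <- reg
  }
  sequences <- bind_rows(seqs)
  if (n_variants_per_gene > 1) {
    extra <- list()
    for (v in 2:n_variants_per_gene) {
      ext <- mutate(sequences,
                    seq_id = sprintf("%s_v%d", .data$seq_id, v),
                    seq = substr(.data$seq, 1,
                                 pmax(20L, floor(nchar(.data$seq) *
                                                   runif(n(), 0.3, 0.9)))))
      extra[[v - 1L]] <- ext
    }
    sequences <- bind_rows(sequences, bind_rows(extra))
  }
  truth_tbl <- if (length(truth)) bind_rows(truth) else
    tibble(seq_id = character(), motif = character(), region = character(),
           start = integer(), end = integer())
  list(sequences = sequences, regions = bind_rows(regions), truth = truth_tbl)
}
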