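#' Expression floor filter on treatment replicates
#'
#' Keeps genes whose every treatment replicate is strictly above `threshold`
#' normalized counts — the first gate of the candidate-selection workflow.
#'
#' @param table Abundance tibble with a `gene_id` column and treatment
#'   replicate columns.
#' @param threshold Minimum per-replicate value (strict `>`; default 20).
#' @param treatment_cols Tidy-select or character vector of treatment
#'   replicate columns; default: columns starting with `"treatment"`.
#' @return Tibble of surviving rows (a gene set with expression provenance).
#' @export
filter_min_expression <- function(table, threshold = 20,
                                  treatment_cols = NULL) {
  stopifnot(is.data.frame(table), "gene_id" %in% names(table))
  cols <- treatment_cols %||% grep("^treatment", names(table), value = TRUE)
  if (length(cols) < 1) abort("No treatment replicate columns found.")
  m <- as.matrix(table[, cols, drop = FALSE])
  keep <- apply(m, 1, function(r) all(r > threshold))
  as_tibble(table)[keep, , drop = FALSE]
}

#' Build keyword-matched gene lists from annotation terms
#'
#' Case-insensitive substring match of each keyword stem against every term a
#' gene carries; per-stem gene lists are deduplicated. Reproduces the manual
#' step of collecting genes whose ontology terms contain "synap",
#' "translation", "myelin" or "oligodend".
#'
#' @param annotation Tibble with columns `gene_id`, `term`.
#' @param stems Character vector of lowercase stems (default the four above).
#' @return Named list of deduplicated gene id vectors, one per stem.
#' @export
keyword_lists <- function(annotation,
                          stems = c("synap", "translation", "myelin",
                                    "oligodend")) {
  stopifnot(all(c("gene_id", "term") %in% names(annotation)))
  lower <- tolower(annotation$term)
  out <- lapply(stems, function(st) {
    unique(annotation$gene_id[stringr::str_detect(lower, stringr::fixed(st))])
  })
  setNames(out, stems)
}

#' Genes common to multiple keyword lists
#'
#' @param lists Named list of gene id vectors (each deduplicated).
#' @param min_membership Minimum number of distinct lists a gene must appear
#'   in (default 2, i.e. "common to more than one list").
#' @return Sorted character vector of gene ids.
#' @export
multi_list_candidates <- function(lists, min_membership = 2) {
  if (length(lists) < 2) abort("Need at least 2 lists.")
  tallies <- table(unlist(lapply(lists, unique)))
  sort(names(tallies)[tallies >= min_membership])
}

#' Call myelin-enriched transcripts from an abundance table
#'
#' Applies the myelin-transcriptome definition: q-value < `q_max` (strict)
#' and mean FPKM > `min_fpkm` in the control or the treatment group. Fold
#' change (mean treatment / mean control) is attached, and the `localized`
#' column additionally requires fold change > 1 and (when present) the
#' `fully_annotated` flag — the sub-selection taking an enriched set down to
#' the localized, annotated transcripts.
#'
#' When the table has no `q_value` column, Benjamini-Hochberg q-values are
#' computed from `p_value`; provided q-values are used as-is.
#'
#' @param table Abundance tibble: `gene_id`, `treatment_*` and `control_*`
#'   FPKM columns, and `q_value` or `p_value`.
#' @param q_max,min_fpkm Thresholds (strict comparisons; defaults 0.05 and 5).
#' @return Tibble of enriched genes with `mean_treatment`, `mean_control`,
#'   `fold_change`, `q_value`, `localized`.
#' @export
call_myelin_enriched <- function(table, q_max = 0.05, min_fpkm = 5) {
  stopifnot(is.data.frame(table), "gene_id" %in% names(table))
  tcols <- grep("^treatment", names(table), value = TRUE)
  ccols <- grep("^control", names(table), value = TRUE)
  if (!length(tcols) || !length(ccols)) {
    abort("Need treatment_* and control_* FPKM columns.")
  }
  tab <- as_tibble(table)
  if (!"q_value" %in% names(tab)) {
    if (!"p_value" %in% names(tab)) abort("Need a `q_value` or `p_value` column.")
    tab$q_value <- p.adjust(tab$p_value, method = "BH")
  }
  tab$mean_treatment <- rowMeans(tab[, tcols, drop = FALSE])
  tab$mean_control <- rowMeans(tab[, ccols, drop = FALSE])
  tab$fold_change <- tab$mean_treatment / tab$mean_control
  keep <- tab$q_value < q_max &
    (tab$mean_control > min_fpkm | tab$mean_treatment > min_fpkm)
  out <- tab[keep & !is.na(keep), , drop = FALSE]
  ann <- if ("fully_annotated" %in% names(out)) out$fully_annotated else TRUE
  out$localized <- out$fold_change > 1 & ann
  select(out, "gene_id", "mean_treatment", "mean_control", "fold_change",
         "q_value", "localized")
}

#' Keep the longest splice variant per gene
#'
#' @param sequences Sequence tibble with columns `gene_id`, `seq_id`
#'   (transcript), `seq` — or any table with those columns.
#' @return One row per gene: the maximum-length variant, ties broken by the
#'   lexicographically smallest transcript id.
#' @export
select_longest_variant <- function(sequences) {
  stopifnot(all(c("gene_id", "seq_id", "seq") %in% names(sequences)))
  if (nrow(sequences) == 0) abort("`sequences` is empty.")
  as_tibble(sequences) |>
    mutate(.len = nchar(.data$seq)) |>
    group_by(.data$gene_id) |>
    arrange(dplyr::desc(.data$.len), .data$seq_id, .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup() |>
    select(-".len")
}

#' Rank an ontology term table by FDR
#'
#' Filters to FDR < `fdr_max` (strict), sorts ascending by FDR, drops
#' duplicate term names keeping the best FDR, and returns the top `top_n`.
#'
#' @param term_table Tibble with columns `term`, `fdr` (and optionally a gene
#'   count column, carried through).
#' @param fdr_max FDR cutoff (default 0.05).
#' @param top_n Number of terms to keep (default 20).
#' @return Filtered, ranked tibble.
#' @export
rank_terms <- function(term_table, fdr_max = 0.05, top_n = 20) {
  stopifnot(all(c("term", "fdr") %in% names(term_table)))
  as_tibble(term_table) |>
    filter(.data$fdr < fdr_max) |>
    arrange(.data$fdr) |>
    distinct(.data$term, .keep_all = TRUE) |>
    head(top_n)
}
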