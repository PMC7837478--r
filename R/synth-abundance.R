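#' Simulate a replicate FPKM abundance table with planted enrichment
#'
#' Draws per-gene baseline log-FPKM from a normal distribution, plants an
#' `enriched_fraction` of genes whose treatment mean is `fold_change` times
#' the control mean, and adds replicate-level log-normal noise
#' (`dispersion` = SD of log-FPKM across replicates). The default design is
#' 3 treatment replicates (purified myelin) versus 6 controls (cultured
#' oligodendrocyte datasets). Per-gene p-values come from a Welch t test on
#' log FPKM and Benjamini-Hochberg q-values are attached, so the table feeds
#' straight into [call_myelin_enriched()].
#'
#' @param n_genes Number of genes.
#' @param n_treatment_reps,n_control_reps Replicate counts (each >= 2;
#'   defaults 3 and 6).
#' @param baseline_log_fpkm_mean,baseline_log_fpkm_sd Baseline natural-log
#'   FPKM distribution (defaults `log(20)` and 1).
#' @param enriched_fraction Fraction of genes planted as enriched.
#' @param fold_change Treatment/control mean ratio for enriched genes (> 0).
#' @param dispersion Replicate log-FPKM SD (0 gives noiseless replicates).
#' @param prop_fully_annotated Probability a gene carries the
#'   `fully_annotated` flag (default 1).
#' @param seed Integer seed.
#' @return List with `table` (tibble: `gene_id`, `treatment_*`, `control_*`,
#'   `p_value`, `q_value`, `fully_annotated`) and `truth` (tibble: `gene_id`,
#'   `enriched`).
#' @export
sim_abundance <- function(n_genes, n_treatment_reps = 3, n_control_reps = 6,
                          baseline_log_fpkm_mean = log(20),
                          baseline_log_fpkm_sd = 1,
                          enriched_fraction = 0.1, fold_change = 8,
                          dispersion = 0.25, prop_fully_annotated = 1,
                          seed = 1) {
  check_scalar(n_genes, "n_genes", lower = 1)
  if (n_treatment_reps < 2 || n_control_reps < 2) {
    abort("Replicate counts must be at least 2.")
  }
  check_scalar(enriched_fraction, "enriched_fraction", lower = 0, upper = 1)
  if (fold_change <= 0) abort("`fold_change` must be positive.")
  check_scalar(dispersion, "dispersion", lower = 0)
  set.seed(derive_seed(seed, "abundance"))

  gene_id <- sprintf("gene_%05d", seq_len(n_genes))
  enriched <- runif(n_genes) < enriched_fraction
  base <- rnorm(n_genes, baseline_log_fpkm_mean, baseline_log_fpkm_sd)
  mu_t <- base + ifelse(enriched, log(fold_change), 0)
  mu_c <- base
  tmat <- exp(matrix(rnorm(n_genes * n_treatment_reps, mu_t, dispersion),
                     nrow = n_genes))
  cmat <- exp(matrix(rnorm(n_genes * n_control_reps, mu_c, dispersion),
                     nrow = n_genes))
  p <- vapply(seq_len(n_genes), function(i) {
    x <- log(tmat[i, ]); y <- log(cmat[i, ])
    if (sd(x) == 0 && sd(y) == 0) {
      return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
    }
    tryCatch(t.test(x, y)$p.value, error = function(e) 1)
  }, numeric(1))
  tab <- tibble(gene_id = gene_id)
  for (j in seq_len(n_treatment_reps)) tab[[paste0("treatment_", j)]] <- tmat[, j]
  for (j in seq_len(n_control_reps)) tab[[paste0("control_", j)]] <- cmat[, j]
  tab$p_value <- p
  tab$q_value <- p.adjust(p, method = "BH")
  tab$fully_annotated <- runif(n_genes) < prop_fully_annotated
  list(table = tab, truth = tibble(gene_id = gene_id, enriched = enriched))
}

#' Simulate a gene-to-keyword annotation table
#'
#' Assigns each gene 0 or more free-text terms drawn from a vocabulary, so
#' the keyword-list construction ([keyword_lists()]) and multi-list
#' intersection can be exercised against a substring-matching oracle. The
#' default vocabulary mixes terms carrying the canonical stems ("synap",
#' "translation", "myelin", "oligodend") with unrelated terms.
#'
#' @param n_genes Number of genes (ids `gene_00001`, ...).
#' @param vocabulary Character vector of candidate terms (nonempty).
#' @param mean_terms_per_gene Poisson mean number of terms per gene.
#' @param seed Integer seed.
#' @return Tibble with columns `gene_id`, `term` (one row per assignment).
#' @export
sim_annotation <- function(n_genes,
                           vocabulary = c(
                             "Synaptic Signaling", "Chemical Synaptic Transmission",
                             "Regulation of Translation", "Translation Initiation",
                             "Myelination", "Myelin Sheath",
                             "Oligodendrocyte Differentiation",
                             "Cell Cycle", "Ion Transport", "Apoptotic Process"),
                           mean_terms_per_gene = 2, seed = 1) {
  if (length(vocabulary) == 0) abort("`vocabulary` must be nonempty.")
  check_scalar(n_genes, "n_genes", lower = 1)
  set.seed(derive_seed(seed, "annotation"))
  rows <- lapply(seq_len(n_genes), function(i) {
    k <- rpois(1, mean_terms_per_gene)
    if (k == 0) return(NULL)
    tibble(gene_id = sprintf("gene_%05d", i),
           term = sample(vocabulary, min(k, length(vocabulary))))
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) out <- tibble(gene_id = character(), term = character())
  out
}
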