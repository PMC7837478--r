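toy_table <- function() {
  tibble::tibble(
    gene_id = paste0("g", 1:5),
    treatment_1 = c(20, 21, 100, 5, 30),
    treatment_2 = c(25, 21, 90, 200, 30),
    treatment_3 = c(30, 21, 80, 300, 30))
}

test_that("expression floor keeps genes strictly above threshold in all reps", {
  out <- filter_min_expression(toy_table(), 20)
  # (20,25,30) is excluded by the strict boundary; (21,21,21) included
  expect_identical(out$gene_id, c("g2", "g3", "g5"))
  # hand-filtered oracle
  m <- as.matrix(toy_table()[, 2:4])
  expect_identical(out$gene_id,
                   toy_table()$gene_id[apply(m, 1, function(r) all(r > 20))])
  # idempotent
  expect_identical(filter_min_expression(out, 20), out)
  expect_error(filter_min_expression(tibble::tibble(gene_id = "g")), "treatment")
})

test_that("keyword lists are case-insensitive substring matches, deduplicated", {
  ann <- tibble::tibble(
    gene_id = c("a", "a", "b", "c", "c", "d"),
    term = c("Synaptic Signaling", "Regulation of Translation",
             "myelin sheath", "Myelination", "MYELIN assembly", "Cell cycle"))
  kl <- keyword_lists(ann)
  expect_identical(kl$synap, "a")
  expect_identical(kl$translation, "a")
  expect_identical(sort(kl$myelin), c("b", "c"))   # c deduplicated
  expect_identical(kl$oligodend, character(0))
  # substring-scan oracle over a random toy annotation
  set.seed(5)
  ann2 <- tibble::tibble(gene_id = sample(letters[1:10], 30, TRUE),
                         term = sample(c("synapse organization", "x", "Myelin",
                                         "oligodendrocyte dev", "translation"),
                                       30, TRUE))
  kl2 <- keyword_lists(ann2)
  for (stem in names(kl2)) {
    expect_setequal(kl2[[stem]],
                    unique(ann2$gene_id[grepl(stem, tolower(ann2$term),
                                              fixed = TRUE)]))
  }
})

test_that("multi-list intersection finds genes in >= k lists", {
  lists <- list(l1 = c("a", "b", "c"), l2 = c("b", "c", "d"), l3 = "e")
  expect_identical(multi_list_candidates(lists), c("b", "c"))
  expect_identical(multi_list_candidates(list(l1 = "a", l2 = "b")), character(0))
  all4 <- list(a = "g", b = "g", c = "g", d = "g")
  expect_identical(multi_list_candidates(all4, 4), "g")
  expect_error(multi_list_candidates(list(l1 = "a")), "at least 2")
})

test_that("myelin-enrichment calling applies strict q and FPKM gates", {
  tab <- tibble::tibble(
    gene_id = c("q_boundary", "low_fpkm", "one_side", "good", "not_loc"),
    treatment_1 = c(50, 4.9, 5.1, 40, 10), treatment_2 = c(50, 4.9, 5.1, 40, 10),
    treatment_3 = c(50, 4.9, 5.1, 40, 10),
    control_1 = c(10, 4.9, 0.2, 10, 20), control_2 = c(10, 4.9, 0.2, 10, 20),
    q_value = c(0.05, 0.01, 0.01, 0.01, 0.01))
  out <- call_myelin_enriched(tab)
  expect_false("q_boundary" %in% out$gene_id)   # q = 0.05 exactly: excluded
  expect_false("low_fpkm" %in% out$gene_id)     # means 4.9/4.9: excluded
  expect_true("one_side" %in% out$gene_id)      # 5.1 vs 0.2: included
  expect_equal(out$fold_change[out$gene_id == "good"], 4)
  expect_false(out$localized[out$gene_id == "not_loc"])  # fold < 1
  expect_error(call_myelin_enriched(dplyr::select(tab, -"q_value")), "q_value")

  # monotone in q_max: looser thresholds give supersets
  loose <- call_myelin_enriched(tab, q_max = 0.5)
  expect_true(all(out$gene_id %in% loose$gene_id))
})

test_that("BH q-values computed from p match the direct step-up formula", {
  set.seed(12)
  p <- runif(15)
  tab <- tibble::tibble(gene_id = paste0("g", 1:15),
                        treatment_1 = 100, treatment_2 = 100,
                        control_1 = 10, control_2 = 10, p_value = p)
  out <- call_myelin_enriched(tab, q_max = 1.1)
  # direct formula: q_(i) = min_{j >= i} p_(j) * n / j
  o <- order(p)
  q_oracle <- rev(cummin(rev(p[o] * 15 / seq_len(15))))[order(o)]
  expect_equal(out$q_value, pmin(q_oracle, 1)[match(out$gene_id, tab$gene_id)])
})

test_that("longest-variant selection breaks ties by transcript id", {
  seqs <- tibble::tibble(
    gene_id = c("g1", "g2", "g2", "g2", "g3", "g3"),
    seq_id = c("t1", "t2b", "t2a", "t2c", "t3b", "t3a"),
    seq = c("ACGT", strrep("A", 100), strrep("C", 250), strrep("G", 30),
            strrep("T", 100), strrep("A", 100)))
  out <- select_longest_variant(seqs)
  expect_identical(out$seq_id[out$gene_id == "g1"], "t1")
  expect_identical(out$seq_id[out$gene_id == "g2"], "t2a")  # longest (250)
  expect_identical(out$seq_id[out$gene_id == "g3"], "t3a")  # tie -> smaller id
})

test_that("term ranking filters, sorts, deduplicates, truncates", {
  expect_identical(nrow(rank_terms(tibble::tibble(term = character(),
                                                  fdr = numeric()))), 0L)
  set.seed(3)
  tt <- tibble::tibble(term = c(paste0("t", 1:23), "t1", "t2"),
                       fdr = c(runif(20, 0, 0.04), 0.2, 0.5, 0.9, 0.001, 0.002))
  out <- rank_terms(tt)
  expect_lte(nrow(out), 20)
  expect_false(any(duplicated(out$term)))
  expect_true(all(diff(out$fdr) >= 0))
  expect_true(all(out$fdr < 0.05))
  # duplicates keep the best FDR
  expect_equal(out$fdr[out$term == "t1"], min(tt$fdr[tt$term == "t1"]))
  none <- rank_terms(tibble::tibble(term = "a", fdr = 0.2))
  expect_identical(nrow(none), 0L)
})
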