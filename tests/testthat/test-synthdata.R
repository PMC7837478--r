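test_that("transcript generator tiles regions, plants on demand, and is seeded", {
  ts <- sim_transcripts(15, seed = 2)
  ts2 <- sim_transcripts(15, seed = 2)
  expect_identical(ts, ts2)
  # regions tile each transcript with no gaps or overlaps
  for (tx in unique(ts$regions$transcript_id)) {
    r <- dplyr::arrange(ts$regions[ts$regions$transcript_id == tx, ], start)
    expect_identical(r$start[1], 0L)
    expect_equal(r$start[-1], r$end[-nrow(r)])
    L <- nchar(ts$sequences$seq[ts$sequences$seq_id == tx])
    expect_identical(r$end[nrow(r)], as.integer(L))
  }
  # no plants requested -> empty ground truth
  expect_identical(nrow(ts$truth), 0L)
})

test_that("forced plants give exact ground-truth counts and coordinates", {
  ts <- sim_transcripts(
    100, planted_motifs = list(list(consensus = "TGCATGTC",
                                    prob = c(utr3 = 1))), seed = 4)
  expect_identical(nrow(ts$truth), 100L)
  expect_true(all(ts$truth$region == "utr3"))
  # every recorded occurrence is literally present at its coordinates
  for (i in seq_len(nrow(ts$truth))) {
    s <- ts$sequences$seq[ts$sequences$seq_id == ts$truth$seq_id[i]]
    expect_identical(substr(s, ts$truth$start[i] + 1, ts$truth$end[i]),
                     "TGCATGTC")
  }
})

test_that("planting probability is honored within binomial error", {
  ts <- sim_transcripts(
    500, planted_motifs = list(list(consensus = "TGCATGTC",
                                    prob = c(utr3 = 0.4))), seed = 3)
  frac <- nrow(ts$truth) / 500
  expect_lt(abs(frac - 0.4), 3 * sqrt(0.4 * 0.6 / 500))
})

test_that("motif wider than its target region is rejected", {
  expect_error(
    sim_transcripts(3, region_length_ranges = list(utr5 = c(5L, 5L),
                                                   cds = c(30L, 30L),
                                                   utr3 = c(6L, 6L)),
                    planted_motifs = list(list(consensus = "ACGTACGTAC",
                                               prob = c(utr3 = 1))),
                    seed = 1),
    "exceeds")
})

test_that("abundance generator plants exact fold changes and flags truth", {
  noiseless <- sim_abundance(50, fold_change = 4, dispersion = 0,
                             enriched_fraction = 0.3, seed = 6)
  tab <- noiseless$table
  tmean <- rowMeans(tab[, grep("^treatment", names(tab))])
  cmean <- rowMeans(tab[, grep("^control", names(tab))])
  enr <- noiseless$truth$enriched
  expect_true(any(enr))
  expect_equal(tmean[enr] / cmean[enr], rep(4, sum(enr)))
  expect_equal(tmean[!enr] / cmean[!enr], rep(1, sum(!enr)))

  none <- sim_abundance(50, enriched_fraction = 0, seed = 6)
  expect_false(any(none$truth$enriched))
  expect_error(sim_abundance(10, n_treatment_reps = 1), "at least 2")
  expect_identical(sim_abundance(30, seed = 9), sim_abundance(30, seed = 9))
})

test_that("annotation generator feeds the keyword workflow", {
  ann <- sim_annotation(40, seed = 2)
  expect_identical(ann, sim_annotation(40, seed = 2))
  # a vocabulary without any stem yields empty keyword lists downstream
  bare <- sim_annotation(40, vocabulary = c("Cell Cycle", "Ion Transport"),
                         seed = 2)
  kl <- keyword_lists(bare)
  expect_true(all(lengths(kl) == 0))
})

test_that("image generator: pure background, determinism, countable spots", {
  bg_only <- sim_image_stack(shape = c(5, 32, 32), n_sheaths = 2,
                             n_spots_per_sheath = 0, poisson_noise = FALSE,
                             read_noise_sd = 0, membrane_amplitude = 0,
                             background = c(low = 10, high = 20), seed = 1)
  a <- bg_only$stack$channels$mrna
  # every slice equals the pure linear background gradient
  grad <- 10 + (20 - 10) * (0:31) / 31
  for (k in 1:5) expect_equal(a[, , k], matrix(rep(grad, each = 32), 32, 32))

  d1 <- sim_image_stack(shape = c(5, 48, 48), n_sheaths = 2, seed = 7)
  d2 <- sim_image_stack(shape = c(5, 48, 48), n_sheaths = 2, seed = 7)
  expect_identical(d1, d2)

  # noiseless render of 50 well-separated bright spots has exactly 50 local
  # maxima above background (oracle: direct neighborhood scan of the
  # projection)
  ds <- sim_image_stack(shape = c(9, 160, 160), n_sheaths = 10,
                        n_spots_per_sheath = 5, spot_amplitude = 300,
                        terminal_bias = 0, poisson_noise = FALSE,
                        read_noise_sd = 0, min_spot_sep_um = 1,
                        background = c(low = 5, high = 10), seed = 11)
  expect_identical(nrow(ds$truth), 50L)
  proj <- max_project(ds$stack, "mrna")
  nr <- nrow(proj); nc <- ncol(proj)
  n_max <- 0L
  for (i in 2:(nr - 1)) for (j in 2:(nc - 1)) {
    nb <- proj[(i - 1):(i + 1), (j - 1):(j + 1)]
    if (proj[i, j] > 60 && proj[i, j] == max(nb) && sum(nb == proj[i, j]) == 1) {
      n_max <- n_max + 1L
    }
  }
  expect_identical(n_max, 50L)
})
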