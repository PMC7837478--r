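test_that("line profiles sample the scan grid by bilinear interpolation", {
  px <- 0.1
  cst <- matrix(12, 100, 100)
  path <- tibble::tibble(x_um = c(1, 8.2), y_um = c(5, 5))
  pr <- extract_line_profile(cst, path, px)
  expect_identical(nrow(pr), 36L)                 # 7 / 0.2 + 1
  expect_true(all(pr$value == 12))
  expect_equal(pr$distance_um, seq(0, 7, by = 0.2))

  # axis-aligned path over a linear ramp: sampled values linear in distance
  ramp <- outer(rep(1, 100), 0:99)                # value = x_px = x_um / px
  pr2 <- extract_line_profile(ramp, path, px)
  expect_equal(pr2$value, (1 + pr2$distance_um) / px, tolerance = 1e-10)

  short <- tibble::tibble(x_um = c(0, 5), y_um = c(0, 0))
  expect_error(extract_line_profile(cst, short, px), "shorter")
})

test_that("profile normalization divides by the mean and errors on zeros", {
  pr <- structure(tibble::tibble(distance_um = c(0, 0.2, 0.4),
                                 value = c(1, 2, 3)),
                  class = c("line_profile", class(tibble::tibble())))
  np <- normalize_profile(pr)
  expect_equal(np$value, c(0.5, 1, 1.5))
  expect_true(isTRUE(attr(np, "normalized")))
  pr$value <- c(5, 5, 5)
  expect_equal(normalize_profile(pr)$value, c(1, 1, 1))
  pr$value <- c(0, 0, 0)
  expect_error(normalize_profile(pr), "positive")
  # invariant: mean of normalized values is 1
  set.seed(8)
  for (i in 1:20) {
    pr$value <- runif(3, 0.1, 50)
    expect_equal(mean(normalize_profile(pr)$value), 1)
  }
})

test_that("per-distance group comparison uses the stated Wilcoxon rules", {
  grid <- seq(0, 1, by = 0.2)
  mk <- function(vals) {
    purrr::map_dfr(seq_along(vals), function(i)
      tibble::tibble(sheath_id = i, distance_um = grid, value = vals[i]))
  }
  # identical constant groups: z = 0 convention gives p = 1 everywhere
  cmpc <- profile_group_compare(mk(c(2, 2, 2)), mk(c(2, 2, 2)))
  expect_true(all(cmpc$p_value == 1))
  # separated groups: exact two-sided p = 0.1 (enumeration oracle)
  cmp <- profile_group_compare(mk(c(1, 2, 3)), mk(c(4, 5, 6)))
  expect_equal(unique(cmp$p_value), 0.1)
  expect_equal(oracle_wilcox_p(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(unique(cmp$mean_a), 2)
  bad <- mk(c(1, 2)); bad$distance_um <- bad$distance_um + 0.1
  expect_error(profile_group_compare(mk(c(1, 2)), bad), "grid")
})

test_that("rank-sum implementation matches exhaustive enumeration (n <= 6)", {
  set.seed(21)
  for (rep in 1:30) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    v <- sample(1:100, n1 + n2)   # distinct -> no ties
    x <- v[seq_len(n1)]; y <- v[-seq_len(n1)]
    expect_equal(sheathrna:::wilcox_p(x, y), oracle_wilcox_p(x, y),
                 tolerance = 1e-12)
  }
})

test_that("terminal enrichment calls and proportions follow the counts", {
  prof <- tibble::tibble(distance_um = seq(0, 7, 0.2), value = 1)
  prof$value[prof$distance_um <= 2] <- 1.4
  expect_true(terminal_enrichment_call(prof))
  flat <- tibble::tibble(distance_um = seq(0, 7, 0.2), value = 1)
  expect_false(terminal_enrichment_call(flat))
  expect_error(terminal_enrichment_call(prof, terminal_window_um = 7), "smaller")

  counts <- readr::read_tsv(system.file("extdata", "sheath_enrichment_counts.tsv",
                                        package = "sheathrna"),
                            show_col_types = FALSE)
  mbpa <- counts[counts$group == "mbpa", ]
  sv40 <- counts[counts$group == "sv40", ]
  flags_mbpa <- rep(c(TRUE, FALSE), c(mbpa$n_enriched,
                                      mbpa$n_sheaths - mbpa$n_enriched))
  expect_equal(summarize_enrichment(flags_mbpa)$percent, 47)
  expect_equal(proportion_percent(sv40$n_enriched, sv40$n_sheaths, 1), 28.6)
  expect_equal(summarize_enrichment(rep(FALSE, 12))$percent, 0)
})

test_that("cell-body intensities average three 3x3 ROIs and normalize to control", {
  img <- matrix(0, 30, 30)
  img[4:6, 4:6] <- 10; img[14:16, 14:16] <- 20; img[24:26, 24:26] <- 30
  centers <- tibble::tibble(row = c(5, 15, 25), col = c(5, 15, 25))
  expect_equal(cell_body_intensity(img, centers), 20)
  cst <- matrix(7.5, 10, 10)
  expect_equal(cell_body_intensity(cst, tibble::tibble(row = c(2, 5, 8),
                                                       col = c(2, 5, 8))), 7.5)
  expect_error(cell_body_intensity(img, tibble::tibble(row = c(1, 5, 25),
                                                       col = c(1, 5, 25))),
               "bounds")
  ctrl <- c(0.8, 1.0, 1.2)
  expect_equal(mean(normalize_to_control(ctrl, ctrl)), 1)
  expect_equal(normalize_to_control(c(2, 4), c(1, 3)), c(1, 2))
})

test_that("density-length correlation is Spearman with permutation p", {
  up <- tibble::tibble(length_um = 1:6, density = c(2, 4, 6, 8, 10, 12))
  expect_equal(density_length_correlation(up)$rho, 1)
  down <- tibble::tibble(length_um = 1:6, density = 6:1)
  expect_equal(density_length_correlation(down)$rho, -1)
  # five points with one inversion: closed-form rank oracle 1 - 6*sum(d^2)/(n(n^2-1))
  m <- tibble::tibble(length_um = 1:5, density = c(1, 2, 4, 3, 5))
  r <- density_length_correlation(m)
  d2 <- sum((rank(m$length_um) - rank(m$density))^2)
  expect_equal(r$rho, 1 - 6 * d2 / (5 * 24))
  expect_identical(r$method, "exact permutation")
  flatv <- tibble::tibble(length_um = 1:5, density = rep(3, 5))
  expect_identical(density_length_correlation(flatv)$method, "undefined")
  expect_error(density_length_correlation(m[1:2, ]), "at least 3")
})
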