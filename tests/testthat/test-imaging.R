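test_that("max projection matches an elementwise loop oracle", {
  set.seed(1)
  a <- array(runif(6 * 5 * 5), dim = c(6, 5, 5))
  st <- image_stack(list(ch = a), pixel_size_um = 0.1)
  expect_equal(max_project(st, z_range = 3), a[, , 3])
  two <- max_project(st, z_range = c(1, 2))
  expect_equal(two[2, 3], max(a[2, 3, 1], a[2, 3, 2]))
  full <- max_project(st)
  oracle <- matrix(0, 6, 5)
  for (i in 1:6) for (j in 1:5) oracle[i, j] <- max(a[i, j, ])
  expect_equal(full, oracle)
  expect_error(max_project(st, z_range = integer(0)), "empty")
  expect_error(max_project(st, z_range = 9), "outside")
})

test_that("rolling-ball subtraction equals the ball-opening brute force", {
  # constant image -> background equals image -> all zeros
  cst <- matrix(7, 10, 10)
  expect_equal(subtract_background(cst, 2.5), matrix(0, 10, 10))

  # ramp plus one bright spike, radius 2.5
  img <- outer(1:16, 1:16, function(i, j) i + 0.5 * j)
  img[8, 9] <- img[8, 9] + 40
  expect_equal(ball_opening(img, 2.5), oracle_ball_opening(img, 2.5))

  # random images: oracle equivalence plus 0 <= out <= input
  set.seed(42)
  for (n in c(16, 24)) {
    im <- matrix(runif(n * n, 0, 100), n, n)
    sub <- subtract_background(im, 2.5)
    expect_equal(im - sub, pmin(oracle_ball_opening(im, 2.5), im))
    expect_true(all(sub >= 0) && all(sub <= im))
  }
})

test_that("SD thresholding uses the sample SD with a strict inequality", {
  expect_false(any(threshold_mask(matrix(5, 8, 8), 3)))
  img <- matrix(10, 10, 10); img[4, 7] <- 200
  m <- mean(img); s <- sd(as.vector(img))
  expect_equal(m, 11.9); expect_equal(s, 19, tolerance = 1e-2)
  mask <- threshold_mask(img, 3)
  expect_identical(which(mask), which(img == 200))
  # k = 0: strictly above the mean
  img2 <- matrix(c(1, 2, 3, 4), 2, 2)
  expect_equal(threshold_mask(img2, 0), img2 > 2.5)
  expect_error(threshold_mask(img, -1), "nonnegative")
})

test_that("particle analysis measures components like a per-component loop", {
  px <- 0.1
  # empty mask
  expect_identical(nrow(detect_puncta(matrix(FALSE, 5, 5), matrix(0, 5, 5), px)), 0L)
  # one single-pixel punctum: IntDen = intensity * pixel area
  mask <- matrix(FALSE, 6, 6); mask[3, 4] <- TRUE
  inten <- matrix(0, 6, 6); inten[3, 4] <- 40
  p <- detect_puncta(mask, inten, px)
  expect_identical(nrow(p), 1L)
  expect_equal(p$integrated_density, 40 * px^2)
  expect_equal(p$area_um2 * p$mean_intensity, p$integrated_density)

  # diagonal pixels are one 8-connected component
  dmask <- matrix(FALSE, 5, 5); dmask[2, 2] <- TRUE; dmask[3, 3] <- TRUE
  pd <- detect_puncta(dmask, matrix(1, 5, 5), px, area_min_um2 = 0)
  expect_identical(nrow(pd), 1L)
  expect_identical(pd$n_pixels, 2L)

  # two rectangles over a known intensity array vs direct loop oracle
  mask2 <- matrix(FALSE, 12, 12)
  mask2[2:4, 2:5] <- TRUE; mask2[8:9, 7:10] <- TRUE
  set.seed(3); inten2 <- matrix(runif(144, 10, 50), 12, 12)
  p2 <- detect_puncta(mask2, inten2, px, area_min_um2 = 0)
  expect_identical(nrow(p2), 2L)
  for (blk in list(list(r = 2:4, c = 2:5), list(r = 8:9, c = 7:10))) {
    vals <- inten2[blk$r, blk$c]
    npx <- length(vals)
    row <- p2[p2$n_pixels == npx, ]
    expect_equal(row$area_um2, npx * px^2)
    expect_equal(row$mean_intensity, mean(vals))
    expect_equal(row$integrated_density, npx * px^2 * mean(vals))
  }
  expect_error(detect_puncta(mask2, inten2), "calibration")
})

test_that("ROI density excludes border-touching puncta", {
  mask <- matrix(FALSE, 20, 20)
  mask[5:6, 5:6] <- TRUE      # interior
  mask[10:11, 10:11] <- TRUE  # interior
  mask[14:16, 14:16] <- TRUE  # straddles ROI edge at 15
  inten <- matrix(0, 20, 20)
  inten[5:6, 5:6] <- 30; inten[10:11, 10:11] <- 45; inten[14:16, 14:16] <- 10
  p <- detect_puncta(mask, inten, 0.1, area_min_um2 = 0)
  roi <- list(row = c(2, 15), col = c(2, 15))
  res <- roi_puncta_density(p, roi)
  expect_identical(res$n_puncta, 2L)
  expect_equal(res$mean_integrated_density,
               mean(c(4 * 0.01 * 30, 4 * 0.01 * 45)))
  expect_false(res$empty)
  # no puncta at all -> defined empty result
  res0 <- roi_puncta_density(p[0, ], roi)
  expect_true(res0$empty); expect_identical(res0$n_puncta, 0L)
  expect_error(roi_puncta_density(p, list(row = c(5, 5), col = c(1, 2))),
               "roi")
})

test_that("spot calling on synthetic stacks recovers ground truth", {
  ds <- sim_image_stack(n_sheaths = 4, n_spots_per_sheath = 5,
                        spot_amplitude = 300, poisson_noise = FALSE,
                        read_noise_sd = 0, min_spot_sep_um = 0.8, seed = 7)
  proj <- max_project(ds$stack, "mrna")
  p <- detect_puncta(threshold_mask(subtract_background(proj), 3),
                     proj, ds$stack$pixel_size_um)
  # noiseless, bright: perfect precision and recall
  expect_identical(nrow(p), nrow(ds$truth))
  dmat <- outer(ds$truth$x_um, p$centroid_x_um, "-")^2 +
    outer(ds$truth$y_um, p$centroid_y_um, "-")^2
  expect_true(all(sqrt(apply(dmat, 1, min)) < 0.3))
})
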