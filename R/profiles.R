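#' Extract a fluorescence line profile along a sheath
#'
#' Samples the image by bilinear interpolation (1-px line width) at
#' `scan_step_um` spacing along a polyline that starts at the sheath
#' terminus, over a fixed `scan_length_um` grid — so distance 0 is the
#' terminus. Pixel `(i, j)` is centered at `x = (j - 1) * pixel_size_um`,
#' `y = (i - 1) * pixel_size_um`.
#'
#' Paths must be at least `scan_length_um - tol_um` long; a path slightly
#' shorter than the scan length (within tolerance) has its tail samples
#' clamped to the path end so the grid always has
#' `scan_length_um / scan_step_um + 1` samples.
#'
#' @param image 2D matrix.
#' @param path Tibble/data frame of polyline vertices `x_um`, `y_um`,
#'   ordered from the terminus.
#' @param pixel_size_um Calibration.
#' @param scan_length_um,scan_step_um,tol_um Scan geometry (defaults 7.0,
#'   0.2, 0.3 um).
#' @return A `line_profile` tibble: `distance_um`, `value` (raw intensity),
#'   with attribute `normalized = FALSE`.
#' @export
extract_line_profile <- function(image, path, pixel_size_um,
                                 scan_length_um = 7, scan_step_um = 0.2,
                                 tol_um = 0.3) {
  if (!is.matrix(image)) abort("`image` must be a 2D matrix.")
  stopifnot(all(c("x_um", "y_um") %in% names(path)), nrow(path) >= 2)
  check_scalar(pixel_size_um, "pixel_size_um", lower = 0, strict = TRUE)
  nseg <- nrow(path) - 1
  seg_len <- sqrt(diff(path$x_um)^2 + diff(path$y_um)^2)
  total <- sum(seg_len)
  if (total < scan_length_um - tol_um) {
    abort(sprintf("Path length %.2f um shorter than %.2f - %.2f um.",
                  total, scan_length_um, tol_um))
  }
  d <- seq(0, scan_length_um, by = scan_step_um)
  d_clamped <- pmin(d, total)
  cum <- c(0, cumsum(seg_len))
  seg <- findInterval(d_clamped, cum, rightmost.closed = TRUE)
  seg <- pmin(pmax(seg, 1L), nseg)
  t_ <- (d_clamped - cum[seg]) / seg_len[seg]
  px <- path$x_um[seg] + t_ * diff(path$x_um)[seg]
  py <- path$y_um[seg] + t_ * diff(path$y_um)[seg]
  vals <- bilinear_sample(image, px / pixel_size_um + 1, py / pixel_size_um + 1)
  structure(tibble(distance_um = d, value = vals),
            class = c("line_profile", "tbl_df", "tbl", "data.frame"),
            normalized = FALSE)
}

# Bilinear interpolation at fractional (col, row) = (x, y) positions,
# clamped to the image.
bilinear_sample <- function(image, x, y) {
  nr <- nrow(image); nc <- ncol(image)
  x <- pmin(pmax(x, 1), nc); y <- pmin(pmax(y, 1), nr)
  x0 <- pmin(floor(x), nc - 1); y0 <- pmin(floor(y), nr - 1)
  if (nc == 1) x0 <- rep(1, length(x))
  if (nr == 1) y0 <- rep(1, length(y))
  fx <- x - x0; fy <- y - y0
  x1 <- pmin(x0 + 1, nc); y1 <- pmin(y0 + 1, nr)
  image[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
    image[cbind(y0, x1)] * fx * (1 - fy) +
    image[cbind(y1, x0)] * (1 - fx) * fy +
    image[cbind(y1, x1)] * fx * fy
}

#' Normalize a line profile to its own mean
#'
#' Divides each raw value by the profile mean, so the normalized profile has
#' mean exactly 1 — the per-sheath normalization applied before averaging
#' profiles across sheaths.
#'
#' @param profile A `line_profile` (or tibble with `distance_um`, `value`).
#' @return A `line_profile` with normalized `value` and attribute
#'   `normalized = TRUE`.
#' @export
normalize_profile <- function(profile) {
  stopifnot(all(c("distance_um", "value") %in% names(profile)))
  m <- mean(profile$value)
  if (!is.finite(m) || m <= 0) abort("Profile mean must be positive to normalize.")
  structure(tibble(distance_um = profile$distance_um,
                   value = profile$value / m),
            class = c("line_profile", "tbl_df", "tbl", "data.frame"),
            normalized = TRUE)
}

# Two-sided Wilcoxon rank-sum p-value with the conventions used for
# per-distance profile comparison: exact enumeration when min(n) <= 8 and
# there are no ties; otherwise the normal approximation with tie correction
# (no continuity correction), with z = 0 giving p = 1.
wilcox_p <- function(x, y) {
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && min(length(x), length(y)) <= 8
  p <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = FALSE)$p.value)
  if (is.na(p)) 1 else p   # degenerate z = 0 (e.g. all values tied)
}

#' Compare two groups of line profiles distance by distance
#'
#' At each grid distance, reports the group means, 95 percent t confidence
#' intervals of the mean, and the two-sided Wilcoxon rank-sum p-value
#' (exact when the smaller group has at most 8 profiles and values are
#' untied; normal approximation with tie correction otherwise).
#'
#' @param group_a,group_b Long tibbles of (typically normalized) profiles
#'   with columns `sheath_id`, `distance_um`, `value`; both groups must share
#'   the distance grid.
#' @return Tibble: `distance_um`, `mean_a`, `ci_lo_a`, `ci_hi_a`, `mean_b`,
#'   `ci_lo_b`, `ci_hi_b`, `p_value`.
#' @export
profile_group_compare <- function(group_a, group_b) {
  need <- c("sheath_id", "distance_um", "value")
  stopifnot(all(need %in% names(group_a)), all(need %in% names(group_b)))
  da <- sort(unique(group_a$distance_um)); db <- sort(unique(group_b$distance_um))
  if (length(da) != length(db) || any(abs(da - db) > 1e-9)) {
    abort("Groups must share the same distance grid.")
  }
  ci <- function(v) {
    m <- mean(v)
    if (length(v) < 2 || sd(v) == 0) return(c(m, m, m))
    half <- qt(0.975, length(v) - 1) * sd(v) / sqrt(length(v))
    c(m, m - half, m + half)
  }
  purrr::map_dfr(da, function(d) {
    va <- group_a$value[abs(group_a$distance_um - d) < 1e-9]
    vb <- group_b$value[abs(group_b$distance_um - d) < 1e-9]
    ca <- ci(va); cb <- ci(vb)
    tibble(distance_um = d,
           mean_a = ca[1], ci_lo_a = ca[2], ci_hi_a = ca[3],
           mean_b = cb[1], ci_lo_b = cb[2], ci_hi_b = cb[3],
           p_value = wilcox_p(va, vb))
  })
}

#' Call terminal enrichment of a normalized profile
#'
#' A sheath is terminally enriched when the mean normalized intensity within
#' `terminal_window_um` of the terminus strictly exceeds the mean over the
#' rest of the scan by more than `margin` (default 0).
#'
#' @param profile Normalized `line_profile`.
#' @param terminal_window_um Distal window (default 2 um); must be smaller
#'   than the scan length.
#' @param margin Required excess (default 0, strict `>`).
#' @return Logical flag.
#' @export
terminal_enrichment_call <- function(profile, terminal_window_um = 2,
                                     margin = 0) {
  stopifnot(all(c("distance_um", "value") %in% names(profile)))
  scan_len <- max(profile$distance_um)
  if (terminal_window_um >= scan_len) {
    abort("`terminal_window_um` must be smaller than the scan length.")
  }
  near <- profile$value[profile$distance_um <= terminal_window_um]
  far <- profile$value[profile$distance_um > terminal_window_um]
  mean(near) > mean(far) + margin
}

#' @rdname terminal_enrichment_call
#' @param flags Logical vector of per-sheath enrichment calls.
#' @param digits Rounding for the percentage (default 0, integer percent).
#' @return `summarize_enrichment()`: one-row tibble `n_enriched`, `n_sheaths`,
#'   `percent`.
#' @export
summarize_enrichment <- function(flags, digits = 0) {
  stopifnot(is.logical(flags), length(flags) > 0)
  tibble(n_enriched = sum(flags), n_sheaths = length(flags),
         percent = proportion_percent(sum(flags), length(flags), digits))
}

#' Cell-body reporter intensity from three small ROIs
#'
#' The per-cell value is the mean of three 3x3-pixel ROI means placed at the
#' cell periphery, cell center, and in between. `normalize_to_control()`
#' divides each value by the mean of the control group, so the control group
#' normalized by itself has mean exactly 1.
#'
#' @param image 2D matrix.
#' @param roi_centers Data frame of exactly three ROI centers per cell:
#'   columns `row`, `col` (pixel indices).
#' @param roi_half_width Half width of the square ROI (default 1 → 3x3 px).
#' @return Per-cell mean intensity (scalar).
#' @export
cell_body_intensity <- function(image, roi_centers, roi_half_width = 1) {
  stopifnot(is.matrix(image), all(c("row", "col") %in% names(roi_centers)))
  if (nrow(roi_centers) != 3) abort("Exactly three ROI centers per cell.")
  h <- roi_half_width
  means <- vapply(seq_len(3), function(k) {
    r <- roi_centers$row[k]; cc <- roi_centers$col[k]
    if (r - h < 1 || r + h > nrow(image) || cc - h < 1 || cc + h > ncol(image)) {
      abort("ROI out of image bounds.")
    }
    mean(image[(r - h):(r + h), (cc - h):(cc + h)])
  }, numeric(1))
  mean(means)
}

#' @rdname cell_body_intensity
#' @param values,control_values Numeric vectors of per-cell values.
#' @export
normalize_to_control <- function(values, control_values) {
  m <- mean(control_values)
  if (!is.finite(m) || m <= 0) abort("Control mean must be positive.")
  values / m
}

#' Spearman correlation of puncta density with sheath length
#'
#' Spearman's rho with average ranks for ties, and a permutation p-value:
#' exact over all permutations for n <= 8, seeded Monte Carlo otherwise.
#'
#' @param measurements Tibble with columns `length_um` and `density`.
#' @param n_perm Monte Carlo permutations when n > 8 (default 10000).
#' @param seed Seed for the Monte Carlo permutations.
#' @return One-row tibble: `rho`, `p_value`, `n`, `method`; `rho` is `NA`
#'   (with `method = "undefined"`) when either variable is constant.
#' @export
density_length_correlation <- function(measurements, n_perm = 10000, seed = 1) {
  stopifnot(all(c("length_um", "density") %in% names(measurements)))
  x <- measurements$length_um; y <- measurements$density
  n <- length(x)
  if (n < 3) abort("Need at least 3 sheaths.")
  if (sd(x) == 0 || sd(y) == 0) {
    return(tibble(rho = NA_real_, p_value = NA_real_, n = n,
                  method = "undefined"))
  }
  rho <- cor(x, y, method = "spearman")
  rx <- rank(x)
  ry <- rank(y)
  if (n <= 8) {
    perms <- all_permutations(n)
    rhos <- apply(perms, 1, function(p) cor(rx, ry[p]))
    p_val <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    set.seed(derive_seed(seed, "spearman"))
    rhos <- vapply(seq_len(n_perm), function(i) cor(rx, sample(ry)),
                   numeric(1))
    p_val <- (sum(abs(rhos) >= abs(rho) - 1e-12) + 1) / (n_perm + 1)
    method <- "monte carlo"
  }
  tibble(rho = rho, p_value = p_val, n = n, method = method)
}

# All permutations of 1..n as a matrix (n! rows); n is small (<= 8).
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}
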