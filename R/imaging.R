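#' Maximum z-projection
#'
#' Pixelwise maximum over a range of slices of one channel.
#'
#' @param stack An [image_stack].
#' @param channel Channel name or index (default first channel).
#' @param z_range Integer slice indices (default all slices).
#' @return A 2D matrix.
#' @export
max_project <- function(stack, channel = 1, z_range = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  a <- stack$channels[[channel]]
  nz <- dim(a)[3]
  z_range <- z_range %||% seq_len(nz)
  if (length(z_range) == 0) abort("`z_range` is empty.")
  if (any(z_range < 1 | z_range > nz)) abort("`z_range` outside the stack.")
  apply(a[, , z_range, drop = FALSE], c(1, 2), max)
}

# Ball (sphere-cap) structuring element offsets and heights for radius r px.
ball_element <- function(radius) {
  r <- ceiling(radius)
  off <- expand.grid(dy = -r:r, dx = -r:r)
  keep <- off$dy^2 + off$dx^2 <= radius^2
  off <- off[keep, , drop = FALSE]
  off$h <- sqrt(radius^2 - off$dy^2 - off$dx^2)
  off
}

# Shift a matrix by (dy, dx) with edge replication.
shift_replicate <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) + dy, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dx, 1L), nc)
  m[ri, ci, drop = FALSE]
}

#' Rolling-ball background subtraction
#'
#' Estimates the background as the grayscale opening of the image by a
#' ball-shaped (sphere-cap) structuring element of the given radius —
#' erosion `min(I(p+o) - h(o))` followed by dilation `max(E(p-o) + h(o))`
#' with `h(o) = sqrt(r^2 - |o|^2)` and edge replication at the borders — and
#' returns `image - background`, clipped at 0. The radius is in pixels.
#'
#' @param image 2D numeric matrix.
#' @param radius Ball radius in pixels (default 2.5).
#' @return Matrix of the same size, `0 <= out <= image`.
#' @export
subtract_background <- function(image, radius = 2.5) {
  if (!is.matrix(image)) abort("`image` must be a 2D matrix.")
  check_scalar(radius, "radius", lower = 0, strict = TRUE)
  bg <- ball_opening(image, radius)
  pmax(image - bg, 0)
}

#' @rdname subtract_background
#' @details `ball_opening()` returns the background estimate itself.
#' @export
ball_opening <- function(image, radius = 2.5) {
  if (!is.matrix(image)) abort("`image` must be a 2D matrix.")
  el <- ball_element(radius)
  ero <- NULL
  for (i in seq_len(nrow(el))) {
    cand <- shift_replicate(image, el$dy[i], el$dx[i]) - el$h[i]
    ero <- if (is.null(ero)) cand else pmin(ero, cand)
  }
  dil <- NULL
  for (i in seq_len(nrow(el))) {
    cand <- shift_replicate(ero, -el$dy[i], -el$dx[i]) + el$h[i]
    dil <- if (is.null(dil)) cand else pmax(dil, cand)
  }
  dil
}

#' Threshold an image at k standard deviations above the mean
#'
#' `mask = image > mean(image) + k * sd(image)` with the sample SD (n - 1)
#' and a strict inequality, so a constant image yields an empty mask.
#'
#' @param image 2D numeric matrix (nonempty).
#' @param k SD multiplier (default 3; must be >= 0).
#' @return Logical matrix.
#' @export
threshold_mask <- function(image, k = 3) {
  if (!is.matrix(image) || length(image) == 0) abort("`image` must be a nonempty matrix.")
  if (k < 0) abort("`k` must be nonnegative.")
  image > mean(image) + k * sd(as.vector(image))
}

# 8-connected labeling of a logical mask (two-pass union-find).
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  parent <- integer(0)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  nxt <- 0L
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      if (!mask[i, j]) next
      nb <- integer(0)
      if (i > 1 && mask[i - 1, j]) nb <- c(nb, lab[i - 1, j])
      if (j > 1) {
        if (mask[i, j - 1]) nb <- c(nb, lab[i, j - 1])
        if (i > 1 && mask[i - 1, j - 1]) nb <- c(nb, lab[i - 1, j - 1])
        if (i < nr && mask[i + 1, j - 1]) nb <- c(nb, lab[i + 1, j - 1])
      }
      if (!length(nb)) {
        nxt <- nxt + 1L
        parent[nxt] <- nxt
        lab[i, j] <- nxt
      } else {
        roots <- vapply(unique(nb), find, integer(1))
        r0 <- min(roots)
        lab[i, j] <- r0
        for (r in roots) parent[r] <- r0
      }
    }
  }
  if (nxt > 0) {
    roots <- vapply(seq_len(nxt), find, integer(1))
    relab <- match(roots, sort(unique(roots)))
    pos <- which(lab > 0)
    lab[pos] <- relab[lab[pos]]
  }
  lab
}

# Perimeter of a labeled component by boundary-segment counting: the number
# of pixel edges between a component pixel and a non-component pixel (or the
# image border).
component_perimeter <- function(lab, id) {
  inside <- lab == id
  nr <- nrow(inside); nc <- ncol(inside)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- inside
  core <- pad[2:(nr + 1), 2:(nc + 1)]
  sum(core & !pad[1:nr, 2:(nc + 1)]) + sum(core & !pad[3:(nr + 2), 2:(nc + 1)]) +
    sum(core & !pad[2:(nr + 1), 1:nc]) + sum(core & !pad[2:(nr + 1), 3:(nc + 2)])
}

#' Particle analysis: detect puncta in a thresholded mask
#'
#' Labels 8-connected components of the mask, filters them by calibrated
#' area and circularity, and measures each surviving punctum on the
#' intensity image: area (um^2), mean intensity, and integrated density
#' (area x mean intensity, calibrated).
#'
#' Circularity is `4 * pi * A / P^2` with `A`, `P` in pixel units and the
#' perimeter counted as exposed pixel edges, clamped to at most 1.
#'
#' @param mask Logical matrix (from [threshold_mask()]).
#' @param intensity_image Numeric matrix congruent with `mask`.
#' @param pixel_size_um Pixel size in um (required for calibrated areas).
#' @param area_min_um2,area_max_um2 Area filter in um^2 (defaults 0.01, Inf).
#' @param circularity_range Allowed circularity interval (default `c(0, 1)`).
#' @return Tibble of puncta: `label`, `n_pixels`, `area_um2`,
#'   `mean_intensity`, `integrated_density`, `centroid_x_um`,
#'   `centroid_y_um`.
#' @export
detect_puncta <- function(mask, intensity_image, pixel_size_um,
                          area_min_um2 = 0.01, area_max_um2 = Inf,
                          circularity_range = c(0, 1)) {
  if (!is.matrix(mask) || !is.logical(mask)) abort("`mask` must be a logical matrix.")
  if (!is.matrix(intensity_image) || !all(dim(mask) == dim(intensity_image))) {
    abort("`intensity_image` must be a matrix congruent with `mask`.")
  }
  if (missing(pixel_size_um)) abort("`pixel_size_um` calibration is required.")
  check_scalar(pixel_size_um, "pixel_size_um", lower = 0, strict = TRUE)
  lab <- label_components(mask)
  n <- max(lab)
  empty <- tibble(label = integer(), n_pixels = integer(), area_um2 = numeric(),
                  mean_intensity = numeric(), integrated_density = numeric(),
                  centroid_x_um = numeric(), centroid_y_um = numeric())
  if (n == 0) return(empty)
  px_area <- pixel_size_um^2
  rows <- lapply(seq_len(n), function(id) {
    idx <- which(lab == id, arr.ind = TRUE)
    npx <- nrow(idx)
    area <- npx * px_area
    if (area < area_min_um2 || area > area_max_um2) return(NULL)
    perim <- component_perimeter(lab, id)
    circ <- min(4 * pi * npx / perim^2, 1)
    if (circ < circularity_range[1] || circ > circularity_range[2]) return(NULL)
    vals <- intensity_image[idx]
    tibble(label = id, n_pixels = npx, area_um2 = area,
           mean_intensity = mean(vals),
           integrated_density = area * mean(vals),
           centroid_x_um = (mean(idx[, 2]) - 1) * pixel_size_um,
           centroid_y_um = (mean(idx[, 1]) - 1) * pixel_size_um)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) empty else
    mutate(out, pixels = purrr::map(.data$label, ~ which(lab == .x, arr.ind = TRUE)))
}

#' Mean puncta density within an ROI
#'
#' Restricts puncta to a rectangular ROI, excludes any punctum whose pixel
#' set touches the ROI border (the border-exclusion rule of particle
#' counting within hand-drawn ROIs), and returns the mean integrated density
#' of the remainder.
#'
#' @param puncta Tibble from [detect_puncta()] (needs the `pixels` column).
#' @param roi Rectangle `list(row = c(r0, r1), col = c(c0, c1))` in pixel
#'   indices (inclusive).
#' @return One-row tibble: `n_puncta`, `mean_integrated_density`, `empty`
#'   (`TRUE` when no punctum remains; the mean is then `NA`).
#' @export
roi_puncta_density <- function(puncta, roi) {
  if (!is.list(roi) || !all(c("row", "col") %in% names(roi)) ||
      roi$row[1] >= roi$row[2] || roi$col[1] >= roi$col[2]) {
    abort("`roi` must be list(row = c(r0, r1), col = c(c0, c1)) with r0 < r1, c0 < c1.")
  }
  if (nrow(puncta) == 0) {
    return(tibble(n_puncta = 0L, mean_integrated_density = NA_real_,
                  empty = TRUE))
  }
  status <- vapply(puncta$pixels, function(px) {
    r <- px[, 1]; cc <- px[, 2]
    inside <- r >= roi$row[1] & r <= roi$row[2] &
      cc >= roi$col[1] & cc <= roi$col[2]
    if (!any(inside)) return("outside")
    on_border <- r == roi$row[1] | r == roi$row[2] |
      cc == roi$col[1] | cc == roi$col[2]
    if (any(inside & on_border) || !all(inside)) "border" else "interior"
  }, character(1))
  keep <- puncta[status == "interior", , drop = FALSE]
  tibble(n_puncta = nrow(keep),
         mean_integrated_density = if (nrow(keep)) mean(keep$integrated_density)
                                   else NA_real_,
         empty = nrow(keep) == 0)
}
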