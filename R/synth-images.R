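#' Simulate a two-channel fluorescence stack of myelin sheaths
#'
#' Renders elongated sheath structures (membrane channel) with
#' diffraction-limited mRNA puncta (mRNA channel) over a smooth background,
#' with a standard fluorescence camera noise model
#' (Poisson shot noise on the signal plus Gaussian read noise), and returns
#' exact ground truth for every rendered spot plus the sheath skeleton
#' polylines needed for line-scan analysis.
#'
#' Sheaths are horizontal capsules at distinct rows; the *terminus* of each
#' sheath is its left end, and skeleton vertices are ordered from the
#' terminus. Spots are isotropic 3D Gaussians in physical units sampled onto
#' the voxel grid; a `terminal_bias` fraction of each sheath's spots is
#' forced into the distal `terminal_window_um` of the sheath.
#'
#' @param shape Voxel counts, named or ordered `(z, y, x)` (default
#'   `c(13, 96, 96)`).
#' @param pixel_size_um,z_step_um Calibration (defaults 0.1 and 0.3 um).
#' @param n_sheaths Number of sheaths.
#' @param sheath_length_range_um Length range in um (default 7-9).
#' @param n_spots_per_sheath Spots rendered per sheath.
#' @param spot_sigma_um Gaussian PSF sigma (default 0.15 um).
#' @param spot_amplitude Peak spot intensity in photons (default 150).
#' @param terminal_bias Fraction of spots forced into the distal window
#'   (default 0 = uniform along the sheath).
#' @param terminal_window_um Distal window length (default 2 um).
#' @param background Background `c(low, high)`: constant `low` plus a linear
#'   gradient rising to `high` across x (mRNA channel).
#' @param membrane_amplitude,membrane_sigma_um Membrane tube intensity/width.
#' @param poisson_noise Apply Poisson shot noise (default `TRUE`).
#' @param read_noise_sd Gaussian read noise SD (default 2; 0 disables).
#' @param min_spot_sep_um Optional minimum lateral (x, y) spot separation
#'   enforced by rejection sampling (default 0 = off), so spots stay
#'   resolvable in a maximum projection.
#' @param seed Integer seed; identical arguments give identical output.
#' @return List with `stack` (an `image_stack`: channels `mrna`, `membrane`,
#'   each a `[y, x, z]` array, plus calibration), `truth` (tibble of spots:
#'   `sheath_id`, `x_um`, `y_um`, `z_um`, `amplitude`) and `sheaths`
#'   (tibble of skeleton vertices: `sheath_id`, `vertex`, `x_um`, `y_um`,
#'   `z_um`, `length_um`; vertex 1 = terminus).
#' @export
sim_image_stack <- function(shape = c(z = 13, y = 96, x = 96),
                            pixel_size_um = 0.1, z_step_um = 0.3,
                            n_sheaths = 4, sheath_length_range_um = c(7, 9),
                            n_spots_per_sheath = 8, spot_sigma_um = 0.15,
                            spot_amplitude = 150, terminal_bias = 0,
                            terminal_window_um = 2,
                            background = c(low = 10, high = 20),
                            membrane_amplitude = 80, membrane_sigma_um = 0.25,
                            poisson_noise = TRUE, read_noise_sd = 2,
                            min_spot_sep_um = 0, seed = 1) {
  if (any(shape <= 0) || length(shape) != 3) abort("`shape` must be 3 positive counts.")
  check_scalar(pixel_size_um, "pixel_size_um", lower = 0, strict = TRUE)
  check_scalar(z_step_um, "z_step_um", lower = 0, strict = TRUE)
  check_scalar(terminal_bias, "terminal_bias", lower = 0, upper = 1)
  check_scalar(n_spots_per_sheath, "n_spots_per_sheath", lower = 0)
  check_scalar(read_noise_sd, "read_noise_sd", lower = 0)
  nz <- shape[[1]]; ny <- shape[[2]]; nx <- shape[[3]]
  set.seed(derive_seed(seed, "images"))
  xs <- (seq_len(nx) - 1) * pixel_size_um
  ys <- (seq_len(ny) - 1) * pixel_size_um
  zs <- (seq_len(nz) - 1) * z_step_um
  fov_x <- xs[nx]; fov_y <- ys[ny]

  # background gradient along x (mRNA channel); constant floor for membrane
  grad <- background[[1]] + (background[[2]] - background[[1]]) *
    (if (nx > 1) (seq_len(nx) - 1) / (nx - 1) else 0)
  mrna <- array(rep(rep(grad, each = ny), nz), dim = c(ny, nx, nz))
  memb <- array(background[[1]], dim = c(ny, nx, nz))

  # sheath geometry: horizontal capsules at well-separated rows
  lens <- runif(n_sheaths, sheath_length_range_um[1], sheath_length_range_um[2])
  lens <- pmin(lens, fov_x - 2 * pixel_size_um)
  y0 <- (seq_len(n_sheaths) - 0.5) / n_sheaths * fov_y +
    runif(n_sheaths, -0.02, 0.02) * fov_y
  y0 <- pmin(pmax(y0, 0), fov_y)
  x0 <- runif(n_sheaths, 0, fov_x - lens)
  z0 <- zs[pmin(nz, pmax(1, round(nz / 2 + runif(n_sheaths, -1, 1))))]

  sheaths <- tibble(
    sheath_id = rep(seq_len(n_sheaths), each = 2),
    vertex = rep(1:2, n_sheaths),
    x_um = as.vector(rbind(x0, x0 + lens)),
    y_um = rep(y0, each = 2),
    z_um = rep(z0, each = 2),
    length_um = rep(lens, each = 2))

  # membrane tube
  for (s in seq_len(n_sheaths)) {
    dx <- pmax(x0[s] - xs, xs - (x0[s] + lens[s]), 0)
    dy <- ys - y0[s]
    d2 <- outer(dy^2, dx^2, "+")
    lat <- membrane_amplitude * exp(-d2 / (2 * membrane_sigma_um^2))
    gz <- exp(-(zs - z0[s])^2 / (2 * (2 * membrane_sigma_um)^2))
    for (k in seq_len(nz)) memb[, , k] <- memb[, , k] + lat * gz[k]
  }

  # spot placement
  spots <- list()
  placed <- matrix(numeric(0), ncol = 3)
  n_spots <- round(n_spots_per_sheath)
  for (s in seq_len(n_sheaths)) {
    for (j in seq_len(n_spots)) {
      for (try in 1:200) {
        d <- if (runif(1) < terminal_bias) {
          runif(1, 0, min(terminal_window_um, lens[s]))
        } else runif(1, 0, lens[s])
        sx <- x0[s] + d
        sy <- y0[s] + runif(1, -0.5, 0.5) * pixel_size_um
        sz <- z0[s]
        if (min_spot_sep_um <= 0 || nrow(placed) == 0 ||
            min(sqrt((placed[, 1] - sx)^2 + (placed[, 2] - sy)^2)) >
              min_spot_sep_um) break
      }
      placed <- rbind(placed, c(sx, sy, sz))
      spots[[length(spots) + 1L]] <- tibble(
        sheath_id = s, x_um = sx, y_um = sy, z_um = sz,
        amplitude = spot_amplitude)
    }
  }
  truth <- if (length(spots)) bind_rows(spots) else
    tibble(sheath_id = integer(), x_um = numeric(), y_um = numeric(),
           z_um = numeric(), amplitude = numeric())

  # render spots as isotropic 3D Gaussians (local 4-sigma windows)
  for (r in seq_len(nrow(truth))) {
    sx <- truth$x_um[r]; sy <- truth$y_um[r]; sz <- truth$z_um[r]
    ix <- which(abs(xs - sx) <= 4 * spot_sigma_um)
    iy <- which(abs(ys - sy) <= 4 * spot_sigma_um)
    iz <- which(abs(zs - sz) <= 4 * spot_sigma_um)
    if (!length(ix) || !length(iy) || !length(iz)) next
    gx <- exp(-(xs[ix] - sx)^2 / (2 * spot_sigma_um^2))
    gy <- exp(-(ys[iy] - sy)^2 / (2 * spot_sigma_um^2))
    gz <- exp(-(zs[iz] - sz)^2 / (2 * spot_sigma_um^2))
    blob <- truth$amplitude[r] * outer(gy, gx)
    for (k in seq_along(iz)) {
      mrna[iy, ix, iz[k]] <- mrna[iy, ix, iz[k]] + blob * gz[k]
    }
  }

  add_noise <- function(a) {
    if (poisson_noise) a <- array(rpois(length(a), pmax(a, 0)), dim = dim(a))
    if (read_noise_sd > 0) a <- a + rnorm(length(a), 0, read_noise_sd)
    pmax(a, 0)
  }
  mrna <- add_noise(mrna); memb <- add_noise(memb)

  stack <- image_stack(channels = list(mrna = mrna, membrane = memb),
                       pixel_size_um = pixel_size_um, z_step_um = z_step_um)
  list(stack = stack, truth = truth, sheaths = sheaths)
}

#' Calibrated multi-channel image stack
#'
#' @param channels Named list of nonnegative `[y, x, z]` arrays (2D matrices
#'   are promoted to single-slice stacks), all the same dimension.
#' @param pixel_size_um,z_step_um Positive calibration in um.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(channels, pixel_size_um, z_step_um = 0.3) {
  if (!is.list(channels) || is.null(names(channels))) {
    abort("`channels` must be a named list of arrays.")
  }
  channels <- lapply(channels, function(a) {
    if (is.matrix(a)) a <- array(a, dim = c(dim(a), 1))
    if (length(dim(a)) != 3) abort("Each channel must be a 2D or 3D array.")
    if (any(!is.finite(a))) abort("Channel intensities must be finite.")
    a
  })
  dims <- lapply(channels, dim)
  if (length(unique(dims)) != 1) abort("All channels must share dimensions.")
  check_scalar(pixel_size_um, "pixel_size_um", lower = 0, strict = TRUE)
  check_scalar(z_step_um, "z_step_um", lower = 0, strict = TRUE)
  structure(list(channels = channels, pixel_size_um = pixel_size_um,
                 z_step_um = z_step_um),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<image_stack> %d channel(s) [%s], %dx%d px x %d slices, %.3f um/px, %.2f um z-step\n",
              length(x$channels), paste(names(x$channels), collapse = ", "),
              d[1], d[2], d[3], x$pixel_size_um, x$z_step_um))
  invisible(x)
}
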