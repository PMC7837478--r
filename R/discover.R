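#' Discover shared motifs by ZOOPS expectation-maximization
#'
#' Classic MEME-style discovery under the zero-or-one-occurrence-per-sequence
#' (ZOOPS) model. For each trial width, candidate position probability
#' matrices are seeded from enumerated input subsequences, screened with one
#' EM step, and the best seeds are refined by full EM. The E-step computes,
#' per sequence, the posterior over "no site" versus each start position; the
#' M-step re-estimates the PPM (with a Dirichlet pseudocount) and the site
#' prior. The 0-order background is estimated from the input once and held
#' fixed. After a motif is accepted, its sites (posterior site probability
#' > 0.5) are masked and discovery repeats, up to `max_motifs` motifs.
#'
#' @param sequences Sequence tibble, named character vector, or DNAStringSet;
#'   at least 2 sequences, each at least `width_min` long.
#' @param width_min,width_max Trial motif widths (every width in the range is
#'   tried; ranking across widths uses a BIC-penalized log-likelihood ratio).
#' @param max_motifs Maximum number of motifs to return (default 20).
#' @param n_seed_starts Number of screened seeds refined by full EM per width.
#' @param max_em_iters,tol EM iteration cap and relative objective tolerance.
#' @param max_seed_candidates Cap on enumerated seed subsequences screened per
#'   width (subsampled deterministically from `seed` if exceeded).
#' @param pseudocount Dirichlet pseudocount per PPM cell in the M-step.
#' @param min_llr Stop early when a motif's log-likelihood ratio versus the
#'   background-only model falls below this (default 0: keep any improvement).
#' @param seed Integer seed controlling seed subsampling.
#' @return List of [motif] objects, each carrying attributes
#'   `sites` (tibble: seq_id, start, posterior), `llr`, and
#'   `objective_trace` (the EM objective per iteration, nondecreasing).
#' @export
discover_motifs <- function(sequences, width_min = 6, width_max = 12,
                            max_motifs = 20, n_seed_starts = 5,
                            max_em_iters = 100, tol = 1e-6,
                            max_seed_candidates = 600,
                            pseudocount = 0.1, min_llr = 0, seed = 1) {
  tbl <- as_seq_tbl(sequences)
  if (nrow(tbl) < 2) abort("Need at least 2 sequences.")
  check_scalar(width_min, "width_min", lower = 4)
  check_scalar(width_max, "width_max", lower = width_min)
  lens <- nchar(tbl$seq)
  if (any(lens < width_min)) abort("All sequences must be at least `width_min` long.")
  width_max <- min(width_max, min(lens))
  enc <- lapply(tbl$seq, encode_seq)
  if (any(vapply(enc, anyNA, logical(1)))) {
    abort("Discovery input must be ACGT/U only.")
  }
  bg <- base_composition(tbl)
  bg <- pmax(bg, 1e-6); bg <- bg / sum(bg)
  masked <- lapply(lens, function(L) rep(FALSE, L))

  motifs <- list()
  set.seed(derive_seed(seed, "discover"))
  for (k in seq_len(max_motifs)) {
    best <- NULL
    for (w in seq.int(width_min, width_max)) {
      fit <- zoops_best_fit(enc, masked, w, bg, n_seed_starts,
                            max_em_iters, tol, max_seed_candidates, pseudocount)
      if (is.null(fit)) next
      # BIC-style penalty: 3w free PPM parameters + site prior
      pen <- fit$llr - 0.5 * (3 * w + 1) * log(max(2, fit$n_windows))
      if (is.null(best) || pen > best$pen) { best <- fit; best$pen <- pen }
    }
    if (is.null(best) || best$llr <= min_llr) break
    m <- new_motif(best$ppm, background = bg, nsites = best$n_sites,
                   name = sprintf("motif_%d", k))
    sites <- best$sites
    sites$seq_id <- tbl$seq_id[sites$seq_index]
    attr(m, "sites") <- select(sites, "seq_id", "start", "posterior")
    attr(m, "llr") <- best$llr
    attr(m, "objective_trace") <- best$trace
    motifs[[k]] <- m
    # erase found sites before searching for the next motif
    for (r in seq_len(nrow(sites))) {
      i <- sites$seq_index[r]
      pos <- sites$start[r] + seq_len(motif_width(m))  # 1-based positions
      masked[[i]][pos] <- TRUE
    }
    if (nrow(sites) == 0) break
  }
  motifs
}

# Enumerate usable windows (not overlapping masked positions) for width w.
# Returns matrix W (n x w) of base codes, seq index, and 0-based starts.
enumerate_windows <- function(enc, masked, w) {
  out_w <- list(); out_i <- list(); out_s <- list()
  for (i in seq_along(enc)) {
    L <- length(enc[[i]])
    if (L < w) next
    nwin <- L - w + 1L
    ok <- !vapply(seq_len(nwin), function(s) any(masked[[i]][s:(s + w - 1L)]),
                  logical(1))
    if (!any(ok)) next
    starts <- which(ok)
    W <- t(vapply(starts, function(s) enc[[i]][s:(s + w - 1L)], integer(w)))
    out_w[[length(out_w) + 1L]] <- W
    out_i[[length(out_i) + 1L]] <- rep(i, length(starts))
    out_s[[length(out_s) + 1L]] <- starts - 1L
  }
  if (!length(out_w)) return(NULL)
  list(W = do.call(rbind, out_w), seq_index = unlist(out_i),
       start = unlist(out_s))
}

# One E-step + objective under the ZOOPS model for PPM `ppm`, prior `gamma`.
zoops_estep <- function(win, ppm, gamma, bg, n_seq) {
  lr <- log(ppm) - log(bg)          # 4 x w, may contain -Inf only if ppm==0
  w <- ncol(ppm)
  s <- numeric(nrow(win$W))
  for (j in seq_len(w)) s <- s + lr[cbind(win$W[, j], j)]
  ratio <- exp(s)
  m_i <- tabulate(win$seq_index, nbins = n_seq)      # usable windows per seq
  A <- numeric(n_seq)
  A[sort(unique(win$seq_index))] <- rowsum(ratio, win$seq_index)[, 1]
  has <- m_i > 0
  denom <- ifelse(has, (1 - gamma) + gamma * A / pmax(m_i, 1), 1)
  z0 <- ifelse(has, (1 - gamma) / denom, 1)
  zwin <- (gamma / m_i[win$seq_index]) * ratio / denom[win$seq_index]
  ll <- sum(log(denom[has]))                          # modulo constant bg term
  list(zwin = zwin, z0 = z0, ll = ll)
}

# Full ZOOPS EM from seed PPMs; returns the best fit across seeds.
zoops_best_fit <- function(enc, masked, w, bg, n_seed_starts,
                           max_em_iters, tol, max_seed_candidates, pc) {
  win <- enumerate_windows(enc, masked, w)
  if (is.null(win) || nrow(win$W) < 2) return(NULL)
  n_seq <- length(enc)

  seed_rows <- seq_len(nrow(win$W))
  if (length(seed_rows) > max_seed_candidates) {
    seed_rows <- sort(sample(seed_rows, max_seed_candidates))
  }
  seed_ppm <- function(row) {
    p <- matrix((1 - 0.82) / 3, 4, w)
    p[cbind(win$W[row, ], seq_len(w))] <- 0.82
    p
  }

  # screen: one EM step per seed, rank by objective
  gamma0 <- 0.5
  screen_obj <- vapply(seed_rows, function(r) {
    e <- zoops_estep(win, seed_ppm(r), gamma0, bg, n_seq)
    e$ll
  }, numeric(1))
  top <- seed_rows[order(screen_obj, decreasing = TRUE)[
    seq_len(min(n_seed_starts, length(seed_rows)))]]

  run_em <- function(ppm, gamma) {
    trace <- numeric(0)
    prior_term <- function(p) sum(pc * log(pmax(p, 1e-300)))
    obj_old <- -Inf
    for (it in seq_len(max_em_iters)) {
      e <- zoops_estep(win, ppm, gamma, bg, n_seq)
      obj <- e$ll + prior_term(ppm)
      trace <- c(trace, obj)
      if (is.finite(obj_old) && obj - obj_old <= tol * (abs(obj_old) + 1e-8)) {
        break
      }
      obj_old <- obj
      # M-step
      tot <- sum(e$zwin)
      C <- matrix(0, 4, w)
      for (j in seq_len(w)) {
        C[, j] <- vapply(1:4, function(b) sum(e$zwin[win$W[, j] == b]),
                         numeric(1))
      }
      ppm <- sweep(C + pc, 2, colSums(C) + 4 * pc, "/")
      gamma <- min(max(mean(1 - e$z0), 1e-4), 1 - 1e-4)
    }
    e <- zoops_estep(win, ppm, gamma, bg, n_seq)
    list(ppm = ppm, gamma = gamma, ll = e$ll, e = e, trace = trace)
  }

  fits <- lapply(top, function(r) run_em(seed_ppm(r), gamma0))
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "ll"))]]

  # hard site assignments: per sequence, best window where P(site) > 0.5
  zwin <- best$e$zwin
  site_rows <- integer(0)
  for (i in seq_len(n_seq)) {
    idx <- which(win$seq_index == i)
    if (!length(idx)) next
    if ((1 - best$e$z0[i]) > 0.5) {
      site_rows <- c(site_rows, idx[which.max(zwin[idx])])
    }
  }
  sites <- tibble(seq_index = win$seq_index[site_rows],
                  start = win$start[site_rows],
                  posterior = 1 - best$e$z0[win$seq_index[site_rows]])
  list(ppm = best$ppm, llr = best$ll, n_sites = length(site_rows),
       sites = sites, trace = best$trace, n_windows = nrow(win$W))
}
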