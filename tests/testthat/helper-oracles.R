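# Independent brute-force oracles used across tests. These deliberately use
# naive per-element loops, enumeration or closed forms, not the package's
# vectorized code paths.

# Grayscale opening by a ball (sphere-cap) structuring element, per-pixel
# double loop with edge replication.
oracle_ball_opening <- function(img, radius) {
  r <- ceiling(radius)
  nr <- nrow(img); nc <- ncol(img)
  offs <- expand.grid(dy = -r:r, dx = -r:r)
  offs <- offs[offs$dy^2 + offs$dx^2 <= radius^2, ]
  offs$h <- sqrt(radius^2 - offs$dy^2 - offs$dx^2)
  at <- function(m, i, j) m[min(max(i, 1), nr), min(max(j, 1), nc)]
  ero <- matrix(NA_real_, nr, nc)
  for (i in 1:nr) for (j in 1:nc) {
    v <- Inf
    for (k in seq_len(nrow(offs))) {
      v <- min(v, at(img, i + offs$dy[k], j + offs$dx[k]) - offs$h[k])
    }
    ero[i, j] <- v
  }
  dil <- matrix(NA_real_, nr, nc)
  for (i in 1:nr) for (j in 1:nc) {
    v <- -Inf
    for (k in seq_len(nrow(offs))) {
      v <- max(v, at(ero, i - offs$dy[k], j - offs$dx[k]) + offs$h[k])
    }
    dil[i, j] <- v
  }
  dil
}

# Two-sided rank-sum p-value by exhaustive enumeration of all C(n1+n2, n1)
# assignments of the pooled ranks to group 1 (no ties assumed).
oracle_wilcox_p <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  ranks <- rank(c(x, y))
  w_obs <- sum(ranks[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  combos <- utils::combn(n, n1)
  w_all <- apply(combos, 2, function(idx) sum(seq_len(n)[idx]))
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# One-sided (greater) Fisher p by direct hypergeometric enumeration with
# choose(), for a 2x2 table a,b (foreground present/absent), c,d (control).
oracle_fisher_greater <- function(a, b, c_, d) {
  n_fg <- a + b; n_bg <- c_ + d; k <- a + c_
  xs <- max(0, k - n_bg):min(n_fg, k)
  probs <- choose(n_fg, xs) * choose(n_bg, k - xs) / choose(n_fg + n_bg, k)
  sum(probs[xs >= a])
}

# PWM p-values by exhaustive enumeration of all 4^w windows on the same
# 1/1000-bit integer grid the package scans on.
oracle_pwm_pvalues <- function(ppm, background, pseudocount = 0.1,
                               granularity = 1e-3) {
  padj <- sweep(ppm + pseudocount * background, 2, 1 + pseudocount, "/")
  lo <- log2(padj / background)
  ints <- round(lo / granularity)
  w <- ncol(ppm)
  grid <- as.matrix(expand.grid(rep(list(1:4), w)))
  sc <- numeric(nrow(grid)); pr <- numeric(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    sc[r] <- sum(ints[cbind(grid[r, ], seq_len(w))])
    pr[r] <- prod(background[grid[r, ]])
  }
  function(score_bits) {
    si <- round(score_bits / granularity)
    sum(pr[sc >= si])
  }
}

random_ppm <- function(w) {
  m <- matrix(stats::rexp(4 * w), 4, w)
  sweep(m, 2, colSums(m), "/")
}

# Hamming distance between two equal-length strings.
str_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Count dinucleotides of a sequence string.
dinuc_counts <- function(s) {
  v <- strsplit(s, "")[[1]]
  table(paste0(v[-length(v)], v[-1]))
}
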