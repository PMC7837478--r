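#' Shuffle sequences preserving composition
#'
#' Per-sequence shuffles used to build control sets for motif enrichment.
#' `order = "mono"` permutes letters (base counts preserved exactly);
#' `order = "di"` performs an Euler-path doublet shuffle (Altschul-Erickson)
#' preserving the exact dinucleotide multiset of each sequence.
#'
#' @param sequences Sequence tibble, named character vector, or DNAStringSet.
#' @param order `"mono"` or `"di"`.
#' @param seed Integer seed.
#' @return Tibble with columns `seq_id` (suffixed `_shuf`), `seq`.
#' @export
shuffle_sequences <- function(sequences, order = c("mono", "di"), seed = 1) {
  order <- match.arg(order)
  tbl <- as_seq_tbl(sequences)
  set.seed(derive_seed(seed, paste0("shuffle-", order)))
  shuf <- vapply(tbl$seq, function(s) {
    v <- strsplit(s, "", fixed = TRUE)[[1]]
    if (length(v) < 3) return(s)
    if (order == "mono") paste(sample(v), collapse = "")
    else doublet_shuffle(v)
  }, character(1), USE.NAMES = FALSE)
  tibble(seq_id = paste0(tbl$seq_id, "_shuf"), seq = shuf)
}

# Altschul-Erickson doublet shuffle: treat the sequence as an Euler walk on
# the graph of symbols with edges s[i] -> s[i+1]; fix a random last-exit edge
# per vertex forming a tree into the final symbol, shuffle remaining edges,
# and rebuild the walk.
doublet_shuffle <- function(v) {
  syms <- unique(v)
  if (length(syms) == 1) return(paste(v, collapse = ""))
  n <- length(v)
  from <- v[-n]; to <- v[-1]
  last_sym <- v[n]
  edges <- split(to, factor(from, levels = syms))
  for (tries in 1:1000) {
    last_exit <- lapply(edges, function(e) if (length(e)) sample(e, 1) else NULL)
    # check every vertex with out-edges reaches last_sym via last-exit edges
    ok <- TRUE
    for (s in syms) {
      if (s == last_sym || !length(edges[[s]])) next
      cur <- s; seen <- character(0)
      repeat {
        if (cur == last_sym) break
        if (cur %in% seen || is.null(last_exit[[cur]])) { ok <- FALSE; break }
        seen <- c(seen, cur)
        cur <- last_exit[[cur]]
      }
      if (!ok) break
    }
    if (ok) break
  }
  if (!ok) return(paste(v, collapse = ""))  # give up; keep original
  # shuffle non-last edges, append the fixed last-exit edge
  pool <- edges
  for (s in syms) {
    e <- pool[[s]]
    if (!length(e)) next
    le <- last_exit[[s]]
    if (s != last_sym && !is.null(le)) {
      e <- e[-match(le, e)]
      pool[[s]] <- c(sample(e, length(e)), le)
    } else {
      pool[[s]] <- sample(e, length(e))
    }
  }
  out <- character(n); out[1] <- v[1]
  ptr <- setNames(rep(1L, length(syms)), syms)
  cur <- v[1]
  for (i in 2:n) {
    nxt <- pool[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}

#' Motif enrichment against a control sequence set
#'
#' Labels each foreground and control sequence present/absent for the motif
#' (at least one scan hit at `p_max`), builds the 2x2 table, and tests
#' enrichment with a one-sided Fisher exact test (hypergeometric tail,
#' alternative: foreground more present). When no control set is supplied,
#' composition-preserving shuffles of the foreground are used, mirroring the
#' shuffled-input control of motif-enrichment tools.
#'
#' @param foreground Sequence tibble / named character vector.
#' @param motif A [motif].
#' @param background Optional control sequence set; default `NULL` generates
#'   shuffles of `foreground`.
#' @param p_max Per-window scan p-value threshold (default 1e-4).
#' @param shuffle_order `"mono"` or `"di"` shuffle for the generated control.
#' @param seed Seed for the shuffle.
#' @return One-row tibble: present/absent counts in both sets, `odds_ratio`
#'   (Haldane 0.5 correction when a cell is 0) and one-sided `p_value`.
#' @export
enrichment_test <- function(foreground, motif, background = NULL,
                            p_max = 1e-4, shuffle_order = "mono", seed = 1) {
  fg <- as_seq_tbl(foreground)
  if (nrow(fg) == 0) abort("`foreground` is empty.")
  bgset <- if (is.null(background)) {
    shuffle_sequences(fg, order = shuffle_order, seed = seed)
  } else as_seq_tbl(background)

  present_in <- function(tbl) {
    hits <- scan_sequences(tbl, motif, p_max = p_max)
    length(unique(hits$seq_id))
  }
  a <- present_in(fg);      b <- nrow(fg) - a
  c_ <- present_in(bgset);  d <- nrow(bgset) - c_
  tab <- matrix(c(a, b, c_, d), nrow = 2,
                dimnames = list(c("present", "absent"),
                                c("foreground", "control")))
  p <- fisher.test(t(tab), alternative = "greater")$p.value
  or <- if (any(tab == 0)) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
  } else (a * d) / (b * c_)
  tibble(fg_present = a, fg_absent = b,
         bg_present = c_, bg_absent = d,
         odds_ratio = or, p_value = p,
         shuffle_order = if (is.null(background)) shuffle_order else NA_character_,
         seed = if (is.null(background)) seed else NA_integer_)
}
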