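# Independent brute-force oracles, coded from the definitions, not from the
# package implementation.

# cell-by-cell MAD filter: recompute medians/MADs from scratch and apply the
# three rules literally to each cell in turn
brute_mad_filter <- function(umi, ngene, mito_pct,
                             m_mult = 5, u_mult = 3, g_mult = 3) {
  keep <- logical(length(umi))
  for (i in seq_along(umi)) {
    mm <- stats::median(mito_pct)
    dm <- stats::median(abs(mito_pct - mm))
    mu <- stats::median(umi)
    du <- stats::median(abs(umi - mu))
    mg <- stats::median(ngene)
    dg <- stats::median(abs(ngene - mg))
    keep[i] <- !(mito_pct[i] > mm + m_mult * dm) &&
               !(abs(umi[i] - mu) > u_mult * du) &&
               !(abs(ngene[i] - mg) > g_mult * dg)
  }
  keep
}

# BH step-up by the textbook rule: sort, take (m / i) * p_(i), enforce
# monotonicity from the largest rank down, cap at 1, map back
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- (m / seq_len(m)) * ps
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# AUC as the average over all positive x negative pairs, ties worth 0.5
brute_auc <- function(score, label) {
  pos <- score[label]
  neg <- score[!label]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + (p > n) + 0.5 * (p == n)
  }
  tot / (length(pos) * length(neg))
}

# disc membership by direct enumeration over every grid bin
brute_disc_count <- function(center, radius, rows, cols) {
  cnt <- 0L
  for (x in seq_len(cols)) for (y in seq_len(rows)) {
    if (sqrt((x - center[1])^2 + (y - center[2])^2) <= radius) cnt <- cnt + 1L
  }
  cnt
}

f1_score <- function(called, truth) {
  tp <- sum(called & truth)
  if (tp == 0) return(0)
  prec <- tp / sum(called)
  rec <- tp / sum(truth)
  2 * prec * rec / (prec + rec)
}
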