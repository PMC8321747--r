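# Independent oracles, kept deliberately naive.

# exhaustive COW: enumerate every internal-boundary offset combination and
# return the best summed segment correlation (linear interpolation onto the
# reference grid, zero-variance segments count 0)
cow_brute_force <- function(x, ref, bounds, slack) {
  n_seg <- length(bounds) - 1
  warp_corr <- function(a, b, u0, u1) {
    len <- u1 - u0 + 1
    pos <- a + (b - a) * (seq_len(len) - 1) / (len - 1)
    lo <- pmin(pmax(floor(pos), 1), length(x) - 1)
    v <- x[lo] * (1 - (pos - lo)) + x[lo + 1] * (pos - lo)
    r <- ref[u0:u1]
    if (stats::sd(v) < 1e-6 || stats::sd(r) < 1e-6) return(0)
    stats::cor(v, r)
  }
  inner <- n_seg - 1
  if (inner == 0)
    return(warp_corr(bounds[1], bounds[2], bounds[1], bounds[2]))
  grids <- rep(list(-slack:slack), inner)
  combos <- as.matrix(expand.grid(grids))
  best <- -Inf
  for (i in seq_len(nrow(combos))) {
    off <- c(0, combos[i, ], 0)
    tot <- 0
    for (s in seq_len(n_seg))
      tot <- tot + warp_corr(bounds[s] + off[s], bounds[s + 1] + off[s + 1],
                             bounds[s], bounds[s + 1])
    if (tot > best) best <- tot
  }
  best
}

# brute-force farthest pair by double loop
ks_pair_oracle <- function(X) {
  m <- nrow(X)
  best <- c(NA, NA); bd <- -1
  for (i in seq_len(m - 1))
    for (j in (i + 1):m) {
      d <- sqrt(sum((X[i, ] - X[j, ])^2))
      if (d > bd) { bd <- d; best <- c(i, j) }
    }
  best
}

# per-class efficiency by direct counting over the label vectors
efficiency_oracle <- function(y_true, y_pred, cl) {
  pos <- y_true == cl
  sens <- sum(pos & y_pred == cl) / sum(pos)
  spec <- sum(!pos & y_pred != cl) / sum(!pos)
  sqrt(sens * spec)
}
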