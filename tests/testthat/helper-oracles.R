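# Independent brute-force oracles used across test files. These deliberately
# avoid the package's own implementation paths.

# Exhaustive isodata criterion: over all candidate thresholds, find the one
# closest to the fixed point t = mean(mu_below, mu_above).
oracle_isodata <- function(v, n_bins = 256) {
  rng <- range(v)
  width <- diff(rng) / n_bins
  centers <- rng[1] + (seq_len(n_bins) - 0.5) * width
  best <- NULL; best_gap <- Inf
  for (t in centers) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (!length(lo) || !length(hi)) next
    fix <- (mean(lo) + mean(hi)) / 2
    gap <- abs(fix - t)
    if (gap < best_gap) { best_gap <- gap; best <- fix }
  }
  best
}

# Direct min-then-max (grayscale opening) with a disc structuring element,
# evaluated by explicit loops. Small inputs only.
oracle_opening_disc <- function(img, radius) {
  n <- nrow(img); m <- ncol(img)
  offs <- expand.grid(dy = -radius:radius, dx = -radius:radius)
  offs <- offs[sqrt(offs$dy^2 + offs$dx^2) <= radius + 1e-9, ]
  er <- matrix(Inf, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    ys <- i + offs$dy; xs <- j + offs$dx
    ok <- ys >= 1 & ys <= n & xs >= 1 & xs <= m
    er[i, j] <- min(img[cbind(ys[ok], xs[ok])])
  }
  di <- matrix(-Inf, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    ys <- i + offs$dy; xs <- j + offs$dx
    ok <- ys >= 1 & ys <= n & xs >= 1 & xs <= m
    di[i, j] <- max(er[cbind(ys[ok], xs[ok])])
  }
  di
}

# Burst counting straight from ground-truth event times (no detection):
# bins of width bin_s where >= frac of the active units fire, merged runs.
oracle_burst_count <- function(event_list, duration_s, bin_s, frac) {
  active <- event_list[vapply(event_list, length, integer(1)) >= 1]
  edges <- seq(0, duration_s + bin_s, by = bin_s)
  counts <- integer(length(edges) - 1)
  for (ev in active) {
    b <- unique(pmin(findInterval(ev, edges), length(counts)))
    counts[b] <- counts[b] + 1L
  }
  qual <- counts >= frac * length(active)
  sum(rle(qual)$values)
}

disc_mask <- function(size, cx, cy, r) {
  xy <- expand.grid(y = seq_len(size), x = seq_len(size))
  m <- matrix(FALSE, size, size)
  m[sqrt((xy$x - cx)^2 + (xy$y - cy)^2) <= r] <- TRUE
  m
}
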