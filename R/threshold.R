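#' Automatic global histogram thresholds (Isodata, Triangle)
#'
#' Both criteria operate on a 256-bin histogram of the image intensities.
#'
#' * `isodata`: the iterative inter-means fixed point
#'   `t = (mean(below t) + mean(above t)) / 2`, the classic ridler-calvard
#'   procedure used for nucleus and neurite masks.
#' * `triangle`: the threshold maximizing the perpendicular distance between
#'   the histogram and the chord from the histogram peak to the far end of the
#'   longer tail; suited to images dominated by background with a sparse
#'   bright tail (puncta, fibrils).
#'
#' @param image A [field_image()] or numeric matrix/vector.
#' @param method `"isodata"` or `"triangle"`.
#' @param n_bins Number of histogram bins (default 256).
#' @return The threshold on the intensity scale of the input; pixels strictly
#'   above it are foreground.
#' @export
auto_threshold <- function(image, method = c("isodata", "triangle"),
                           n_bins = 256) {
  method <- match.arg(method)
  v <- as.vector(if (inherits(image, "field_image")) image$pixels else image)
  v <- v[is.finite(v)]
  if (!length(v)) stop("No finite intensities.", call. = FALSE)
  rng <- range(v)
  if (diff(rng) <= 0) {
    stop("Cannot threshold a constant image.", call. = FALSE)
  }
  width <- diff(rng) / n_bins
  # bin i covers [min + (i-1) w, min + i w); top value folded into last bin
  idx <- pmin(floor((v - rng[1]) / width) + 1, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  centers <- rng[1] + (seq_len(n_bins) - 0.5) * width
  switch(method,
    isodata = threshold_isodata(counts, centers),
    triangle = threshold_triangle(counts, centers)
  )
}

threshold_isodata <- function(counts, centers) {
  t_bin <- which(cumsum(counts) >= sum(counts) / 2)[1] # start near median
  for (iter in 1:200) {
    below <- seq_len(t_bin)
    above <- setdiff(seq_along(counts), below)
    n_lo <- sum(counts[below]); n_hi <- sum(counts[above])
    if (n_lo == 0 || n_hi == 0) {
      # move toward the populated side
      t_bin <- if (n_lo == 0) t_bin + 1 else t_bin - 1
      next
    }
    mu_lo <- sum(counts[below] * centers[below]) / n_lo
    mu_hi <- sum(counts[above] * centers[above]) / n_hi
    t_new <- (mu_lo + mu_hi) / 2
    new_bin <- max(1, min(length(counts), findInterval(t_new, centers)))
    if (new_bin == t_bin) return(t_new)
    t_bin <- new_bin
  }
  t_new
}

threshold_triangle <- function(counts, centers) {
  peak <- which.max(counts)
  nz <- which(counts > 0)
  lo <- nz[1]; hi <- nz[length(nz)]
  # pick the longer tail; mirror so that the tail is to the right of the peak
  flip <- (peak - lo) > (hi - peak)
  if (flip) {
    counts <- rev(counts)
    peak <- length(counts) - peak + 1
    hi <- length(counts) - lo + 1
  }
  if (hi <= peak) return(centers[ceiling(length(centers) / 2)])
  h <- counts / max(counts)
  xs <- seq.int(peak, hi)
  # distance from (x, h[x]) to the line from (peak, 1) to (hi, 0)
  dx <- hi - peak
  dy <- 0 - 1
  d <- abs(dy * (xs - peak) - dx * (h[xs] - 1)) / sqrt(dx^2 + dy^2)
  best <- xs[which.max(d)]
  if (flip) best <- length(counts) - best + 1
  centers[best]
}
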