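# Functional-connectivity analysis of calcium time-lapse recordings:
# trace extraction, glutamate-based neuron gating, event detection,
# network burst statistics, and subpopulation comparison.

#' Calcium recording container
#'
#' @param traces Cells x frames numeric matrix of raw fluorescence.
#' @param fps Frame rate, Hz.
#' @param duration_s Recording duration in seconds; defaults to
#'   `ncol(traces) / fps`.
#' @param stim_window Integer `c(first, last)` frame (1-based, inclusive) of
#'   the terminal glutamate epoch, or `NULL` for recordings without a
#'   stimulus (genetically encoded indicator mode).
#' @param cell_ids Optional cell identifiers.
#' @return A `calcium_recording` object.
#' @export
calcium_recording <- function(traces, fps, duration_s = ncol(traces) / fps,
                              stim_window = NULL, cell_ids = NULL) {
  traces <- as.matrix(traces)
  if (!is.numeric(traces)) stop("`traces` must be numeric.", call. = FALSE)
  n_frames <- ncol(traces)
  if (abs(n_frames - round(duration_s * fps)) > 0.5) {
    stop("frames must equal round(duration_s * fps).", call. = FALSE)
  }
  if (!is.null(stim_window)) {
    stim_window <- as.integer(stim_window)
    if (length(stim_window) != 2 || stim_window[1] < 1 ||
        stim_window[2] > n_frames || stim_window[1] > stim_window[2]) {
      stop("`stim_window` must lie inside the recording.", call. = FALSE)
    }
  }
  if (is.null(cell_ids)) cell_ids <- seq_len(nrow(traces))
  structure(
    list(traces = traces, fps = fps, duration_s = duration_s,
         stim_window = stim_window, cell_ids = cell_ids),
    class = "calcium_recording"
  )
}

#' @export
print.calcium_recording <- function(x, ...) {
  cat(sprintf("<calcium_recording> %d cell(s) x %d frames @ %g fps%s\n",
              nrow(x$traces), ncol(x$traces), x$fps,
              if (is.null(x$stim_window)) " (no stimulus window)"
              else sprintf(", stimulus frames %d-%d",
                           x$stim_window[1], x$stim_window[2])))
  invisible(x)
}

spontaneous_frames <- function(rec) {
  f <- seq_len(ncol(rec$traces))
  if (is.null(rec$stim_window)) f
  else f[f < rec$stim_window[1] | f > rec$stim_window[2]]
}

#' Extract per-cell fluorescence traces from a movie
#'
#' Each trace is the per-frame mean intensity over the pixels of a labelled
#' ROI. Empty ROIs are excluded with a warning.
#'
#' @param movie 3D array `(y, x, frame)`.
#' @param rois A [label_map()] matching the movie geometry.
#' @param fps Frame rate, Hz.
#' @param stim_window Optional glutamate epoch, as in [calcium_recording()].
#' @return A [calcium_recording()]; `cell_ids` are the ROI labels.
#' @export
extract_traces <- function(movie, rois, fps, stim_window = NULL) {
  stopifnot(inherits(rois, "label_map"))
  d <- dim(movie)
  if (length(d) != 3 || !all(d[1:2] == dim(rois$labels))) {
    stop("ROI geometry must match the movie.", call. = FALSE)
  }
  lab <- as.vector(rois$labels)
  ids <- sort(setdiff(unique(lab), 0L))
  sizes <- tabulate(lab, nbins = max(c(ids, 1L)))
  empty <- setdiff(seq_len(max(c(ids, 0L))), ids)
  if (length(empty)) {
    warning("Empty ROI label(s) excluded: ", paste(empty, collapse = ", "),
            call. = FALSE)
  }
  flat <- matrix(movie, d[1] * d[2], d[3])
  sel <- lab > 0
  sums <- rowsum(flat[sel, , drop = FALSE], lab[sel])
  ids_out <- as.integer(rownames(sums))
  traces <- sums / sizes[ids_out]
  dimnames(traces) <- NULL
  calcium_recording(traces, fps = fps, stim_window = stim_window,
                    cell_ids = ids_out)
}

#' Normalize traces to dF/F0 with a rolling-percentile baseline
#'
#' `F0` is a running low percentile of the raw trace (window in seconds),
#' which tracks slow drift while ignoring transients.
#'
#' @param rec A [calcium_recording()].
#' @param baseline_percentile Percentile used for `F0` (default 10).
#' @param window_s Baseline window length (default 30 s).
#' @return Matrix of dF/F0 values, same shape as `rec$traces`.
#' @export
delta_f_over_f <- function(rec, baseline_percentile = 10, window_s = 30) {
  stopifnot(inherits(rec, "calcium_recording"))
  w <- max(3L, round(window_s * rec$fps))
  half <- w %/% 2
  n <- ncol(rec$traces)
  # evaluate the rolling percentile on a coarse grid and interpolate; the
  # baseline varies slowly by construction
  grid <- unique(c(seq(1, n, by = max(1L, half %/% 4)), n))
  t(apply(rec$traces, 1, function(tr) {
    if (all(is.na(tr))) stop("All-NaN trace.", call. = FALSE)
    f0g <- vapply(grid, function(i) {
      lo <- max(1, i - half); hi <- min(n, i + half)
      stats::quantile(tr[lo:hi], baseline_percentile / 100, names = FALSE,
                      na.rm = TRUE)
    }, numeric(1))
    f0 <- stats::approx(grid, f0g, xout = seq_len(n), rule = 2)$y
    f0[f0 <= 0] <- mean(abs(tr)) + 1e-9
    (tr - f0) / f0
  }))
}

#' Gate neurons by their glutamate response
#'
#' A cell is classified as a neuron when its mean dF/F0 inside the terminal
#' glutamate window exceeds `response_factor` times the robust SD
#' (MAD-based) of its pre-stimulus dF/F0. Cells failing the gate are
#' non-neuronal and excluded from network metrics. Recordings without a
#' stimulus window skip classification: all cells are retained and the
#' result is flagged (`mode = "no-stimulus"`), matching indicator constructs
#' whose expression is restricted to neurons.
#'
#' @param rec A [calcium_recording()].
#' @param response_factor Gate multiplier (default 5).
#' @param subpopulation Optional per-cell categorical labels (e.g. Tau
#'   aggregate-positive / -negative), defined for neurons.
#' @return Tibble (class `cell_classification`): `cell`, `is_neuron`,
#'   `stim_response`, `gate`, `subpopulation`; attribute `mode` is
#'   `"glutamate"` or `"no-stimulus"`.
#' @export
classify_glutamate_responders <- function(rec, response_factor = 5,
                                          subpopulation = NULL) {
  stopifnot(inherits(rec, "calcium_recording"))
  n <- nrow(rec$traces)
  if (is.null(subpopulation)) subpopulation <- rep(NA_character_, n)
  if (is.null(rec$stim_window)) {
    out <- tibble::tibble(cell = rec$cell_ids, is_neuron = TRUE,
                          stim_response = NA_real_, gate = NA_real_,
                          subpopulation = as.character(subpopulation))
    attr(out, "mode") <- "no-stimulus"
    class(out) <- c("cell_classification", class(out))
    return(out)
  }
  dff <- delta_f_over_f(rec)
  pre <- seq_len(rec$stim_window[1] - 1)
  stim <- rec$stim_window[1]:rec$stim_window[2]
  resp <- rowMeans(dff[, stim, drop = FALSE])
  gate <- response_factor *
    apply(dff[, pre, drop = FALSE], 1, stats::mad)
  out <- tibble::tibble(cell = rec$cell_ids, is_neuron = resp > gate,
                        stim_response = resp, gate = gate,
                        subpopulation = ifelse(resp > gate,
                                               as.character(subpopulation),
                                               NA_character_))
  attr(out, "mode") <- "glutamate"
  class(out) <- c("cell_classification", class(out))
  out
}

local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer())
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

peak_prominence <- function(x, i) {
  # height above the higher of the two bracketing valleys, where a valley
  # extends to the nearest sample exceeding the peak (or the trace end)
  left <- x[seq_len(i - 1)]
  hi_l <- which(left > x[i])
  lo_l <- if (length(hi_l)) min(x[(max(hi_l) + 1):(i - 1)]) else min(left)
  right <- x[(i + 1):length(x)]
  hi_r <- which(right > x[i])
  lo_r <- if (length(hi_r)) min(x[(i + 1):(i + min(hi_r) - 1)]) else min(right)
  x[i] - max(lo_l, lo_r)
}

#' Detect calcium transients in one trace
#'
#' Works on dF/F0 with a rolling low-percentile baseline. The trace is
#' lightly smoothed (boxcar of `smooth_frames`), and peaks are local maxima
#' exceeding the spontaneous-epoch median by `k_mad` times the MAD-based
#' robust SD, with at least `min_prominence` prominence. Frames in the
#' stimulus window never yield peaks.
#'
#' @param trace Numeric vector (raw fluorescence), or a
#'   [calcium_recording()] plus `cell` index.
#' @param fps Frame rate, Hz.
#' @param stim_window Optional stimulus epoch `c(first, last)` (1-based).
#' @param baseline_percentile Rolling-baseline percentile (default 10).
#' @param k_mad Detection threshold in robust SDs (default 5).
#' @param min_prominence Minimum peak prominence in dF/F0 units
#'   (default 0.05).
#' @param smooth_frames Boxcar width applied to dF/F0 before the maxima
#'   search (default 3 frames, about one transient at 2 fps; 1 disables).
#' @return Tibble: `frame`, `time_s`, `dff` for each detected peak.
#' @export
detect_peaks <- function(trace, fps, stim_window = NULL,
                         baseline_percentile = 10, k_mad = 5,
                         min_prominence = 0.05, smooth_frames = 3) {
  if (length(trace) < 10) stop("Need >= 10 frames.", call. = FALSE)
  if (all(is.na(trace))) stop("All-NaN trace.", call. = FALSE)
  rec <- calcium_recording(matrix(trace, 1), fps = fps,
                           stim_window = stim_window)
  dff <- delta_f_over_f(rec, baseline_percentile)[1, ]
  peaks_from_dff(dff, fps, spontaneous_frames(rec), k_mad, min_prominence,
                 smooth_frames)
}

peaks_from_dff <- function(dff, fps, keep, k_mad = 5, min_prominence = 0.05,
                           smooth_frames = 3) {
  if (smooth_frames > 1) {
    k <- rep(1 / smooth_frames, smooth_frames)
    dff <- stats::filter(dff, k, sides = 2)
    dff[is.na(dff)] <- 0
    dff <- as.numeric(dff)
  }
  med <- stats::median(dff[keep])
  sigma <- stats::mad(dff[keep])
  thr <- med + k_mad * sigma
  cand <- local_maxima(dff)
  cand <- cand[cand %in% keep & dff[cand] > thr]
  cand <- cand[vapply(cand, function(i) peak_prominence(dff, i), numeric(1))
               >= min_prominence]
  tibble::tibble(frame = cand, time_s = (cand - 1) / fps, dff = dff[cand])
}

#' Per-neuron event trains
#'
#' Runs [detect_peaks()] on every neuron retained by the classification.
#'
#' @param rec A [calcium_recording()].
#' @param cls A `cell_classification` from
#'   [classify_glutamate_responders()].
#' @param ... Passed to [detect_peaks()].
#' @return Tibble (class `event_trains`): `cell`, `n_events`, `events`
#'   (list-column of peak-time vectors, seconds).
#' @export
event_trains <- function(rec, cls, ...) {
  stopifnot(inherits(rec, "calcium_recording"),
            inherits(cls, "cell_classification"))
  neurons <- cls$cell[cls$is_neuron]
  rows <- match(neurons, rec$cell_ids)
  dots <- list(...)
  dff <- do.call(delta_f_over_f,
                 c(list(rec), dots[intersect(names(dots),
                                             "baseline_percentile")]))
  keep <- spontaneous_frames(rec)
  pk_args <- dots[intersect(names(dots),
                            c("k_mad", "min_prominence", "smooth_frames"))]
  ev <- lapply(rows, function(r) {
    do.call(peaks_from_dff,
            c(list(dff[r, ], rec$fps, keep), pk_args))$time_s
  })
  out <- tibble::tibble(cell = neurons,
                        n_events = vapply(ev, length, integer(1)),
                        events = ev)
  class(out) <- c("event_trains", class(out))
  out
}

#' Percentage of active neurons
#'
#' A neuron is active when it shows at least one detected peak during the
#' spontaneous epoch. Network metrics are reported "not determined" (ND)
#' when fewer than 5 active neurons are present in the field.
#'
#' @param trains An `event_trains` tibble.
#' @return One-row tibble: `n_neurons`, `n_active`, `pct_active` (`NA` when
#'   there are no neurons), `nd_flag` (`TRUE` when `n_active < 5`).
#' @export
percent_active <- function(trains) {
  stopifnot(inherits(trains, "event_trains"))
  n <- nrow(trains)
  n_active <- sum(trains$n_events >= 1)
  tibble::tibble(
    n_neurons = n,
    n_active = n_active,
    pct_active = if (n > 0) 100 * n_active / n else NA_real_,
    nd_flag = n_active < 5
  )
}

#' Detect synchronous network bursts
#'
#' Events of all active neurons are binned; bins where the fraction of
#' active neurons firing reaches `participation_frac` qualify, and adjacent
#' qualifying bins merge into one burst. The frequency denominator is the
#' analyzed (spontaneous) duration. Undefined (ND) when fewer than 5 active
#' neurons are available.
#'
#' @param trains An `event_trains` tibble.
#' @param duration_s Spontaneous (analyzed) duration in seconds.
#' @param bin_s Bin width (default 1 s).
#' @param participation_frac Fraction of active neurons required
#'   (default 0.5).
#' @return List: `burst_times_s` (burst-start times), `n_bursts`,
#'   `burst_frequency` (bursts/min; `NA` when ND), `nd_flag`.
#' @export
detect_network_bursts <- function(trains, duration_s, bin_s = 1,
                                  participation_frac = 0.5) {
  stopifnot(inherits(trains, "event_trains"))
  active <- trains[trains$n_events >= 1, ]
  if (nrow(active) < 5) {
    return(list(burst_times_s = numeric(), n_bursts = NA_integer_,
                burst_frequency = NA_real_, nd_flag = TRUE))
  }
  edges <- seq(0, duration_s + bin_s, by = bin_s)
  counts <- integer(length(edges) - 1)
  for (ev in active$events) {
    b <- unique(pmin(findInterval(ev, edges), length(counts)))
    counts[b] <- counts[b] + 1L
  }
  qual <- counts >= participation_frac * nrow(active)
  runs <- rle(qual)
  starts <- cumsum(c(1, runs$lengths))[seq_along(runs$lengths)]
  burst_bins <- starts[runs$values]
  list(
    burst_times_s = edges[burst_bins],
    n_bursts = length(burst_bins),
    burst_frequency = length(burst_bins) / (duration_s / 60),
    nd_flag = FALSE
  )
}

#' Mean pairwise burst correlation
#'
#' Mean of the off-diagonal entries of the pairwise Pearson correlation
#' matrix of the neurons' dF/F0 traces, computed on the spontaneous epoch
#' only. Constant traces are excluded with a warning.
#'
#' @param rec A [calcium_recording()].
#' @param cls A `cell_classification`.
#' @param cells Optional subset of cell ids (defaults to all neurons).
#' @param active_only Restrict to neurons with at least one event (requires
#'   `trains`).
#' @param trains Optional `event_trains`, needed for `active_only`.
#' @return List: `mean_r` (`NA` if < 2 usable neurons), `n_used`,
#'   `cor_matrix`.
#' @export
burst_correlation <- function(rec, cls, cells = NULL, active_only = FALSE,
                              trains = NULL) {
  stopifnot(inherits(rec, "calcium_recording"),
            inherits(cls, "cell_classification"))
  use <- cls$cell[cls$is_neuron]
  if (!is.null(cells)) use <- intersect(use, cells)
  if (active_only) {
    if (is.null(trains)) stop("`active_only` needs `trains`.", call. = FALSE)
    use <- intersect(use, trains$cell[trains$n_events >= 1])
  }
  rows <- match(use, rec$cell_ids)
  keep_f <- spontaneous_frames(rec)
  dff <- delta_f_over_f(rec)[rows, keep_f, drop = FALSE]
  sds <- apply(dff, 1, stats::sd)
  if (any(sds == 0)) {
    warning("Excluding ", sum(sds == 0), " constant trace(s).", call. = FALSE)
    dff <- dff[sds > 0, , drop = FALSE]
    use <- use[sds > 0]
  }
  if (nrow(dff) < 2) {
    return(list(mean_r = NA_real_, n_used = nrow(dff), cor_matrix = NULL))
  }
  cm <- stats::cor(t(dff))
  list(mean_r = mean(cm[lower.tri(cm)]), n_used = nrow(dff),
       cor_matrix = cm)
}

#' Field-level network activity metrics
#'
#' Convenience wrapper: classification, event trains, percentage active,
#' burst frequency and burst correlation for one recording.
#'
#' @param rec A [calcium_recording()].
#' @param cls Optional precomputed classification.
#' @param bin_s,participation_frac Burst-detection settings.
#' @param ... Passed to [detect_peaks()] via [event_trains()].
#' @return One-row tibble: `n_neurons`, `n_active`, `pct_active`,
#'   `burst_frequency`, `burst_correlation`, `nd_flag`.
#' @export
network_metrics <- function(rec, cls = NULL, bin_s = 1,
                            participation_frac = 0.5, ...) {
  if (is.null(cls)) cls <- classify_glutamate_responders(rec)
  trains <- event_trains(rec, cls, ...)
  act <- percent_active(trains)
  spont_s <- length(spontaneous_frames(rec)) / rec$fps
  bursts <- detect_network_bursts(trains, spont_s, bin_s, participation_frac)
  bc <- if (act$nd_flag) list(mean_r = NA_real_)
        else burst_correlation(rec, cls)
  tibble::tibble(
    n_neurons = act$n_neurons, n_active = act$n_active,
    pct_active = act$pct_active,
    burst_frequency = bursts$burst_frequency,
    burst_correlation = bc$mean_r,
    nd_flag = act$nd_flag
  )
}

#' Network metrics per neuronal subpopulation
#'
#' Computes all network metrics separately for each subpopulation label
#' (e.g. Tau aggregate-positive vs. -negative neurons in the same field) and
#' reports, in addition, each subgroup's mean correlation with the whole
#' network. Empty subgroups are skipped with a notice; a single-member
#' subgroup has an undefined burst correlation.
#'
#' @param rec A [calcium_recording()].
#' @param cls A `cell_classification` whose `subpopulation` column is set
#'   for neurons.
#' @param ... Passed to [detect_peaks()].
#' @return Tibble with one row per subpopulation: the [network_metrics()]
#'   columns plus `subpopulation`, `n_cells` and `cross_network_r`.
#' @export
subpopulation_metrics <- function(rec, cls, ...) {
  stopifnot(inherits(cls, "cell_classification"))
  subs <- unique(stats::na.omit(cls$subpopulation))
  if (!length(subs)) {
    message("No subpopulation labels present; nothing to compare.")
    return(tibble::tibble())
  }
  keep_f <- spontaneous_frames(rec)
  all_neurons <- match(cls$cell[cls$is_neuron], rec$cell_ids)
  dff_all <- delta_f_over_f(rec)[, keep_f, drop = FALSE]
  net_mean <- colMeans(dff_all[all_neurons, , drop = FALSE])
  out <- list()
  for (s in subs) {
    cells <- cls$cell[cls$is_neuron & !is.na(cls$subpopulation) &
                        cls$subpopulation == s]
    if (!length(cells)) {
      message("Subpopulation '", s, "' is empty; skipped.")
      next
    }
    sub_cls <- cls[cls$cell %in% cells, ]
    trains <- event_trains(rec, sub_cls, ...)
    act <- percent_active(trains)
    spont_s <- length(keep_f) / rec$fps
    bursts <- detect_network_bursts(trains, spont_s)
    bc <- if (length(cells) >= 2) burst_correlation(rec, cls, cells = cells)
          else list(mean_r = NA_real_)
    rows <- match(cells, rec$cell_ids)
    cross <- mean(vapply(rows, function(r) {
      if (stats::sd(dff_all[r, ]) == 0) return(NA_real_)
      stats::cor(dff_all[r, ], net_mean)
    }, numeric(1)), na.rm = TRUE)
    out[[s]] <- tibble::tibble(
      subpopulation = s, n_cells = length(cells),
      n_active = act$n_active, pct_active = act$pct_active,
      burst_frequency = bursts$burst_frequency,
      burst_correlation = bc$mean_r,
      cross_network_r = cross,
      nd_flag = act$nd_flag
    )
  }
  dplyr::bind_rows(out)
}
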