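test_that("default recording geometry matches the acquisition protocol", {
  sc <- synth_calcium_recording(n_cells = 10, seed = 1)
  rec <- sc$recording
  expect_equal(ncol(rec$traces), 520) # 260 s at 2 fps
  expect_equal(rec$stim_window, c(481L, 520L)) # terminal 20 s
  expect_error(calcium_recording(matrix(0, 2, 100), fps = 2,
                                 duration_s = 260),
               "round")
  expect_error(calcium_recording(matrix(0, 2, 520), fps = 2,
                                 stim_window = c(500, 530)),
               "inside")
})

test_that("the generator honours activity and synchrony contracts", {
  sc <- synth_calcium_recording(n_cells = 30, active_fraction = 0,
                                seed = 2)
  pre <- sc$recording$traces[, 1:480]
  # no transients before the stimulus: traces stay near baseline
  expect_lt(max(apply(pre, 1, function(x) diff(range(x)))), 0.3)
  sc2 <- synth_calcium_recording(n_cells = 30, sync_prob = 1, seed = 3)
  nb <- length(sc2$truth$burst_times_s)
  active <- sc2$truth$cells$cell[sc2$truth$cells$is_active]
  for (ci in active) {
    expect_equal(length(sc2$truth$events[[ci]]), nb)
  }
  a <- synth_calcium_recording(n_cells = 12, seed = 7)
  b <- synth_calcium_recording(n_cells = 12, seed = 7)
  expect_identical(a$recording$traces, b$recording$traces)
})

test_that("traces are ROI means of the movie", {
  set.seed(17)
  movie <- array(runif(10 * 12 * 20), c(10, 12, 20))
  rois <- matrix(0L, 10, 12)
  rois[2:3, 2:3] <- 1L  # 4-px ROI
  rois[7, 9] <- 2L      # single pixel
  rec <- extract_traces(movie, label_map(rois), fps = 2)
  manual <- vapply(1:20, function(f) mean(movie[2:3, 2:3, f]), numeric(1))
  expect_equal(rec$traces[1, ], manual)
  expect_equal(rec$traces[2, ], movie[7, 9, ])
  flat <- array(0.4, c(5, 5, 8))
  rec2 <- extract_traces(flat, label_map(matrix(1L, 5, 5)), fps = 2)
  expect_equal(as.vector(rec2$traces), rep(0.4, 8))
})

test_that("glutamate gating separates neurons from other cells", {
  for (seed in c(4, 8, 15)) {
    sc <- synth_calcium_recording(seed = seed)
    cls <- classify_glutamate_responders(sc$recording)
    expect_identical(cls$is_neuron, sc$truth$cells$is_neuron)
  }
})

test_that("recordings without a stimulus window retain all cells, flagged", {
  sc <- synth_calcium_recording(n_cells = 10, seed = 5)
  rec <- calcium_recording(sc$recording$traces, fps = 2) # drop the window
  cls <- classify_glutamate_responders(rec)
  expect_true(all(cls$is_neuron))
  expect_identical(attr(cls, "mode"), "no-stimulus")
})

test_that("peak detection finds planted transients and ignores noise", {
  set.seed(18)
  tr <- 1 + rnorm(520, 0, 0.02)
  t_s <- (0:519) / 2
  tr <- tr * (1 + 0.6 * exp(-(pmax(t_s - 100, 0)) / 1.5) * (t_s >= 100))
  pk <- detect_peaks(tr, fps = 2, stim_window = c(481, 520))
  expect_equal(nrow(pk), 1)
  expect_equal(pk$time_s, 100, tolerance = 1.5)
  # pure noise at the default threshold: almost never a peak
  n_fp <- vapply(1:40, function(i) {
    nrow(detect_peaks(1 + rnorm(520, 0, 0.03), 2, c(481, 520)))
  }, numeric(1))
  expect_lte(mean(n_fp > 0), 0.05)
  expect_error(detect_peaks(rep(NA_real_, 520), 2), "NaN")
  expect_error(detect_peaks(rnorm(5), 2), ">= 10")
})

test_that("event counts track the generator's ground truth", {
  sc <- synth_calcium_recording(seed = 6)
  cls <- classify_glutamate_responders(sc$recording)
  trains <- event_trains(sc$recording, cls)
  truth <- sc$truth$cells[match(trains$cell, sc$truth$cells$cell), ]
  err <- abs(trains$n_events - truth$n_events)
  expect_lte(mean(err), 1)   # typical deviation within one event
  expect_true(all(err <= 2)) # bursts < 1.5 s apart can merge at 2 fps
})

test_that("percent active and the ND rule follow the definitions", {
  mk_trains <- function(n_events) {
    out <- tibble::tibble(cell = seq_along(n_events), n_events = n_events,
                          events = lapply(n_events, function(k)
                            if (k > 0) seq_len(k) * 10 else numeric()))
    class(out) <- c("event_trains", class(out))
    out
  }
  silent <- percent_active(mk_trains(rep(0L, 8)))
  expect_equal(silent$pct_active, 0)
  expect_true(silent$nd_flag)
  act <- percent_active(mk_trains(c(rep(1L, 6), rep(0L, 4))))
  expect_equal(act$pct_active, 60)
  expect_false(act$nd_flag)
  four <- percent_active(mk_trains(c(rep(2L, 4), rep(0L, 6))))
  expect_true(four$nd_flag)
})

test_that("network burst detection matches a ground-truth binning oracle", {
  sc <- synth_calcium_recording(seed = 10, sync_prob = 0.95)
  cls <- classify_glutamate_responders(sc$recording)
  trains <- event_trains(sc$recording, cls)
  det <- detect_network_bursts(trains, duration_s = 240)
  oracle <- oracle_burst_count(sc$truth$events, 240, 1, 0.5)
  expect_equal(det$n_bursts, oracle, tolerance = 1)
  # all-silent network: ND
  empty <- trains; empty$n_events <- 0L
  empty$events <- lapply(empty$events, function(x) numeric())
  nd <- detect_network_bursts(empty, 240)
  expect_true(nd$nd_flag)
  # halving the bin width leaves isolated truth bursts intact
  expect_equal(oracle_burst_count(sc$truth$events, 240, 0.5, 0.5),
               oracle, tolerance = 1)
})

test_that("burst correlation has the exact limits and synchrony ordering", {
  # oscillation fast against the 30 s baseline window, so dF/F0 is affine
  base <- 1 + 0.2 * sin((0:519) / 2 * 2 * pi / 8)
  rec <- calcium_recording(rbind(base, base, base), fps = 2,
                           stim_window = c(481, 520))
  cls <- classify_glutamate_responders(rec)
  cls$is_neuron <- TRUE
  bc <- burst_correlation(rec, cls)
  expect_equal(bc$mean_r, 1, tolerance = 1e-9)
  anti <- 2 - base
  rec2 <- calcium_recording(rbind(base, anti), fps = 2,
                            stim_window = c(481, 520))
  cls2 <- classify_glutamate_responders(rec2); cls2$is_neuron <- TRUE
  expect_equal(burst_correlation(rec2, cls2)$mean_r, -1, tolerance = 0.05)
  rs <- vapply(c(0.2, 0.5, 0.9), function(sp) {
    sc <- synth_calcium_recording(sync_prob = sp, seed = 42)
    network_metrics(sc$recording)$burst_correlation
  }, numeric(1))
  expect_true(all(diff(rs) > 0))
})

test_that("network metrics are invariant to positive affine trace scaling", {
  sc <- synth_calcium_recording(n_cells = 20, seed = 20)
  m0 <- network_metrics(sc$recording)
  scaled <- calcium_recording(3 * sc$recording$traces + 2, fps = 2,
                              stim_window = sc$recording$stim_window)
  m1 <- network_metrics(scaled)
  expect_equal(m1$pct_active, m0$pct_active)
  expect_equal(m1$burst_frequency, m0$burst_frequency)
  expect_equal(m1$burst_correlation, m0$burst_correlation, tolerance = 0.02)
})

test_that("subpopulation metrics respect exchangeability and ordering", {
  sc <- synth_calcium_recording(seed = 21)
  sub <- ifelse(seq_len(50) %% 2 == 0, "pos", "neg")
  cls <- classify_glutamate_responders(sc$recording, subpopulation = sub)
  sm <- subpopulation_metrics(sc$recording, cls)
  expect_equal(nrow(sm), 2)
  # both subgroups sampled from the same process: similar activity
  expect_lt(abs(diff(sm$pct_active)), 35)
  expect_true(all(is.finite(sm$cross_network_r)))
  # a single-member subgroup has no pairwise correlation
  sub2 <- rep(NA_character_, 50)
  neurons <- cls$cell[cls$is_neuron]
  sub2[neurons[1]] <- "lonely"
  sub2[neurons[-1]] <- "rest"
  cls2 <- classify_glutamate_responders(sc$recording, subpopulation = sub2)
  sm2 <- subpopulation_metrics(sc$recording, cls2)
  expect_true(is.na(sm2$burst_correlation[sm2$subpopulation == "lonely"]))
})
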