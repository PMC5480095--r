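make_static_movie <- function(n = 64, frames = 10, seed = 22) {
  set.seed(seed)
  frame <- matrix(runif(n * n), n)
  array(rep(frame, frames), c(n, n, frames))
}

test_that("a static movie gives identical kymograph columns", {
  movie <- make_static_movie()
  poly <- cbind(c(5, 55), c(10, 50))
  suppressWarnings(
    kym <- build_kymograph(movie, poly, pixel_size = 0.25,
                           frame_interval_s = 2))
  expect_true(all(abs(kym$map - kym$map[, 1]) < 1e-12))
})

test_that("a 1-px-wide line read at width 1 returns the path intensities", {
  movie <- array(0, c(32, 32, 3))
  movie[16, , ] <- 0.8 # horizontal bright line at y = 16
  poly <- cbind(c(2, 30), c(16, 16))
  suppressWarnings(
    kym <- build_kymograph(movie, poly, width_px = 1, pixel_size = 1,
                           frame_interval_s = 2))
  expect_true(all(abs(kym$map - 0.8) < 1e-9))
})

test_that("manual velocity is pure slope arithmetic", {
  suppressWarnings(
    kym <- kymograph(matrix(0, 50, 30), pixel_size = 0.25,
                     frame_interval_s = 2))
  tr <- measure_velocity(kym, rbind(c(0, 0), c(40, 20)))
  expect_equal(tr$velocity_um_s, 0.25)
  vert <- measure_velocity(kym, rbind(c(10, 0), c(10, 20)))
  expect_equal(vert$velocity_um_s, 0)
  expect_error(measure_velocity(kym, rbind(c(0, 5), c(40, 5))), "frame")
})

test_that("auto tracking recovers the planted comet velocity", {
  cm <- synth_comet_movie(n_comets = 10, velocity_um_s = 0.2, seed = 3)
  kym <- build_kymograph(cm$movie, cm$polyline, pixel_size = cm$pixel_size,
                         frame_interval_s = cm$frame_interval_s)
  tr <- measure_velocity(kym, "auto")
  expect_lt(abs(attr(tr, "mean_velocity_um_s") - 0.2), 0.02)
})

test_that("stationary comets give vertical streaks (zero velocity)", {
  cm <- synth_comet_movie(n_comets = 4, velocity_um_s = 0, seed = 4)
  kym <- build_kymograph(cm$movie, cm$polyline, pixel_size = cm$pixel_size,
                         frame_interval_s = cm$frame_interval_s)
  tr <- measure_velocity(kym, "auto")
  expect_lt(attr(tr, "mean_velocity_um_s"), 0.01)
})

test_that("velocity is invariant to polyline orientation", {
  cm <- synth_comet_movie(n_comets = 6, velocity_um_s = 0.2, seed = 5)
  kf <- build_kymograph(cm$movie, cm$polyline, pixel_size = cm$pixel_size,
                        frame_interval_s = cm$frame_interval_s)
  kr <- build_kymograph(cm$movie, cm$polyline[nrow(cm$polyline):1, ],
                        pixel_size = cm$pixel_size,
                        frame_interval_s = cm$frame_interval_s)
  vf <- attr(measure_velocity(kf, "auto"), "mean_velocity_um_s")
  vr <- attr(measure_velocity(kr, "auto"), "mean_velocity_um_s")
  expect_equal(vf, vr, tolerance = 0.01)
})

test_that("kymograph construction commutes with frame cropping", {
  cm <- synth_comet_movie(n_comets = 5, velocity_um_s = 0.2, seed = 6)
  full <- build_kymograph(cm$movie, cm$polyline, pixel_size = cm$pixel_size,
                          frame_interval_s = cm$frame_interval_s)
  cropped <- build_kymograph(cm$movie[, , 1:15], cm$polyline,
                             pixel_size = cm$pixel_size,
                             frame_interval_s = cm$frame_interval_s)
  expect_equal(cropped$map, full$map[, 1:15])
})

test_that("geometry violations and short paths are reported", {
  movie <- make_static_movie(32, 3)
  expect_error(build_kymograph(movie, cbind(c(-5, 10), c(5, 10))),
               "bounds")
  expect_warning(kymograph(matrix(0, 30, 10), pixel_size = 0.25,
                           frame_interval_s = 2),
                 "20 um")
  cm <- synth_comet_movie(n_comets = 2, seed = 7)
  expect_equal(cm$truth$path_length_um, 25, tolerance = 0.5)
})
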