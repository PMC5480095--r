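test_that("blank images yield an empty label map, not an error", {
  img <- field_image(matrix(0.01, 64, 64), "dapi")
  lm <- segment_nuclei(img, fixed_threshold = 0.1)
  expect_equal(n_objects(lm), 0)
})

test_that("objects below the minimum nucleus area are removed as debris", {
  ps <- default_pixel_size()
  size <- 128
  r80 <- um_to_px(sqrt(80 / pi), ps)  # area 80 um^2 < 90 um^2 cut
  r120 <- um_to_px(sqrt(120 / pi), ps)
  img <- matrix(0.02, size, size)
  img[disc_mask(size, 35, 35, r80)] <- 0.7
  img[disc_mask(size, 90, 90, r120)] <- 0.7
  fi <- field_image(img, "dapi", ps)
  # threshold at half-maximum so the smoothed footprint matches the object
  lm <- segment_nuclei(fi, 0.35)
  expect_equal(n_objects(lm), 1)
  lm_all <- segment_nuclei(fi, 0.35, min_area_um2 = 0)
  expect_equal(n_objects(lm_all), 2)
})

test_that("touching nuclei are split and the count recovered", {
  errs <- vapply(c(1, 7), function(seed) {
    sn <- synth_nuclei_field(60, crowding = 0.3, seed = seed, size_px = 1024)
    n_objects(segment_nuclei(sn$nuclei, 0.1)) - 60
  }, numeric(1))
  expect_true(all(abs(errs) <= 0.02 * 60))
})

test_that("watershed conserves the thresholded foreground exactly", {
  sn <- synth_nuclei_field(40, crowding = 0.4, seed = 11, size_px = 1024)
  lm <- segment_nuclei(sn$nuclei, 0.1)
  unf <- attr(lm, "unfiltered")
  sm <- neurohcs:::gaussian_blur(sn$nuclei$pixels,
                                 um_to_px(1.75, sn$nuclei$pixel_size))
  expect_identical(sum(unf$labels > 0), sum(sm > 0.1))
})

test_that("nucleus count is invariant to a matched intensity offset", {
  sn <- synth_nuclei_field(25, seed = 12, size_px = 512)
  lm0 <- segment_nuclei(sn$nuclei, 0.1)
  shifted <- field_image(sn$nuclei$pixels + 0.2, "dapi",
                         sn$nuclei$pixel_size)
  lm1 <- segment_nuclei(shifted, 0.3)
  expect_equal(n_objects(lm1), n_objects(lm0))
})

test_that("PI classification recovers the planted dead fraction", {
  sn <- synth_nuclei_field(60, dead_fraction = 0.2, seed = 13, size_px = 1024)
  lm <- segment_nuclei(sn$nuclei, 0.1)
  cy <- classify_pi_positive(lm, sn$pi, 0.3)
  expect_equal(cy$n_pi_positive, 12)
  expect_equal(cy$pct_pi_positive, 100 * 12 / cy$n_nuclei,
               tolerance = 1e-12)
  # PI threshold below the global minimum marks every nucleus
  all_pos <- classify_pi_positive(lm, sn$pi, -1)
  expect_equal(all_pos$pct_pi_positive, 100)
  # dark PI channel marks none
  dark <- field_image(matrix(0, 1024, 1024), "pi", sn$pi$pixel_size)
  expect_equal(classify_pi_positive(lm, dark, 0.3)$pct_pi_positive, 0)
})

test_that("a field without nuclei gives an undefined percentage, not zero", {
  lm <- label_map(matrix(0L, 32, 32))
  pi_img <- field_image(matrix(0.1, 32, 32), "pi")
  out <- classify_pi_positive(lm, pi_img, 0.3)
  expect_true(is.na(out$pct_pi_positive))
  expect_equal(out$n_nuclei, 0L)
})

test_that("the nuclei generator honours its determinism and truth contracts", {
  a <- synth_nuclei_field(20, dead_fraction = 0.25, seed = 99, size_px = 256,
                          mean_area_um2 = 60)
  b <- synth_nuclei_field(20, dead_fraction = 0.25, seed = 99, size_px = 256,
                          mean_area_um2 = 60)
  expect_identical(a$nuclei$pixels, b$nuclei$pixels)
  expect_identical(a$pi$pixels, b$pi$pixels)
  expect_equal(sum(a$truth$nuclei$is_dead), 5)
  blank <- synth_nuclei_field(0, seed = 1, size_px = 64)
  expect_equal(nrow(blank$truth$nuclei), 0)
  expect_error(synth_nuclei_field(10, dead_fraction = 1.2), "\\[0, 1\\]")
  # noiseless render: label ground truth re-measures to the truth table
  nl <- synth_nuclei_field(12, seed = 5, size_px = 512, noise_sd = 0,
                           photons = Inf)
  counts <- tabulate(nl$truth$labels[nl$truth$labels > 0], 12)
  expect_equal(px_area_to_um2(counts, default_pixel_size()),
               nl$truth$nuclei$area_um2, tolerance = 0.2)
})
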