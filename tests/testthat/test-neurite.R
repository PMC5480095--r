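test_that("the dual mask recovers faint branches that mask 1 misses", {
  for (seed in c(3, 21)) {
    nf <- synth_neurite_field(total_neurite_length_um = 2000,
                              synapse_density_true = 0, coloc_rho = 0.9,
                              seed = seed, size_px = 512)
    msk <- segment_neurites(subtract_background(nf$tubulin))
    truth <- nf$truth$mask
    rec_union <- sum(msk$mask & truth) / sum(truth)
    rec_m1 <- sum(attr(msk, "mask1") & truth) / sum(truth)
    expect_gte(rec_union, 0.8)
    expect_gte(rec_union, rec_m1)
    # union mask area is never below mask 1 alone
    expect_gte(sum(msk$mask), sum(attr(msk, "mask1")))
  }
})

test_that("mask area is the calibrated true-pixel count", {
  m <- matrix(FALSE, 10, 10); m[2:4, 2:6] <- TRUE
  nm <- neurite_mask(m, pixel_size = 0.5)
  expect_equal(nm$area_um2, 15 * 0.25)
})

test_that("a constant image produces an empty mask with a warning", {
  img <- field_image(matrix(0.2, 64, 64), "tub")
  expect_warning(msk <- segment_neurites(img), "Constant")
  expect_equal(msk$area_um2, 0)
})

test_that("intensity ratios recover planted contrasts inside the mask", {
  set.seed(14)
  m <- matrix(runif(64 * 64) < 0.3, 64, 64)
  nm <- neurite_mask(m)
  den <- field_image(matrix(runif(64 * 64, 0.4, 0.6), 64), "tub")
  expect_equal(intensity_ratio(den, den, nm), 1)
  num2 <- field_image(2 * den$pixels, "acet")
  expect_equal(intensity_ratio(num2, den, nm), 2)
  num06 <- field_image(0.6 * den$pixels, "acet")
  expect_equal(intensity_ratio(num06, den, nm), 0.6, tolerance = 1e-12)
  # undefined cases flagged, not zeroed
  empty <- neurite_mask(matrix(FALSE, 64, 64))
  expect_true(is.na(intensity_ratio(den, den, empty)))
  zero_den <- field_image(matrix(0, 64, 64), "tub")
  expect_true(is.na(intensity_ratio(den, zero_den, nm)))
})
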