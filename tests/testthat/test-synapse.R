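test_that("a blank image contains no spots", {
  img <- field_image(matrix(0.02, 128, 128), "syn")
  spots <- detect_synapse_spots(img)
  expect_equal(nrow(spots), 0)
})

test_that("planted puncta are counted at the planted density", {
  nf <- synth_neurite_field(2000, synapse_density_true = 0.05,
                            coloc_rho = 0.9, seed = 3, size_px = 512)
  spots <- detect_synapse_spots(subtract_background(nf$synaptophysin))
  expect_equal(nrow(spots), nf$truth$n_spots, tolerance = 0.02)
  dens <- synapse_density(spots, neurite_mask(nf$truth$mask))
  expect_equal(dens, nf$truth$synapse_density_true, tolerance = 0.1)
})

test_that("zero planted density renders and detects no spots", {
  nf <- synth_neurite_field(1000, synapse_density_true = 0, coloc_rho = 0.9,
                            seed = 4, size_px = 256)
  expect_equal(nf$truth$n_spots, 0)
  spots <- detect_synapse_spots(subtract_background(nf$synaptophysin))
  expect_lte(nrow(spots), 2) # at most stray noise detections
})

test_that("sub-lobe noise crossings are rejected by the size filter", {
  nf <- synth_neurite_field(2000, synapse_density_true = 0.05,
                            coloc_rho = 0.9, seed = 9, size_px = 512)
  spots <- detect_synapse_spots(subtract_background(nf$synaptophysin))
  expect_gt(attr(spots, "n_rejected"), 0)
  expect_true(all(spots$area_um2 >= 0.75))
})

test_that("synapse density is count over calibrated neurite area", {
  nm <- neurite_mask(matrix(TRUE, 100, 100), pixel_size = sqrt(0.1))
  expect_equal(synapse_density(100, nm), 100 / 1000)
  expect_equal(synapse_density(0, nm), 0)
  empty <- neurite_mask(matrix(FALSE, 10, 10))
  expect_true(is.na(synapse_density(5, empty)))
})
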