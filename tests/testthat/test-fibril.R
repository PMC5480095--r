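test_that("round blobs are never retained as fibrils", {
  ff <- synth_fibril_field(n_fibrils = 0, n_round_blobs = 5, seed = 41,
                           size_px = 512)
  full <- neurite_mask(matrix(TRUE, 512, 512))
  fib <- segment_fibrils(ff$pftaa, full)
  expect_equal(nrow(fib$particles), 0)
  expect_equal(fib$fibril_load_um2, 0)
})

test_that("disjoint rods are all retained and the load matches the truth", {
  ff <- synth_fibril_field(n_fibrils = 3, n_round_blobs = 4, seed = 5,
                           size_px = 512)
  expect_equal(sum(ff$truth$particles$type == "fibril"), 3)
  # generator construction guarantees the shape classes
  expect_true(all(ff$truth$particles$circularity[
    ff$truth$particles$type == "fibril"] < 0.30))
  expect_true(all(ff$truth$particles$circularity[
    ff$truth$particles$type == "blob"] > 0.6))
  fib <- segment_fibrils(ff$pftaa, neurite_mask(ff$mask))
  expect_equal(nrow(fib$particles), 3)
  expect_equal(fib$fibril_load_um2, ff$truth$fibril_area_um2,
               tolerance = 0.05)
})

test_that("rods outside the MT mask contribute nothing to the load", {
  ff <- synth_fibril_field(n_fibrils = 3, seed = 6, size_px = 512)
  none <- neurite_mask(matrix(FALSE, 512, 512))
  fib <- segment_fibrils(ff$pftaa, none)
  expect_equal(fib$fibril_load_um2, 0)
  expect_gt(nrow(fib$particles), 0) # particles exist, just off the mask
})

test_that("relaxing the size or circularity filter never loses particles", {
  ff <- synth_fibril_field(n_fibrils = 4, n_round_blobs = 3, seed = 7,
                           size_px = 512)
  mt <- neurite_mask(matrix(TRUE, 512, 512))
  strict <- segment_fibrils(ff$pftaa, mt, min_area_um2 = 15,
                            circ_range = c(0, 0.30))
  relaxed <- segment_fibrils(ff$pftaa, mt, min_area_um2 = 5,
                             circ_range = c(0, 0.9))
  expect_gte(nrow(relaxed$particles), nrow(strict$particles))
  expect_true(all(strict$particles$label %in% relaxed$particles$label))
})

test_that("centroid-mode intersection is available as an alternative", {
  ff <- synth_fibril_field(n_fibrils = 2, seed = 8, size_px = 512)
  fib <- segment_fibrils(ff$pftaa, neurite_mask(ff$mask), mode = "centroid")
  expect_gt(fib$fibril_load_um2, 0)
})
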