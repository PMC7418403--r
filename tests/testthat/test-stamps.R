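test_that("stamps satisfy their per-class shape contracts across seeds", {
  for (seed in 1:15) {
    rod <- make_cell_stamp("rod", 0.5, seed = seed)
    idx <- which(rod$mask == 1, arr.ind = TRUE)
    expect_gte(micromorph:::axis_ratio_from_coords(idx[, 1], idx[, 2]), 3)

    amo <- make_cell_stamp("amoeboid", 0.5, seed = seed)
    idx <- which(amo$mask == 1, arr.ind = TRUE)
    expect_lt(micromorph:::axis_ratio_from_coords(idx[, 1], idx[, 2]), 1.5)

    dys <- make_cell_stamp("dystrophic", 0.5, seed = seed)
    expect_gte(max(bfs_label_oracle(dys$mask)), 2)

    for (cls in c("ramified", "amoeboid", "hypertrophic", "rod")) {
      st <- make_cell_stamp(cls, 0.5, seed = seed)
      expect_equal(max(bfs_label_oracle(st$mask)), 1)
      expect_gte(sum(st$mask), 1)
    }
  }
})

test_that("the documented dystrophic example stamp is fragmented", {
  st <- make_cell_stamp("dystrophic", 0.5, seed = 7)
  expect_gte(max(bfs_label_oracle(st$mask)), 2)
})

test_that("unknown morphology classes are rejected by name", {
  expect_error(make_cell_stamp("spindle", 0.5), "spindle")
  expect_error(make_cell_stamp("rod", pixel_scale = 0))
})

test_that("stamps are reproducible from a seed and scale with pixel size", {
  a <- make_cell_stamp("ramified", 0.5, seed = 5)
  b <- make_cell_stamp("ramified", 0.5, seed = 5)
  expect_identical(a$mask, b$mask)
  # halving the um/px doubles the raster footprint, roughly
  big <- make_cell_stamp("amoeboid", 0.25, seed = 5)
  small <- make_cell_stamp("amoeboid", 0.5, seed = 5)
  expect_gt(sum(big$mask) / sum(small$mask), 3)
  expect_lt(sum(big$mask) / sum(small$mask), 5)
})
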