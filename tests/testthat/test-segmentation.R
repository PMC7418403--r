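test_that("an all-white raster yields an empty mask", {
  img <- array(1, c(20, 20, 3))
  expect_equal(sum(dab_mask(img)), 0)
})

test_that("a pure DAB-coloured blob is recovered exactly", {
  img <- array(1, c(40, 40, 3))
  blob <- matrix(0L, 40, 40)
  blob[10:30, 10:30][disc_mask(8) == 1] <- 1L
  rgb <- micromorph:::hsv_to_rgb(15 / 255, 70 / 255, 0.45)
  for (ch in 1:3) {
    pl <- img[, , ch]; pl[blob == 1] <- rgb[ch]; img[, , ch] <- pl
  }
  expect_equal(dab_mask(img), blob)
})

test_that("non-RGB input is rejected with a format error", {
  expect_error(dab_mask(matrix(1, 10, 10)), "RGB")
  expect_error(dab_mask(array(1, c(10, 10, 4))), "RGB")
})

test_that("threshold constructor enforces its invariants", {
  expect_error(hsv_thresholds(hue_min = 40, hue_max = 10), "hue_min")
  expect_error(hsv_thresholds(sat_min = 90, sat_max = 10), "sat_min")
  expect_error(hsv_thresholds(hue_max = 300), "255")
})

test_that("widening the saturation band never shrinks the mask", {
  rr <- render_region(region_spec(image_shape = c(200, 200),
                                  target_burden = 6, seed = 5))
  narrow <- dab_mask(rr$image$pixels, hsv_thresholds(sat_min = 65,
                                                     sat_max = 75))
  wide <- dab_mask(rr$image$pixels, hsv_thresholds(sat_min = 55,
                                                   sat_max = 90))
  expect_true(all(wide[narrow == 1] == 1))
})

test_that("size exclusion keeps exactly the cells above the cutoff", {
  # one 8-px disc (4 um at 0.5 um/px) is excluded entirely
  m8 <- disc_mask(4)
  expect_length(extract_cells(m8, min_diameter = 5, pixel_scale = 0.5), 0)
  # of diameters {8, 12, 20, 40} px exactly three survive the 10-px cutoff
  m <- discs_fixture(c(8, 12, 20, 40))
  cells <- extract_cells(m, min_diameter = 5, pixel_scale = 0.5)
  expect_length(cells, 3)
})

test_that("raising the exclusion diameter never increases the cell count", {
  set.seed(31)
  m <- matrix(as.integer(matrix(runif(64 * 64), 64) > 0.75), 64)
  n_prev <- Inf
  for (d in c(0, 2, 4, 6, 8)) {
    n <- length(extract_cells(m, min_diameter = d, pixel_scale = 0.5))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("component labelling matches an independent BFS oracle", {
  set.seed(17)
  for (i in 1:100) {
    m <- matrix(as.integer(matrix(runif(64 * 64), 64) > 0.7), 64)
    # both label components in column-major scan order, so the label
    # images must agree exactly
    expect_identical(label_components(m), bfs_label_oracle(m))
  }
})

test_that("measured cell features respect their invariants", {
  m <- discs_fixture(c(12, 20, 40))
  cells <- extract_cells(m, min_diameter = 5, pixel_scale = 0.5)
  tab <- cells_table(cells)
  expect_true(all(tab$area_um2 > 0))
  expect_true(all(tab$perimeter_um > 0))
  expect_true(all(tab$circularity >= 0 & tab$circularity <= 1))
  expect_equal(tab$equiv_diam_um, 2 * sqrt(tab$area_um2 / pi))
})
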