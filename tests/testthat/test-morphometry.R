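square_fixture <- function(side_obj, canvas = 110) {
  m <- matrix(0L, canvas, canvas)
  m[6:(5 + side_obj), 6:(5 + side_obj)] <- 1L
  m
}

test_that("areal fraction is exact arithmetic on the mask", {
  expect_equal(areal_fraction(matrix(0L, 50, 50)), 0)
  m <- matrix(0L, 1000, 1000)
  m[seq_len(250000)] <- 1L
  expect_equal(areal_fraction(m), 25)
  sq <- data.frame(index = 0, row = 1, col = 1, side = 1000)
  expect_equal(areal_fraction(m, sq), 25)
  expect_error(areal_fraction(matrix(0L, 10, 10), sq), "side")
})

test_that("circularity of canonical shapes matches theory", {
  # rasterized large disc: estimator error stays within 5% of a circle
  disc <- disc_mask(50)
  cell <- extract_cells(disc, min_diameter = 0, pixel_scale = 0.5)[[1]]
  expect_gte(cell_circularity(cell), 0.95)
  # rasterized square: pi/4 within 0.02
  sqc <- extract_cells(square_fixture(100), min_diameter = 0,
                       pixel_scale = 0.5)[[1]]
  expect_equal(cell_circularity(sqc), pi / 4, tolerance = 0.02 / (pi / 4))
})

test_that("perimeter of a 100x100 px square is 200 um within 2%", {
  cell <- extract_cells(square_fixture(100), min_diameter = 0,
                        pixel_scale = 0.5)[[1]]
  expect_equal(cell_perimeter(cell, 0.5), 200, tolerance = 0.02)
})

test_that("a one-pixel object has the documented degenerate values", {
  m <- matrix(0L, 5, 5); m[3, 3] <- 1L
  cell <- extract_cells(m, min_diameter = 0, pixel_scale = 0.5)[[1]]
  expect_equal(cell$perimeter_px, pi)
  expect_equal(cell_circularity(cell), 1)
})

test_that("scaling a disc by two doubles its perimeter within 2%", {
  p <- vapply(c(25, 50), function(r) {
    cell <- extract_cells(disc_mask(r), min_diameter = 0,
                          pixel_scale = 0.5)[[1]]
    cell$perimeter_px
  }, 0)
  expect_equal(p[2] / p[1], 2, tolerance = 0.02)
})

test_that("region aggregation is mean-of-means over non-empty squares", {
  sq <- data.frame(square = 0:9, burden = 1:10,
                   mean_circularity = rep(0.5, 10),
                   mean_perimeter = rep(30, 10), n_cells = rep(2, 10))
  agg <- aggregate_region(sq)
  expect_equal(agg$burden, 5.5)

  two <- data.frame(square = 0:1, burden = c(1, 1),
                    mean_circularity = c(0.2, 0.8),
                    mean_perimeter = c(10, 20), n_cells = c(1, 99))
  agg2 <- aggregate_region(two)
  expect_equal(agg2$circularity, 0.5) # not the pooled-cell mean 0.794

  empty <- data.frame(square = 0:2, burden = c(0, 0, 0),
                      mean_circularity = rep(NA_real_, 3),
                      mean_perimeter = rep(NA_real_, 3), n_cells = rep(0, 3))
  agg3 <- aggregate_region(empty)
  expect_equal(agg3$burden, 0)
  expect_true(is.na(agg3$circularity))
  expect_equal(agg3$n_squares_used, 0)
})

test_that("aggregating identical squares is idempotent", {
  sq <- data.frame(square = 0:9, burden = rep(4.2, 10),
                   mean_circularity = rep(0.37, 10),
                   mean_perimeter = rep(55.5, 10), n_cells = rep(7, 10))
  agg <- aggregate_region(sq)
  expect_equal(agg$burden, 4.2)
  expect_equal(agg$circularity, 0.37)
  expect_equal(agg$perimeter, 55.5)
})

test_that("burden basis switch uses raw versus filtered masks", {
  m <- discs_fixture(c(8, 20))
  cells <- extract_cells(m, min_diameter = 5, pixel_scale = 0.5)
  raw <- square_metrics(m, cells, burden_basis = "raw")
  fil <- square_metrics(m, cells, burden_basis = "filtered")
  expect_gt(raw$burden, fil$burden) # the 8-px disc counts only in raw
  expect_equal(fil$burden, 100 * sum(cells[[1]]$area_px) / length(m))
})

test_that("shape metrics separate amoeboid from ramified regions", {
  for (seed in 1:3) {
    circ_of <- function(mix) {
      rr <- render_region(region_spec(image_shape = c(400, 400),
                                      target_burden = 4, class_mix = mix,
                                      seed = seed))
      m <- dab_mask(rr$image$pixels)
      cells <- extract_cells(m, 5, 0.5)
      c(mean(vapply(cells, `[[`, 1, "circularity")),
        mean(vapply(cells, `[[`, 1, "perimeter_um")))
    }
    amo <- circ_of(c(amoeboid = 1))
    ram <- circ_of(c(ramified = 1))
    expect_gte(amo[1] - ram[1], 0.3) # amoeboid rounder by >= 0.3
    expect_gt(ram[2], amo[2])        # ramified cells have larger perimeter
  }
})
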