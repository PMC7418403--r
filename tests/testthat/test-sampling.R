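test_that("an exactly square-sized ROI forces the single placement", {
  sq <- sample_squares(roi_rect(100, 100), n = 1, side = 100, seed = 1)
  expect_equal(sq$row, 1)
  expect_equal(sq$col, 1)
})

test_that("square sampling is reproducible from a seed", {
  a <- sample_squares(roi_rect(700, 700), n = 10, side = 100, seed = 42)
  b <- sample_squares(roi_rect(700, 700), n = 10, side = 100, seed = 42)
  expect_identical(a, b)
})

test_that("disjoint mode yields pairwise intersection area zero", {
  sq <- sample_squares(roi_rect(700, 700), n = 10, side = 100, seed = 7)
  for (i in 1:9) for (j in (i + 1):10) {
    a <- c(sq$row[i], sq$col[i], sq$side[i])
    b <- c(sq$row[j], sq$col[j], sq$side[j])
    expect_equal(rect_intersection_oracle(a, b), 0)
  }
})

test_that("every returned square is contained in the ROI polygon", {
  # L-shaped ROI
  poly <- cbind(row = c(0.5, 0.5, 200.5, 200.5, 400.5, 400.5),
                col = c(0.5, 400.5, 400.5, 200.5, 200.5, 0.5))
  sq <- sample_squares(poly, n = 8, side = 60, seed = 3)
  for (i in seq_len(nrow(sq))) {
    r <- sq$row[i]; c <- sq$col[i]; s <- sq$side[i]
    corners_r <- c(r, r, r + s - 1, r + s - 1)
    corners_c <- c(c, c + s - 1, c, c + s - 1)
    expect_true(all(point_in_polygon(corners_r, corners_c, poly)))
  }
})

test_that("top-left positions are uniform over the admissible set", {
  # 419x419 ROI with side 100 admits a 320x320 grid; bin into 4x4 cells
  sq <- sample_squares(roi_rect(419, 419), n = 10000, side = 100, seed = 4,
                       disjoint = FALSE)
  br <- cut(sq$row, c(0, 80, 160, 240, 320))
  bc <- cut(sq$col, c(0, 80, 160, 240, 320))
  p <- suppressWarnings(stats::chisq.test(table(br, bc))$p.value)
  expect_gt(p, 0.01)
})

test_that("undersized ROIs and jammed disjoint placements raise clear errors", {
  expect_error(sample_squares(roi_rect(80, 80), n = 1, side = 100),
               "available extent")
  # 10 disjoint 100-px squares at ~57% coverage sit at the jamming limit
  expect_error(sample_squares(roi_rect(419, 419), n = 10, side = 100,
                              seed = 5, max_tries = 2000),
               "overlap mode")
})

test_that("GeoJSON-style polygon files round trip", {
  poly <- list(type = "Polygon",
               coordinates = list(list(c(0.5, 0.5), c(200.5, 0.5),
                                       c(200.5, 150.5), c(0.5, 150.5))))
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(poly, path, auto_unbox = TRUE)
  back <- read_roi_polygon(path)
  expect_equal(back[, "row"], c(0.5, 0.5, 150.5, 150.5))
  expect_equal(back[, "col"], c(0.5, 200.5, 200.5, 0.5))
  unlink(path)
})
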