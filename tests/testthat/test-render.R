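test_that("a zero-burden spec renders an image with no DAB pixels", {
  rr <- render_region(region_spec(image_shape = c(200, 200),
                                  target_burden = 0, seed = 1))
  expect_equal(rr$truth$planted_burden, 0)
  expect_equal(sum(dab_mask(rr$image$pixels)), 0)
})

test_that("rendering is bit-reproducible from the spec", {
  sp <- region_spec(image_shape = c(300, 300), target_burden = 5, seed = 42)
  expect_identical(render_region(sp)$image$pixels,
                   render_region(sp)$image$pixels)
})

test_that("realised burden lands within 10% relative of the target", {
  for (seed in 1:4) {
    sp <- region_spec(image_shape = c(400, 400), target_burden = 5,
                      seed = seed)
    rr <- render_region(sp)
    expect_gte(rr$truth$planted_burden, 4.5 - 1e-9)
    expect_lte(rr$truth$planted_burden, 5.5 + 1e-9)
  }
})

test_that("stored ground-truth burden equals the rendered foreground", {
  rr <- render_region(region_spec(image_shape = c(300, 300),
                                  target_burden = 8, seed = 9))
  recomputed <- 100 * sum(rr$truth$mask) / length(rr$truth$mask)
  expect_equal(rr$truth$planted_burden, recomputed, tolerance = 1e-12)
})

test_that("rendered colours land inside the detector bands with margin", {
  rr <- render_region(region_spec(image_shape = c(300, 300),
                                  target_burden = 6, seed = 3))
  hsv <- rgb_to_hsv255(rr$image$pixels)
  fg <- rr$truth$mask == 1
  expect_true(all(hsv[, , 1][fg] >= 0 & hsv[, , 1][fg] <= 30))
  expect_true(all(hsv[, , 2][fg] >= 60 & hsv[, , 2][fg] <= 80))
  # background/nuclei never enter both bands at once
  bg_in <- (hsv[, , 1] >= 0 & hsv[, , 1] <= 30 &
            hsv[, , 2] >= 60 & hsv[, , 2] <= 80) & !fg
  expect_equal(sum(bg_in), 0)
})

test_that("infeasible burden targets raise an explicit error", {
  expect_error(render_region(region_spec(image_shape = c(80, 80),
                                         target_burden = 95, seed = 1)),
               "infeasible")
})

test_that("raising the amoeboid share raises planted mean circularity", {
  mean_circ <- function(amo, seed) {
    mix <- c(ramified = 1 - amo, amoeboid = amo)
    rr <- render_region(region_spec(image_shape = c(400, 400),
                                    target_burden = 4, class_mix = mix,
                                    seed = seed))
    mean(rr$truth$planted_cells$circularity)
  }
  for (seed in 1:3) {
    lo <- mean_circ(0.1, seed)
    hi <- mean_circ(0.9, seed)
    expect_gt(hi, lo)
  }
})

test_that("planted dystrophic fraction is non-decreasing in severity", {
  frac <- vapply(1:5, function(sev) {
    rr <- render_region(region_spec(image_shape = c(560, 560),
                                    layout = "spaced", n_cells = 25,
                                    dystrophy_severity = sev, seed = 11))
    mean(rr$truth$planted_cells$is_dystrophic)
  }, 0)
  expect_true(all(diff(frac) >= 0))
  expect_equal(frac[1], 0)
  expect_equal(frac[5], 1)
})

test_that("region images survive a TIFF round trip unchanged", {
  rr <- render_region(region_spec(image_shape = c(120, 120),
                                  target_burden = 3, seed = 2))
  path <- tempfile(fileext = ".tif")
  write_region_image(rr$image, path)
  back <- read_region_image(path, pixel_scale = 0.5)
  expect_equal(back$pixels, rr$image$pixels, tolerance = 1e-9)
  unlink(path)
})
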