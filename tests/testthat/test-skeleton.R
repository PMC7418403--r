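test_that("a straight bar skeletonises to two endpoints with no tortuosity", {
  m <- matrix(0L, 20, 110)
  m[9:11, 6:105] <- 1L
  sk <- skeletonize_cell(m, pixel_scale = 0.5)
  expect_equal(sk$n_endpoints, 2)
  expect_equal(sk$n_junctions, 0)
  expect_lt(sk$tortuosity, 1.05)
  expect_equal(sk$n_fragments, 1)
})

test_that("a filled disc reads as soma with negligible process length", {
  m <- disc_mask(20)
  sk <- skeletonize_cell(m, pixel_scale = 0.5)
  expect_true(sk$soma_detected)
  expect_gte(sk$soma_diameter, 7)
  # skeleton of a disc is tiny relative to its size
  expect_lt(sk$total_process_length, 2 * 20 * 0.5)
})

test_that("skeleton endpoints recover planted branch tips within one", {
  hits <- 0; total <- 0
  for (seed in 1:12) {
    st <- make_cell_stamp("ramified", 0.5, seed = seed)
    sk <- skeletonize_cell(st$mask, pixel_scale = 0.5)
    total <- total + 1
    if (abs(sk$n_endpoints - st$n_tips) <= 1) hits <- hits + 1
  }
  expect_gte(hits / total, 0.8)
})

test_that("fragment counts follow the mask's component structure", {
  m <- discs_fixture(c(14, 14, 14))
  sk <- skeletonize_cell(m, pixel_scale = 0.5)
  expect_equal(sk$n_fragments, 3)
  expect_gte(sk$tortuosity, 1)
  expect_gte(sk$total_process_length, 0)
})

test_that("process width tracks the drawn process thickness", {
  thin <- make_cell_stamp("ramified", 0.5, seed = 2)
  thick <- make_cell_stamp("hypertrophic", 0.5, seed = 2)
  w_thin <- skeletonize_cell(thin$mask, 0.5)$mean_process_width
  w_thick <- skeletonize_cell(thick$mask, 0.5)$mean_process_width
  expect_lt(w_thin, 2)
  expect_gte(w_thick, 2)
})
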