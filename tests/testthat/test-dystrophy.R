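classified_df <- function(n_dys, n_norm, soma_frac = 1) {
  n <- n_dys + n_norm
  data.frame(
    cluster = seq_len(n),
    morph_class = c(rep("dystrophic", n_dys), rep("ramified", n_norm)),
    soma_detected = c(rep(TRUE, round(soma_frac * n_dys)),
                      rep(FALSE, n_dys - round(soma_frac * n_dys)),
                      rep(TRUE, n_norm)))
}

test_that("the ordinal score mapping follows the rubric boundaries", {
  expect_equal(score_dystrophy(classified_df(0, 20))$score, 1L)
  expect_equal(score_dystrophy(classified_df(6, 14))$score, 2L)  # f = 0.3
  expect_equal(score_dystrophy(classified_df(14, 6))$score, 3L)  # f = 0.7
  expect_equal(score_dystrophy(classified_df(20, 0, 0.8))$score, 4L)
  expect_equal(score_dystrophy(classified_df(20, 0, 0.1))$score, 5L)
  # exactly half dystrophic is still mild (at least half non-dystrophic)
  expect_equal(score_dystrophy(classified_df(10, 10))$score, 2L)
})

test_that("punctate staining forces the very-severe score", {
  expect_equal(score_dystrophy(classified_df(2, 18), punctate = 0.6)$score,
               5L)
  # no cells at all: punctate staining scores 5, clean emptiness is undefined
  none <- classified_df(0, 0)
  expect_equal(score_dystrophy(none, punctate = 0.7)$score, 5L)
  und <- score_dystrophy(none, punctate = 0.1)
  expect_true(is.na(und$score))
  expect_false(und$defined)
})

test_that("the score is monotone in the dystrophic fraction", {
  prev <- 0L
  for (k in 0:20) {
    s <- score_dystrophy(classified_df(k, 20 - k, soma_frac = 0.5))$score
    expect_gte(s, prev)
    prev <- s
  }
})

test_that("presence calls follow the at-least-one-cell rule", {
  none <- data.frame(morph_class = rep("ramified", 5))
  p0 <- morphology_presence(none)
  expect_false(p0$rod_present)
  one <- data.frame(morph_class = c(rep("ramified", 9), "rod"))
  expect_true(morphology_presence(one)$rod_present)
  many <- data.frame(morph_class = rep("hypertrophic", 25))
  pm <- morphology_presence(many)
  expect_true(pm$hypertrophic_present)
  expect_true(pm$hypertrophic_frequent)
  expect_false(morphology_presence(one)$rod_frequent)
})

test_that("generator stamps classify to their archetypes", {
  rod <- make_cell_stamp("rod", 0.5, seed = 3)
  cl <- mask_as_cluster(rod$mask)
  expect_equal(classify_cell(cl, skeletonize_cell(cl)), "rod")
  dys <- make_cell_stamp("dystrophic", 0.5, seed = 3)
  cl2 <- mask_as_cluster(dys$mask)
  expect_equal(classify_cell(cl2, skeletonize_cell(cl2)), "dystrophic")
  amo <- make_cell_stamp("amoeboid", 0.5, seed = 3)
  cl3 <- mask_as_cluster(amo$mask)
  expect_equal(classify_cell(cl3, skeletonize_cell(cl3)), "amoeboid")
})

test_that("punctate index is the small-component area fraction", {
  expect_equal(punctate_index(matrix(0L, 30, 30)), 0)
  m <- discs_fixture(c(6, 20)) # 6-px disc is debris, 20-px disc a cell
  q <- punctate_index(m, pixel_scale = 0.5, min_diameter = 5)
  areas <- tabulate(bfs_label_oracle(m)[bfs_label_oracle(m) > 0])
  expect_equal(q, min(areas) / sum(areas))
})

test_that("fragment linking groups split cells and keeps neighbours apart", {
  # a fragmented cell: two blobs 4 px apart; a distinct cell 40 px away
  m <- matrix(0L, 60, 120)
  m[20:30, 10:20] <- 1L
  m[20:30, 25:35] <- 1L   # 4-px gap: same cell cluster
  m[20:30, 76:86] <- 1L   # far away: separate cell
  cells <- extract_cells(m, min_diameter = 5, pixel_scale = 0.5)
  expect_length(cells, 3)
  clusters <- cluster_cells(cells, dim(m), pixel_scale = 0.5,
                            link_radius = 3)
  expect_length(clusters, 2)
  sizes <- sort(vapply(clusters, function(x) length(x$members), 0L))
  expect_equal(sizes, c(1L, 2L))
})

test_that("dystrophy scoring refuses non-Iba1 markers", {
  rr <- render_region(region_spec(image_shape = c(200, 200),
                                  target_burden = 2, seed = 1))
  img <- rr$image
  img$marker <- "CD68"
  expect_error(analyze_region_image(img, n_squares = 1, side = 200,
                                    dystrophy = TRUE),
               "Iba1")
})
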