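test_that("Kruskal-Wallis handles degenerate and textbook inputs", {
  expect_equal(kruskal_wallis(rep(3, 9), rep(1:3, 3))$statistic, 0)
  expect_equal(kruskal_wallis(rep(3, 9), rep(1:3, 3))$p_value, 1)
  kw <- kruskal_wallis(1:9, rep(1:3, each = 3), method = "exact")
  expect_equal(kw$statistic, 7.2, tolerance = 1e-12)
  expect_equal(kw$p_value, brute_kw_p(1:9, rep(1:3, each = 3)),
               tolerance = 1e-12)
  expect_error(kruskal_wallis(1:5, c(1, 1, 1, 1, 1)), "2 groups")
})

test_that("asymptotic Kruskal-Wallis agrees with the base implementation", {
  set.seed(11)
  for (i in 1:25) {
    x <- round(rnorm(24), 1)
    g <- factor(sample(1:3, 24, replace = TRUE))
    if (nlevels(droplevels(g)) < 3) next
    ours <- kruskal_wallis(x, g, method = "asymptotic")
    base <- stats::kruskal.test(x, g)
    expect_equal(ours$statistic, unname(base$statistic), tolerance = 1e-12)
    expect_equal(ours$p_value, base$p.value, tolerance = 1e-12)
  }
})

test_that("Dunn pairs behave on identical groups and count combinations", {
  dn <- dunn_posthoc(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(dn$z[1], 0)
  expect_equal(dn$p_value[1], 1)
  dn4 <- dunn_posthoc(rnorm(20), rep(1:4, 5))
  expect_equal(nrow(dn4), 4 * 3 / 2)
  expect_error(dunn_posthoc(1:5, rep(1, 5)), "2 groups")
})

test_that("exact Dunn p-values match full permutation enumeration", {
  set.seed(21)
  for (i in 1:5) {
    x <- sample(1:5, 6, replace = TRUE)
    g <- c(1, 1, 2, 2, 3, 3)
    dn <- dunn_posthoc(x, g, method = "exact")
    expect_equal(dn$p_value, brute_dunn_all(x, g), tolerance = 1e-9)
  }
})

test_that("rank-sum matches its examples and the enumeration oracle", {
  rs <- rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(rs$statistic, 0)
  expect_equal(rs$p_value, 0.1)
  expect_equal(rank_sum(c(2, 2, 5), c(2, 2, 5))$p_value, 1)
  set.seed(5)
  for (i in 1:60) {
    a <- sample(1:6, sample(2:6, 1), replace = TRUE)
    b <- sample(1:6, sample(2:6, 1), replace = TRUE)
    expect_equal(rank_sum(a, b, method = "exact")$p_value,
                 brute_ranksum_p(a, b), tolerance = 1e-12)
  }
})

test_that("signed-rank handles zeros, ties and the all-positive example", {
  d <- wilcoxon_signed_rank(rep(0, 6))
  expect_equal(d$p_value, 1)
  expect_true(d$degenerate)
  expect_equal(wilcoxon_signed_rank(c(1, 2, 3, 4, 5))$p_value, 1 / 16)
  set.seed(6)
  for (i in 1:60) {
    dd <- sample(c(-4:-1, 1:4), sample(3:11, 1), replace = TRUE)
    expect_equal(wilcoxon_signed_rank(dd, method = "exact")$p_value,
                 brute_signedrank_p(dd), tolerance = 1e-12)
  }
})

test_that("paired signed-rank drops zero differences", {
  x <- c(1, 2, 3, 4, 5); y <- c(1, 2, 3, 1, 1)
  t <- wilcoxon_signed_rank(x, y)
  expect_equal(t$n_used, 2L)
})

test_that("Fisher's exact test matches enumeration and rejects bad input", {
  expect_equal(fisher_exact(matrix(c(1, 1, 1, 1), 2))$p_value, 1)
  expect_equal(fisher_exact(matrix(c(5, 0, 0, 5), 2))$p_value, 2 / 252,
               tolerance = 1e-9)
  set.seed(7)
  for (i in 1:60) {
    tab <- matrix(sample(0:8, 4, replace = TRUE), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact(tab)$p_value, brute_fisher_p(tab),
                 tolerance = 1e-7)
  }
  expect_error(fisher_exact(matrix(c(0, 0, 1, 2), 2)), "margin")
  expect_error(fisher_exact(matrix(c(0.5, 1, 1, 2), 2)), "integer")
})

test_that("exact statistics are invariant to input order", {
  set.seed(8)
  a <- sample(1:9, 5, replace = TRUE); b <- sample(1:9, 5, replace = TRUE)
  expect_equal(rank_sum(a, b, method = "exact")$p_value,
               rank_sum(rev(a), rev(b), method = "exact")$p_value)
  d <- c(3, -1, 2, -4, 5)
  expect_equal(wilcoxon_signed_rank(d, method = "exact")$p_value,
               wilcoxon_signed_rank(rev(d), method = "exact")$p_value)
})
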