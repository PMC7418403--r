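test_that("the study configuration yields 60 cases in the printed groups", {
  co <- make_synthetic_cohort(cohort_config_study(seed = 2), render = FALSE)
  cases <- co$cases
  expect_equal(nrow(cases), 60)
  expect_equal(sum(cases$level1 == "FTLD"), 50)
  expect_equal(sum(cases$level1 == "AD"), 5)
  expect_equal(sum(cases$level1 == "Control"), 5)
  expect_equal(sum(cases$level2 == "FTLD-tau", na.rm = TRUE), 20)
  expect_equal(sum(cases$level2 == "FTLD-TDP", na.rm = TRUE), 26)
  expect_equal(sum(cases$level2 == "FTLD-FUS", na.rm = TRUE), 4)
  expect_equal(sum(cases$level4 == "FTLD-TDPA", na.rm = TRUE), 16)
  expect_equal(sum(cases$genetic == "genetic", na.rm = TRUE), 19)
  expect_equal(sum(cases$genetic == "sporadic", na.rm = TRUE), 31)
  # the genetic-comparison C9orf72 group holds TDPA cases only
  c9 <- cases$level6 == "FTLD-C9orf72" & !is.na(cases$level6)
  expect_true(all(cases$level4[c9] == "FTLD-TDPA"))
  expect_equal(sum(c9), 5)
})

test_that("a small cohort produces the expected record and image counts", {
  cfg <- cohort_config_demo(n_per_group = 3, seed = 1)
  co <- make_synthetic_cohort(cfg, render = TRUE)
  expect_equal(nrow(co$cases), 6)
  expect_length(co$regions, 24) # 6 cases x 4 regions x 1 marker
})

test_that("case records are reproducible from the seed", {
  a <- make_case_records(cohort_config_study(seed = 9))
  b <- make_case_records(cohort_config_study(seed = 9))
  expect_identical(a, b)
  c2 <- make_case_records(cohort_config_study(seed = 10))
  expect_false(identical(a, c2))
})

test_that("demographics are drawn inside the configured ranges", {
  cases <- make_case_records(cohort_config_study(seed = 3))
  ctrl <- cases[cases$level1 == "Control", ]
  expect_true(all(is.na(ctrl$aao)))
  expect_true(all(ctrl$aad >= 38 & ctrl$aad <= 80))
  fus <- cases[cases$group == "FTLD-FUS", ]
  expect_true(all(fus$aao >= 40 & fus$aao <= 51))
  expect_true(all(cases$sex %in% c("M", "F")))
})

test_that("hierarchy violations are rejected by name", {
  cases <- make_case_records(cohort_config_study(seed = 1))
  bad <- cases
  i <- which(bad$level4 == "FTLD-TDPC")[1]
  bad$genetic[i] <- "genetic"
  expect_error(validate_case_records(bad), "sporadic")
  bad2 <- cases
  j <- which(bad2$level4 == "FTLD-TDPB")[1]
  bad2$level6[j] <- "FTLD-C9orf72"
  expect_error(validate_case_records(bad2), "FTLD-TDPA")
  bad3 <- cases
  k <- which(bad3$level1 == "Control")[1]
  bad3$aao[k] <- 65
  expect_error(validate_case_records(bad3), "onset")
})

test_that("level groupings follow the six-level design", {
  cases <- make_case_records(cohort_config_study(seed = 4))
  expect_equal(nlevels(level_groups(cases, 1)), 3)
  expect_equal(nlevels(level_groups(cases, 2)), 5)
  l5 <- level_groups(cases, 5)
  expect_setequal(levels(l5), c("Control", "Sporadic FTLD-TDPA",
                                "FTLD-GRN", "FTLD-C9orf72"))
  expect_equal(sum(!is.na(l5)), 20) # 5 controls + 15 TDPA subtype cases
  l6 <- level_groups(cases, 6)
  expect_setequal(levels(l6), c("Control", "FTLD-GRN", "FTLD-C9orf72",
                                "FTLD-MAPT"))
})

test_that("level comparisons produce the combinatorially right output", {
  set.seed(12)
  cases <- make_case_records(cohort_config_study(seed = 4))
  metrics <- expand.grid(case_id = cases$case_id,
                         marker = "Iba1", region = c("FG", "FW", "TG", "TW"),
                         stringsAsFactors = FALSE)
  metrics$burden <- runif(nrow(metrics), 1, 8)
  metrics$circularity <- runif(nrow(metrics), 0.2, 0.8)
  metrics$perimeter <- runif(nrow(metrics), 20, 80)
  metrics$dystrophy_score <- sample(1:5, nrow(metrics), replace = TRUE)
  lr <- run_level(metrics, cases, 2)
  res <- lr$results
  # k = 5 groups: Dunn emits k(k-1)/2 pairs per metric x region
  dunn_fg <- res[res$test == "dunn" & res$metric == "burden" &
                   res$region == "FG", ]
  expect_equal(nrow(dunn_fg), 10)
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  expect_true(all(c("results", "heatmaps") %in% names(lr)))
  hm <- lr$heatmaps[["burden|Iba1"]]
  expect_equal(colnames(hm$between), c("FG", "FW", "TG", "TW"))
  expect_true(all(hm$between_class %in%
                    c("p<0.01", "0.01-0.05", ">=0.05", NA)))
})

test_that("two identical groups rarely reach significance under the null", {
  set.seed(33)
  hits <- 0; B <- 200
  for (i in 1:B) {
    t <- rank_sum(rnorm(10), rnorm(10))
    if (t$p_value < 0.05) hits <- hits + 1
  }
  expect_lte(hits / B, 0.1) # about the nominal 5% false-positive rate
})
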