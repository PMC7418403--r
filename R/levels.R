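LEVEL_NAMES <- c("overall groups", "main FTLD subtypes",
                 "FTLD-tau subtypes", "FTLD-TDP subtypes",
                 "sporadic/genetic FTLD-TDPA", "genetic FTLD subtypes")

#' Group labels of the cases at one comparison level
#'
#' @param cases case-record data.frame.
#' @param level integer 1-6.
#' @return factor of group labels; NA for cases outside the level's
#'   universe.
#' @export
level_groups <- function(cases, level) {
  stopifnot(level %in% 1:6)
  factor(cases[[paste0("level", level)]])
}

sig_class <- function(p) {
  cut(p, breaks = c(-Inf, 0.01, 0.05, Inf),
      labels = c("p<0.01", "0.01-0.05", ">=0.05"), right = FALSE)
}

# between-group comparison of one metric vector (per case) across groups
compare_groups <- function(values, groups, label, marker, region, level,
                           adjust = "none") {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- droplevels(factor(groups[ok]))
  k <- nlevels(groups)
  if (k < 2 || length(values) < 3) return(NULL)
  rows <- list()
  if (k == 2) {
    sp <- split(values, groups)
    t <- rank_sum(sp[[1]], sp[[2]])
    rows[[1]] <- data.frame(
      level = level, metric = label, marker = marker, region = region,
      test = "rank_sum", group1 = levels(groups)[1],
      group2 = levels(groups)[2], statistic = t$statistic,
      p_value = t$p_value, n = paste(lengths(sp), collapse = "/"))
  } else {
    kw <- kruskal_wallis(values, groups)
    rows[[1]] <- data.frame(
      level = level, metric = label, marker = marker, region = region,
      test = "kruskal_wallis", group1 = "all", group2 = "all",
      statistic = kw$statistic, p_value = kw$p_value,
      n = paste(kw$n, collapse = "/"))
    dn <- dunn_posthoc(values, groups, adjust = adjust)
    sp <- split(values, groups)
    for (i in seq_len(nrow(dn))) {
      rows[[length(rows) + 1]] <- data.frame(
        level = level, metric = label, marker = marker, region = region,
        test = "dunn", group1 = dn$group1[i], group2 = dn$group2[i],
        statistic = dn$z[i], p_value = dn$p_value[i],
        n = paste(lengths(sp[c(dn$group1[i], dn$group2[i])]),
                  collapse = "/"))
    }
  }
  do.call(rbind, rows)
}

#' Run one level of the hierarchical group comparison
#'
#' For every metric (burden, circularity, perimeter per marker; dystrophy
#' score for Iba1) and region, compares the level's groups with a
#' Kruskal-Wallis test followed by Dunn's post hoc pairs (rank-sum when the
#' level has exactly two groups); compares grey versus white matter within
#' each lobe and group with paired Wilcoxon signed-rank tests; compares
#' demographics (onset, death, duration, post-mortem delay) with the same
#' rank machinery and sex with Fisher's exact test. P values are unadjusted
#' by default, matching a fixed p < 0.05 threshold; Holm or
#' Benjamini-Hochberg adjustment of Dunn pairs is available via `adjust`.
#'
#' @param metrics region-metrics table ([run_synthetic_study()] or
#'   [analyze_region_image()] rows).
#' @param cases case-record table.
#' @param level integer 1-6.
#' @param adjust p adjustment for Dunn pairs (`"none"`, `"holm"`, `"BH"`,
#'   ...).
#' @return list of class `level_comparison`: `results` (long-format
#'   comparison table with significance classes) and `heatmaps` (per
#'   metric x marker: p-value and significance-class matrices, group pairs
#'   x regions, plus paired grey-vs-white matrices).
#' @export
run_level <- function(metrics, cases, level, adjust = "none") {
  validate_case_records(cases)
  glab <- level_groups(cases, level)
  if (all(is.na(glab)))
    stop(sprintf("level %d has an empty group universe", level))
  case_group <- setNames(as.character(glab), cases$case_id)
  rows <- list()
  metric_cols <- c(burden = "burden", circularity = "circularity",
                   perimeter = "perimeter",
                   dystrophy_score = "dystrophy_score")
  for (marker in unique(metrics$marker)) {
    mm <- metrics[metrics$marker == marker, ]
    cols <- if (marker == "Iba1") metric_cols
            else metric_cols[names(metric_cols) != "dystrophy_score"]
    for (mc in names(cols)) {
      for (region in REGIONS) {
        sub <- mm[mm$region == region, ]
        vals <- sub[[cols[mc]]]
        grp <- case_group[sub$case_id]
        rows[[length(rows) + 1]] <-
          compare_groups(vals, grp, mc, marker, region, level, adjust)
      }
      # paired grey vs white within each lobe, per group
      for (lobe in c("frontal", "temporal")) {
        gw <- if (lobe == "frontal") c("FG", "FW") else c("TG", "TW")
        wide <- merge(
          mm[mm$region == gw[1], c("case_id", cols[mc])],
          mm[mm$region == gw[2], c("case_id", cols[mc])],
          by = "case_id", suffixes = c("_g", "_w"))
        wide$group <- case_group[wide$case_id]
        for (g in unique(stats::na.omit(wide$group))) {
          sub <- wide[!is.na(wide$group) & wide$group == g, ]
          x <- sub[[paste0(cols[mc], "_g")]]
          y <- sub[[paste0(cols[mc], "_w")]]
          ok <- !is.na(x) & !is.na(y)
          if (sum(ok) < 2) next
          t <- wilcoxon_signed_rank(x[ok], y[ok])
          rows[[length(rows) + 1]] <- data.frame(
            level = level, metric = mc, marker = marker,
            region = paste(gw, collapse = " vs "), test = "wilcoxon_paired",
            group1 = g, group2 = g, statistic = t$statistic,
            p_value = t$p_value, n = as.character(sum(ok)))
        }
      }
    }
  }
  # demographics across the level's groups
  demo <- intersect(c("aao", "aad", "duration", "pm_delay"), names(cases))
  for (dc in demo) {
    rows[[length(rows) + 1]] <-
      compare_groups(cases[[dc]], glab, dc, "demographics", "all", level)
  }
  if ("sex" %in% names(cases)) {
    tab <- table(cases$sex, glab)
    if (nrow(tab) == 2 && ncol(tab) >= 2 && all(rowSums(tab) > 0) &&
        all(colSums(tab) > 0)) {
      ft <- fisher_exact(matrix(tab, nrow = 2))
      rows[[length(rows) + 1]] <- data.frame(
        level = level, metric = "sex", marker = "demographics",
        region = "all", test = "fisher_exact",
        group1 = "all", group2 = "all", statistic = NA_real_,
        p_value = ft$p_value, n = as.character(sum(tab)))
    }
  }
  results <- do.call(rbind, Filter(Negate(is.null), rows))
  rownames(results) <- NULL
  results$significance <- sig_class(results$p_value)
  structure(list(results = results, heatmaps = level_heatmaps(results),
                 level = level, level_name = LEVEL_NAMES[level]),
            class = "level_comparison")
}

#' Heat-map matrices of a level's p-values
#'
#' One pair of matrices (p values and significance classes: p < 0.01,
#' 0.01-0.05, >= 0.05, mirroring the red/white/blue convention) per metric
#' and marker; rows are group pairs (between-group tests) or groups (paired
#' grey-vs-white tests), columns are regions.
#'
#' @param results long-format results from [run_level()].
#' @return nested list: `[[metric_marker]]$between`, `$between_class`,
#'   `$paired`, `$paired_class`.
#' @export
level_heatmaps <- function(results) {
  out <- list()
  pairwise <- results[results$test %in% c("dunn", "rank_sum"), ]
  paired <- results[results$test == "wilcoxon_paired", ]
  for (key in unique(paste(results$metric, results$marker, sep = "|"))) {
    km <- strsplit(key, "|", fixed = TRUE)[[1]]
    sel <- pairwise$metric == km[1] & pairwise$marker == km[2]
    ent <- list()
    if (any(sel)) {
      sub <- pairwise[sel, ]
      sub$pair <- paste(sub$group1, "vs", sub$group2)
      m <- matrix(NA_real_, length(unique(sub$pair)), length(REGIONS),
                  dimnames = list(unique(sub$pair), REGIONS))
      for (i in seq_len(nrow(sub)))
        if (sub$region[i] %in% REGIONS)
          m[sub$pair[i], sub$region[i]] <- sub$p_value[i]
      ent$between <- m
      ent$between_class <- matrix(as.character(sig_class(m)), nrow(m),
                                  dimnames = dimnames(m))
    }
    sel2 <- paired$metric == km[1] & paired$marker == km[2]
    if (any(sel2)) {
      sub <- paired[sel2, ]
      grs <- unique(sub$group1)
      regs <- unique(sub$region)
      m <- matrix(NA_real_, length(grs), length(regs),
                  dimnames = list(grs, regs))
      for (i in seq_len(nrow(sub)))
        m[sub$group1[i], sub$region[i]] <- sub$p_value[i]
      ent$paired <- m
      ent$paired_class <- matrix(as.character(sig_class(m)), nrow(m),
                                 dimnames = dimnames(m))
    }
    if (length(ent) > 0) out[[key]] <- ent
  }
  out
}
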