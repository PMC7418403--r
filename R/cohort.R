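REGIONS <- c("FG", "FW", "TG", "TW")
MARKERS <- c("CD68", "CR3_43", "Iba1")

grp_row <- function(group, n, l1, l2, l3, l4, l5, l6, genetic,
                    aao, aad, dur, pm, m, f) {
  data.frame(group = group, n = n, level1 = l1, level2 = l2, level3 = l3,
             level4 = l4, level5 = l5, level6 = l6, genetic = genetic,
             aao_lo = aao[1], aao_hi = aao[2], aad_lo = aad[1],
             aad_hi = aad[2], dur_lo = dur[1], dur_hi = dur[2],
             pm_lo = pm[1], pm_hi = pm[2], m = m, f = f,
             stringsAsFactors = FALSE)
}

#' Study group structure: sixty cases across the diagnosis hierarchy
#'
#' One row per finest pathological group with its labels at the six
#' comparison levels (overall groups; main FTLD subtypes + AD; FTLD-tau
#' subtypes; FTLD-TDP subtypes; sporadic/genetic FTLD-TDPA; genetic
#' subtypes, where the FTLD-C9orf72 group holds FTLD-TDPA cases only),
#' group sizes, sex counts and demographic ranges used by the synthetic
#' cohort generator.
#'
#' @return data.frame with 14 rows (60 cases).
#' @export
study_groups_table <- function() {
  na2 <- c(NA_real_, NA_real_)
  tdpa_aao <- c(50, 76); tdpa_aad <- c(53.1, 78.6)
  tdpa_dur <- c(2.1, 10.3); tdpa_pm <- c(29.3, 157.6)
  rbind(
    grp_row("Control", 5, "Control", "Control", "Control", "Control",
            "Control", "Control", NA, na2, c(38, 80), na2, c(24.0, 80.6),
            1, 4),
    grp_row("AD", 5, "AD", "AD", NA, NA, NA, NA, NA,
            c(49, 65), c(62, 73), c(5, 17), c(31.1, 76.7), 3, 2),
    grp_row("FTLD-CBD", 5, "FTLD", "FTLD-tau", "FTLD-CBD", NA, NA, NA,
            "sporadic", c(57, 65), c(64.8, 73.8), c(5.5, 11.1),
            c(37.2, 103.3), 2, 3),
    grp_row("FTLD-MAPT", 5, "FTLD", "FTLD-tau", "FTLD-MAPT", NA, NA,
            "FTLD-MAPT", "genetic", c(37, 58), c(52.4, 68.4), c(8.1, 16.4),
            c(24.0, 64.0), 2, 3),
    grp_row("FTLD-Picks", 5, "FTLD", "FTLD-tau", "FTLD-Picks", NA, NA, NA,
            "sporadic", c(52, 64), c(63.5, 75.6), c(5.5, 15.6),
            c(24.0, 94.7), 5, 0),
    grp_row("FTLD-PSP", 5, "FTLD", "FTLD-tau", "FTLD-PSP", NA, NA, NA,
            "sporadic", c(62, 71), c(68.0, 84.0), c(6.0, 13.0),
            c(25.5, 86.4), 4, 1),
    grp_row("FTLD-TDPA-sporadic", 5, "FTLD", "FTLD-TDP", NA, "FTLD-TDPA",
            "Sporadic FTLD-TDPA", NA, "sporadic", tdpa_aao, tdpa_aad,
            tdpa_dur, tdpa_pm, 2, 3),
    grp_row("FTLD-GRN", 5, "FTLD", "FTLD-TDP", NA, "FTLD-TDPA", "FTLD-GRN",
            "FTLD-GRN", "genetic", tdpa_aao, tdpa_aad, tdpa_dur, tdpa_pm,
            2, 3),
    grp_row("FTLD-C9orf72-TDPA", 5, "FTLD", "FTLD-TDP", NA, "FTLD-TDPA",
            "FTLD-C9orf72", "FTLD-C9orf72", "genetic", tdpa_aao, tdpa_aad,
            tdpa_dur, tdpa_pm, 1, 4),
    grp_row("FTLD-TBK1", 1, "FTLD", "FTLD-TDP", NA, "FTLD-TDPA", NA, NA,
            "genetic", tdpa_aao, tdpa_aad, tdpa_dur, tdpa_pm, 1, 0),
    grp_row("FTLD-TDPB-sporadic", 2, "FTLD", "FTLD-TDP", NA, "FTLD-TDPB",
            NA, NA, "sporadic", c(50, 63), c(56.2, 67.2), c(4.2, 8.1),
            c(10.8, 96.0), 1, 1),
    grp_row("FTLD-TDPB-C9orf72", 3, "FTLD", "FTLD-TDP", NA, "FTLD-TDPB",
            NA, NA, "genetic", c(50, 63), c(56.2, 67.2), c(4.2, 8.1),
            c(10.8, 96.0), 1, 2),
    grp_row("FTLD-TDPC", 5, "FTLD", "FTLD-TDP", NA, "FTLD-TDPC", NA, NA,
            "sporadic", c(52, 64), c(65.4, 78.6), c(10.3, 18.7),
            c(19.0, 83.7), 3, 2),
    grp_row("FTLD-FUS", 4, "FTLD", "FTLD-FUS", NA, NA, NA, NA, "sporadic",
            c(40, 51), c(51.3, 60.4), c(5.5, 11.3), c(12.0, 72.0), 4, 0)
  )
}

#' Validate case records against the diagnosis hierarchy
#'
#' Checks that child-level labels are consistent with their parents (for
#' example FTLD-GRN implies FTLD-TDPA implies FTLD-TDP implies FTLD), that
#' the genetic-subtype level contains only FTLD-TDPA cases in its
#' FTLD-C9orf72 group, that FTLD-TDPC cases are sporadic, and that controls
#' carry no age at onset.
#'
#' @param cases case-record data.frame.
#' @return invisibly TRUE; stops with a validation error otherwise.
#' @export
validate_case_records <- function(cases) {
  need <- c("case_id", "group", paste0("level", 1:6), "sex")
  miss <- setdiff(need, names(cases))
  if (length(miss) > 0)
    stop("case records lack columns: ", paste(miss, collapse = ", "))
  bad <- function(cond, msg) {
    i <- which(cond)
    if (length(i) > 0)
      stop(sprintf("case %s: %s", cases$case_id[i[1]], msg))
  }
  l2 <- cases$level2; l3 <- cases$level3; l4 <- cases$level4
  l5 <- cases$level5; l6 <- cases$level6
  is_tau3 <- !is.na(l3) & l3 %in% c("FTLD-CBD", "FTLD-MAPT", "FTLD-Picks",
                                    "FTLD-PSP")
  bad(is_tau3 & l2 != "FTLD-tau",
      "an FTLD-tau subtype label requires level2 == FTLD-tau")
  is_tdp4 <- !is.na(l4) & l4 %in% c("FTLD-TDPA", "FTLD-TDPB", "FTLD-TDPC")
  bad(is_tdp4 & l2 != "FTLD-TDP",
      "an FTLD-TDP subtype label requires level2 == FTLD-TDP")
  in_l5 <- !is.na(l5) & l5 %in% c("Sporadic FTLD-TDPA", "FTLD-GRN",
                                  "FTLD-C9orf72")
  bad(in_l5 & (is.na(l4) | l4 != "FTLD-TDPA"),
      "level-5 groups contain FTLD-TDPA cases only")
  bad(!is.na(l6) & l6 == "FTLD-C9orf72" & (is.na(l4) | l4 != "FTLD-TDPA"),
      "the genetic-level FTLD-C9orf72 group includes only FTLD-TDPA cases")
  bad(!is.na(l6) & l6 == "FTLD-GRN" & (is.na(l4) | l4 != "FTLD-TDPA"),
      "FTLD-GRN cases have FTLD-TDPA pathology")
  bad(!is.na(l6) & l6 == "FTLD-MAPT" & (is.na(l3) | l3 != "FTLD-MAPT"),
      "the genetic-level FTLD-MAPT group requires level3 == FTLD-MAPT")
  if ("genetic" %in% names(cases)) {
    bad(!is.na(l4) & l4 == "FTLD-TDPC" & !is.na(cases$genetic) &
          cases$genetic == "genetic",
        "FTLD-TDPC is a sporadic pathology and cannot be marked genetic")
    bad(!is.na(l5) & l5 %in% c("FTLD-GRN", "FTLD-C9orf72") &
          !is.na(cases$genetic) & cases$genetic == "sporadic",
        "mutation-defined groups must be marked genetic")
  }
  if ("aao" %in% names(cases))
    bad(cases$level1 == "Control" & !is.na(cases$aao),
        "controls have no age at symptom onset (n/a)")
  invisible(TRUE)
}

#' Build a synthetic cohort configuration
#'
#' @param groups group table as in [study_groups_table()] (any subset of
#'   columns beyond `group`, `n`, `level1` is optional).
#' @param markers markers to render per case.
#' @param image_shape canvas per region, `c(rows, cols)` px.
#' @param pixel_scale micrometres per pixel.
#' @param n_squares,square_side,disjoint sampling-square settings used when
#'   the cohort is analysed.
#' @param seed master seed; all per-case/marker/region seeds derive from it.
#' @param spec_fn function `(case_id, group, marker, region, seed,
#'   image_shape, pixel_scale)` returning a [region_spec()]; defaults to a
#'   moderate-burden template.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(groups, markers = "Iba1",
                          image_shape = c(600, 600), pixel_scale = 0.5,
                          n_squares = 4, square_side = 150, disjoint = TRUE,
                          seed = 1, spec_fn = NULL) {
  stopifnot(is.data.frame(groups), all(c("group", "n") %in% names(groups)),
            all(groups$n >= 1))
  for (lv in paste0("level", 1:6))
    if (!lv %in% names(groups)) groups[[lv]] <- groups$group
  if (!"level1" %in% names(groups)) groups$level1 <- groups$group
  if (is.null(spec_fn)) spec_fn <- default_spec_fn
  stopifnot(all(markers %in% MARKERS))
  structure(list(groups = groups, markers = markers,
                 image_shape = as.integer(image_shape),
                 pixel_scale = pixel_scale, n_squares = n_squares,
                 square_side = square_side, disjoint = disjoint,
                 seed = as.integer(seed), spec_fn = spec_fn),
            class = "cohort_config")
}

default_spec_fn <- function(case_id, group, marker, region, seed,
                            image_shape, pixel_scale) {
  set.seed(seed)
  grey <- region %in% c("FG", "TG")
  region_spec(region_label = region, image_shape = image_shape,
              pixel_scale = pixel_scale,
              target_burden = runif(1, 2, 4) * if (grey) 1 else 1.5,
              dystrophy_severity = 1, layout = "random", seed = seed)
}

#' Cohort configuration mirroring the study's group structure
#'
#' Sixty synthetic cases (50 FTLD, five AD, five controls) across the full
#' diagnosis hierarchy, with demographics drawn uniformly from the group
#' ranges.
#'
#' @inheritParams cohort_config
#' @param ... passed to [cohort_config()].
#' @return a `cohort_config`.
#' @export
cohort_config_study <- function(markers = "Iba1", seed = 1, ...) {
  cohort_config(study_groups_table(), markers = markers, seed = seed, ...)
}

#' Cohort configuration with planted grey/white-matter contrasts
#'
#' One disease-like group whose regions carry the qualitative contrasts seen
#' in diseased tissue: higher white-matter burden (CD68), more activated
#' (rounder) microglia in grey matter (amoeboid-heavy grey mix versus
#' ramified-heavy white mix), and more severe white-matter dystrophy (Iba1
#' severities 3-4 in white versus 1-2 in grey).
#'
#' @param n cases in the group.
#' @param burden_grey grey-matter burden range (%), drawn per case and lobe.
#' @param white_factor white/grey burden ratio range.
#' @param seed master seed.
#' @param ... passed to [cohort_config()].
#' @return a `cohort_config`.
#' @export
cohort_config_contrast <- function(n = 20, burden_grey = c(2.5, 4),
                                   white_factor = c(1.7, 2.0), seed = 1,
                                   image_shape = c(440, 440),
                                   n_squares = 4, square_side = 110,
                                   n_cells = 16, ...) {
  groups <- data.frame(group = "FTLD", n = n, level1 = "FTLD",
                       aao_lo = 50, aao_hi = 70, aad_lo = 60, aad_hi = 80,
                       dur_lo = 4, dur_hi = 15, pm_lo = 20, pm_hi = 100,
                       m = 1, f = 1, stringsAsFactors = FALSE)
  mix_grey <- c(ramified = 0.25, amoeboid = 0.55, hypertrophic = 0.2)
  mix_white <- c(ramified = 0.65, amoeboid = 0.15, hypertrophic = 0.2)
  spec_fn <- function(case_id, group, marker, region, seed_r, image_shape,
                      pixel_scale) {
    grey <- region %in% c("FG", "TG")
    lobe <- if (region %in% c("FG", "FW")) "frontal" else "temporal"
    # lobe-level draws shared by the grey and white region of a case
    set.seed(derive_seed(seed_r, "lobe", case_id, marker, lobe))
    base <- runif(1, burden_grey[1], burden_grey[2])
    fac <- runif(1, white_factor[1], white_factor[2])
    sev_grey <- sample(1:2, 1)
    sev_white <- sample(3:4, 1)
    if (marker == "Iba1") {
      region_spec(region_label = region, image_shape = image_shape,
                  pixel_scale = pixel_scale, layout = "spaced",
                  n_cells = n_cells,
                  class_mix = if (grey) mix_grey else mix_white,
                  dystrophy_severity = if (grey) sev_grey else sev_white,
                  seed = derive_seed(seed_r, "render", case_id, marker,
                                     region))
    } else {
      region_spec(region_label = region, image_shape = image_shape,
                  pixel_scale = pixel_scale, layout = "random",
                  target_burden = if (grey) base else base * fac,
                  class_mix = if (grey) mix_grey else mix_white,
                  dystrophy_severity = 1,
                  seed = derive_seed(seed_r, "render", case_id, marker,
                                     region))
    }
  }
  cohort_config(groups, markers = c("CD68", "Iba1"), seed = seed,
                image_shape = image_shape, n_squares = n_squares,
                square_side = square_side, spec_fn = spec_fn, ...)
}

#' Generate the case records of a synthetic cohort
#'
#' @param config a `cohort_config`.
#' @return data.frame with one row per case: identifiers, six-level labels,
#'   sex and demographics (uniform over the configured ranges; controls'
#'   onset and duration are NA).
#' @export
make_case_records <- function(config) {
  g <- config$groups
  rows <- list()
  idx <- 0L
  for (i in seq_len(nrow(g))) {
    for (j in seq_len(g$n[i])) {
      idx <- idx + 1L
      case_id <- sprintf("case_%03d", idx)
      set.seed(derive_seed(config$seed, "demographics", case_id))
      draw <- function(lo, hi) {
        if (is.null(lo) || is.na(lo)) NA_real_
        else round(runif(1, lo, hi), 1)
      }
      p_m <- if (!is.null(g$m)) {
        tot <- g$m[i] + g$f[i]
        if (is.na(tot) || tot == 0) 0.5 else g$m[i] / tot
      } else 0.5
      rows[[idx]] <- data.frame(
        case_id = case_id, group = g$group[i],
        level1 = g$level1[i], level2 = g$level2[i], level3 = g$level3[i],
        level4 = g$level4[i], level5 = g$level5[i], level6 = g$level6[i],
        genetic = if ("genetic" %in% names(g)) g$genetic[i] else NA,
        sex = if (runif(1) < p_m) "M" else "F",
        aao = draw(g$aao_lo[i], g$aao_hi[i]),
        aad = draw(g$aad_lo[i], g$aad_hi[i]),
        duration = draw(g$dur_lo[i], g$dur_hi[i]),
        pm_delay = draw(g$pm_lo[i], g$pm_hi[i]),
        stringsAsFactors = FALSE)
    }
  }
  cases <- do.call(rbind, rows)
  validate_case_records(cases)
  cases
}

#' Generate a synthetic cohort: case records, region specs and images
#'
#' Emits one case record per synthetic case with diagnosis labels at all six
#' hierarchy levels, plus a rendered region image (4 regions x configured
#' markers) and its ground truth per case. With `render = FALSE` only the
#' records and region specs are returned (metadata mode, e.g. for statistics
#' work); with `out_dir` set, images are written as TIFF and paths returned
#' instead of in-memory rasters.
#'
#' @param config a `cohort_config`.
#' @param render render region images.
#' @param out_dir optional directory for TIFF output.
#' @return list: `cases` (data.frame), `regions` (named list
#'   `case|marker|region` of `spec`, `truth`, `image` or `path`).
#' @export
make_synthetic_cohort <- function(config, render = TRUE, out_dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  cases <- make_case_records(config)
  regions <- list()
  for (i in seq_len(nrow(cases))) {
    for (marker in config$markers) {
      for (region in REGIONS) {
        key <- paste(cases$case_id[i], marker, region, sep = "|")
        seed_r <- derive_seed(config$seed, "region", cases$case_id[i],
                              marker, region)
        spec <- config$spec_fn(cases$case_id[i], cases$group[i], marker,
                               region, seed_r, config$image_shape,
                               config$pixel_scale)
        entry <- list(spec = spec)
        if (render) {
          rr <- render_region(spec)
          rr$image$marker <- marker
          rr$image$case_id <- cases$case_id[i]
          entry$truth <- rr$truth
          if (!is.null(out_dir)) {
            dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
            path <- file.path(out_dir, paste0(gsub("\\|", "_", key), ".tif"))
            write_region_image(rr$image, path)
            entry$path <- path
          } else {
            entry$image <- rr$image
          }
        }
        regions[[key]] <- entry
      }
    }
  }
  list(cases = cases, regions = regions)
}
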