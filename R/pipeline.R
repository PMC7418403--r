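SCHEMA_VERSION <- "micromorph/v1"

write_table_tsv <- function(df, path, table_name) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# schema: %s/%s", SCHEMA_VERSION, table_name), con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' Read a pipeline TSV table
#' @param path TSV path written by [run_pipeline()].
#' @return data.frame.
#' @export
read_table_tsv <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

config_hash <- function(config) {
  # stable 31-bit content hash of the serialisable parts of the config
  strip <- function(x) {
    if (is.function(x)) return("<function>")
    if (is.data.frame(x)) x <- as.list(x)
    if (is.list(x)) return(lapply(unclass(x), strip))
    unclass(x)
  }
  config <- config[setdiff(names(config), "out_dir")] # content, not location
  ser <- jsonlite::toJSON(strip(config), auto_unbox = TRUE, digits = NA,
                          null = "null")
  sprintf("%08x", derive_seed(0, as.character(ser)))
}

#' Assemble and validate a pipeline run configuration
#'
#' Accepts a named list or a YAML file path; unknown keys are rejected and
#' threshold invariants (for instance `hue_max >= hue_min`) are enforced
#' before any computation. Fields: `seed`, `out_dir`, `cohort` (a
#' [cohort_config()]; or a preset name `"demo"`, `"contrast"` or `"study"`
#' with `cohort_args`), `thresholds` (arguments of [hsv_thresholds()]),
#' `min_diameter`, `burden_basis`, `dystrophy` (arguments of
#' [dystrophy_thresholds()]), `levels` (which comparison levels to run),
#' `adjust`.
#'
#' @param config named list or YAML path.
#' @param ... overrides applied on top of `config`.
#' @return list of class `run_config`.
#' @export
run_config <- function(config = list(), ...) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  over <- list(...)
  config[names(over)] <- over
  defaults <- list(seed = 1L, out_dir = NULL, cohort = "demo",
                   cohort_args = list(), thresholds = list(),
                   min_diameter = 5, burden_basis = "raw",
                   dystrophy = list(), levels = 1L, adjust = "none")
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0)
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  cfg <- defaults
  cfg[names(config)] <- config
  cfg$thresholds <- do.call(hsv_thresholds, cfg$thresholds)
  cfg$dystrophy <- do.call(dystrophy_thresholds, cfg$dystrophy)
  if (is.character(cfg$cohort)) {
    builder <- switch(cfg$cohort,
                      demo = cohort_config_demo,
                      contrast = cohort_config_contrast,
                      study = cohort_config_study,
                      stop("unknown cohort preset: ", cfg$cohort))
    cfg$cohort <- do.call(builder, c(cfg$cohort_args,
                                     list(seed = cfg$seed)))
  }
  stopifnot(inherits(cfg$cohort, "cohort_config"))
  if (!all(cfg$levels %in% 1:6)) stop("levels must be in 1..6")
  structure(cfg, class = "run_config")
}

#' Small two-group demonstration cohort configuration
#'
#' @param n_per_group cases per group.
#' @param seed master seed.
#' @param ... passed to [cohort_config()].
#' @return a `cohort_config` with two groups on small canvases.
#' @export
cohort_config_demo <- function(n_per_group = 3, seed = 1, ...) {
  groups <- data.frame(group = c("GroupA", "GroupB"),
                       n = c(n_per_group, n_per_group),
                       level1 = c("GroupA", "GroupB"),
                       aao_lo = 55, aao_hi = 70, aad_lo = 65, aad_hi = 80,
                       dur_lo = 5, dur_hi = 12, pm_lo = 20, pm_hi = 90,
                       m = 1, f = 1, stringsAsFactors = FALSE)
  spec_fn <- function(case_id, group, marker, region, seed_r, image_shape,
                      pixel_scale) {
    set.seed(seed_r)
    region_spec(region_label = region, image_shape = image_shape,
                pixel_scale = pixel_scale,
                target_burden = runif(1, 2, 5) *
                  (if (group == "GroupB") 1.6 else 1),
                layout = "random", seed = seed_r)
  }
  args <- list(...)
  if (is.null(args$image_shape)) args$image_shape <- c(360, 360)
  if (is.null(args$n_squares)) args$n_squares <- 4
  if (is.null(args$square_side)) args$square_side <- 90
  do.call(cohort_config, c(list(groups = groups, markers = "Iba1",
                                seed = seed, spec_fn = spec_fn), args))
}

#' Run the full pipeline: generate, sample, segment, measure, score, compare
#'
#' Orchestrates generator, sampling, segmentation, morphometry, dystrophy
#' scoring and group statistics from a single configuration with
#' deterministic seeding: re-running the same configuration reproduces
#' byte-identical output tables. When `out_dir` is set, writes
#' `case_records.tsv`, `region_metrics.tsv`, `comparisons.tsv`, heat-map
#' CSVs, a structured `run.log` (one event per line) and a `manifest.json`
#' recording the configuration hash, seed and package version.
#'
#' @param config a [run_config()], or anything accepted by it.
#' @param ... overrides passed to [run_config()].
#' @return list: `cases`, `metrics`, `comparisons`, `heatmaps`, `files`,
#'   `manifest`.
#' @export
run_pipeline <- function(config = list(), ...) {
  cfg <- if (inherits(config, "run_config")) config
         else run_config(config, ...)
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))
  note("event=start seed=%d hash=%s", cfg$seed, config_hash(cfg))
  study <- run_synthetic_study(cfg$cohort, thresholds = cfg$thresholds,
                               min_diameter = cfg$min_diameter,
                               burden_basis = cfg$burden_basis,
                               dyst_thresholds = cfg$dystrophy)
  note("event=analysed cases=%d regions=%d", nrow(study$cases),
       nrow(study$metrics))
  comparisons <- list(); heatmaps <- list()
  for (lv in cfg$levels) {
    lr <- run_level(study$metrics, study$cases, lv, adjust = cfg$adjust)
    comparisons[[length(comparisons) + 1]] <- lr$results
    heatmaps[[paste0("level", lv)]] <- lr$heatmaps
    note("event=level level=%d tests=%d", lv, nrow(lr$results))
  }
  comparisons <- do.call(rbind, comparisons)
  manifest <- list(schema = SCHEMA_VERSION,
                   package_version = as.character(
                     utils::packageVersion("micromorph")),
                   seed = cfg$seed, config_hash = config_hash(cfg),
                   n_cases = nrow(study$cases),
                   n_regions = nrow(study$metrics))
  files <- character(0)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    f <- function(name) file.path(cfg$out_dir, name)
    write_table_tsv(study$cases, f("case_records.tsv"), "case_records")
    write_table_tsv(study$metrics, f("region_metrics.tsv"),
                    "region_metrics")
    write_table_tsv(study$truth, f("ground_truth.tsv"), "ground_truth")
    write_table_tsv(comparisons, f("comparisons.tsv"), "comparisons")
    files <- c(f("case_records.tsv"), f("region_metrics.tsv"),
               f("ground_truth.tsv"), f("comparisons.tsv"))
    for (lv in names(heatmaps)) {
      for (key in names(heatmaps[[lv]])) {
        ent <- heatmaps[[lv]][[key]]
        for (kind in intersect(c("between", "paired"), names(ent))) {
          path <- f(sprintf("heatmap_%s_%s_%s.csv", lv,
                            gsub("|", "_", key, fixed = TRUE), kind))
          utils::write.csv(ent[[kind]], path)
          files <- c(files, path)
          path2 <- f(sprintf("heatmap_%s_%s_%s_class.csv", lv,
                             gsub("|", "_", key, fixed = TRUE), kind))
          utils::write.csv(ent[[paste0(kind, "_class")]], path2)
          files <- c(files, path2)
        }
      }
    }
    jsonlite::write_json(manifest, f("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE)
    note("event=written files=%d", length(files) + 1)
    writeLines(log, f("run.log"))
    files <- c(files, f("manifest.json"), f("run.log"))
  }
  list(cases = study$cases, metrics = study$metrics,
       comparisons = comparisons, heatmaps = heatmaps, files = files,
       manifest = manifest, log = log)
}

#' Run the statistics stage standalone on written tables
#'
#' Reads `region_metrics.tsv` and `case_records.tsv` produced by
#' [run_pipeline()] and reruns the level comparisons, so the statistics
#' stage is reproducible from the tabular interface alone.
#'
#' @param metrics_tsv,cases_tsv paths to the stage-input tables.
#' @param levels comparison levels to run.
#' @param adjust p adjustment for Dunn pairs.
#' @return long-format comparisons data.frame.
#' @export
stats_from_files <- function(metrics_tsv, cases_tsv, levels = 1L,
                             adjust = "none") {
  metrics <- read_table_tsv(metrics_tsv)
  cases <- read_table_tsv(cases_tsv)
  for (lv in c("level2", "level3", "level4", "level5", "level6", "genetic"))
    if (!lv %in% names(cases)) cases[[lv]] <- NA
  out <- lapply(levels, function(lv)
    run_level(metrics, cases, lv, adjust = adjust)$results)
  do.call(rbind, out)
}
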