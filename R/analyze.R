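#' Analyse one region image: squares, segmentation, morphometry, dystrophy
#'
#' Runs the full per-region protocol: places the random analysis squares in
#' the ROI, thresholds each square to a DAB mask, extracts cells above the
#' exclusion diameter, computes per-square burden/circularity/perimeter,
#' aggregates square means to region means, and (for the pan-microglial
#' Iba1 marker) pools the cells across squares to classify morphologies,
#' score dystrophy and call rod/hypertrophic presence.
#'
#' @param image a [region_image()].
#' @param thresholds an [hsv_thresholds()] object.
#' @param min_diameter cell exclusion diameter (um).
#' @param n_squares,side,disjoint square sampling settings (see
#'   [sample_squares()]).
#' @param seed seed for square placement.
#' @param burden_basis `"raw"` or `"filtered"` (see [square_metrics()]).
#' @param dystrophy compute the dystrophy score and presence calls; only
#'   valid for Iba1 (dystrophy is assessed on the Iba1-stained slides).
#' @param dyst_thresholds a [dystrophy_thresholds()] list.
#' @return list of class `region_analysis`: `squares`, `square_metrics`,
#'   `region` (aggregate row incl. dystrophy fields), `cells` (pooled, in
#'   region coordinates), `classified`, `dystrophy`, `presence`.
#' @export
analyze_region_image <- function(image, thresholds = hsv_thresholds(),
                                 min_diameter = 5, n_squares = 10,
                                 side = 1000, disjoint = TRUE, seed = 1,
                                 burden_basis = "raw",
                                 dystrophy = image$marker == "Iba1",
                                 dyst_thresholds = dystrophy_thresholds()) {
  stopifnot(inherits(image, "region_image"))
  if (dystrophy && image$marker != "Iba1")
    stop("dystrophy is assessed on Iba1-stained slides only, not ",
         image$marker)
  squares <- sample_squares(image, n = n_squares, side = side, seed = seed,
                            disjoint = disjoint)
  sq_rows <- list()
  all_cells <- list()
  masks <- list()
  for (i in seq_len(nrow(squares))) {
    sq <- squares[i, ]
    px <- square_pixels(image$pixels, sq)
    mask <- dab_mask(px, thresholds)
    cells <- extract_cells(mask, min_diameter, image$pixel_scale)
    # shift cell offsets from square frame to region frame
    cells <- lapply(cells, function(cell) {
      cell$offset <- cell$offset + c(sq$row - 1L, sq$col - 1L)
      cell$centroid <- cell$centroid + c(sq$row - 1, sq$col - 1)
      cell
    })
    sq_rows[[i]] <- cbind(data.frame(square = sq$index),
                          square_metrics(mask, cells, sq, burden_basis))
    all_cells <- c(all_cells, cells)
    masks[[i]] <- mask
  }
  sq_df <- do.call(rbind, sq_rows)
  region <- aggregate_region(sq_df)
  classified <- NULL; dyst <- NULL; presence <- NULL
  if (dystrophy) {
    classified <- classify_region_cells(all_cells, dim(image$pixels)[1:2],
                                        image$pixel_scale, dyst_thresholds)
    q <- punctate_index(masks, image$pixel_scale, min_diameter)
    dyst <- score_dystrophy(classified, q, dyst_thresholds)
    presence <- morphology_presence(classified,
                                    dyst_thresholds$frequent_min)
    region$dystrophy_score <- dyst$score
    region$rod_present <- presence$rod_present
    region$hypertrophic_present <- presence$hypertrophic_present
  } else {
    region$dystrophy_score <- NA_integer_
    region$rod_present <- NA
    region$hypertrophic_present <- NA
  }
  structure(list(squares = squares, square_metrics = sq_df, region = region,
                 cells = all_cells, classified = classified,
                 dystrophy = dyst, presence = presence),
            class = "region_analysis")
}

region_metrics_row <- function(case_id, marker, region_label, analysis) {
  cbind(data.frame(case_id = case_id, marker = marker,
                   region = region_label), analysis$region)
}

#' Generate and analyse a synthetic cohort in one pass
#'
#' Streams through every case x marker x region of the configuration:
#' renders the synthetic section, analyses it with
#' [analyze_region_image()], and discards the raster. Returns the region
#' metrics table used by the group statistics, together with the case
#' records and the planted ground truth summary.
#'
#' @param config a [cohort_config()].
#' @param thresholds,min_diameter,burden_basis,dyst_thresholds analysis
#'   settings (see [analyze_region_image()]).
#' @param progress print one line per case.
#' @return list: `cases`, `metrics` (one row per case x marker x region),
#'   `truth` (planted burden/severity per region).
#' @export
run_synthetic_study <- function(config, thresholds = hsv_thresholds(),
                                min_diameter = 5, burden_basis = "raw",
                                dyst_thresholds = dystrophy_thresholds(),
                                progress = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  cases <- make_case_records(config)
  mrows <- list(); trows <- list()
  for (i in seq_len(nrow(cases))) {
    if (progress) message("analysing ", cases$case_id[i])
    for (marker in config$markers) {
      for (region in REGIONS) {
        seed_r <- derive_seed(config$seed, "region", cases$case_id[i],
                              marker, region)
        spec <- config$spec_fn(cases$case_id[i], cases$group[i], marker,
                               region, seed_r, config$image_shape,
                               config$pixel_scale)
        rr <- render_region(spec)
        rr$image$marker <- marker
        rr$image$case_id <- cases$case_id[i]
        an <- analyze_region_image(
          rr$image, thresholds = thresholds, min_diameter = min_diameter,
          n_squares = config$n_squares, side = config$square_side,
          disjoint = config$disjoint,
          seed = derive_seed(config$seed, "squares", cases$case_id[i],
                             marker, region),
          burden_basis = burden_basis,
          dyst_thresholds = dyst_thresholds)
        mrows[[length(mrows) + 1]] <-
          region_metrics_row(cases$case_id[i], marker, region, an)
        trows[[length(trows) + 1]] <- data.frame(
          case_id = cases$case_id[i], marker = marker, region = region,
          planted_burden = rr$truth$planted_burden,
          planted_severity = rr$truth$planted_severity)
      }
    }
  }
  list(cases = cases, metrics = do.call(rbind, mrows),
       truth = do.call(rbind, trows))
}
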