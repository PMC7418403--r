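#' Thresholds for the morphology classifier and dystrophy score
#'
#' Every tunable of the skeleton-based classifier and of the ordinal dystrophy
#' score is a named entry here. Lengths and diameters are micrometres.
#'
#' @param frag_min fragments (8-connected components per cell cluster) at or
#'   above which a cell is dystrophic (cytoplasmic fragmentation).
#' @param bead_min bead count at or above which a cell is dystrophic.
#' @param bead_thin_max maximum median process width for bead search.
#' @param bead_prom minimum width prominence of a bead.
#' @param bead_w_min minimum absolute width (um) of a bead: a bead must be a
#'   resolvable swelling, not a rasterisation bulge on a sub-resolution
#'   process.
#' @param bead_w_max maximum width (um) of a bead (wider maxima are somata).
#' @param bead_ratio minimum bead width relative to the branch median.
#' @param tort_max tortuosity above which a cell is dystrophic.
#' @param deramified_max maximum endpoint count of a deramified cell.
#' @param length_min process length (um) below which a soma-bearing,
#'   non-round cell counts as deramified.
#' @param width_hyper process width (um) at or above which processes count as
#'   thickened (hypertrophic).
#' @param bushy_min minimum endpoint count of a bushy (hypertrophic) cell.
#' @param circ_amoeboid circularity at or above which a cell is amoeboid.
#' @param rod_axis minimum major/minor axis ratio of a rod.
#' @param rod_junction_max maximum skeleton junctions of a rod.
#' @param soma_min minimum maximal-inscribed-disc diameter (um) for a
#'   detected soma.
#' @param link_radius gap (um) across which fragments are linked into one
#'   cell cluster.
#' @param frequent_min cell count at or above which a morphology is flagged
#'   frequent.
#' @param punctate_cutoff equivalent diameter (um) below which stained
#'   components count as punctate debris.
#' @param q_punctate punctate-area fraction at or above which staining is
#'   generalised punctate (very severe dystrophy).
#' @param f_none dystrophic fraction at or below which a region scores 1.
#' @param f_all dystrophic fraction at or above which all cells count
#'   dystrophic (scores 4-5).
#' @param s_min intact-soma fraction separating severe (4) from very severe
#'   (5) dystrophy.
#' @return named list of class `dystrophy_thresholds`.
#' @export
dystrophy_thresholds <- function(frag_min = 2, bead_min = 3,
                                 bead_thin_max = 2.8, bead_prom = 0.8,
                                 bead_ratio = 1.8, bead_w_min = 1.7,
                                 bead_w_max = 3.2,
                                 tort_max = 1.8,
                                 deramified_max = 2, length_min = 15,
                                 width_hyper = 2.0, bushy_min = 4,
                                 circ_amoeboid = 0.6, rod_axis = 3,
                                 rod_junction_max = 1, soma_min = 7,
                                 link_radius = 3, frequent_min = 10,
                                 punctate_cutoff = 5, q_punctate = 0.5,
                                 f_none = 0.05, f_all = 0.95, s_min = 0.25) {
  structure(as.list(environment()), class = "dystrophy_thresholds")
}

#' Classify one cell into a morphology archetype
#'
#' Priority-ordered decision tree over the skeleton summary and shape
#' features. Dystrophic evidence (fragmentation, beading, tortuosity, or a
#' deramified soma with few short processes and low circularity) is checked
#' first, then rod (elongated, at most one branch point), then hypertrophic
#' (thickened processes, bushy), then amoeboid (round), else ramified.
#'
#' @param cell a `cell_object` or cell cluster (needs `axis_ratio` and
#'   `circularity`).
#' @param skel its [skeletonize_cell()] summary.
#' @param thresholds a [dystrophy_thresholds()] list.
#' @return one of `"dystrophic"`, `"rod"`, `"hypertrophic"`, `"amoeboid"`,
#'   `"ramified"`.
#' @export
classify_cell <- function(cell, skel, thresholds = dystrophy_thresholds()) {
  th <- thresholds
  if (skel$n_fragments >= th$frag_min ||
      skel$bead_count >= th$bead_min ||
      skel$tortuosity > th$tort_max ||
      (skel$n_endpoints <= th$deramified_max &&
       skel$total_process_length < th$length_min &&
       skel$soma_detected && cell$circularity < th$circ_amoeboid))
    return("dystrophic")
  if (cell$axis_ratio >= th$rod_axis &&
      skel$n_junctions <= th$rod_junction_max)
    return("rod")
  if (skel$mean_process_width >= th$width_hyper &&
      skel$n_endpoints >= th$bushy_min)
    return("hypertrophic")
  if (cell$circularity >= th$circ_amoeboid) return("amoeboid")
  "ramified"
}

# build a cluster object (cell-like) from a binary mask patch
cluster_from_mask <- function(mask, offset = c(0L, 0L), members = integer(),
                              pixel_scale = 0.5) {
  idx <- which(mask != 0, arr.ind = TRUE)
  area <- nrow(idx)
  lab <- cpp_label8(mask)
  per <- 0
  for (k in seq_len(max(lab))) per <- per + perimeter_px(lab == k)
  structure(list(
    mask = mask, offset = offset, members = members,
    n_fragments = max(lab),
    area_px = area, area_um2 = area * pixel_scale^2,
    perimeter_px = per, perimeter_um = per * pixel_scale,
    equiv_diam_um = 2 * sqrt(area * pixel_scale^2 / pi),
    centroid = c(mean(idx[, 1]) + offset[1], mean(idx[, 2]) + offset[2]),
    axis_ratio = axis_ratio_from_coords(idx[, 1], idx[, 2]),
    circularity = if (area <= 1) 1 else min(4 * pi * area / per^2, 1),
    pixel_scale = pixel_scale
  ), class = c("cell_cluster", "cell_object"))
}

#' Group detected cells into cell clusters across small gaps
#'
#' Fragments of one dystrophic cell appear as separate connected components;
#' components whose masks lie within `link_radius` micrometres of each other
#' (Euclidean dilation linkage) are attributed to one cell cluster for
#' classification and scoring.
#'
#' @param cells list of `cell_object`s (in a common parent coordinate frame).
#' @param dim parent raster dimensions `c(rows, cols)`.
#' @param pixel_scale micrometres per pixel.
#' @param link_radius linking gap in micrometres.
#' @return list of cluster objects (see `cluster_from_mask`).
#' @export
cluster_cells <- function(cells, dim, pixel_scale = 0.5, link_radius = 3) {
  if (length(cells) == 0) return(list())
  full <- matrix(0L, dim[1], dim[2])
  for (cell in cells) {
    r0 <- cell$offset[1]; c0 <- cell$offset[2]
    rr <- (r0 + 1):(r0 + nrow(cell$mask))
    cc <- (c0 + 1):(c0 + ncol(cell$mask))
    full[rr, cc] <- pmax(full[rr, cc], cell$mask)
  }
  linked <- dilate_mask(full, link_radius / pixel_scale)
  lab <- cpp_label8(linked)
  cl_of_cell <- vapply(cells, function(cell) {
    p <- which(cell$mask != 0, arr.ind = TRUE)[1, ]
    lab[cell$offset[1] + p[1], cell$offset[2] + p[2]]
  }, 0L)
  out <- list()
  for (cl in sort(unique(cl_of_cell))) {
    members <- which(cl_of_cell == cl)
    # union of member masks over the cluster's bounding box only
    r0 <- as.integer(min(vapply(cells[members],
                                function(x) x$offset[1], 0)))
    c0 <- as.integer(min(vapply(cells[members],
                                function(x) x$offset[2], 0)))
    r1 <- as.integer(max(vapply(cells[members],
                                function(x) x$offset[1] + nrow(x$mask), 0)))
    c1 <- as.integer(max(vapply(cells[members],
                                function(x) x$offset[2] + ncol(x$mask), 0)))
    sub <- matrix(0L, r1 - r0 + 2L, c1 - c0 + 2L)
    for (m in members) {
      cell <- cells[[m]]
      rr <- (cell$offset[1] - r0 + 2):(cell$offset[1] - r0 + 1 +
                                         nrow(cell$mask))
      cc <- (cell$offset[2] - c0 + 2):(cell$offset[2] - c0 + 1 +
                                         ncol(cell$mask))
      sub[rr, cc] <- pmax(sub[rr, cc], cell$mask)
    }
    out[[length(out) + 1]] <-
      cluster_from_mask(sub, c(r0 - 1L, c0 - 1L), members, pixel_scale)
  }
  out
}

#' Cluster, skeletonise and classify all cells of a region
#'
#' @param cells list of `cell_object`s pooled across the region's squares
#'   (coordinates in a common frame).
#' @param dim parent raster dimensions.
#' @param pixel_scale micrometres per pixel.
#' @param thresholds a [dystrophy_thresholds()] list.
#' @return data.frame with one row per cell cluster: `morph_class` and the
#'   skeleton-summary fields.
#' @export
classify_region_cells <- function(cells, dim, pixel_scale = 0.5,
                                  thresholds = dystrophy_thresholds()) {
  clusters <- cluster_cells(cells, dim, pixel_scale, thresholds$link_radius)
  if (length(clusters) == 0)
    return(data.frame(cluster = integer(), morph_class = character(),
                      n_fragments = integer(), n_endpoints = integer(),
                      n_junctions = integer(), total_process_length = numeric(),
                      mean_process_width = numeric(), tortuosity = numeric(),
                      bead_count = integer(), soma_detected = logical(),
                      axis_ratio = numeric(), circularity = numeric(),
                      area_um2 = numeric(), n_members = integer()))
  rows <- lapply(seq_along(clusters), function(i) {
    cl <- clusters[[i]]
    sk <- skeletonize_cell(cl, pixel_scale, thresholds)
    data.frame(cluster = i,
               morph_class = classify_cell(cl, sk, thresholds),
               n_fragments = sk$n_fragments, n_endpoints = sk$n_endpoints,
               n_junctions = sk$n_junctions,
               total_process_length = sk$total_process_length,
               mean_process_width = sk$mean_process_width,
               tortuosity = sk$tortuosity, bead_count = sk$bead_count,
               soma_detected = sk$soma_detected, axis_ratio = cl$axis_ratio,
               circularity = cl$circularity, area_um2 = cl$area_um2,
               n_members = length(cl$members))
  })
  do.call(rbind, rows)
}

#' Punctate-staining index of a mask
#'
#' Fraction of the stained area lying in components below the exclusion
#' diameter: generalised punctate staining is sub-cellular debris, exactly
#' what the cell size filter removes.
#'
#' @param masks a binary matrix or a list of binary matrices (pooled).
#' @param pixel_scale micrometres per pixel.
#' @param min_diameter exclusion diameter in micrometres.
#' @return fraction in `[0, 1]`; 0 for an empty mask.
#' @export
punctate_index <- function(masks, pixel_scale = 0.5, min_diameter = 5) {
  if (is.matrix(masks)) masks <- list(masks)
  small <- 0; total <- 0
  for (m in masks) {
    lab <- cpp_label8(matrix(as.integer(m != 0), nrow = nrow(m)))
    if (max(lab) == 0) next
    areas <- tabulate(lab[lab > 0], max(lab))
    eqd <- 2 * sqrt(areas * pixel_scale^2 / pi)
    total <- total + sum(areas)
    small <- small + sum(areas[eqd < min_diameter])
  }
  if (total == 0) return(0)
  small / total
}

#' Ordinal dystrophy score of a region
#'
#' Operationalises the visual 1-5 rubric from the classified cell clusters:
#' with dystrophic fraction `f`, intact-soma fraction `s` among dystrophic
#' cells and punctate index `q`, the score is 1 when `f <= f_none` (no
#' dystrophy), 2 when `f <= 0.5` (at least half non-dystrophic), 3 when
#' `f < f_all` (most dystrophic), 4 when `f >= f_all` and `s >= s_min` (all
#' dystrophic, cell bodies still visible) and 5 when `f >= f_all` with
#' `s < s_min`, or whenever `q >= q_punctate` (only generalised punctate
#' staining). With no cells at all the score is 5 if staining is punctate,
#' otherwise undefined (absence of staining is not severe dystrophy).
#'
#' @param classified data.frame from [classify_region_cells()].
#' @param punctate punctate index of the region's raw masks
#'   ([punctate_index()]).
#' @param thresholds a [dystrophy_thresholds()] list.
#' @return list of class `dystrophy_score`: `score` (1-5 or NA),
#'   `dystrophic_fraction`, `intact_soma_fraction`, `punctate_index`,
#'   `defined`.
#' @export
score_dystrophy <- function(classified, punctate = 0,
                            thresholds = dystrophy_thresholds()) {
  th <- thresholds
  n <- nrow(classified)
  if (n == 0) {
    sc <- if (punctate >= th$q_punctate) 5L else NA_integer_
    return(structure(list(score = sc, dystrophic_fraction = NA_real_,
                          intact_soma_fraction = NA_real_,
                          punctate_index = punctate,
                          defined = !is.na(sc)),
                     class = "dystrophy_score"))
  }
  dys <- classified$morph_class == "dystrophic"
  f <- mean(dys)
  s <- if (any(dys)) mean(classified$soma_detected[dys]) else NA_real_
  score <- if (punctate >= th$q_punctate) 5L
    else if (f <= th$f_none) 1L
    else if (f <= 0.5) 2L
    else if (f < th$f_all) 3L
    else if (!is.na(s) && s >= th$s_min) 4L
    else 5L
  structure(list(score = score, dystrophic_fraction = f,
                 intact_soma_fraction = s, punctate_index = punctate,
                 defined = TRUE),
            class = "dystrophy_score")
}

#' Rod-shaped and hypertrophic presence calls
#'
#' A morphology is recorded present when at least one cell of that class is
#' seen in at least one of the region's squares, and flagged frequent when at
#' least `frequent_min` are seen.
#'
#' @param classified data.frame from [classify_region_cells()].
#' @param frequent_min count at or above which the morphology is frequent.
#' @return list: `rod_present`, `rod_frequent`, `hypertrophic_present`,
#'   `hypertrophic_frequent`, `rod_count`, `hypertrophic_count`.
#' @export
morphology_presence <- function(classified, frequent_min = 10) {
  nrod <- sum(classified$morph_class == "rod")
  nhyp <- sum(classified$morph_class == "hypertrophic")
  list(rod_present = nrod >= 1, rod_frequent = nrod >= frequent_min,
       hypertrophic_present = nhyp >= 1,
       hypertrophic_frequent = nhyp >= frequent_min,
       rod_count = nrod, hypertrophic_count = nhyp)
}
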