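#' HSV colour thresholds for DAB detection
#'
#' Thresholds on the 0-255 hue/saturation/brightness scale used by common
#' raster tools. A pixel is DAB-positive when its hue lies in
#' `[hue_min, hue_max]`, its saturation in `[sat_min, sat_max]` and (if a
#' value band is set) its brightness in `[value_min, value_max]`. The defaults
#' are hue 0-30 and saturation 60-80, the pre-set band that selects brown DAB
#' staining over the blue haematoxylin counterstain.
#'
#' @param hue_min,hue_max hue band, 0-255.
#' @param sat_min,sat_max saturation band, 0-255.
#' @param value_min,value_max optional brightness band, 0-255 (default: open).
#' @return an object of class `hsv_thresholds`.
#' @export
hsv_thresholds <- function(hue_min = 0, hue_max = 30, sat_min = 60,
                           sat_max = 80, value_min = 0, value_max = 255) {
  if (hue_min > hue_max) stop("hue_min must be <= hue_max")
  if (sat_min > sat_max) stop("sat_min must be <= sat_max")
  if (value_min > value_max) stop("value_min must be <= value_max")
  rng <- c(hue_min, hue_max, sat_min, sat_max, value_min, value_max)
  if (any(rng < 0 | rng > 255)) stop("thresholds must lie in [0, 255]")
  structure(list(hue_min = hue_min, hue_max = hue_max, sat_min = sat_min,
                 sat_max = sat_max, value_min = value_min,
                 value_max = value_max),
            class = "hsv_thresholds")
}

#' Convert an RGB raster to HSV on the 0-255 scale
#'
#' @param pixels numeric array `[rows, cols, 3]` with channels in `[0, 1]`
#'   (or 0-255; detected by range).
#' @return numeric array `[rows, cols, 3]` with hue, saturation and value
#'   each on 0-255.
#' @export
rgb_to_hsv255 <- function(pixels) {
  if (length(dim(pixels)) != 3 || dim(pixels)[3] != 3)
    stop("input is not an RGB raster (rows x cols x 3)")
  mx <- max(pixels)
  if (mx > 1 + 1e-9) pixels <- pixels / 255
  d <- dim(pixels)
  hsv <- grDevices::rgb2hsv(r = as.vector(pixels[, , 1]),
                            g = as.vector(pixels[, , 2]),
                            b = as.vector(pixels[, , 3]),
                            maxColorValue = 1)
  out <- array(0, d)
  out[, , 1] <- hsv[1, ] * 255
  out[, , 2] <- hsv[2, ] * 255
  out[, , 3] <- hsv[3, ] * 255
  out
}

#' Threshold an RGB square to a DAB-positive binary mask
#'
#' @param pixels RGB raster `[rows, cols, 3]`.
#' @param thresholds an [hsv_thresholds()] object.
#' @return integer matrix, 1 where the pixel colour falls inside the DAB band.
#' @export
dab_mask <- function(pixels, thresholds = hsv_thresholds()) {
  stopifnot(inherits(thresholds, "hsv_thresholds"))
  hsv <- rgb_to_hsv255(pixels)
  m <- (hsv[, , 1] >= thresholds$hue_min) & (hsv[, , 1] <= thresholds$hue_max) &
       (hsv[, , 2] >= thresholds$sat_min) & (hsv[, , 2] <= thresholds$sat_max) &
       (hsv[, , 3] >= thresholds$value_min) & (hsv[, , 3] <= thresholds$value_max)
  matrix(as.integer(m), nrow = dim(pixels)[1])
}

#' Label 8-connected components of a binary mask
#'
#' @param mask binary matrix (nonzero = foreground).
#' @return integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask) {
  cpp_label8(matrix(as.integer(mask != 0), nrow = nrow(mask)))
}

# perimeter (px) of a single 8-connected component: corner-corrected boundary
# chain (axial 1, diagonal sqrt(2), -0.15 per direction change, + pi for the
# half-pixel offset of the closed outer contour). A 1-px object measures pi.
perimeter_px <- function(mask) {
  if (sum(mask != 0) <= 1) return(pi)
  st <- cpp_chain_stats(matrix(as.integer(mask != 0), nrow = nrow(mask)))
  max(st[1] + sqrt(2) * st[2] - 0.15 * st[3] + pi, pi)
}

#' Extract DAB-positive cell objects from a binary mask
#'
#' Labels 8-connected components, measures each (area, perimeter, centroid,
#' equivalent diameter, axis ratio, circularity) and removes components whose
#' equivalent-circle diameter is below `min_diameter` (default 5 micrometres,
#' i.e. ten pixels at 0.5 um/px) so that out-of-plane cell parts are not
#' selected as cells.
#'
#' @param mask binary matrix from [dab_mask()].
#' @param min_diameter exclusion diameter in micrometres.
#' @param pixel_scale physical pixel size in micrometres per pixel.
#' @return list of `cell_object`s; possibly empty. Each carries its mask patch
#'   (`mask`, with `offset` locating it in the parent raster) and measured
#'   fields `area_px`, `area_um2`, `perimeter_px`, `perimeter_um`,
#'   `equiv_diam_um`, `centroid`, `axis_ratio`, `circularity`.
#' @export
extract_cells <- function(mask, min_diameter = 5, pixel_scale = 0.5) {
  stopifnot(pixel_scale > 0)
  lab <- label_components(mask)
  n <- max(lab)
  if (n == 0) return(list())
  idx <- which(lab > 0)
  coord <- arrayInd(idx, dim(lab))
  labs <- lab[idx]
  cells <- vector("list", n)
  keep <- logical(n)
  ord <- order(labs)
  coord <- coord[ord, , drop = FALSE]
  labs <- labs[ord]
  bounds <- c(0, cumsum(tabulate(labs, n)))
  for (k in seq_len(n)) {
    rows <- coord[(bounds[k] + 1):bounds[k + 1], 1]
    cols <- coord[(bounds[k] + 1):bounds[k + 1], 2]
    area <- length(rows)
    area_um2 <- area * pixel_scale^2
    eqd <- 2 * sqrt(area_um2 / pi)
    if (eqd < min_diameter) next
    r0 <- min(rows); c0 <- min(cols)
    patch <- matrix(0L, max(rows) - r0 + 1, max(cols) - c0 + 1)
    patch[cbind(rows - r0 + 1, cols - c0 + 1)] <- 1L
    per_px <- perimeter_px(patch)
    cells[[k]] <- structure(list(
      label = k,
      mask = patch,
      offset = c(r0 - 1L, c0 - 1L),
      area_px = area,
      area_um2 = area_um2,
      perimeter_px = per_px,
      perimeter_um = per_px * pixel_scale,
      equiv_diam_um = eqd,
      centroid = c(mean(rows), mean(cols)),
      axis_ratio = axis_ratio_from_coords(rows, cols),
      circularity = if (area == 1) 1 else min(4 * pi * area / per_px^2, 1),
      pixel_scale = pixel_scale
    ), class = "cell_object")
    keep[k] <- TRUE
  }
  cells[keep]
}

#' Tabulate measured cell features
#'
#' @param cells list of `cell_object`s from [extract_cells()].
#' @return data.frame with one row per cell.
#' @export
cells_table <- function(cells) {
  if (length(cells) == 0)
    return(data.frame(label = integer(), area_um2 = numeric(),
                      perimeter_um = numeric(), equiv_diam_um = numeric(),
                      circularity = numeric(), axis_ratio = numeric(),
                      centroid_row = numeric(), centroid_col = numeric()))
  data.frame(
    label = vapply(cells, `[[`, 1L, "label"),
    area_um2 = vapply(cells, `[[`, 1, "area_um2"),
    perimeter_um = vapply(cells, `[[`, 1, "perimeter_um"),
    equiv_diam_um = vapply(cells, `[[`, 1, "equiv_diam_um"),
    circularity = vapply(cells, `[[`, 1, "circularity"),
    axis_ratio = vapply(cells, `[[`, 1, "axis_ratio"),
    centroid_row = vapply(cells, function(x) x$centroid[1], 1),
    centroid_col = vapply(cells, function(x) x$centroid[2], 1)
  )
}
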