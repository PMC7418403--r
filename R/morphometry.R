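#' Areal fraction of a binary mask
#'
#' Microglial burden for one sampling square: the percentage of pixels stained
#' with DAB.
#'
#' @param mask binary matrix.
#' @param square optional `SamplingSquare` row (from [sample_squares()]); when
#'   given, the mask dimensions must equal the square side.
#' @return percentage in `[0, 100]`.
#' @export
areal_fraction <- function(mask, square = NULL) {
  if (!is.null(square)) {
    side <- if (is.data.frame(square)) square$side[1] else square["side"]
    if (nrow(mask) != side || ncol(mask) != side)
      stop(sprintf("mask is %dx%d but the sampling square side is %d",
                   nrow(mask), ncol(mask), side))
  }
  100 * sum(mask != 0) / length(mask)
}

#' Circularity of a cell
#'
#' `4 * pi * area / perimeter^2`, clipped to `[0, 1]`: 1 for a perfect circle
#' (amoeboid, activated morphology), lower for branched (ramified) cells.
#' A degenerate one-pixel object is defined to have circularity 1.
#'
#' @param cell a `cell_object`.
#' @return circularity in `[0, 1]`.
#' @export
cell_circularity <- function(cell) {
  stopifnot(cell$area_px > 0, cell$perimeter_px > 0)
  if (cell$area_px == 1) return(1)
  min(4 * pi * cell$area_px / cell$perimeter_px^2, 1)
}

#' Perimeter of a cell in micrometres
#'
#' Boundary length of the cell's outer contour (corner-corrected boundary
#' chain; holes are not counted), scaled by the pixel size. A one-pixel object
#' measures `pi` pixels.
#'
#' @param cell a `cell_object`.
#' @param pixel_scale micrometres per pixel.
#' @return perimeter in micrometres.
#' @export
cell_perimeter <- function(cell, pixel_scale = cell$pixel_scale) {
  stopifnot(pixel_scale > 0)
  cell$perimeter_px * pixel_scale
}

#' Per-square burden and morphometry summary
#'
#' @param mask raw DAB mask of the square.
#' @param cells cells surviving the size exclusion ([extract_cells()]).
#' @param square optional square row for the dimension contract.
#' @param burden_basis `"raw"` (default) computes the percentage area from the
#'   thresholded mask before size exclusion; `"filtered"` from the surviving
#'   cells only.
#' @return one-row data.frame: `burden`, `mean_circularity`, `mean_perimeter`
#'   (NA when the square holds no cells), `n_cells`.
#' @export
square_metrics <- function(mask, cells, square = NULL,
                           burden_basis = c("raw", "filtered")) {
  burden_basis <- match.arg(burden_basis)
  if (burden_basis == "raw") {
    burden <- areal_fraction(mask, square)
  } else {
    fg <- sum(vapply(cells, `[[`, 1, "area_px"))
    burden <- 100 * fg / length(mask)
  }
  n <- length(cells)
  data.frame(
    burden = burden,
    mean_circularity = if (n > 0)
      mean(vapply(cells, `[[`, 1, "circularity")) else NA_real_,
    mean_perimeter = if (n > 0)
      mean(vapply(cells, `[[`, 1, "perimeter_um")) else NA_real_,
    n_cells = n
  )
}

#' Aggregate square metrics to region means
#'
#' Burden is the unweighted mean over all squares. Circularity and perimeter
#' are means of square means (not pooled-cell means), taken over the squares
#' that contain at least one cell; with no such square they are NA (absence of
#' cells is not a shape statement), and `n_squares_used` records the
#' denominator.
#'
#' @param per_square data.frame with one row per square ([square_metrics()]).
#' @return one-row data.frame: `burden`, `circularity`, `perimeter`,
#'   `n_squares`, `n_squares_used`, `n_cells`.
#' @export
aggregate_region <- function(per_square) {
  stopifnot(is.data.frame(per_square), nrow(per_square) >= 1)
  used <- which(per_square$n_cells > 0)
  data.frame(
    burden = mean(per_square$burden),
    circularity = if (length(used) > 0)
      mean(per_square$mean_circularity[used]) else NA_real_,
    perimeter = if (length(used) > 0)
      mean(per_square$mean_perimeter[used]) else NA_real_,
    n_squares = nrow(per_square),
    n_squares_used = length(used),
    n_cells = sum(per_square$n_cells)
  )
}
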