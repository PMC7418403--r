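#' A region image with physical scale and region-of-interest polygon
#'
#' @param pixels RGB array `[rows, cols, 3]` in `[0, 1]`.
#' @param pixel_scale micrometres per pixel (> 0).
#' @param roi two-column matrix of polygon vertices (row, col) in pixel
#'   coordinates; default: the full raster rectangle.
#' @param region_label one of FG, FW, TG, TW (frontal/temporal grey/white).
#' @param marker one of CD68, CR3_43, Iba1.
#' @param case_id opaque case identifier.
#' @return an object of class `region_image`.
#' @export
region_image <- function(pixels, pixel_scale, roi = NULL,
                         region_label = c("FG", "FW", "TG", "TW"),
                         marker = c("Iba1", "CD68", "CR3_43"),
                         case_id = "case") {
  region_label <- match.arg(region_label)
  marker <- match.arg(marker)
  stopifnot(length(dim(pixels)) == 3, dim(pixels)[3] == 3, pixel_scale > 0)
  if (is.null(roi)) roi <- roi_rect(dim(pixels)[1], dim(pixels)[2])
  stopifnot(is.matrix(roi), ncol(roi) == 2)
  structure(list(pixels = pixels, pixel_scale = pixel_scale, roi = roi,
                 region_label = region_label, marker = marker,
                 case_id = case_id),
            class = "region_image")
}

#' Rectangular ROI polygon covering an `nr` x `nc` raster
#' @param nr,nc raster dimensions in pixels.
#' @return two-column matrix of (row, col) vertices.
#' @export
roi_rect <- function(nr, nc) {
  cbind(row = c(0.5, 0.5, nr + 0.5, nr + 0.5),
        col = c(0.5, nc + 0.5, nc + 0.5, 0.5))
}

#' Read a ROI polygon from a GeoJSON-style file
#'
#' Expects a JSON object with `"type": "Polygon"` and
#' `"coordinates": [[[x, y], ...]]` in pixel coordinates (x = column,
#' y = row).
#'
#' @param path file path.
#' @return two-column matrix of (row, col) vertices.
#' @export
read_roi_polygon <- function(path) {
  g <- jsonlite::fromJSON(path)
  if (is.null(g$type) || g$type != "Polygon")
    stop("ROI file does not contain a Polygon object")
  xy <- g$coordinates
  if (is.list(xy)) xy <- xy[[1]]
  if (length(dim(xy)) == 3) xy <- xy[1, , ]
  cbind(row = xy[, 2], col = xy[, 1])
}

#' Place random analysis squares inside a region of interest
#'
#' Draws `n` axis-aligned squares of side `side` pixels whose positions are
#' uniform over the admissible top-left pixels, i.e. those for which the
#' square's four corners and centre lie inside the ROI polygon (exact
#' rasterised containment is available with `containment = "raster"`).
#' Squares cover the half-open pixel ranges `[r, r+side) x [c, c+side)`.
#' By default squares are pairwise disjoint (rejection sampling with a retry
#' cap); set `disjoint = FALSE` to allow overlap.
#'
#' @param image a `region_image`, or a two-column ROI polygon matrix.
#' @param n number of squares (the protocol uses ten per region).
#' @param side square side in pixels (1000 px = 500 um at 0.5 um/px).
#' @param seed optional integer seed (sets the RNG).
#' @param disjoint require pairwise-disjoint squares.
#' @param containment `"corners"` (corners + centre in polygon) or `"raster"`
#'   (every pixel of the square inside the rasterised ROI).
#' @param max_tries rejection-sampling cap.
#' @return data.frame with columns `index` (0-based), `row`, `col` (1-based
#'   top-left pixel), `side`.
#' @export
sample_squares <- function(image, n = 10, side = 1000, seed = NULL,
                           disjoint = TRUE,
                           containment = c("corners", "raster"),
                           max_tries = 400L * n) {
  containment <- match.arg(containment)
  if (inherits(image, "region_image")) poly <- image$roi
  else if (is.matrix(image) && ncol(image) == 2) poly <- image
  else stop("image must be a region_image or a two-column ROI polygon")
  stopifnot(side > 0, n >= 1)
  if (!is.null(seed)) set.seed(seed)
  rlo <- ceiling(min(poly[, 1]) + 0.5)
  rhi <- floor(max(poly[, 1]) - 0.5) - side + 1
  clo <- ceiling(min(poly[, 2]) + 0.5)
  chi <- floor(max(poly[, 2]) - 0.5) - side + 1
  if (rhi < rlo || chi < clo)
    stop(sprintf(paste0("ROI too small for a %d-px square: available extent ",
                        "%d x %d px"), side,
                 floor(max(poly[, 1]) - min(poly[, 1])),
                 floor(max(poly[, 2]) - min(poly[, 2]))))
  roi_mask <- NULL
  if (containment == "raster") {
    nr <- floor(max(poly[, 1])); nc <- floor(max(poly[, 2]))
    gr <- rep(seq_len(nr), nc); gc <- rep(seq_len(nc), each = nr)
    roi_mask <- matrix(point_in_polygon(gr, gc, poly), nr, nc)
  }
  admissible <- function(r, c) {
    if (containment == "corners") {
      pts_r <- c(r, r, r + side - 1, r + side - 1, r + (side - 1) / 2)
      pts_c <- c(c, c + side - 1, c, c + side - 1, c + (side - 1) / 2)
      all(point_in_polygon(pts_r, pts_c, poly))
    } else {
      all(roi_mask[r:(r + side - 1), c:(c + side - 1)])
    }
  }
  out <- matrix(NA_integer_, n, 2)
  got <- 0L
  tries <- 0L
  while (got < n) {
    if (tries >= max_tries) {
      if (disjoint)
        stop(sprintf(paste0("could not place %d disjoint %d-px squares in ",
                            "the ROI after %d tries; consider disjoint = ",
                            "FALSE (overlap mode)"), n, side, max_tries))
      stop(sprintf("could not place %d squares in the ROI after %d tries",
                   n, max_tries))
    }
    tries <- tries + 1L
    r <- if (rhi > rlo) sample.int(rhi - rlo + 1L, 1L) + rlo - 1L else rlo
    c <- if (chi > clo) sample.int(chi - clo + 1L, 1L) + clo - 1L else clo
    if (!admissible(r, c)) next
    if (disjoint && got > 0) {
      ov <- abs(out[seq_len(got), 1] - r) < side &
            abs(out[seq_len(got), 2] - c) < side
      if (any(ov)) next
    }
    got <- got + 1L
    out[got, ] <- c(r, c)
  }
  data.frame(index = 0:(n - 1), row = out[, 1], col = out[, 2], side = side)
}

# extract the pixel block of one square from an RGB raster
square_pixels <- function(pixels, square_row) {
  r <- square_row$row; c <- square_row$col; s <- square_row$side
  pixels[r:(r + s - 1), c:(c + s - 1), , drop = FALSE]
}
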