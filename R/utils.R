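#' Derive a reproducible stage seed from a master seed
#'
#' Hashes a master seed together with any number of string keys (stage name,
#' case id, region label, ...) into an integer seed below 2^31. Adding a case
#' to a cohort therefore never perturbs the random stream of other cases.
#'
#' @param master integer master seed.
#' @param ... character scalars identifying the stage/case/region.
#' @return an integer seed in [1, 2^31 - 2].
#' @export
derive_seed <- function(master, ...) {
  s <- paste(c(...), collapse = "/")
  h <- (as.double(master) %% 2147483647) + 1
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  as.integer(h) + 1L
}

# vectorised HSV (fractions in [0,1]) -> RGB (fractions in [0,1])
hsv_to_rgb <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6) %% 6
  f <- h6 - floor(h6)
  p <- v * (1 - s)
  q <- v * (1 - f * s)
  t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  cbind(r, g, b)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Point-in-polygon test (even-odd rule)
#'
#' @param r,c numeric vectors of point coordinates (row, col).
#' @param poly two-column matrix of polygon vertices (row, col), not closed.
#' @return logical vector, TRUE where the point lies inside the polygon.
#' @export
point_in_polygon <- function(r, c, poly) {
  stopifnot(is.matrix(poly), ncol(poly) == 2, nrow(poly) >= 3)
  n <- nrow(poly)
  inside <- rep(FALSE, length(r))
  j <- n
  for (i in seq_len(n)) {
    yi <- poly[i, 1]; xi <- poly[i, 2]
    yj <- poly[j, 1]; xj <- poly[j, 2]
    crosses <- ((yi > r) != (yj > r)) &
      (c < (xj - xi) * (r - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses & !is.na(crosses))
    j <- i
  }
  inside
}

# number of 8-neighbours set, per pixel, for a binary matrix
neighbour_count8 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0L, nr + 2, nc + 2)
  p[2:(nr + 1), 2:(nc + 1)] <- m
  out <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- out + p[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  }
  out
}

# circular crossing number: 0->1 transitions around each pixel's 8-neighbour
# ring; 1 at path ends, 2 on path interiors (even across diagonal corners),
# >= 3 at true branch points
crossing_number8 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0L, nr + 2, nc + 2)
  p[2:(nr + 1), 2:(nc + 1)] <- m
  sh <- function(dr, dc) p[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  ring <- list(sh(-1, 0), sh(-1, 1), sh(0, 1), sh(1, 1),
               sh(1, 0), sh(1, -1), sh(0, -1), sh(-1, -1))
  out <- matrix(0L, nr, nc)
  for (i in seq_along(ring)) {
    j <- if (i == length(ring)) 1L else i + 1L
    out <- out + (ring[[i]] == 0L & ring[[j]] == 1L)
  }
  out
}

# counts of adjacent foreground pairs (axial, diagonal) inside a binary matrix;
# used for skeleton arc length (each pair counted once)
adjacency_counts <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0L, nr + 2, nc + 2)
  p[2:(nr + 1), 2:(nc + 1)] <- m
  ax <- sum(p[2:(nr + 1), 2:(nc + 1)] & p[2:(nr + 1), 3:(nc + 2)]) +
        sum(p[2:(nr + 1), 2:(nc + 1)] & p[3:(nr + 2), 2:(nc + 1)])
  di <- sum(p[2:(nr + 1), 2:(nc + 1)] & p[3:(nr + 2), 3:(nc + 2)]) +
        sum(p[2:(nr + 1), 2:(nc + 1)] & p[3:(nr + 2), 1:nc])
  c(axial = ax, diagonal = di)
}

# Euclidean distance transform of a binary matrix (foreground distance to
# background), with the matrix border treated as background.
dist_transform <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0, nr + 2, nc + 2)
  p[2:(nr + 1), 2:(nc + 1)] <- m
  d <- EBImage::distmap(p)
  as.matrix(d)[2:(nr + 1), 2:(nc + 1)]
}

# crop a binary matrix to its foreground bounding box with `pad` background px
crop_to_bbox <- function(m, pad = 1L) {
  idx <- which(m != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) return(list(mask = m, offset = c(0L, 0L)))
  r0 <- max(1L, min(idx[, 1]) - pad); r1 <- min(nrow(m), max(idx[, 1]) + pad)
  c0 <- max(1L, min(idx[, 2]) - pad); c1 <- min(ncol(m), max(idx[, 2]) + pad)
  list(mask = m[r0:r1, c0:c1, drop = FALSE], offset = c(r0 - 1L, c0 - 1L))
}

# second-moment major/minor axis ratio of a set of pixel coordinates
axis_ratio_from_coords <- function(rows, cols) {
  if (length(rows) < 2) return(1)
  # + 1/12: variance of a unit pixel, keeps 1-px-wide objects non-degenerate
  crr <- stats::var(rows) * (length(rows) - 1) / length(rows) + 1 / 12
  ccc <- stats::var(cols) * (length(cols) - 1) / length(cols) + 1 / 12
  crc <- stats::cov(rows, cols) * (length(rows) - 1) / length(rows)
  tr <- crr + ccc
  det <- crr * ccc - crc^2
  disc <- sqrt(max(tr^2 / 4 - det, 0))
  l1 <- tr / 2 + disc
  l2 <- max(tr / 2 - disc, 1e-9)
  sqrt(l1 / l2)
}
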