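MORPH_CLASSES <- c("ramified", "amoeboid", "hypertrophic", "rod", "dystrophic")

# --- raster painting primitives on a local canvas ------------------------
# canvas: integer matrix; coordinates are (row, col) with origin at [1,1]

paint_disc <- function(canvas, r0, c0, rad) {
  rr <- clip(floor(r0 - rad):ceiling(r0 + rad), 1, nrow(canvas))
  cc <- clip(floor(c0 - rad):ceiling(c0 + rad), 1, ncol(canvas))
  rr <- unique(rr); cc <- unique(cc)
  g <- expand.grid(r = rr, c = cc)
  inside <- (g$r - r0)^2 + (g$c - c0)^2 <= rad^2
  canvas[cbind(g$r[inside], g$c[inside])] <- 1L
  canvas
}

# thick line segment ("capsule"): pixels within halfw of the segment
paint_capsule <- function(canvas, r1, c1, r2, c2, halfw) {
  rlo <- clip(floor(min(r1, r2) - halfw), 1, nrow(canvas))
  rhi <- clip(ceiling(max(r1, r2) + halfw), 1, nrow(canvas))
  clo <- clip(floor(min(c1, c2) - halfw), 1, ncol(canvas))
  chi <- clip(ceiling(max(c1, c2) + halfw), 1, ncol(canvas))
  g <- expand.grid(r = rlo:rhi, c = clo:chi)
  vr <- r2 - r1; vc <- c2 - c1
  len2 <- vr^2 + vc^2
  if (len2 < 1e-12) {
    d2 <- (g$r - r1)^2 + (g$c - c1)^2
  } else {
    t <- clip(((g$r - r1) * vr + (g$c - c1) * vc) / len2, 0, 1)
    d2 <- (g$r - (r1 + t * vr))^2 + (g$c - (c1 + t * vc))^2
  }
  inside <- d2 <= halfw^2
  canvas[cbind(g$r[inside], g$c[inside])] <- 1L
  canvas
}

# polyline of capsules from a start point along a vector of headings/lengths
paint_polyline <- function(canvas, r0, c0, headings, lengths, halfw) {
  r <- r0; c <- c0
  for (i in seq_along(headings)) {
    r2 <- r + lengths[i] * sin(headings[i])
    c2 <- c + lengths[i] * cos(headings[i])
    canvas <- paint_capsule(canvas, r, c, r2, c2, halfw)
    r <- r2; c <- c2
  }
  canvas
}

n_components <- function(mask) max(cpp_label8(mask))

# --- stamp constructors (sizes in micrometres, converted by pixel_scale) --

stamp_ramified <- function(sc) {
  soma_r <- runif(1, 2.1, 2.7) / sc
  nb <- sample(4:7, 1)
  blen <- runif(nb, 9, 15) / sc
  halfw <- runif(1, 0.55, 0.8) / sc
  reach <- soma_r + max(blen) + 4
  d <- 2 * ceiling(reach) + 3
  ctr <- (d + 1) / 2
  m <- matrix(0L, d, d)
  m <- paint_disc(m, ctr, ctr, soma_r)
  ang <- 2 * pi * (seq_len(nb) - 1) / nb + runif(1, 0, 2 * pi) +
    runif(nb, -0.25, 0.25)
  tips <- nb
  for (i in seq_len(nb)) {
    segs <- c(ang[i], ang[i] + runif(1, -0.3, 0.3))
    m <- paint_polyline(m, ctr + 0.8 * soma_r * sin(ang[i]),
                        ctr + 0.8 * soma_r * cos(ang[i]),
                        segs, rep(blen[i] / 2, 2), halfw)
  }
  if (runif(1) < 0.45) { # one side twig
    i <- sample(nb, 1)
    mid_r <- ctr + (soma_r + blen[i] / 2) * sin(ang[i])
    mid_c <- ctr + (soma_r + blen[i] / 2) * cos(ang[i])
    twig_ang <- ang[i] + sample(c(-1, 1), 1) * runif(1, 0.7, 1.1)
    twig_len <- runif(1, 4, 7) / sc
    m <- paint_capsule(m, mid_r, mid_c,
                       mid_r + twig_len * sin(twig_ang),
                       mid_c + twig_len * cos(twig_ang), halfw)
    tips <- tips + 1
  }
  list(mask = m, n_tips = tips, diam = 2 * (soma_r + max(blen)) * sc)
}

stamp_amoeboid <- function(sc) {
  for (try in 1:20) {
    a <- runif(1, 4.2, 5.2) / sc
    b <- a / runif(1, 1.05, 1.35)
    th <- runif(1, 0, pi)
    d <- 2 * ceiling(a) + 5
    ctr <- (d + 1) / 2
    g <- expand.grid(r = 1:d, c = 1:d)
    u <- (g$r - ctr) * cos(th) - (g$c - ctr) * sin(th)
    v <- (g$r - ctr) * sin(th) + (g$c - ctr) * cos(th)
    m <- matrix(0L, d, d)
    m[cbind(g$r, g$c)[u^2 / a^2 + v^2 / b^2 <= 1, , drop = FALSE]] <- 1L
    idx <- which(m == 1L, arr.ind = TRUE)
    if (axis_ratio_from_coords(idx[, 1], idx[, 2]) < 1.5)
      return(list(mask = m, n_tips = 0, diam = 2 * a * sc))
  }
  stop("could not construct an amoeboid stamp with axis ratio < 1.5")
}

stamp_hypertrophic <- function(sc) {
  soma_r <- runif(1, 3.2, 4.0) / sc
  nb <- sample(5:8, 1)
  blen <- runif(nb, 4.5, 7) / sc
  halfw <- runif(1, 1.3, 1.7) / sc
  d <- 2 * ceiling(soma_r + max(blen) + 4) + 3
  ctr <- (d + 1) / 2
  m <- matrix(0L, d, d)
  m <- paint_disc(m, ctr, ctr, soma_r)
  ang <- 2 * pi * (seq_len(nb) - 1) / nb + runif(1, 0, 2 * pi) +
    runif(nb, -0.2, 0.2)
  for (i in seq_len(nb))
    m <- paint_capsule(m, ctr + 0.7 * soma_r * sin(ang[i]),
                       ctr + 0.7 * soma_r * cos(ang[i]),
                       ctr + (soma_r + blen[i]) * sin(ang[i]),
                       ctr + (soma_r + blen[i]) * cos(ang[i]), halfw)
  list(mask = m, n_tips = nb, diam = 2 * (soma_r + max(blen)) * sc)
}

stamp_rod <- function(sc) {
  for (try in 1:20) {
    halfw <- runif(1, 0.95, 1.2) / sc
    len <- runif(1, 18, 26) / sc
    if (len < 3.6 * 2 * halfw) next
    th <- runif(1, 0, pi)
    bend <- runif(1, -0.1, 0.1)
    d <- 2 * ceiling(len / 2 + halfw) + 5
    ctr <- (d + 1) / 2
    m <- matrix(0L, d, d)
    m <- paint_polyline(m, ctr - len / 2 * sin(th), ctr - len / 2 * cos(th),
                        c(th, th + bend), c(len / 2, len / 2), halfw)
    idx <- which(m == 1L, arr.ind = TRUE)
    if (axis_ratio_from_coords(idx[, 1], idx[, 2]) >= 3)
      return(list(mask = m, n_tips = 2, diam = len * sc))
  }
  stop("could not construct a rod stamp with axis ratio >= 3")
}

# dystrophic: fragmented cytoplasm/processes (always >= 2 components).
# with_soma keeps one intact soma fragment (severity-4 appearance); without,
# only chunky process fragments remain (severity-5 appearance).
stamp_dystrophic <- function(sc, with_soma = TRUE) {
  for (try in 1:30) {
    # radial reach: soma (4.5 um) + gap (2 um) + fragment length (13 um)
    d <- 2 * ceiling(20 / sc) + 7
    ctr <- (d + 1) / 2
    m <- matrix(0L, d, d)
    halfw <- runif(1, 1.2, 1.5) / sc
    if (with_soma) {
      soma_r <- 4.5 / sc
      m <- paint_disc(m, ctr, ctr, soma_r)
      k <- sample(2:3, 1)
      ang <- runif(1, 0, 2 * pi) + 2 * pi * (seq_len(k) - 1) / k +
        runif(k, -0.3, 0.3)
      for (i in seq_len(k)) {
        gap <- runif(1, 1.6, 2.0) / sc
        flen <- runif(1, 11, 13) / sc
        # centreline offset by halfw so the rounded cap does not bridge
        # the planted gap back to the soma
        r_in <- soma_r + gap + halfw
        r_out <- soma_r + gap + flen - halfw
        m <- paint_capsule(m, ctr + r_in * sin(ang[i]),
                           ctr + r_in * cos(ang[i]),
                           ctr + r_out * sin(ang[i]),
                           ctr + r_out * cos(ang[i]), halfw)
      }
      nfr_min <- 2
    } else {
      k <- sample(3:4, 1)
      ang <- runif(1, 0, 2 * pi) + 2 * pi * (seq_len(k) - 1) / k +
        runif(k, -0.25, 0.25)
      for (i in seq_len(k)) {
        # fragments stay within the cluster-linking gap of each other
        rad <- runif(1, 1.5, 3) / sc
        flen <- runif(1, 11, 13) / sc
        m <- paint_capsule(m, ctr + rad * sin(ang[i]),
                           ctr + rad * cos(ang[i]),
                           ctr + (rad + flen) * sin(ang[i]),
                           ctr + (rad + flen) * cos(ang[i]), halfw)
      }
      nfr_min <- 2
    }
    if (n_components(m) >= nfr_min)
      return(list(mask = m, n_tips = NA_integer_, diam = 22))
  }
  stop("could not construct a fragmented dystrophic stamp")
}

#' Generate a synthetic microglial cell stamp
#'
#' Builds a binary raster patch of one cell of the requested morphology
#' archetype. Construction contracts: rod stamps have a second-moment
#' major/minor axis ratio of at least 3; amoeboid stamps below 1.5;
#' dystrophic stamps are fragmented into at least two 8-connected components
#' (cytoplasmic fragmentation); all other classes are single components.
#'
#' @param morph_class one of `ramified`, `amoeboid`, `hypertrophic`, `rod`,
#'   `dystrophic`.
#' @param pixel_scale micrometres per pixel (> 0).
#' @param seed optional integer seed.
#' @param with_soma for dystrophic stamps: keep an intact soma fragment.
#' @return an object of class `cell_stamp`: `morph_class`, `mask` (binary
#'   patch cropped to content), `anchor` (patch centre, row/col),
#'   `nominal_diameter` (um), `n_tips` (planted branch tips, NA for
#'   dystrophic), `circularity` (measured on the stamp).
#' @export
make_cell_stamp <- function(morph_class, pixel_scale = 0.5, seed = NULL,
                            with_soma = TRUE) {
  if (length(morph_class) != 1 || !morph_class %in% MORPH_CLASSES)
    stop(sprintf("unknown morphology class '%s' (expected one of %s)",
                 as.character(morph_class)[1],
                 paste(MORPH_CLASSES, collapse = ", ")))
  stopifnot(pixel_scale > 0)
  if (!is.null(seed)) set.seed(seed)
  raw <- switch(morph_class,
                ramified = stamp_ramified(pixel_scale),
                amoeboid = stamp_amoeboid(pixel_scale),
                hypertrophic = stamp_hypertrophic(pixel_scale),
                rod = stamp_rod(pixel_scale),
                dystrophic = stamp_dystrophic(pixel_scale, with_soma))
  cr <- crop_to_bbox(raw$mask, pad = 1L)
  m <- cr$mask
  # measured stamp circularity (multi-fragment: pooled area / summed contours)
  lab <- cpp_label8(m)
  area <- sum(m)
  per <- 0
  for (k in seq_len(max(lab))) per <- per + perimeter_px(lab == k)
  structure(list(
    morph_class = morph_class,
    mask = m,
    anchor = c(round(nrow(m) / 2), round(ncol(m) / 2)),
    nominal_diameter = raw$diam,
    n_tips = raw$n_tips,
    circularity = min(4 * pi * area / per^2, 1),
    pixel_scale = pixel_scale
  ), class = "cell_stamp")
}
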