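#' Specification for one synthetic stained region
#'
#' Describes a synthetic DAB/haematoxylin section region: canvas size and
#' physical scale, the target DAB areal fraction, the morphology mix of the
#' planted (non-dystrophic) cells, the planted dystrophy severity, and the
#' background (nucleus density, stain-noise amplitude).
#'
#' Two layouts are supported. `"random"` places cells uniformly (overlap
#' allowed, merged cells counted once in burden) and rejection-samples
#' placements until the realised burden is within 10% relative of
#' `target_burden`. `"spaced"` plants exactly `n_cells` cells on a jittered
#' grid with guaranteed separation, with the dystrophic fraction set by the
#' severity preset (0, 0.32, 0.72, 1, 1 for severities 1-5); severity 5 adds
#' sub-cellular punctate debris and plants soma-less fragments. The spaced
#' layout is the clear-cut parameterisation used for dystrophy-score work,
#' where cell identity, not areal fraction, is controlled.
#'
#' @param region_label FG, FW, TG or TW.
#' @param image_shape canvas `c(rows, cols)` in pixels.
#' @param pixel_scale micrometres per pixel.
#' @param target_burden target DAB percentage area in `[0, 100]` (random
#'   layout).
#' @param class_mix named probability vector over the normal morphology
#'   classes (and optionally rod); must sum to 1.
#' @param dystrophy_severity planted ordinal severity 1-5.
#' @param layout `"random"` or `"spaced"`.
#' @param n_cells number of planted cells (spaced layout).
#' @param nucleus_density haematoxylin nuclei per pixel^2.
#' @param stain_noise stain-noise amplitude multiplier (1 = default jitter).
#' @param seed integer seed; rendering is bit-reproducible given the spec.
#' @return an object of class `region_spec`.
#' @export
region_spec <- function(region_label = "FG", image_shape = c(2000, 2000),
                        pixel_scale = 0.5, target_burden = 5,
                        class_mix = c(ramified = 0.45, amoeboid = 0.3,
                                      hypertrophic = 0.25),
                        dystrophy_severity = 1,
                        layout = c("random", "spaced"), n_cells = 25,
                        nucleus_density = 1e-4, stain_noise = 1, seed = 1) {
  layout <- match.arg(layout)
  stopifnot(length(image_shape) == 2, all(image_shape >= 64), pixel_scale > 0)
  if (target_burden < 0 || target_burden > 100)
    stop("target_burden must lie in [0, 100]")
  if (!dystrophy_severity %in% 1:5)
    stop("dystrophy_severity must be an integer in 1..5")
  if (is.null(names(class_mix)) ||
      !all(names(class_mix) %in% MORPH_CLASSES))
    stop("class_mix must be named with morphology classes")
  if (abs(sum(class_mix) - 1) > 1e-9)
    stop("class_mix must sum to 1")
  structure(list(region_label = region_label,
                 image_shape = as.integer(image_shape),
                 pixel_scale = pixel_scale, target_burden = target_burden,
                 class_mix = class_mix,
                 dystrophy_severity = as.integer(dystrophy_severity),
                 layout = layout, n_cells = as.integer(n_cells),
                 nucleus_density = nucleus_density,
                 stain_noise = stain_noise, seed = as.integer(seed)),
            class = "region_spec")
}

# dystrophic fraction planted at each severity (spaced layout)
severity_fraction <- c(0, 0.32, 0.72, 1, 1)

paste_patch <- function(mask, patch, r0, c0) {
  # r0, c0: top-left of the patch in the parent (1-based); clipped placement
  pr <- nrow(patch); pc <- ncol(patch)
  rr <- r0:(r0 + pr - 1); cc <- c0:(c0 + pc - 1)
  ok_r <- rr >= 1 & rr <= nrow(mask)
  ok_c <- cc >= 1 & cc <= ncol(mask)
  sub <- patch[ok_r, ok_c, drop = FALSE]
  mask[rr[ok_r], cc[ok_c]] <- pmax(mask[rr[ok_r], cc[ok_c]], sub)
  mask
}

place_random_burden <- function(spec) {
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  mask <- matrix(0L, nr, nc)
  planted <- list()
  npx <- nr * nc
  target <- round(spec$target_burden / 100 * npx)
  if (target == 0)
    return(list(mask = mask, planted = planted))
  if (spec$target_burden > 60)
    stop(sprintf(paste0("target burden %.3g%% is infeasible: above ~60%% ",
                        "areal fraction overlapping cell stamps no longer ",
                        "resemble stained tissue"), spec$target_burden))
  lo <- ceiling(0.9 * target); hi <- floor(1.1 * target)
  cur <- 0L
  rejects <- 0L
  classes <- names(spec$class_mix)
  while (cur < lo) {
    if (rejects > 500L)
      stop(sprintf(paste0("target burden %.3g%% is infeasible for a %dx%d ",
                          "canvas (placement rejection cap reached at ",
                          "%.3g%% realised)"),
                   spec$target_burden, nr, nc, 100 * cur / npx))
    cls <- sample(classes, 1, prob = spec$class_mix)
    st <- make_cell_stamp(cls, spec$pixel_scale)
    pr <- nrow(st$mask); pc <- ncol(st$mask)
    if (pr >= nr || pc >= nc) { rejects <- rejects + 1L; next }
    r0 <- sample.int(nr - pr + 1L, 1L)
    c0 <- sample.int(nc - pc + 1L, 1L)
    sub <- mask[r0:(r0 + pr - 1), c0:(c0 + pc - 1)]
    added <- sum(st$mask == 1L & sub == 0L)
    if (added == 0L || cur + added > hi) { rejects <- rejects + 1L; next }
    mask[r0:(r0 + pr - 1), c0:(c0 + pc - 1)] <- pmax(sub, st$mask)
    cur <- cur + added
    planted[[length(planted) + 1]] <- data.frame(
      morph_class = cls,
      centroid_row = r0 + st$anchor[1] - 1,
      centroid_col = c0 + st$anchor[2] - 1,
      area_px = sum(st$mask),
      is_dystrophic = cls == "dystrophic",
      circularity = st$circularity,
      n_tips = if (is.na(st$n_tips)) NA_integer_ else st$n_tips)
  }
  list(mask = mask, planted = planted)
}

place_spaced <- function(spec) {
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  sc <- spec$pixel_scale
  mask <- matrix(0L, nr, nc)
  pitch <- ceiling(55 / sc)      # 55 um between cell centres
  margin <- ceiling(23 / sc)
  grows <- seq(margin, nr - margin, by = pitch)
  gcols <- seq(margin, nc - margin, by = pitch)
  capacity <- length(grows) * length(gcols)
  n <- spec$n_cells
  if (n > capacity)
    stop(sprintf(paste0("cannot place %d separated cells on a %dx%d canvas ",
                        "(capacity %d at %.0f um spacing)"),
                 n, nr, nc, capacity, pitch * sc))
  sites <- expand.grid(r = grows, c = gcols)
  sites <- sites[sample.int(nrow(sites), n), , drop = FALSE]
  f <- severity_fraction[spec$dystrophy_severity]
  n_dys <- round(f * n)
  classes <- character(n)
  if (n_dys > 0) classes[seq_len(n_dys)] <- "dystrophic"
  if (n_dys < n)
    classes[(n_dys + 1):n] <- sample(names(spec$class_mix), n - n_dys,
                                     replace = TRUE, prob = spec$class_mix)
  classes <- classes[sample.int(n)]
  with_soma <- spec$dystrophy_severity <= 4
  jit <- floor(4 / sc)
  planted <- vector("list", n)
  for (i in seq_len(n)) {
    st <- make_cell_stamp(classes[i], sc, with_soma = with_soma)
    r0 <- round(sites$r[i] + runif(1, -jit, jit) - st$anchor[1])
    c0 <- round(sites$c[i] + runif(1, -jit, jit) - st$anchor[2])
    mask <- paste_patch(mask, st$mask, r0, c0)
    planted[[i]] <- data.frame(
      morph_class = classes[i],
      centroid_row = r0 + st$anchor[1] - 1,
      centroid_col = c0 + st$anchor[2] - 1,
      area_px = sum(st$mask),
      is_dystrophic = classes[i] == "dystrophic",
      circularity = st$circularity,
      n_tips = if (is.na(st$n_tips)) NA_integer_ else st$n_tips)
  }
  n_puncta <- 0L
  if (spec$dystrophy_severity == 5) {
    # generalised punctate staining: sub-exclusion-diameter debris, planted
    # until it holds ~55% of the total stained area
    cell_area <- sum(mask)
    target <- 1.5 * cell_area
    punct <- 0
    while (punct < target) {
      rad <- runif(1, 0.75, 1.3) / sc
      r0 <- runif(1, margin / 2, nr - margin / 2)
      c0 <- runif(1, margin / 2, nc - margin / 2)
      rr <- clip(floor(r0 - rad):ceiling(r0 + rad), 1, nr)
      cc <- clip(floor(c0 - rad):ceiling(c0 + rad), 1, nc)
      g <- expand.grid(r = unique(rr), c = unique(cc))
      g <- g[(g$r - r0)^2 + (g$c - c0)^2 <= rad^2, , drop = FALSE]
      idx <- cbind(g$r, g$c)
      punct <- punct + sum(mask[idx] == 0L)
      mask[idx] <- 1L
      n_puncta <- n_puncta + 1L
    }
  }
  list(mask = mask, planted = planted, n_puncta = n_puncta)
}

#' Render a synthetic stained region with ground truth
#'
#' Produces an 8-bit RGB raster in which DAB-positive cell pixels are brown
#' (hue about 15, saturation about 70 on the 0-255 scale, inside the default
#' detector band), haematoxylin nuclei blue-violet (hue about 150) and the
#' background near-white (saturation below 40), together with the matching
#' ground-truth record. Rendering is bit-reproducible from the spec.
#'
#' @param spec a [region_spec()].
#' @return list with `image` (a [region_image()]), `truth` (planted cell
#'   table, `planted_burden` %, `planted_severity`, presence flags, the
#'   planted binary `mask`) and `spec`.
#' @export
render_region <- function(spec) {
  stopifnot(inherits(spec, "region_spec"))
  set.seed(spec$seed)
  placed <- if (spec$layout == "random") place_random_burden(spec)
            else place_spaced(spec)
  mask <- placed$mask
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  npx <- nr * nc
  noise <- spec$stain_noise

  # background: near-white with a faint cool tint (saturation stays < 40)
  v_bg <- clip(0.95 + rnorm(npx, 0, 0.008 * noise), 0.90, 0.985)
  img <- array(0, c(nr, nc, 3))
  img[, , 1] <- v_bg - 0.004
  img[, , 2] <- v_bg
  img[, , 3] <- clip(v_bg + 0.004, 0, 1)

  # haematoxylin nuclei (drawn under the DAB mask)
  n_nuc <- round(spec$nucleus_density * npx)
  if (n_nuc > 0) {
    nucmask <- matrix(0L, nr, nc)
    nr0 <- runif(n_nuc, 3, nr - 2)
    nc0 <- runif(n_nuc, 3, nc - 2)
    rad <- runif(n_nuc, 1.5, 3) / spec$pixel_scale
    for (i in seq_len(n_nuc))
      nucmask <- paint_disc(nucmask, nr0[i], nc0[i], rad[i])
    nid <- which(nucmask == 1L & mask == 0L)
    if (length(nid) > 0) {
      h <- clip(150 + rnorm(length(nid), 0, 4 * noise), 138, 162) / 255
      s <- clip(115 + rnorm(length(nid), 0, 8 * noise), 80, 150) / 255
      v <- clip(125 + rnorm(length(nid), 0, 10 * noise), 90, 160) / 255
      rgb <- hsv_to_rgb(h, s, v)
      for (ch in 1:3) {
        pl <- img[, , ch]; pl[nid] <- rgb[, ch]; img[, , ch] <- pl
      }
    }
  }

  # DAB-brown cell pixels: hue and saturation inside the detector band with
  # margin for 8-bit quantisation
  did <- which(mask == 1L)
  if (length(did) > 0) {
    h <- clip(15 + runif(length(did), -5, 5) * noise, 8, 22) / 255
    s <- clip(70 + runif(length(did), -4, 4) * noise, 64, 76) / 255
    v <- runif(length(did), 0.35, 0.55)
    rgb <- hsv_to_rgb(h, s, v)
    for (ch in 1:3) {
      pl <- img[, , ch]; pl[did] <- rgb[, ch]; img[, , ch] <- pl
    }
  }

  img <- round(img * 255) / 255 # 8-bit quantisation: in-memory == on-disk

  planted <- if (length(placed$planted) > 0) do.call(rbind, placed$planted)
             else data.frame(morph_class = character(),
                             centroid_row = numeric(),
                             centroid_col = numeric(), area_px = numeric(),
                             is_dystrophic = logical(),
                             circularity = numeric(), n_tips = integer())
  truth <- list(
    planted_cells = planted,
    planted_burden = 100 * sum(mask) / npx,
    planted_severity = spec$dystrophy_severity,
    planted_rod_present = any(planted$morph_class == "rod"),
    planted_hypertrophic_present = any(planted$morph_class == "hypertrophic"),
    n_puncta = if (is.null(placed$n_puncta)) 0L else placed$n_puncta,
    mask = mask
  )
  list(image = region_image(img, spec$pixel_scale,
                            region_label = spec$region_label),
       truth = truth, spec = spec)
}

#' Write a rendered region image to disk
#'
#' @param image a `region_image`.
#' @param path output path; format chosen by extension (`.tif`/`.tiff` or
#'   `.png`), 8-bit RGB.
#' @export
write_region_image <- function(image, path) {
  stopifnot(inherits(image, "region_image"))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(image$pixels, path, bits.per.sample = 8L)
  } else if (ext == "png") {
    png::writePNG(image$pixels, path)
  } else stop("unsupported image format: ", ext)
  invisible(path)
}

#' Read a region image from disk
#'
#' @param path TIFF or PNG path.
#' @param pixel_scale micrometres per pixel of the stored raster.
#' @param ... passed to [region_image()] (region label, marker, case id).
#' @return a `region_image`.
#' @export
read_region_image <- function(path, pixel_scale, ...) {
  ext <- tolower(tools::file_ext(path))
  px <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
        else if (ext == "png") png::readPNG(path)
        else stop("unsupported image format: ", ext)
  if (length(dim(px)) == 3 && dim(px)[3] == 4) px <- px[, , 1:3]
  region_image(px, pixel_scale, ...)
}
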