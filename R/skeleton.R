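# Euclidean dilation of a binary mask by `radius` pixels
dilate_mask <- function(mask, radius) {
  nr <- nrow(mask); nc <- ncol(mask)
  p <- matrix(1, nr + 2, nc + 2)
  p[2:(nr + 1), 2:(nc + 1)] <- 1 - (mask != 0)
  d <- as.matrix(EBImage::distmap(p))[2:(nr + 1), 2:(nc + 1)]
  matrix(as.integer(mask != 0 | d <= radius), nr, nc)
}

# order the pixels of a (near-)simple skeleton branch into a path
order_branch_path <- function(coords) {
  n <- nrow(coords)
  if (n <= 2) return(seq_len(n))
  adj <- function(i, j) max(abs(coords[i, ] - coords[j, ])) == 1
  deg <- integer(n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && adj(i, j)) deg[i] <- deg[i] + 1L
  start <- which(deg == 1)[1]
  if (is.na(start)) start <- 1L
  path <- integer(n); used <- logical(n)
  path[1] <- start; used[start] <- TRUE
  for (k in 2:n) {
    prev <- path[k - 1]
    nxt <- which(!used & vapply(seq_len(n), function(j) adj(prev, j), TRUE))
    if (length(nxt) == 0) return(path[seq_len(k - 1)])
    path[k] <- nxt[1]; used[nxt[1]] <- TRUE
  }
  path
}

#' Skeleton summary of a cell (or fragmented cell cluster)
#'
#' Thins the mask to a medial-axis skeleton (Zhang-Suen) and summarises the
#' process architecture: skeleton endpoints (process tips), junctions (branch
#' points), total process length, a robust process width from the distance
#' transform along the skeleton (soma region excluded), branch tortuosity
#' (arc/chord), bead count (isolated width maxima on thin processes, the
#' beading seen in dystrophic cells), and soma detection via the maximal
#' inscribed disc.
#'
#' @param cell a `cell_object`, a cell cluster, or a binary mask matrix.
#' @param pixel_scale micrometres per pixel.
#' @param thresholds a [dystrophy_thresholds()] list (soma and bead settings).
#' @return an object of class `skeleton_summary` with fields `n_fragments`,
#'   `n_endpoints`, `n_junctions`, `total_process_length` (um),
#'   `mean_process_width` (um), `tortuosity` (>= 1), `bead_count`,
#'   `soma_detected`, `soma_diameter` (um).
#' @export
skeletonize_cell <- function(cell, pixel_scale = NULL,
                             thresholds = dystrophy_thresholds()) {
  if (is.matrix(cell)) {
    mask <- matrix(as.integer(cell != 0), nrow = nrow(cell))
    sc <- pixel_scale
  } else {
    mask <- cell$mask
    sc <- if (is.null(pixel_scale)) cell$pixel_scale else pixel_scale
  }
  stopifnot(!is.null(sc), sc > 0, sum(mask) > 0)
  lab <- cpp_label8(mask)
  nfrag <- max(lab)
  dt <- dist_transform(mask)
  maxdt <- max(dt)
  soma_diam <- (2 * maxdt - 1) * sc
  soma_detected <- soma_diam >= thresholds$soma_min
  soma_ctr <- arrayInd(which.max(dt), dim(dt))[1, ]

  skel <- matrix(0L, nrow(mask), ncol(mask))
  for (k in seq_len(nfrag)) {
    comp <- matrix(as.integer(lab == k), nrow = nrow(lab))
    skel <- skel | cpp_thin(comp)
  }
  skel <- matrix(as.integer(skel), nrow = nrow(mask))
  sidx <- which(skel == 1L)
  if (length(sidx) == 0) { # fully eroded dot
    return(structure(list(n_fragments = nfrag, n_endpoints = 0L,
                          n_junctions = 0L, total_process_length = 0,
                          mean_process_width = soma_diam, tortuosity = 1,
                          bead_count = 0L, soma_detected = soma_detected,
                          soma_diameter = soma_diam),
                     class = "skeleton_summary"))
  }
  cnt <- neighbour_count8(skel)
  cross <- crossing_number8(skel)
  n_end <- sum(skel == 1L & cnt == 1L)
  # branch points via the crossing number: raw neighbour counts flag the
  # corner pixels of diagonal runs as spurious junctions
  junc <- matrix(as.integer(skel == 1L & cross >= 3L), nrow = nrow(skel))
  n_junc <- if (sum(junc) > 0) max(cpp_label8(junc)) else 0L
  adj <- adjacency_counts(skel)
  total_len <- (adj["axial"] + sqrt(2) * adj["diagonal"]) * sc

  widths <- (2 * dt[sidx] - 1) * sc
  scoord <- arrayInd(sidx, dim(skel))
  # the widest point acts as the soma zone for width/bead profiling even
  # when it is below the soma-detection diameter
  away <- sqrt((scoord[, 1] - soma_ctr[1])^2 +
               (scoord[, 2] - soma_ctr[2])^2) > 1.5 * maxdt
  wproc <- if (any(away)) widths[away] else widths
  width <- stats::median(wproc)
  in_soma_zone <- matrix(FALSE, nrow(skel), ncol(skel))
  in_soma_zone[scoord[!away, , drop = FALSE]] <- TRUE

  # width maxima within a few pixels of a branch point are junction
  # geometry, not beads; exclude that zone from bead candidacy
  jzone <- if (sum(junc) > 0) dilate_mask(junc, 3) == 1L
           else matrix(FALSE, nrow(skel), ncol(skel))
  # branches: skeleton minus junction pixels, cut at the soma zone so that
  # two radial processes joined across the soma are not read as one
  # hairpin branch
  branches <- matrix(as.integer(skel == 1L & cross < 3L & !in_soma_zone),
                     nrow = nrow(skel))
  blab <- cpp_label8(branches)
  torts <- numeric(0)
  beads <- 0L
  for (k in seq_len(max(blab))) {
    bidx <- which(blab == k)
    if (length(bidx) < 5) next
    bmask <- matrix(as.integer(blab == k), nrow = nrow(blab))
    # only simple paths contribute (no internal branching left over)
    if (any(neighbour_count8(bmask)[bidx] > 2)) next
    bcoord <- arrayInd(bidx, dim(blab))
    ba <- adjacency_counts(bmask)
    arc <- ba["axial"] + sqrt(2) * ba["diagonal"]
    path <- order_branch_path(bcoord)
    if (length(path) < length(bidx)) next
    ends <- bcoord[path[c(1, length(path))], , drop = FALSE]
    chord <- sqrt(sum((ends[1, ] - ends[2, ])^2))
    if (chord >= 5) torts <- c(torts, unname(arc) / chord)
    # beading: isolated width maxima on thin processes; the raw width
    # profile is smoothed first because rasterisation makes the distance
    # transform oscillate along straight branches
    w <- (2 * dt[cbind(bcoord[path, 1], bcoord[path, 2])] - 1) * sc
    if (length(w) >= 7 && stats::median(w) <= thresholds$bead_thin_max) {
      ws <- stats::filter(w, rep(1 / 3, 3), sides = 2)
      ws[is.na(ws)] <- w[is.na(ws)]
      ws <- as.numeric(ws)
      med <- stats::median(ws)
      near_junc <- jzone[cbind(bcoord[path, 1], bcoord[path, 2])]
      for (i in 3:(length(ws) - 2)) {
        win <- ws[max(1, i - 4):min(length(ws), i + 4)]
        if (!near_junc[i] && ws[i] > ws[i - 1] && ws[i] >= ws[i + 1] &&
            ws[i] >= thresholds$bead_ratio * med &&
            ws[i] >= thresholds$bead_w_min &&
            ws[i] <= thresholds$bead_w_max &&
            ws[i] - min(win) >= thresholds$bead_prom)
          beads <- beads + 1L
      }
    }
  }
  structure(list(n_fragments = nfrag, n_endpoints = n_end,
                 n_junctions = n_junc,
                 total_process_length = unname(total_len),
                 mean_process_width = width,
                 tortuosity = if (length(torts) > 0) mean(torts) else 1,
                 bead_count = beads, soma_detected = soma_detected,
                 soma_diameter = soma_diam),
            class = "skeleton_summary")
}
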