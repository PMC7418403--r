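# Independent oracles used for cross-checking the package implementations.
# They are deliberately written as plain breadth-first searches and brute
# enumerations, sharing no code with the package internals.

# 8-connected labelling by queue-based flood fill
bfs_label_oracle <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (mask[i, j] != 0 && lab[i, j] == 0L) {
      nxt <- nxt + 1L
      queue <- list(c(i, j)); lab[i, j] <- nxt
      while (length(queue) > 0) {
        p <- queue[[1]]; queue <- queue[-1]
        for (dr in -1:1) for (dc in -1:1) {
          ni <- p[1] + dr; nj <- p[2] + dc
          if (ni >= 1 && ni <= nr && nj >= 1 && nj <= nc &&
              mask[ni, nj] != 0 && lab[ni, nj] == 0L) {
            lab[ni, nj] <- nxt
            queue[[length(queue) + 1]] <- c(ni, nj)
          }
        }
      }
    }
  }
  lab
}

# all permutations of 1..n (n <= 8)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  out
}

kw_stat_oracle <- function(x, g) {
  N <- length(x); r <- rank(x)
  Rj <- tapply(r, g, sum); n <- tabulate(factor(g))
  H <- 12 / (N * (N + 1)) * sum(Rj^2 / n) - 3 * (N + 1)
  tt <- table(x)
  ct <- 1 - sum(tt^3 - tt) / (N^3 - N)
  if (ct <= 0) 0 else H / ct
}

# Kruskal-Wallis permutation p by iterating over every permutation of the
# observations (distinct from the package's combination enumeration)
brute_kw_p <- function(x, g) {
  N <- length(x)
  perms <- all_perms(N)
  h_obs <- kw_stat_oracle(x, g)
  hs <- apply(perms, 1, function(p) kw_stat_oracle(x[p], g))
  mean(hs >= h_obs - 1e-9)
}

dunn_z_oracle <- function(x, g, i, j) {
  N <- length(x); r <- rank(x)
  rb <- tapply(r, g, mean); n <- tabulate(factor(g))
  tt <- table(x)
  v <- N * (N + 1) / 12 - sum(tt^3 - tt) / (12 * (N - 1))
  se <- sqrt(v * (1 / n[i] + 1 / n[j]))
  if (se == 0) 0 else (rb[i] - rb[j]) / se
}

# all pairwise Dunn permutation p-values in one enumeration pass
brute_dunn_all <- function(x, g) {
  k <- nlevels(factor(g))
  pairs <- t(utils::combn(k, 2))
  perms <- all_perms(length(x))
  z_obs <- vapply(seq_len(nrow(pairs)), function(t)
    dunn_z_oracle(x, g, pairs[t, 1], pairs[t, 2]), 0)
  zs <- t(apply(perms, 1, function(p)
    vapply(seq_len(nrow(pairs)), function(t)
      dunn_z_oracle(x[p], g, pairs[t, 1], pairs[t, 2]), 0)))
  vapply(seq_len(nrow(pairs)), function(t)
    mean(abs(zs[, t]) >= abs(z_obs[t]) - 1e-9), 0)
}

brute_ranksum_p <- function(a, b) {
  na <- length(a); N <- na + length(b)
  r <- rank(c(a, b))
  cmb <- utils::combn(N, na)
  U <- apply(cmb, 2, function(ix) sum(r[ix]) - na * (na + 1) / 2)
  uo <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  min(1, 2 * min(mean(U <= uo + 1e-9), mean(U >= uo - 1e-9)))
}

# signed-rank p by explicit 2^n sign enumeration
brute_signedrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- signs %*% r
  min(1, 2 * min(mean(Ws <= W + 1e-9), mean(Ws >= W - 1e-9)))
}

# two-sided Fisher p for a 2x2 table by hypergeometric enumeration
brute_fisher_p <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  xs <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(xs, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# intersection area of two axis-aligned squares given as (row, col, side)
rect_intersection_oracle <- function(a, b) {
  dr <- min(a[1] + a[3], b[1] + b[3]) - max(a[1], b[1])
  dc <- min(a[2] + a[3], b[2] + b[3]) - max(a[2], b[2])
  max(dr, 0) * max(dc, 0)
}

# rasterised disc: pixels whose centres lie within `r` of the centre
disc_mask <- function(r, pad = 2) {
  d <- 2 * r + 1 + 2 * pad
  ctr <- (d + 1) / 2
  m <- matrix(0L, d, d)
  for (i in 1:d) for (j in 1:d)
    if ((i - ctr)^2 + (j - ctr)^2 <= r^2) m[i, j] <- 1L
  m
}

# place several discs of given pixel diameters on one canvas, well separated
discs_fixture <- function(diams, gap = 30) {
  side <- max(diams) + gap
  n <- length(diams)
  m <- matrix(0L, side + gap, n * side + gap)
  for (k in seq_len(n)) {
    r <- diams[k] / 2
    ctr_r <- gap / 2 + side / 2
    ctr_c <- (k - 1) * side + side / 2 + gap / 2
    for (i in seq_len(nrow(m))) {
      cols <- which((i - ctr_r)^2 + (seq_len(ncol(m)) - ctr_c)^2 <= r^2)
      if (length(cols) > 0) m[i, cols] <- 1L
    }
  }
  m
}

# wrap a binary mask as a cell-like object for the classifier
mask_as_cluster <- function(mask, pixel_scale = 0.5) {
  micromorph:::cluster_from_mask(matrix(as.integer(mask != 0),
                                        nrow = nrow(mask)),
                                 pixel_scale = pixel_scale)
}
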