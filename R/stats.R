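# --- internal helpers ----------------------------------------------------

# two-sided p for a discrete statistic: doubled smaller tail, capped at 1
two_sided <- function(p_lo, p_hi) min(1, 2 * min(p_lo, p_hi))

as_groups <- function(x, g) {
  if (is.list(x) && is.null(g)) {
    g <- rep(seq_along(x), lengths(x))
    x <- unlist(x, use.names = FALSE)
  }
  stopifnot(length(x) == length(g))
  g <- factor(g)
  if (any(tabulate(g) == 0) || nlevels(g) < 2)
    stop("each group must contain at least one observation (>= 2 groups)")
  list(x = as.numeric(x), g = g)
}

# enumerate all distinct assignments of `vals` into groups of sizes `sizes`
# and call fun(list_of_group_values) for each; returns a list of results
enumerate_assignments <- function(vals, sizes, fun) {
  out <- list()
  recurse <- function(remaining_idx, k, picked) {
    if (k > length(sizes)) {
      out[[length(out) + 1]] <<- fun(lapply(picked, function(i) vals[i]))
      return(invisible())
    }
    if (k == length(sizes)) {
      recurse(integer(0), k + 1L, c(picked, list(remaining_idx)))
      return(invisible())
    }
    cmb <- combn(length(remaining_idx), sizes[k])
    for (j in seq_len(ncol(cmb))) {
      take <- remaining_idx[cmb[, j]]
      recurse(setdiff(remaining_idx, take), k + 1L, c(picked, list(take)))
    }
  }
  recurse(seq_along(vals), 1L, list())
  out
}

kw_statistic <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  n <- lengths(groups)
  N <- length(x)
  r <- rank(x)
  Rj <- vapply(split(r, rep(seq_along(groups), n)), sum, 0)
  H <- 12 / (N * (N + 1)) * sum(Rj^2 / n) - 3 * (N + 1)
  ties <- table(x)
  tie_term <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (tie_term <= 0) return(0) # all observations equal
  H / tie_term
}

# --- exported tests ------------------------------------------------------

#' Kruskal-Wallis rank test with tie correction
#'
#' H is tie-corrected; with all observations equal H is defined as 0 (p = 1).
#' The p-value comes from the chi-square approximation (df = k - 1), or from
#' exhaustive permutation enumeration for small samples (`method = "exact"`,
#' chosen automatically for total n <= 12).
#'
#' @param x numeric vector of observations, or a list of group samples.
#' @param g group labels (ignored when `x` is a list).
#' @param method `"auto"`, `"asymptotic"` or `"exact"`.
#' @return list of class `mg_test`: `statistic` (H), `p_value`, `df`,
#'   `method`, `n`.
#' @export
kruskal_wallis <- function(x, g = NULL, method = c("auto", "asymptotic",
                                                   "exact")) {
  method <- match.arg(method)
  d <- as_groups(x, g)
  groups <- split(d$x, d$g)
  N <- length(d$x)
  if (N < 3) stop("need at least 3 observations in total")
  k <- length(groups)
  H <- kw_statistic(groups)
  # enumeration grows multinomially; auto-exact only for very small samples,
  # the n <= 12 exact mode remains available via method = "exact"
  exact <- method == "exact" || (method == "auto" && N <= 9)
  if (exact) {
    Hs <- unlist(enumerate_assignments(d$x, lengths(groups), kw_statistic))
    p <- mean(Hs >= H - 1e-9)
  } else {
    p <- if (length(unique(d$x)) == 1) 1
         else pchisq(H, k - 1, lower.tail = FALSE)
  }
  structure(list(statistic = unname(H), p_value = unname(p), df = k - 1,
                 method = if (exact) "exact" else "chi-square",
                 n = lengths(groups)),
            class = "mg_test")
}

dunn_z <- function(groups, pair_idx) {
  x <- unlist(groups, use.names = FALSE)
  n <- lengths(groups)
  N <- length(x)
  r <- rank(x)
  rbar <- vapply(split(r, rep(seq_along(groups), n)), mean, 0)
  ties <- table(x)
  tie_sum <- sum(ties^3 - ties)
  v <- N * (N + 1) / 12 - tie_sum / (12 * (N - 1))
  vapply(seq_len(nrow(pair_idx)), function(t) {
    i <- pair_idx[t, 1]; j <- pair_idx[t, 2]
    se <- sqrt(v * (1 / n[i] + 1 / n[j]))
    if (se == 0) 0 else (rbar[i] - rbar[j]) / se
  }, 0)
}

#' Dunn's post hoc pairwise comparisons after Kruskal-Wallis
#'
#' Pairwise z statistics from mean-rank differences with tie-corrected
#' variance, two-sided p-values, unadjusted by default (`p.adjust` methods
#' available via `adjust`). `method = "exact"` computes each pair's p by
#' exhaustive enumeration of group assignments (auto for total n <= 12 when
#' `method = "auto"`).
#'
#' @param x numeric vector or list of group samples.
#' @param g group labels (ignored when `x` is a list).
#' @param adjust p adjustment method (`"none"`, `"holm"`, `"bonferroni"`,
#'   `"BH"`, ...; see [stats::p.adjust()]).
#' @param method `"auto"`, `"asymptotic"` or `"exact"`.
#' @return data.frame with one row per group pair: `group1`, `group2`, `z`,
#'   `p_value`.
#' @export
dunn_posthoc <- function(x, g = NULL, adjust = "none",
                         method = c("auto", "asymptotic", "exact")) {
  method <- match.arg(method)
  d <- as_groups(x, g)
  groups <- split(d$x, d$g)
  k <- length(groups)
  if (k < 2) stop("need at least 2 groups")
  N <- length(d$x)
  pair_idx <- t(combn(k, 2))
  z <- dunn_z(groups, pair_idx)
  exact <- method == "exact" || (method == "auto" && N <= 9)
  if (exact) {
    zs <- enumerate_assignments(d$x, lengths(groups),
                                function(gr) dunn_z(gr, pair_idx))
    zs <- matrix(unlist(zs), ncol = nrow(pair_idx), byrow = TRUE)
    p <- vapply(seq_len(nrow(pair_idx)), function(t)
      mean(abs(zs[, t]) >= abs(z[t]) - 1e-9), 0)
  } else {
    p <- 2 * pnorm(-abs(z))
  }
  p <- stats::p.adjust(p, method = adjust)
  data.frame(group1 = levels(d$g)[pair_idx[, 1]],
             group2 = levels(d$g)[pair_idx[, 2]],
             z = z, p_value = p)
}

#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' U statistic from midranks. Exact p by enumeration of the U distribution
#' over all subsets (auto for total n <= 12, handles ties); otherwise a
#' tie-corrected normal approximation (no continuity correction). Two-sided
#' p is the doubled smaller tail, capped at 1.
#'
#' @param a,b numeric samples.
#' @param method `"auto"`, `"asymptotic"` or `"exact"`.
#' @return list of class `mg_test`: `statistic` (U for sample `a`),
#'   `p_value`, `method`, `n`.
#' @export
rank_sum <- function(a, b, method = c("auto", "asymptotic", "exact")) {
  method <- match.arg(method)
  stopifnot(length(a) >= 1, length(b) >= 1)
  na <- length(a); nb <- length(b); N <- na + nb
  r <- rank(c(a, b))
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  exact <- method == "exact" || (method == "auto" && N <= 12)
  if (exact) {
    cmb <- combn(N, na)
    Us <- colSums(matrix(r[cmb], nrow = na)) - na * (na + 1) / 2
    p <- two_sided(mean(Us <= U + 1e-9), mean(Us >= U - 1e-9))
  } else {
    mu <- na * nb / 2
    ties <- table(r)
    sig2 <- na * nb / 12 *
      ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sig2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu) / sqrt(sig2)
      p <- 2 * pnorm(-abs(z))
    }
  }
  structure(list(statistic = unname(U), p_value = unname(min(p, 1)),
                 method = if (exact) "exact" else "normal",
                 n = c(na, nb)),
            class = "mg_test")
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Differences of exactly zero are dropped (classic convention; `zeros =
#' "pratt"` keeps them in the ranking). W is the positive-rank sum over
#' midranks of |d|. The exact null distribution is computed by convolution
#' over the (possibly tied) ranks for n <= 25; above that a normal
#' approximation with tie and zero corrections is used. If every difference
#' is zero the result is degenerate with p = 1.
#'
#' @param x first sample, list of pairs, or vector of differences.
#' @param y optional second sample (paired with `x`).
#' @param method `"auto"`, `"asymptotic"` or `"exact"`.
#' @param zeros `"drop"` (default) or `"pratt"`.
#' @return list of class `mg_test`: `statistic` (W), `p_value`, `n_used`,
#'   `method`, `degenerate`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL,
                                 method = c("auto", "asymptotic", "exact"),
                                 zeros = c("drop", "pratt")) {
  method <- match.arg(method)
  zeros <- match.arg(zeros)
  d <- if (is.null(y)) as.numeric(x) else as.numeric(x) - as.numeric(y)
  stopifnot(length(d) >= 1)
  if (all(d == 0))
    return(structure(list(statistic = 0, p_value = 1, n_used = 0L,
                          method = "degenerate", degenerate = TRUE),
                     class = "mg_test"))
  if (zeros == "drop") d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  if (zeros == "pratt") {
    W <- sum(r[d > 0])
    r_nz <- r[d != 0]
  } else {
    W <- sum(r[d > 0])
    r_nz <- r
  }
  exact <- (method == "exact" || (method == "auto" && length(r_nz) <= 25)) &&
    zeros == "drop"
  if (exact) {
    # exact distribution of W by convolution over doubled ranks (integers)
    r2 <- round(2 * r_nz)
    S <- sum(r2)
    f <- numeric(S + 1)
    f[1] <- 1
    for (rr in r2) {
      g <- f
      g[(rr + 1):(S + 1)] <- g[(rr + 1):(S + 1)] + f[1:(S + 1 - rr)]
      f <- g
    }
    f <- f / 2^length(r2)
    W2 <- round(2 * W)
    p_lo <- sum(f[1:(W2 + 1)])
    p_hi <- sum(f[(W2 + 1):(S + 1)])
    p <- two_sided(p_lo, p_hi)
    meth <- "exact"
  } else {
    # under random signs of the nonzero differences, E[W] = sum(r)/2 and
    # Var(W) = sum(r^2)/4 exactly (ties and Pratt zeros included)
    mu <- sum(r_nz) / 2
    sig2 <- sum(r_nz^2) / 4
    if (sig2 <= 0) p <- 1 else p <- 2 * pnorm(-abs((W - mu) / sqrt(sig2)))
    meth <- "normal"
  }
  structure(list(statistic = unname(W), p_value = unname(min(p, 1)),
                 n_used = length(r_nz), method = meth, degenerate = FALSE),
            class = "mg_test")
}

#' Fisher's exact test for a 2 x k contingency table
#'
#' Two-sided p by summing the probabilities of tables (with the observed
#' margins) no more probable than the observed one, via
#' [stats::fisher.test()].
#'
#' @param table 2 x k matrix of nonnegative integer counts.
#' @return list of class `mg_test`: `p_value`, `n`.
#' @export
fisher_exact <- function(table) {
  stopifnot(is.matrix(table), nrow(table) == 2)
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be nonnegative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("both margins must be positive (a zero margin carries no information)")
  p <- stats::fisher.test(table)$p.value
  structure(list(statistic = NA_real_, p_value = unname(min(p, 1)),
                 method = "fisher", n = sum(table)),
            class = "mg_test")
}
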