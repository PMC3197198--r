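## Community statistics implemented from first principles: square-root
## transform, Bray-Curtis dissimilarity, Kruskal non-metric MDS with
## isotonic regression, one-way/pairwise ANOSIM with permutation p-values,
## and SIMPER decomposition of between-group dissimilarity.

#' Square-root transform a feature matrix
#'
#' Element-wise square root, applied before Bray-Curtis to reduce the
#' emphasis on high-abundance features. No re-normalization afterwards.
#'
#' @param m non-negative numeric matrix (samples x features).
#' @return Matrix of the same shape and class.
#' @export
sqrt_transform <- function(m) {
  if (any(m < 0)) {
    stop_scatyper("negative values in feature matrix",
                  "scatyper_invalid_input")
  }
  out <- sqrt(m)
  attributes(out) <- attributes(m)
  out
}

#' Bray-Curtis dissimilarity matrix
#'
#' For samples i and j, `d(i,j) = sum_k |x_ik - x_jk| / sum_k (x_ik + x_jk)`.
#' Values lie in \[0, 1\]; 0 means identical compositions, 1 disjoint
#' support. A pair of all-zero rows is defined as distance 0, with a
#' warning.
#'
#' @param m non-negative matrix with >= 2 rows (samples).
#' @return Symmetric matrix with zero diagonal, row/col names from `m`.
#' @export
bray_curtis <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2L) {
    stop_scatyper("need at least 2 samples", "scatyper_invalid_input")
  }
  if (any(m < 0)) {
    stop_scatyper("negative values in feature matrix",
                  "scatyper_invalid_input")
  }
  num <- as.matrix(dist(m, method = "manhattan"))
  den <- outer(rowSums(m), rowSums(m), "+")
  zero <- den == 0
  if (any(zero[upper.tri(zero)])) {
    warning("pair(s) of all-zero samples: dissimilarity defined as 0")
    den[zero] <- 1
  }
  d <- num / den
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

upper_pairs <- function(n) {
  pr <- combn(n, 2L)
  list(i = pr[1L, ], j = pr[2L, ])
}

## Enumerate all distinct assignments of the multiset of group labels to
## positions (n! / prod(n_k!) labelings). Used for exact ANOSIM p-values
## on small designs.
enumerate_labelings <- function(labels) {
  labels <- as.character(labels)
  recurse <- function(remaining, positions) {
    lev <- unique(remaining)
    if (length(lev) == 1L) {
      return(list(rep(lev, length(positions))))
    }
    l1 <- lev[1L]
    k <- sum(remaining == l1)
    picks <- combn(length(positions), k, simplify = FALSE)
    out <- list()
    for (p in picks) {
      rest <- recurse(remaining[remaining != l1], positions[-p])
      for (r in rest) {
        v <- character(length(positions))
        v[p] <- l1
        v[-p] <- r
        out[[length(out) + 1L]] <- v
      }
    }
    out
  }
  recurse(labels, seq_along(labels))
}

n_distinct_labelings <- function(labels) {
  n <- length(labels)
  exp(lfactorial(n) - sum(lfactorial(table(labels))))
}

#' One-way analysis of similarities (ANOSIM)
#'
#' Rank-based test of group separation on a dissimilarity matrix. All
#' n(n-1)/2 dissimilarities are ranked (average ranks on ties) and
#' `R = (mean between-group rank - mean within-group rank) / (M/2)` with
#' `M = n(n-1)/2`. R near 0 indicates no separation, near 1 complete
#' separation; negative values indicate greater variation within than
#' between groups. The p-value is obtained by random relabeling of samples
#' with the +1 correction, `p = (1 + #{R_perm >= R_obs}) / (1 + B)`; when
#' the number of distinct labelings is at most `n_permutations` the exact
#' permutation distribution is enumerated instead.
#'
#' @param d symmetric dissimilarity matrix (or `dist`).
#' @param grouping factor-like vector of group labels, aligned with the
#'   rows of `d` (or named by sample id).
#' @param n_permutations number of random relabelings (default 999).
#' @param seed integer seed for the permutation stream.
#' @param pairwise if `TRUE`, additionally run each pair of levels
#'   separately on the corresponding submatrix.
#' @return Object of class `anosim_result`: `statistic`, `p_value`,
#'   `n_permutations` (actually used), `exact` flag, `grouping`, and
#'   optionally `pairwise` (data frame of level pairs).
#' @export
anosim <- function(d, grouping, n_permutations = 999, seed = 1L,
                   pairwise = FALSE) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (!is.null(names(grouping)) && !is.null(rownames(d))) {
    grouping <- grouping[rownames(d)]
  }
  grouping <- as.character(grouping)
  stopifnot(length(grouping) == n)
  sizes <- table(grouping)
  if (length(sizes) < 2L || any(sizes < 2L)) {
    stop_scatyper("each group must have >= 2 samples and >= 2 groups",
                  "scatyper_invalid_grouping")
  }
  pr <- upper_pairs(n)
  dv <- d[cbind(pr$i, pr$j)]
  rk <- rank(dv)                      # average ranks on ties
  M <- length(rk)
  S_all <- sum(rk)
  r_stat_cols <- function(lab_mat) {
    ## lab_mat: n x B matrix of labels; returns R per column
    W <- lab_mat[pr$i, , drop = FALSE] == lab_mat[pr$j, , drop = FALSE]
    sw <- colSums(rk * W)
    nw <- colSums(W)
    rw <- sw / nw
    rb <- (S_all - sw) / (M - nw)
    (rb - rw) / (M / 2)
  }
  R_obs <- r_stat_cols(matrix(grouping, ncol = 1))[1]

  total <- n_distinct_labelings(grouping)
  if (total <= n_permutations) {
    labs <- enumerate_labelings(grouping)
    lab_mat <- matrix(unlist(labs), nrow = n)
    Rp <- r_stat_cols(lab_mat)
    p <- sum(Rp >= R_obs - 1e-12) / length(Rp)
    used <- length(Rp)
    exact <- TRUE
  } else {
    set.seed(substream_seed(seed, "anosim/perm"))
    P <- replicate(n_permutations, sample.int(n))
    lab_mat <- matrix(grouping[P], nrow = n)
    Rp <- r_stat_cols(lab_mat)
    p <- (1 + sum(Rp >= R_obs - 1e-12)) / (1 + n_permutations)
    used <- n_permutations
    exact <- FALSE
  }
  res <- structure(list(
    statistic = unname(R_obs), p_value = p, n_permutations = used,
    exact = exact, grouping = grouping, permuted_R = Rp
  ), class = "anosim_result")
  if (pairwise) {
    lv <- names(sizes)
    combos <- combn(lv, 2L, simplify = FALSE)
    rows <- lapply(combos, function(pair) {
      keep <- grouping %in% pair
      sub <- anosim(d[keep, keep, drop = FALSE], grouping[keep],
                    n_permutations = n_permutations, seed = seed,
                    pairwise = FALSE)
      data.frame(level1 = pair[1], level2 = pair[2],
                 R = sub$statistic, p_value = sub$p_value,
                 n_permutations = sub$n_permutations,
                 stringsAsFactors = FALSE)
    })
    res$pairwise <- do.call(rbind, rows)
  }
  res
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("ANOSIM: R = %.4f, p = %.4g (%s%d permutations)\n",
              x$statistic, x$p_value, if (x$exact) "exact, " else "",
              x$n_permutations))
  if (!is.null(x$pairwise)) {
    cat("Pairwise comparisons:\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

#' SIMPER: similarity percentage decomposition
#'
#' Decomposes the average Bray-Curtis dissimilarity between two groups into
#' per-feature contributions. For each between-group sample pair (i, j) the
#' feature term is `c_k = |x_ik - x_jk| / sum_m (x_im + x_jm)`; averaging
#' over pairs gives the per-feature contribution, whose sum is the average
#' between-group dissimilarity. Features are ranked by percent contribution
#' and the top 10 extracted.
#'
#' @param m feature matrix (samples x features).
#' @param grouping group labels aligned with rows of `m`.
#' @param pair character vector of the two levels to compare.
#' @return Object of class `simper_result`: `average_dissimilarity`,
#'   `contributions` (data frame sorted by contribution: feature, average
#'   contribution, percent, cumulative percent), `top10`, `degenerate` flag
#'   (`TRUE` when the groups are identical and percents are undefined).
#' @export
simper <- function(m, grouping, pair = NULL) {
  m <- as.matrix(m)
  grouping <- as.character(grouping)
  if (is.null(pair)) pair <- unique(grouping)[1:2]
  ia <- which(grouping == pair[1])
  ib <- which(grouping == pair[2])
  if (!length(ia) || !length(ib)) {
    stop_scatyper("both groups must be non-empty", "scatyper_invalid_grouping")
  }
  acc <- numeric(ncol(m))
  n_pairs <- 0L
  for (i in ia) for (j in ib) {
    den <- sum(m[i, ] + m[j, ])
    if (den > 0) acc <- acc + abs(m[i, ] - m[j, ]) / den
    n_pairs <- n_pairs + 1L
  }
  delta_k <- acc / n_pairs
  delta <- sum(delta_k)
  degenerate <- delta == 0
  pct <- if (degenerate) rep(NA_real_, length(delta_k)) else
    100 * delta_k / delta
  ord <- order(delta_k, decreasing = TRUE)
  contributions <- data.frame(
    feature = colnames(m)[ord] %||% as.character(ord),
    contribution = delta_k[ord],
    percent = pct[ord],
    stringsAsFactors = FALSE
  )
  contributions$cumulative_percent <- cumsum(contributions$percent)
  rownames(contributions) <- NULL
  structure(list(
    pair = pair,
    average_dissimilarity = delta,
    contributions = contributions,
    top10 = head(contributions, 10L),
    degenerate = degenerate
  ), class = "simper_result")
}

#' @export
print.simper_result <- function(x, ...) {
  cat(sprintf("SIMPER %s vs %s: average dissimilarity %.4f%s\n",
              x$pair[1], x$pair[2], x$average_dissimilarity,
              if (x$degenerate) " (degenerate: groups identical)" else ""))
  print(x$top10, row.names = FALSE)
  invisible(x)
}

## One Kruskal NMDS start: alternating isotonic regression (via isoreg,
## i.e. pool-adjacent-violators) and gradient descent on stress-1 with a
## step-halving line search. Both alternation steps are non-increasing in
## stress, so the recorded trace is monotone.
nmds_one_start <- function(d, x, ord, max_iter, tol) {
  n <- nrow(x)
  pr <- upper_pairs(n)
  eps <- 1e-12
  conf_dist <- function(x) {
    dx <- x[pr$i, , drop = FALSE] - x[pr$j, , drop = FALSE]
    sqrt(rowSums(dx^2)) + eps
  }
  disparities <- function(dh) {
    fit <- isoreg(dh[ord])$yf
    out <- numeric(length(dh))
    out[ord] <- fit
    out
  }
  stress_of <- function(dh, dsp) sqrt(sum((dh - dsp)^2) / sum(dh^2))
  gradient <- function(x, dh, dsp, S) {
    A <- sum((dh - dsp)^2)
    B <- sum(dh^2)
    g <- matrix(0, n, ncol(x))
    w1 <- (dh - dsp) / dh
    diff <- x[pr$i, , drop = FALSE] - x[pr$j, , drop = FALSE]
    for (a in seq_len(ncol(x))) {
      contrib_A <- w1 * diff[, a]
      contrib_B <- diff[, a]
      gA <- gB <- numeric(n)
      gA_i <- tapply(contrib_A, pr$i, sum); gA[as.integer(names(gA_i))] <- gA_i
      gA_j <- tapply(contrib_A, pr$j, sum)
      gA[as.integer(names(gA_j))] <- gA[as.integer(names(gA_j))] - gA_j
      gB_i <- tapply(contrib_B, pr$i, sum); gB[as.integer(names(gB_i))] <- gB_i
      gB_j <- tapply(contrib_B, pr$j, sum)
      gB[as.integer(names(gB_j))] <- gB[as.integer(names(gB_j))] - gB_j
      g[, a] <- (S / 2) * (2 * gA / A - 2 * gB / B)
    }
    g
  }
  dh <- conf_dist(x)
  dsp <- disparities(dh)
  S <- stress_of(dh, dsp)
  trace <- S
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    if (S < 1e-12) { converged <- TRUE; break }
    g <- gradient(x, dh, dsp, S)
    gn <- sqrt(sum(g^2))
    if (gn < 1e-14) { converged <- TRUE; break }
    step <- 0.1 * sqrt(sum(x^2)) / gn
    improved <- FALSE
    for (h in 1:20) {
      x_new <- x - step * g
      dh_new <- conf_dist(x_new)
      S_new <- stress_of(dh_new, dsp)
      if (S_new < S) { improved <- TRUE; break }
      step <- step / 2
    }
    if (!improved) { converged <- TRUE; break }
    x <- x_new
    dh <- dh_new
    dsp <- disparities(dh)
    S_next <- stress_of(dh, dsp)
    trace <- c(trace, S_next)
    if (S - S_next < tol) { S <- S_next; converged <- TRUE; break }
    S <- S_next
  }
  list(x = x, stress = S, trace = trace, converged = converged)
}

#' Non-metric multidimensional scaling (Kruskal)
#'
#' Minimizes Kruskal stress-1,
#' `sqrt( sum (dhat_ij - dstar_ij)^2 / sum dhat_ij^2 )`, where `dhat` are
#' configuration distances and `dstar` the isotonic (monotone) regression
#' of `dhat` on the rank order of the input dissimilarities. Each start
#' alternates pool-adjacent-violators isotonic regression with a
#' step-halving gradient descent on stress, so stress is non-increasing
#' within a start. The best of `n_starts` random initializations is
#' returned; deterministic for a fixed seed.
#'
#' @param d symmetric dissimilarity matrix.
#' @param dims embedding dimension (default 2).
#' @param n_starts random starting configurations (default 200).
#' @param max_iter iterations per start (default 300).
#' @param tol convergence tolerance on the stress decrease (default 1e-6).
#' @param seed integer seed.
#' @return Object of class `nmds_result`: `points` (n x dims, centered),
#'   `stress`, `best_start`, `start_stresses`, `trace` (stress per
#'   iteration of the best start), `converged`, `seed`.
#' @export
nmds <- function(d, dims = 2L, n_starts = 200L, max_iter = 300L,
                 tol = 1e-6, seed = 1L) {
  d <- as.matrix(d)
  n <- nrow(d)
  stopifnot(n >= 3L, isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
  pr <- upper_pairs(n)
  dv <- d[cbind(pr$i, pr$j)]
  ord <- order(dv)
  set.seed(substream_seed(seed, "nmds/starts"))
  best <- NULL
  start_stresses <- numeric(n_starts)
  for (s in seq_len(n_starts)) {
    x0 <- matrix(runif(n * dims, -1, 1), n, dims)
    fit <- nmds_one_start(d, x0, ord, max_iter, tol)
    start_stresses[s] <- fit$stress
    if (is.null(best) || fit$stress < best$stress) {
      best <- fit
      best$index <- s
    }
  }
  pts <- scale(best$x, center = TRUE, scale = FALSE)
  attr(pts, "scaled:center") <- NULL
  rownames(pts) <- rownames(d)
  structure(list(
    points = pts, stress = best$stress, best_start = best$index,
    start_stresses = start_stresses, trace = best$trace,
    converged = best$converged, n_starts = n_starts, seed = seed
  ), class = "nmds_result")
}

#' @export
print.nmds_result <- function(x, ...) {
  cat(sprintf("NMDS (%d starts): best stress %.6f at start %d%s\n",
              x$n_starts, x$stress, x$best_start,
              if (!x$converged) " [not converged]" else ""))
  invisible(x)
}
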