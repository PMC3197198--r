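# Independent oracles, deliberately naive, used to cross-check the
# package implementations.

# Bray-Curtis by explicit double loop over the formula.
oracle_bray <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- sum(abs(m[i, ] - m[j, ]))
    den <- sum(m[i, ] + m[j, ])
    d[i, j] <- if (den == 0) 0 else num / den
  }
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

# ANOSIM R for one labeling, written independently of the package.
oracle_anosim_r <- function(d, grouping) {
  n <- nrow(d)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  dv <- d[pairs]
  rk <- rank(dv)
  within <- grouping[pairs[, 1]] == grouping[pairs[, 2]]
  (mean(rk[!within]) - mean(rk[within])) / (length(rk) / 2)
}

# Exhaustive ANOSIM permutation distribution for 2 groups.
oracle_anosim_exhaustive <- function(d, grouping) {
  n <- nrow(d)
  lv <- unique(grouping)
  k <- sum(grouping == lv[1])
  sets <- combn(n, k, simplify = FALSE)
  vapply(sets, function(s) {
    g <- rep(lv[2], n)
    g[s] <- lv[1]
    oracle_anosim_r(d, g)
  }, numeric(1))
}

# Brute-force TRF: scan for the recognition site as a plain substring,
# cut at site start + offset, take the minimum (or length if no site).
oracle_trf <- function(seq, site, offset) {
  len <- nchar(seq)
  starts <- integer(0)
  for (i in seq_len(len - nchar(site) + 1L)) {
    if (substr(seq, i, i + nchar(site) - 1L) == site) {
      starts <- c(starts, i - 1L)
    }
  }
  if (!length(starts)) {
    list(forward = len, reverse = len, uncut = TRUE)
  } else {
    cuts <- starts + offset
    list(forward = min(cuts), reverse = len - max(cuts), uncut = FALSE)
  }
}

# Kruskal stress-1 of a fixed configuration against a dissimilarity
# matrix, via isotonic regression on the dissimilarity rank order.
oracle_stress1 <- function(d, points) {
  n <- nrow(d)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  dv <- d[pairs]
  dh <- sqrt(rowSums((points[pairs[, 1], , drop = FALSE] -
                        points[pairs[, 2], , drop = FALSE])^2))
  ord <- order(dv)
  disp <- numeric(length(dh))
  disp[ord] <- isoreg(dh[ord])$yf
  sqrt(sum((dh - disp)^2) / sum(dh^2))
}

# Hamming identity for equal-length sequences (the optimal global
# alignment is gapless at these gap costs when substitutions are sparse).
oracle_hamming_identity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  mean(ca == cb)
}
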