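## Richness and diversity estimators on cluster-size distributions:
## Chao1, Shannon-Wiener, and analytic rarefaction.

check_counts <- function(counts) {
  if (length(counts) == 0L) {
    stop_scatyper("empty abundance vector", "scatyper_invalid_input")
  }
  if (any(counts < 1 | counts != round(counts))) {
    stop_scatyper("counts must be positive integers",
                  "scatyper_invalid_input")
  }
  as.integer(counts)
}

#' Chao1 richness estimator
#'
#' Classic form `S_obs + F1^2 / (2 F2)` from the singleton (F1) and
#' doubleton (F2) counts; when `F2 = 0` or `bias_corrected = TRUE`, the
#' bias-corrected form `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` is used, which
#' also avoids the division by zero.
#'
#' @param counts positive integer bin sizes.
#' @param bias_corrected force the bias-corrected form.
#' @return Estimate, always `>= S_obs`.
#' @export
#' @examples
#' chao1(c(1, 1, 2, 5))  # 4 + 4/2 = 6
chao1 <- function(counts, bias_corrected = FALSE) {
  counts <- check_counts(counts)
  s_obs <- length(counts)
  f1 <- sum(counts == 1L)
  f2 <- sum(counts == 2L)
  if (bias_corrected || f2 == 0L) {
    s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  } else {
    s_obs + f1^2 / (2 * f2)
  }
}

#' Shannon-Wiener diversity index
#'
#' `H' = -sum_i (n_i/N) log(n_i/N)`, natural log by default (the DOTUR
#' convention); pass `base = 2` for bits.
#'
#' @param counts positive integer bin sizes.
#' @param base logarithm base (default `exp(1)`).
#' @return H' >= 0.
#' @export
shannon_index <- function(counts, base = exp(1)) {
  counts <- check_counts(counts)
  p <- counts / sum(counts)
  -sum(p * log(p, base = base))
}

#' Analytic rarefaction curve
#'
#' Expected richness in a random subsample of size n without replacement:
#' `E[S_n] = sum_i (1 - C(N - n_i, n) / C(N, n))`, computed with
#' log-binomials for numerical stability.
#'
#' @param counts positive integer bin sizes.
#' @param depths subsample sizes, each in `[1, N]`.
#' @return Data frame with `depth` and `expected_richness`.
#' @export
#' @examples
#' rarefaction_curve(c(5, 5), 2)$expected_richness  # 2 - 20/45
rarefaction_curve <- function(counts, depths) {
  counts <- check_counts(counts)
  N <- sum(counts)
  if (any(depths < 1 | depths > N | depths != round(depths))) {
    stop_scatyper(sprintf("depths must be integers in [1, %d]", N),
                  "scatyper_invalid_parameter")
  }
  es <- vapply(depths, function(n) {
    term <- ifelse(N - counts >= n,
                   exp(lchoose(N - counts, n) - lchoose(N, n)),
                   0)
    sum(1 - term)
  }, numeric(1))
  data.frame(depth = as.integer(depths), expected_richness = es)
}
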