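# Fixture builders shared across test files.

# A community_truth object with hand-chosen abundances (rows on the
# simplex), bypassing the stochastic generator.
make_truth <- function(abundance, design = NULL) {
  if (is.null(design)) {
    design <- data.frame(sample_id = rownames(abundance),
                         animal = 8, week = 2, hour = 1,
                         fraction = "fiber", stringsAsFactors = FALSE)
  }
  structure(list(types = colnames(abundance), abundance = abundance,
                 design = design, effects = list(), decay = NA, seed = 0L),
            class = "community_truth")
}

# Peak tables built directly from height vectors (one sample each).
make_peaks <- function(heights, sizes = seq(100, by = 10,
                                            length.out = length(heights)),
                       sample_id = "s1", enzyme = "AluI") {
  n <- length(heights)
  t <- data.frame(sample_id = rep(sample_id, n), dye = rep("NED", n),
                  enzyme = rep(enzyme, n), size_bp = sizes,
                  height_rfu = heights, stringsAsFactors = FALSE)
  class(t) <- c("peak_table", "data.frame")
  t
}

# A dissimilarity matrix with perfect group separation: small within-group,
# large between-group values.
make_separated_dist <- function(sizes = c(3, 3), within = 0.1,
                                between = 0.9) {
  n <- sum(sizes)
  g <- rep(seq_along(sizes), sizes)
  d <- matrix(between, n, n)
  d[outer(g, g, "==")] <- within
  diag(d) <- 0
  dimnames(d) <- list(paste0("s", 1:n), paste0("s", 1:n))
  list(d = d, grouping = paste0("g", g))
}

# The standard 20-type divergent library used by the recovery tests:
# between-type identity < 65% (trimmed), within-type > 85%.
make_divergent_library <- function(k_types = 20, depth = 17, seed = 3,
                                   error = TRUE) {
  mod <- type_sequence_model(between_type_substitution_rate = 0.5,
                             within_type_error_rate = if (error) 0.02 else 0,
                             seed = seed)
  ts <- simulate_type_sequences(mod, k_types, seed = seed)
  truth <- simulate_community(
    k_types,
    effects = list(fraction_lfc_sd = 0.5, week_slope_sd = 0.2,
                   animal_concentration = 150),
    decay = 0.95, seed = seed
  )
  clones <- simulate_clone_library(truth, ts, depth,
                                   model = if (error) mod else NULL,
                                   seed = seed)
  list(model = mod, type_seqs = ts, truth = truth, clones = clones)
}
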