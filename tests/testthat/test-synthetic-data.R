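test_that("community abundances lie on the simplex and are reproducible", {
  tr <- simulate_community(12, seed = 7)
  expect_equal(unname(rowSums(tr$abundance)), rep(1, 36), tolerance = 1e-12)
  expect_true(all(tr$abundance >= 0))
  expect_equal(nrow(tr$design), 36L)

  tr2 <- simulate_community(12, seed = 7)
  expect_identical(tr$abundance, tr2$abundance)
  expect_identical(tr$effects, tr2$effects)

  one <- simulate_community(1, seed = 1)
  expect_true(all(one$abundance == 1))

  expect_error(simulate_community(0), class = "scatyper_invalid_parameter")
  expect_error(simulate_community(3, effects = list(fraction_lfc = c(Inf, 0, 0))),
               class = "scatyper_invalid_parameter")
})

test_that("a fiber log-fold effect enriches the type in fiber samples", {
  lfc <- c(2, rep(0, 19))
  hits <- 0L
  for (s in 1:100) {
    tr <- simulate_community(20, effects = list(fraction_lfc = lfc),
                             seed = s)
    fib <- tr$design$fraction == "fiber"
    if (mean(tr$abundance[fib, 1]) > mean(tr$abundance[!fib, 1])) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 95L)
})

test_that("type sequences mutate only inside the spans, primers intact", {
  mod0 <- type_sequence_model(between_type_substitution_rate = 0, seed = 2)
  ts0 <- simulate_type_sequences(mod0, 5, seed = 2)
  expect_true(all(ts0 == mod0$base_sequence))

  mod <- type_sequence_model(between_type_substitution_rate = 0.3, seed = 2)
  ts <- simulate_type_sequences(mod, 6, seed = 2)
  base_chars <- strsplit(mod$base_sequence, "")[[1]]
  mutable <- c(seq.int(mod$conserved_span[1] + 1L, mod$conserved_span[2]),
               seq.int(mod$variable_span[1] + 1L, mod$variable_span[2]))
  for (s in ts) {
    diff <- which(strsplit(s, "")[[1]] != base_chars)
    expect_true(all(diff %in% mutable))
    expect_identical(match_degenerate_primer(s, scac_primers()$fwd)[1], 0L)
  }
})

test_that("pairwise identity of two simulated types equals the site count", {
  mod <- type_sequence_model(between_type_substitution_rate = 0.3, seed = 4)
  ts <- simulate_type_sequences(mod, 2, seed = 4)
  expect_equal(pairwise_identity(ts[1], ts[2]),
               oracle_hamming_identity(ts[1], ts[2]), tolerance = 1e-12)
})

test_that("span validation rejects overlapping or out-of-range spans", {
  expect_error(
    type_sequence_model(conserved_span = c(25, 120),
                        variable_span = c(100, 300), seed = 1),
    class = "scatyper_invalid_parameter"
  )
  expect_error(
    type_sequence_model(variable_span = c(200, 4000), seed = 1),
    class = "scatyper_invalid_parameter"
  )
  expect_error(
    type_sequence_model(between_type_substitution_rate = 0.9),
    class = "scatyper_invalid_parameter"
  )
})

test_that("clone libraries have the right counts, ids and sampling law", {
  tr <- simulate_community(4, seed = 11)
  mod <- type_sequence_model(seed = 11)
  ts <- simulate_type_sequences(mod, 4, seed = 11)

  cl <- simulate_clone_library(tr, ts, depth = 5, seed = 11)
  expect_equal(nrow(cl), 36L * 5L)
  expect_true(all(cl$sample_id %in% tr$design$sample_id))
  expect_true(all(table(cl$sample_id) == 5L))
  expect_true(all(startsWith(cl$clone_id, cl$sample_id)))

  # error rate 0, single dominant type: all clones identical
  ab <- matrix(c(1, 0, 0, 0), 1, 4,
               dimnames = list("s1", names(ts)))
  one <- simulate_clone_library(make_truth(ab), ts, depth = 10, seed = 1)
  expect_equal(length(unique(one$sequence)), 1L)
  expect_identical(unique(one$sequence), unname(ts[1]))

  # binomial sampling oracle: proportions within 3 standard errors
  ab2 <- matrix(c(0.9, 0.1, 0, 0), 1, 4,
                dimnames = list("s1", names(ts)))
  big <- simulate_clone_library(make_truth(ab2), ts, depth = 1000, seed = 5)
  p_hat <- mean(big$type_id == names(ts)[1])
  se <- sqrt(0.9 * 0.1 / 1000)
  expect_lt(abs(p_hat - 0.9), 3 * se)

  expect_error(
    simulate_clone_library(tr, ts[1:2], depth = 3),
    class = "scatyper_consistency_error"
  )
})

test_that("noise-free peak tables reproduce predicted TRFs and abundances", {
  mod <- type_sequence_model(between_type_substitution_rate = 0.4, seed = 8)
  ts <- simulate_type_sequences(mod, 3, seed = 8)
  pr <- scac_primers()
  lib <- predict_trf_library(ts, pr$fwd, pr$rev, enzymes = "AluI")
  ab <- matrix(c(0.25, 0.75, 0), 1, 3, dimnames = list("s1", names(ts)))
  pk <- simulate_peak_tables(
    make_truth(ab), lib, "AluI",
    noise = list(size_sd = 0, height_sd = 0, baseline_rate = 0,
                 total_fluorescence = 10000),
    seed = 1
  )[[1]]
  expect_equal(nrow(pk), 2L)   # zero-abundance type emits no peak
  expect_equal(sort(pk$height_rfu), c(2500, 7500))
  trf_of <- setNames(lib$forward_trf, lib$reference_id)
  expect_setequal(pk$size_bp, unname(trf_of[c("T01", "T02")]))

  expect_error(
    simulate_peak_tables(make_truth(ab), lib, "RsaI", seed = 1),
    class = "scatyper_consistency_error"
  )
})

test_that("size jitter has the configured standard deviation", {
  k <- 5
  n_samp <- 200
  ab <- matrix(1 / k, n_samp, k,
               dimnames = list(sprintf("s%03d", 1:n_samp),
                               sprintf("T%02d", 1:k)))
  trfs <- data.frame(reference_id = colnames(ab), enzyme = "AluI",
                     forward_trf = c(80L, 120L, 160L, 200L, 240L))
  pk <- simulate_peak_tables(
    make_truth(ab), trfs, "AluI",
    noise = list(size_sd = 0.3, height_sd = 0, baseline_rate = 0),
    seed = 13
  )
  all_pk <- do.call(rbind, pk)
  jitter <- all_pk$size_bp - rep(trfs$forward_trf, times = n_samp)
  expect_equal(length(jitter), n_samp * k)
  expect_gt(sd(jitter), 0.25)
  expect_lt(sd(jitter), 0.35)
})

test_that("reference libraries amplify with 16S primers and digest correctly", {
  refs <- simulate_reference_library(5, length = 600, seed = 21)
  expect_length(refs, 5L)
  expect_identical(refs, simulate_reference_library(5, length = 600,
                                                    seed = 21))
  pr <- rrna16s_primers()
  for (i in seq_along(refs)) {
    expect_identical(match_degenerate_primer(refs[[i]], pr$fwd)[1], 0L)
    amp <- extract_amplicon(refs[[i]], pr$fwd, pr$rev)
    expect_equal(amp$length, 600L)
    # AluI cuts equal a brute-force substring scan for AGCT
    cuts <- cut_positions(refs[[i]], "AluI")
    found <- integer(0)
    for (p in seq_len(nchar(refs[[i]]) - 3L)) {
      if (substr(refs[[i]], p, p + 3L) == "AGCT") found <- c(found, p + 1L)
    }
    expect_identical(cuts, found)
  }
  expect_error(simulate_reference_library(0),
               class = "scatyper_invalid_parameter")
})
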