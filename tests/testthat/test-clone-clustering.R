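test_that("ORF trimming finds start/stop boundaries and is idempotent", {
  r <- trim_to_orf("CCATGAAATTTTAA", min_orf_nt = 9)
  expect_identical(r$status, "ok")
  expect_identical(r$sequence, "ATGAAATTT")

  # all stops in every frame: rejected, not an error
  bad <- trim_to_orf(strrep("TAA", 30))
  expect_identical(bad$status, "rejected")

  # already-trimmed ORF passes through unchanged
  orf <- paste0("ATG", strrep("GCA", 30))
  again <- trim_to_orf(orf)
  expect_identical(again$sequence, orf)
  expect_identical(trim_to_orf(again$sequence)$sequence, orf)

  # below the minimum ORF length: rejected with a reason
  short <- trim_to_orf("CCATGAAATTTTAA", min_orf_nt = 60)
  expect_identical(short$status, "rejected")
  expect_match(short$reason, "60")
})

test_that("trim_library splits records into trimmed and rejected", {
  recs <- data.frame(
    clone_id = c("c1", "c2"),
    sequence = c(paste0("GG", "ATG", strrep("CTA", 25), "TGA"),
                 strrep("TAA", 25)),
    stringsAsFactors = FALSE
  )
  out <- trim_library(recs)
  expect_equal(nrow(out$records), 1L)
  expect_identical(out$records$clone_id, "c1")
  expect_identical(out$records$sequence, paste0("ATG", strrep("CTA", 25)))
  expect_equal(nrow(out$rejected), 1L)
  expect_identical(out$rejected$clone_id, "c2")
})

test_that("pairwise identity matches hand alignments and is symmetric", {
  expect_equal(pairwise_identity("ACGTACGT", "ACGTACGT"), 1)
  expect_equal(pairwise_identity("AAAA", "AAAT"), 0.75)
  expect_error(pairwise_identity("", "ACGT"), class = "scatyper_invalid_input")

  set.seed(61)
  for (r in 1:20) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(10:40, 1), TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(10:40, 1), TRUE),
               collapse = "")
    expect_identical(pairwise_identity(a, b), pairwise_identity(b, a))
  }
})

test_that("alignment scores agree with an independent aligner", {
  mat <- Biostrings::nucleotideSubstitutionMatrix(1, -1, baseOnly = TRUE)
  set.seed(67)
  for (r in 1:30) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(5:35, 1), TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(5:35, 1), TRUE),
               collapse = "")
    mine <- pairwise_identity(a, b, details = TRUE)
    ref <- Biostrings::pairwiseAlignment(
      a, b, type = "global", substitutionMatrix = mat,
      gapOpening = 5, gapExtension = 2, scoreOnly = TRUE
    )
    expect_equal(mine$score, ref)
  }
})

test_that("identity on equal-length substitution-only pairs is site count", {
  set.seed(71)
  bases <- c("A", "C", "G", "T")
  for (r in 1:20) {
    a <- sample(bases, 60, TRUE)
    b <- a
    flip <- sample(60, 8)
    for (i in flip) b[i] <- sample(setdiff(bases, a[i]), 1)
    expect_equal(
      pairwise_identity(paste(a, collapse = ""), paste(b, collapse = "")),
      oracle_hamming_identity(paste(a, collapse = ""),
                              paste(b, collapse = "")),
      tolerance = 1e-12
    )
  }
})

test_that("greedy clustering joins the first qualifying bin in order", {
  # identity driven by a lookup table, isolating the greedy rule
  seqs <- c(A = "SEQA", B = "SEQB", C = "SEQC")
  id_tab <- matrix(c(1, 0.95, 0.60,
                     0.95, 1, 0.62,
                     0.60, 0.62, 1), 3, 3,
                   dimnames = list(seqs, seqs))
  lookup <- function(query, founders) id_tab[founders, query]
  cs <- greedy_cluster(seqs, 70, identity_fun = lookup)
  expect_equal(cs$s_obs, 2L)
  expect_identical(cs$bins[[1]]$members, c("A", "B"))
  expect_identical(cs$bins[[2]]$members, "C")
  expect_identical(cs$bins[[1]]$name, "A")   # named by founder clone id

  # at threshold 61, C joins B's... no: C compared to founder A (0.60 < .61),
  # founds its own bin; join-first is founder-based, not best-match
  cs61 <- greedy_cluster(seqs, 61, identity_fun = lookup)
  expect_equal(cs61$s_obs, 2L)

  one <- greedy_cluster(c(x = "ACGTACGTACGT"), 97)
  expect_equal(one$s_obs, 1L)
  expect_identical(one$bins[[1]]$name, "x")

  expect_error(greedy_cluster(seqs, 0), class = "scatyper_invalid_parameter")
})

test_that("exact duplicates co-bin at threshold 100, all else separate", {
  seqs <- c(a = "ACGTACGTAC", b = "ACGTACGTAC", c = "ACGTACGTAT",
            d = "ACGTACGTAC")
  cs <- greedy_cluster(seqs, 100)
  expect_equal(cs$s_obs, 2L)
  expect_identical(cs$bins[[1]]$members, c("a", "b", "d"))
  expect_identical(cs$bins[[2]]$members, "c")
})

test_that("clustering partitions the input and founders stay below threshold", {
  lib <- make_divergent_library(k_types = 6, depth = 4, seed = 9)
  trimmed <- trim_library(lib$clones)$records
  for (thr in c(90, 70, 50)) {
    cs <- greedy_cluster(trimmed, thr)
    expect_setequal(unlist(lapply(cs$bins, `[[`, "members")),
                    trimmed$clone_id)
    expect_equal(sum(cs$sizes), nrow(trimmed))
    # every founder is below threshold identity to all earlier founders
    f <- vapply(cs$bins, `[[`, character(1), "founder_sequence")
    if (length(f) > 1) {
      for (b in 2:length(f)) {
        earlier <- vapply(f[1:(b - 1)], function(x)
          pairwise_identity(x, f[b]), numeric(1))
        expect_true(all(earlier < thr / 100))
      }
    }
  }
})

test_that("threshold sweep is monotone on synthetic libraries", {
  lib <- make_divergent_library(k_types = 8, depth = 5, seed = 13)
  trimmed <- trim_library(lib$clones)$records
  sw <- threshold_sweep(trimmed, thresholds = c(95, 80, 65, 50))
  expect_true(all(diff(sw$table$s_obs) <= 0))
  expect_true(all(sw$table$chao1 >= sw$table$s_obs))
  expect_true(all(sw$table$shannon <= log(sw$table$s_obs) + 1e-9))

  same <- threshold_sweep(c(a = "ACGTACGT", b = "ACGTACGT", c = "ACGTACGT"),
                          thresholds = c(99, 70, 40))
  expect_true(all(same$table$s_obs == 1L))
})

test_that("universal types are those observed in every animal", {
  # hand-built: X in all three animals, Y only in animal 8
  seqs <- c(x1 = "AAAAAAAAAAAA", x2 = "AAAAAAAAAAAA", x3 = "AAAAAAAAAAAA",
            y1 = "GGGGGGGGGGGG")
  cs <- greedy_cluster(seqs, 97)
  clone_samples <- c(x1 = "sA", x2 = "sB", x3 = "sC", y1 = "sA")
  meta <- data.frame(sample_id = c("sA", "sB", "sC"),
                     animal = c(8, 64, 71),
                     fraction = c("fiber", "liquid", "fiber"),
                     stringsAsFactors = FALSE)
  u <- universal_types(cs, clone_samples, meta)
  expect_identical(u$universal_types, "x1")
  # animal 8 carries clones of both types, so only half its clones are
  # in universal types; the other animals carry only the universal one
  expect_equal(unname(u$universal_share[c("8", "64", "71")]), c(0.5, 1, 1))

  # single animal: every observed type is universal by definition
  meta1 <- data.frame(sample_id = c("sA", "sB", "sC"), animal = 8,
                      stringsAsFactors = FALSE)
  u1 <- universal_types(cs, clone_samples, meta1)
  expect_setequal(u1$universal_types, c("x1", "y1"))

  expect_error(universal_types(cs, clone_samples[1:2], meta),
               class = "scatyper_consistency_error")
})

test_that("noise-free clustering recovers the truth's presence pattern", {
  lib <- make_divergent_library(k_types = 8, depth = 6, seed = 17,
                                error = FALSE)
  trimmed <- trim_library(lib$clones)$records
  cs <- greedy_cluster(trimmed, 70)
  u <- universal_types(cs, setNames(lib$clones$sample_id,
                                    lib$clones$clone_id),
                       lib$truth$design)
  # oracle: types with at least one clone in every animal
  ani <- lib$truth$design$animal[match(lib$clones$sample_id,
                                       lib$truth$design$sample_id)]
  present <- table(lib$clones$type_id, ani) > 0
  truth_universal <- rownames(present)[apply(present, 1, all)]
  # map bins back to true types through their founders
  founder_type <- lib$clones$type_id[match(
    vapply(cs$bins, `[[`, character(1), "founder_id"), lib$clones$clone_id)]
  got_universal <- founder_type[match(u$universal_types,
                                      vapply(cs$bins, `[[`, character(1),
                                             "name"))]
  expect_setequal(got_universal, truth_universal)
})
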