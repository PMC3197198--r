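test_that("square-root transform is element-wise with no renormalization", {
  m <- matrix(c(0.25, 0.75, 0, 1), 2, 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("f1", "f2")))
  s <- sqrt_transform(m)
  expect_equal(s["a", "f1"], 0.5)
  expect_equal(unname(s["b", ]), c(0, 1))
  # applying twice equals the fourth root
  expect_equal(unname(sqrt_transform(s)), unname(m^0.25))
  expect_error(sqrt_transform(matrix(-1)), class = "scatyper_invalid_input")
})

test_that("Bray-Curtis matches hand computation and the naive oracle", {
  x <- matrix(c(1, 3, 0, 3, 1, 0), 2, 3, byrow = TRUE,
              dimnames = list(c("a", "b"), NULL))
  expect_equal(bray_curtis(x)["a", "b"], 0.5)

  ident <- matrix(c(1, 2, 1, 2), 2, 2, byrow = TRUE,
                  dimnames = list(c("a", "b"), NULL))
  expect_equal(bray_curtis(ident)["a", "b"], 0)

  disj <- matrix(c(1, 0, 0, 2), 2, 2, byrow = TRUE,
                 dimnames = list(c("a", "b"), NULL))
  expect_equal(bray_curtis(disj)["a", "b"], 1)

  set.seed(41)
  for (r in 1:10) {
    m <- matrix(rexp(8 * 6), 8, 6, dimnames = list(paste0("s", 1:8), NULL))
    expect_equal(bray_curtis(m), oracle_bray(m), tolerance = 1e-12)
  }

  expect_error(bray_curtis(matrix(1, 1, 3)), class = "scatyper_invalid_input")
  zz <- matrix(c(0, 0, 0, 0, 1, 2), 3, 2, byrow = TRUE,
               dimnames = list(c("a", "b", "c"), NULL))
  expect_warning(dz <- bray_curtis(zz), "all-zero")
  expect_equal(dz["a", "b"], 0)
})

test_that("ANOSIM yields R = 1 under complete separation", {
  # all within-group dissimilarities strictly below all between-group ones
  sep <- make_separated_dist(c(3, 3))
  a <- anosim(sep$d, sep$grouping, n_permutations = 999, seed = 1)
  expect_equal(a$statistic, 1)
  expect_lte(a$p_value, 0.1)   # exact: 20 distinct labelings
  expect_true(a$exact)
})

test_that("ANOSIM agrees with exhaustive enumeration on n = 4", {
  m <- matrix(c(1, 0, 0.9, 0.1, 0.2, 0.8, 0, 1), 4, 2, byrow = TRUE,
              dimnames = list(paste0("s", 1:4), NULL))
  d <- bray_curtis(m)
  g <- c("g1", "g1", "g2", "g2")
  a <- anosim(d, g, n_permutations = 999, seed = 1)
  expect_true(a$exact)
  expect_equal(a$n_permutations, 6L)
  r_all <- oracle_anosim_exhaustive(d, g)
  expect_equal(a$statistic, oracle_anosim_r(d, g))
  expect_equal(a$p_value, mean(r_all >= a$statistic - 1e-12))
  expect_equal(sort(a$permuted_R), sort(r_all), tolerance = 1e-12)
})

test_that("ANOSIM null distribution is centered near zero", {
  set.seed(43)
  m <- matrix(rexp(12 * 15), 12, 15, dimnames = list(paste0("s", 1:12), NULL))
  d <- bray_curtis(m)
  a <- anosim(d, rep(c("g1", "g2"), each = 6), n_permutations = 2000,
              seed = 2)
  expect_lt(abs(mean(a$permuted_R)), 0.05)
})

test_that("ANOSIM validates groupings and supports pairwise mode", {
  d <- bray_curtis(matrix(rexp(12), 4, 3,
                          dimnames = list(paste0("s", 1:4), NULL)))
  expect_error(anosim(d, c("a", "a", "a", "b")),
               class = "scatyper_invalid_grouping")

  set.seed(47)
  m <- matrix(rexp(9 * 8), 9, 8, dimnames = list(paste0("s", 1:9), NULL))
  dd <- bray_curtis(m)
  g3 <- rep(c("x", "y", "z"), each = 3)
  pw <- anosim(dd, g3, n_permutations = 499, seed = 3, pairwise = TRUE)
  expect_equal(nrow(pw$pairwise), 3L)
  # each pairwise run equals a standalone run on the submatrix
  sub <- anosim(dd[1:6, 1:6], g3[1:6], n_permutations = 499, seed = 3)
  expect_equal(pw$pairwise$R[1], sub$statistic)
  expect_equal(pw$pairwise$p_value[1], sub$p_value)
})

test_that("Bray-Curtis and ANOSIM R agree with an independent implementation", {
  set.seed(103)
  for (r in 1:5) {
    m <- matrix(rexp(10 * 12), 10, 12,
                dimnames = list(paste0("s", 1:10), NULL))
    m <- m / rowSums(m)
    expect_equal(max(abs(bray_curtis(m) -
                           as.matrix(vegan::vegdist(m, method = "bray")))),
                 0, tolerance = 1e-12)
    g <- rep(c("a", "b"), each = 5)
    mine <- anosim(bray_curtis(m), g, n_permutations = 99, seed = r)
    ref <- vegan::anosim(vegan::vegdist(m, "bray"), factor(g),
                         permutations = 49)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
  }
})

test_that("SIMPER decomposes the average between-group dissimilarity", {
  m <- matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("f1", "f2")))
  s <- simper(m, c("g1", "g2"))
  expect_equal(s$average_dissimilarity, 1)
  expect_equal(sort(s$contributions$contribution), c(0.5, 0.5))
  expect_equal(s$contributions$percent, c(50, 50))

  # identical groups: degenerate, flagged
  m2 <- matrix(c(0.5, 0.5, 0.5, 0.5), 2, 2, byrow = TRUE,
               dimnames = list(c("a", "b"), NULL))
  s2 <- simper(m2, c("g1", "g2"))
  expect_true(s2$degenerate)
  expect_equal(s2$average_dissimilarity, 0)

  # decomposition identity on random matrices
  set.seed(53)
  for (r in 1:5) {
    m3 <- matrix(rexp(8 * 10), 8, 10,
                 dimnames = list(paste0("s", 1:8), paste0("f", 1:10)))
    m3 <- m3 / rowSums(m3)
    g <- rep(c("g1", "g2"), each = 4)
    s3 <- simper(m3, g)
    d3 <- bray_curtis(m3)
    between <- mean(d3[1:4, 5:8])
    expect_equal(s3$average_dissimilarity, between, tolerance = 1e-9)
    expect_equal(sum(s3$contributions$contribution),
                 s3$average_dissimilarity, tolerance = 1e-9)
    expect_equal(sum(s3$contributions$percent), 100, tolerance = 1e-6)
    expect_equal(nrow(s3$top10), 10L)
  }
})

test_that("NMDS embeds exactly embeddable 4-point configurations", {
  pts <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), 4, 2, byrow = TRUE)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(paste0("s", 1:4), paste0("s", 1:4))
  fit <- nmds(d, n_starts = 30, seed = 5)
  expect_lt(fit$stress, 1e-3)
  expect_equal(unname(colMeans(fit$points)), c(0, 0), tolerance = 1e-8)
  expect_equal(fit$stress, min(fit$start_stresses))
})

test_that("stress is invariant under rotation/reflection of the embedding", {
  pts <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), 4, 2, byrow = TRUE)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(paste0("s", 1:4), paste0("s", 1:4))
  fit <- nmds(d, n_starts = 10, seed = 7)
  theta <- 0.7
  rot <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2, 2)
  refl <- diag(c(1, -1))
  for (tr in list(rot, refl)) {
    moved <- fit$points %*% tr
    expect_equal(oracle_stress1(d, moved), oracle_stress1(d, fit$points),
                 tolerance = 1e-10)
  }
})

test_that("stress is non-increasing across iterations within a start", {
  set.seed(59)
  for (r in 1:3) {
    m <- matrix(rexp(8 * 10), 8, 10, dimnames = list(paste0("s", 1:8), NULL))
    d <- bray_curtis(m / rowSums(m))
    fit <- nmds(d, n_starts = 5, seed = r)
    expect_true(all(diff(fit$trace) <= 1e-12))
  }
})
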