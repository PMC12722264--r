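test_that("the VanRaden G reproduces the closed-form 2x1 example", {
  ds <- toy_dataset(matrix(c(0L, 2L), 2, 1))
  G <- grm_vanraden(ds)
  expect_equal(unname(G$values), matrix(c(2, -2, -2, 2), 2))
  expect_equal(unname(G$allele_freqs), 0.5)
})

test_that("G equals a per-entry brute-force oracle, with mean imputation", {
  ds <- random_dataset(10, 20, seed = 8, missing_rate = 0.1)
  G <- grm_vanraden(ds)
  p <- colMeans(ds$calls, na.rm = TRUE) / 2
  denom <- 2 * sum(p * (1 - p))
  oracle <- matrix(0, 10, 10)
  for (i in 1:10) for (j in 1:10) {
    acc <- 0
    for (k in 1:20) {
      xi <- ds$calls[i, k]; xj <- ds$calls[j, k]
      if (is.na(xi)) xi <- 2 * p[k]
      if (is.na(xj)) xj <- 2 * p[k]
      acc <- acc + (xi - 2 * p[k]) * (xj - 2 * p[k])
    }
    oracle[i, j] <- acc / denom
  }
  expect_equal(unname(G$values), oracle, tolerance = 1e-12)
})

test_that("duplicate individuals share diagonal and off-diagonal G entries", {
  base <- random_dataset(4, 30, seed = 9)
  calls <- rbind(base$calls, base$calls[1, ])
  ds <- toy_dataset(calls)
  G <- grm_vanraden(ds)$values
  expect_equal(G[1, 5], G[1, 1])
  expect_equal(G[5, 5], G[1, 1])
})

test_that("monomorphic-only data is a zero-denominator error", {
  expect_error(grm_vanraden(toy_dataset(matrix(2L, 3, 4))), "denominator")
})

test_that("PCA explained fractions are valid and scores permutation-stable", {
  ds <- random_dataset(30, 80, seed = 10)
  pc <- pca_from_grm(grm_vanraden(ds), k = 5)
  expect_true(all(diff(pc$explained_fraction) <= 1e-12))
  expect_lte(sum(pc$explained_fraction), 1 + 1e-9)
  ## permuting markers leaves G (hence scores) unchanged
  perm <- sample(ncol(ds$calls))
  ds2 <- toy_dataset(ds$calls[, perm])
  pc2 <- pca_from_grm(grm_vanraden(ds2), k = 5)
  expect_equal(abs(pc$scores), abs(pc2$scores), tolerance = 1e-8)
})

test_that("identical individuals give a degenerate (zero-variance) PCA", {
  calls <- matrix(rep(c(0L, 1L, 2L), each = 5), 5, 3, byrow = FALSE)
  ds <- toy_dataset(matrix(rep(c(0L, 1L, 2L, 1L), 5), 5, 4, byrow = TRUE))
  pc <- pca_from_grm(grm_vanraden(ds), k = 3)
  expect_true(all(pc$eigenvalues < 1e-10))
})

test_that("heterozygosity matches hand enumeration on a 5x4 toy", {
  calls <- rbind(c(1L, 1L, 1L, 1L),
                 c(0L, 1L, 2L, 1L),
                 c(0L, 0L, 2L, 2L),
                 c(1L, NA, 0L, 2L),
                 c(2L, 1L, 1L, 0L))
  ds <- toy_dataset(calls)
  het <- heterozygosity(ds)
  expect_equal(het$ho$ho, c(1, 0.5, 0, 1 / 3, 0.5))
  p <- colMeans(calls, na.rm = TRUE) / 2
  expect_equal(het$he, mean(2 * p * (1 - p)))
  ## a marker at p = 0.5 contributes an HE term of exactly 0.5
  ds2 <- toy_dataset(matrix(c(0L, 2L), 2, 1))
  expect_equal(heterozygosity(ds2)$he, 0.5)
})

test_that("polymorphic proportion counts markers above the MAF cutoff", {
  expect_equal(polymorphic_proportion(toy_dataset(matrix(0L, 4, 5))), 0)
  ds <- toy_dataset(matrix(rep(c(0L, 2L), 10), 2, 10))
  expect_equal(polymorphic_proportion(ds), 1)
  mixed <- toy_dataset(cbind(matrix(rep(c(0L, 2L), 5), 10, 1),
                             matrix(0L, 10, 2),
                             matrix(c(rep(0L, 9), 1L), 10, 1)))
  expect_equal(polymorphic_proportion(mixed), 0.25)
})

test_that("allele-sharing follows the IBS formula and its symmetries", {
  ds <- toy_dataset(rbind(c(0L, 0L, 2L, 2L), c(0L, 2L, 2L, 0L)))
  res <- pairwise_shared_distance(ds)
  expect_equal(as.numeric(res$shared), 0.5)      # IBS2=2, IBS1=0, m=4
  ident <- toy_dataset(rbind(c(0L, 1L, 2L), c(0L, 1L, 2L)))
  expect_equal(as.numeric(pairwise_shared_distance(ident)$shared), 1)
  expect_equal(as.numeric(pairwise_shared_distance(ident)$distance), 0)
  opp <- toy_dataset(rbind(c(0L, 0L), c(2L, 2L)))
  expect_equal(as.numeric(pairwise_shared_distance(opp)$shared), 0)
  ## invariant to allele-label flips
  ds2 <- random_dataset(6, 25, seed = 12)
  flipped <- toy_dataset(2L - ds2$calls)
  expect_equal(as.numeric(pairwise_shared_distance(ds2)$shared),
               as.numeric(pairwise_shared_distance(flipped)$shared))
})

test_that("F_ST is 1 for fixed opposite alleles, ~0 for identical frequencies", {
  a <- toy_dataset(matrix(0L, 20, 5), population = "A")
  b <- toy_dataset(matrix(2L, 20, 5), population = "B")
  f <- fst_pairwise(a, b)
  expect_equal(f$mean, 1)
  expect_equal(f$theta_overall, 1)

  set.seed(13)
  big <- matrix(rbinom(400 * 50, 2L, rep(runif(50, 0.2, 0.8), each = 400)), 400, 50)
  d1 <- toy_dataset(big[1:200, ], population = "A")
  d2 <- toy_dataset(big[201:400, ], population = "B")
  f0 <- fst_pairwise(d1, d2)
  expect_lt(abs(f0$theta_overall), 0.01)

  ## label swap invariance
  f12 <- fst_pairwise(d1, d2); f21 <- fst_pairwise(d2, d1)
  expect_equal(f12$per_marker$theta, f21$per_marker$theta)

  ## markers monomorphic in both populations are excluded with a count
  d1m <- toy_dataset(cbind(big[1:200, 1:4], 0L), population = "A")
  d2m <- toy_dataset(cbind(big[201:400, 1:4], 0L), population = "B")
  fm <- fst_pairwise(d1m, d2m)
  expect_identical(fm$n_excluded, 1L)
  expect_identical(fm$n_used, 4L)
})
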