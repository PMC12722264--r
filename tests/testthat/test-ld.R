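test_that("genotypic r2 matches the direct correlation oracle and its symmetries", {
  expect_equal(genotype_r2(c(0L, 1L, 2L, 0L), c(0L, 1L, 2L, 0L)), 1)
  expect_equal(genotype_r2(c(0L, 0L, 2L, 2L), c(0L, 2L, 0L, 2L)), 0)
  set.seed(21)
  for (i in 1:5) {
    x <- rbinom(30, 2L, 0.5); y <- rbinom(30, 2L, 0.3)
    x[sample(30, 3)] <- NA
    expect_equal(genotype_r2(x, y), stats::cor(x, y, use = "complete.obs")^2)
    expect_equal(genotype_r2(x, y), genotype_r2(y, x))
    expect_equal(genotype_r2(x, y), genotype_r2(2L - x, y))   # flip-invariant
  }
  expect_true(is.na(genotype_r2(rep(1L, 10), rbinom(10, 2, 0.5))))
  expect_true(is.na(genotype_r2(c(0L, NA), c(NA, 0L))))
})

test_that("EM haplotype frequencies hit the two-homozygote-class fixed point", {
  x <- rep(c(2L, 0L), each = 10); y <- rep(c(2L, 0L), each = 10)
  em <- em_haplotype_freqs(x, y)
  expect_equal(em$fAB, 0.5, tolerance = 1e-9)
  expect_equal(em$fab, 0.5, tolerance = 1e-9)
  expect_equal(em$D, 0.25, tolerance = 1e-9)
  expect_equal(em$Dprime, 1, tolerance = 1e-9)
})

test_that("EM equals direct counting when no double heterozygotes exist", {
  x <- c(2L, 2L, 1L, 0L, 0L, 2L, 1L, 0L)
  y <- c(2L, 1L, 2L, 0L, 1L, 2L, 2L, 0L)   # no (1,1) pair
  em <- em_haplotype_freqs(x, y)
  ## counting oracle: haplotypes resolvable genotype by genotype
  hap <- c(AB = 0, Ab = 0, aB = 0, ab = 0)
  for (i in seq_along(x)) {
    g1 <- x[i]; g2 <- y[i]
    a_each <- c(rep(1, g1), rep(0, 2 - g1))
    b_each <- c(rep(1, g2), rep(0, 2 - g2))
    if (g1 == 1 && g2 == 1) stop("fixture broken")
    for (h in 1:2) {
      key <- paste0(ifelse(a_each[h] == 1, "A", "a"),
                    ifelse(b_each[h] == 1, "B", "b"))
      hap[key] <- hap[key] + 1
    }
  }
  hap <- hap / sum(hap)
  expect_equal(em$fAB, unname(hap["AB"]), tolerance = 1e-9)
  expect_equal(em$fab, unname(hap["ab"]), tolerance = 1e-9)
})

test_that("EM frequencies are marginal-consistent and sum to one", {
  set.seed(22)
  for (i in 1:20) {
    x <- rbinom(40, 2L, runif(1, 0.2, 0.8))
    y <- rbinom(40, 2L, runif(1, 0.2, 0.8))
    if (var(x) == 0 || var(y) == 0) next
    em <- em_haplotype_freqs(x, y)
    expect_equal(em$fAB + em$fAb + em$faB + em$fab, 1, tolerance = 1e-8)
    expect_equal(em$fAB + em$fAb, mean(x) / 2, tolerance = 1e-8)
    expect_equal(em$fAB + em$faB, mean(y) / 2, tolerance = 1e-8)
    expect_lte(abs(em$Dprime), 1 + 1e-9)
  }
})

test_that("the LD scan enumerates exactly the close intra-chromosomal pairs", {
  ds <- random_dataset(20, 3, seed = 23, spacing = 100000L)
  pairs <- ld_scan(ds, max_distance_bp = 1e6)
  expect_identical(nrow(pairs), 3L)

  ## markers on different chromosomes never pair
  m <- toy_markers(4)
  m$chrom <- c("1", "1", "2", "2")
  m$pos_bp <- c(1000L, 2000L, 1000L, 2000L)
  set.seed(1)
  ds2 <- genotype_dataset(matrix(rbinom(80, 2, 0.5), 20, 4), toy_samples(20), m)
  pairs2 <- ld_scan(ds2, max_distance_bp = 1e6)
  expect_true(all(paste(pairs2$marker_i, pairs2$marker_j) %in%
                    c("m001 m002", "m003 m004")))

  ## pair count against a brute-force double loop on a random map
  ds3 <- random_dataset(15, 40, seed = 24, spacing = 37000L)
  maxd <- 300000
  pairs3 <- ld_scan(ds3, max_distance_bp = maxd, with_em = FALSE)
  brute <- 0
  pos <- ds3$markers$pos_bp
  for (i in 1:39) for (j in (i + 1):40) {
    if (pos[j] - pos[i] <= maxd) {
      x <- ds3$calls[, i]; y <- ds3$calls[, j]
      if (var(x) > 0 && var(y) > 0) brute <- brute + 1
    }
  }
  expect_identical(nrow(pairs3), as.integer(brute))
  ## r2 values agree with the plain correlation oracle
  k <- sample(nrow(pairs3), 5)
  for (r in k) {
    i <- match(pairs3$marker_i[r], ds3$markers$marker_id)
    j <- match(pairs3$marker_j[r], ds3$markers$marker_id)
    expect_equal(pairs3$r2[r], cor(ds3$calls[, i], ds3$calls[, j])^2,
                 tolerance = 1e-12)
  }
})

test_that("decay bins partition [10 kb, 1 Mb] with the stated boundaries", {
  expect_identical(unname(ld_bin_assign(15000)[1]), 1L)       # [10,20)
  expect_identical(unname(ld_bin_assign(250000)[1]), 11L)     # [200,300)
  bounds <- attr(ld_bin_assign(15000), "bounds")
  expect_identical(nrow(bounds), 18L)
  ## exhaustive boundary check: every edge +/- 1 bp lands where it should
  edges <- bounds$low_kb * 1000
  for (k in seq_along(edges)) {
    expect_identical(unname(ld_bin_assign(edges[k])[1]), k)          # low edge inclusive
    if (k > 1) expect_identical(unname(ld_bin_assign(edges[k] - 1)[1]), k - 1L)
  }
  expect_identical(unname(ld_bin_assign(1e6)[1]), 18L)        # final bin closed
  expect_true(is.na(ld_bin_assign(1e6 + 1)))
  expect_true(is.na(ld_bin_assign(9999)))
  ## no gaps: every bp in range is assigned
  set.seed(25)
  d <- sample(10000:1000000, 2000)
  expect_false(anyNA(ld_bin_assign(d)))
})

test_that("bins below the pair floor are flagged unreliable", {
  pairs <- data.frame(marker_i = "a", marker_j = "b",
                      distance_bp = c(rep(15000, 49), rep(250000, 50)),
                      r2 = runif(99))
  tab <- bin_ld_decay(pairs, min_pairs = 50)
  expect_false(tab$reliable[tab$bin_low_kb == 10])
  expect_identical(tab$n_pairs[tab$bin_low_kb == 10], 49L)
  expect_true(tab$reliable[tab$bin_low_kb == 200])
  expect_equal(tab$mean_r2[tab$bin_low_kb == 200],
               mean(pairs$r2[pairs$distance_bp == 250000]))
})

test_that("r2 pruning keeps independent markers and satisfies its own bound", {
  ds <- random_dataset(60, 30, seed = 26, spacing = 2000L)
  kept_all <- prune_r2(ds, r2_max = 0.99)
  expect_gte(length(kept_all), 28)    # independent random markers survive

  ## a duplicated marker: exactly one of the pair survives
  calls <- ds$calls
  calls[, 10] <- calls[, 9]
  dup <- toy_dataset(calls, spacing = 2000L)
  kept <- prune_r2(dup, r2_max = 0.8)
  expect_identical(sum(c("m009", "m010") %in% kept), 1L)

  ## defining property on an LD-rich simulated dataset
  cfg <- sim_config(n_populations = 1, n_per_population = 80, n_markers = 200,
                    chromosome_lengths_bp = 4e6, founder_pool_size = 4,
                    recombination_rate = 0.5, seed = 27)
  sim <- draw_population(make_founder_pool(cfg), cfg, 1)
  kept2 <- prune_r2(sim, r2_max = 0.8)
  expect_lt(length(kept2), 200)
  sub <- subset_dataset(sim, markers = kept2)
  idx <- seq_len(nrow(sub$markers))
  for (w in seq(1, length(idx), by = 5)) {
    win <- idx[w:min(length(idx), w + 49)]
    if (length(win) < 2) next
    cm <- suppressWarnings(cor(sub$calls[, win]))^2
    diag(cm) <- 0
    expect_lte(max(cm, na.rm = TRUE), 0.8 + 1e-9)
  }
})

test_that("VIF pruning removes duplicates first and leaves all VIF at or below the cap", {
  ds <- random_dataset(60, 12, seed = 28)
  expect_identical(length(prune_vif(ds)), 12L)   # independent: VIF ~ 1

  calls <- ds$calls
  calls[, 5] <- calls[, 4]
  dup <- toy_dataset(calls)
  kept <- prune_vif(dup)
  expect_identical(sum(c("m004", "m005") %in% kept), 1L)
  expect_true("m004" %in% kept)                  # later duplicate removed

  ## 10-marker window toy with built-in collinearity, verified by regression
  set.seed(29)
  base <- matrix(rbinom(50 * 10, 2L, 0.5), 50, 10)
  base[, 2] <- pmin(2L, pmax(0L, base[, 1] + rbinom(50, 1, 0.1)))  # near-copy
  toy <- toy_dataset(base)
  kept2 <- prune_vif(toy, vif_max = 2)
  sub <- toy$calls[, match(kept2, toy$markers$marker_id), drop = FALSE]
  for (j in seq_len(ncol(sub))) {
    fit <- lm(sub[, j] ~ sub[, -j])
    r2 <- summary(fit)$r.squared
    expect_lte(1 / (1 - r2), 2 + 1e-6)
  }
})
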