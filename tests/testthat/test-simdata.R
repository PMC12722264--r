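test_that("the generator is fully deterministic under a fixed seed", {
  cfg <- sim_config(n_populations = 2, n_per_population = 20, n_markers = 200,
                    chromosome_lengths_bp = rep(4e6, 2), seed = 70)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$merged$calls, s2$merged$calls)
  expect_identical(s1$merged$samples$birth_year, s2$merged$samples$birth_year)
  ## a different seed changes the data
  cfg2 <- sim_config(n_populations = 2, n_per_population = 20, n_markers = 200,
                     chromosome_lengths_bp = rep(4e6, 2), seed = 71)
  expect_false(identical(simulate_study(cfg2)$merged$calls, s1$merged$calls))
  expect_error(sim_config(), "seed is mandatory")
})

test_that("maf_floor = 0.5 pins every founder frequency at one half", {
  cfg <- sim_config(n_populations = 1, n_per_population = 10, n_markers = 100,
                    chromosome_lengths_bp = 2e6, maf_floor = 0.5, seed = 72)
  pool <- make_founder_pool(cfg)
  expect_true(all(pool$chromosomes[[1]]$freq == 0.5))
})

test_that("a two-haplotype pool makes tightly linked markers near-perfectly correlated", {
  cfg <- sim_config(n_populations = 1, n_per_population = 150, n_markers = 60,
                    chromosome_lengths_bp = 2e6, founder_pool_size = 2,
                    recombination_rate = 0.1, divergence_fst = 0,
                    maf_floor = 0.3, seed = 73)
  ds <- draw_population(make_founder_pool(cfg), cfg, 1)
  pairs <- ld_scan(ds, max_distance_bp = 100000, with_em = FALSE)
  expect_gt(mean(pairs$r2), 0.8)
})

test_that("mean r2 declines with distance and with the template-switch rate", {
  mk <- function(rate, seed) {
    cfg <- sim_config(n_populations = 1, n_per_population = 120,
                      n_markers = 400, chromosome_lengths_bp = 8e6,
                      founder_pool_size = 6, recombination_rate = rate,
                      seed = seed)
    ds <- draw_population(make_founder_pool(cfg), cfg, 1)
    bin_ld_decay(ld_scan(ds, with_em = FALSE), min_pairs = 20)
  }
  slow <- mk(0.5, 74)
  fast <- mk(4, 74)
  near <- which(slow$bin_low_kb <= 30)
  far <- which(slow$bin_low_kb >= 700)
  expect_gt(mean(slow$mean_r2[near], na.rm = TRUE),
            mean(slow$mean_r2[far], na.rm = TRUE))
  ## faster switching erodes LD at long range
  expect_gt(mean(slow$mean_r2[far], na.rm = TRUE),
            mean(fast$mean_r2[far], na.rm = TRUE))
})

test_that("realized differentiation is monotone in the divergence target", {
  theta <- sapply(c(0, 0.05, 0.15), function(F) {
    cfg <- sim_config(n_populations = 2, n_per_population = 100,
                      n_markers = 1500, chromosome_lengths_bp = rep(10e6, 2),
                      divergence_fst = F, founder_pool_size = 200, seed = 75)
    pool <- make_founder_pool(cfg)
    fst_pairwise(draw_population(pool, cfg, 1),
                 draw_population(pool, cfg, 2))$theta_overall
  })
  expect_true(all(diff(theta) > 0))
  expect_lt(abs(theta[1]), 0.01)
})

test_that("planted segments are homozygous, recorded, and bounded by the chromosome", {
  cfg <- sim_config(n_populations = 1, n_per_population = 10, n_markers = 500,
                    chromosome_lengths_bp = 10e6, seed = 76)
  ds <- draw_population(make_founder_pool(cfg), cfg, 1)
  plan <- data.frame(length_bp = 3e6, fraction = 0.5)
  ds2 <- plant_autozygosity(ds, plan, seed = 77)
  truth <- attr(ds2, "planted_roh")
  expect_identical(nrow(truth), 5L)   # half of 10 individuals, one locus
  expect_identical(length(unique(truth$start_bp)), 1L)
  for (r in seq_len(nrow(truth))) {
    si <- match(truth$sample_id[r], ds2$samples$sample_id)
    inside <- ds2$markers$pos_bp >= truth$start_bp[r] &
      ds2$markers$pos_bp <= truth$end_bp[r]
    expect_true(all(ds2$calls[si, inside] %in% c(0L, 2L)))
  }
  expect_error(plant_autozygosity(ds, data.frame(length_bp = 2e7, fraction = 0.2),
                                  seed = 1),
               "longer than")
})

test_that("birth years are uniform over the range and trends move frequencies", {
  cfg <- sim_config(n_populations = 1, n_per_population = 300, n_markers = 200,
                    chromosome_lengths_bp = rep(5e6, 2), seed = 78)
  ds <- draw_population(make_founder_pool(cfg), cfg, 1)
  trend <- data.frame(marker = 7, p0 = 0.25, slope_per_year = 0.5 / 63)
  ds2 <- assign_birth_years(ds, trend, c(1961, 2024), polygenic_pve = 0.3,
                            seed = 79)
  yr <- ds2$samples$birth_year
  expect_gte(min(yr), 1961); expect_lte(max(yr), 2024)
  ## close to uniform: compare quartiles to the uniform expectation
  qs <- quantile(yr, c(0.25, 0.75))
  expect_lt(abs(qs[[1]] - (1961 + 0.25 * 63)), 3)
  expect_lt(abs(qs[[2]] - (1961 + 0.75 * 63)), 3)
  ## the trend marker moved: late-born carry the allele more often
  early <- yr <= 1985; late <- yr >= 2000
  f_early <- mean(ds2$calls[early, 7]) / 2
  f_late <- mean(ds2$calls[late, 7]) / 2
  expect_gt(f_late - f_early, 0.2)
  sel <- attr(ds2, "selected_markers")
  expect_identical(sel$marker_id, ds$markers$marker_id[7])
  expect_false(sel$clipped)
  ## a slope pushing outside (0,1) is flagged
  steep <- data.frame(marker = 9, p0 = 0.8, slope_per_year = 0.02)
  ds3 <- assign_birth_years(ds, steep, c(1961, 2024), 0, seed = 80)
  expect_true(attr(ds3, "selected_markers")$clipped)
})

test_that("the polygenic share of birth-year variance is recovered by REML", {
  pves <- sapply(1:3, function(i) {
    cfg <- sim_config(n_populations = 1, n_per_population = 250,
                      n_markers = 600, chromosome_lengths_bp = rep(10e6, 2),
                      polygenic_pve = 0.5, seed = 80 + i)
    ds <- draw_population(make_founder_pool(cfg), cfg, 1)
    ds <- assign_birth_years(ds, NULL, c(1961, 2024), 0.5, seed = 90 + i)
    reml_null(ds$samples$birth_year, grm_vanraden(ds))$pve
  })
  expect_lt(abs(mean(pves) - 0.5), 0.12)   # small-n spot check
})
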