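## dense single-individual fixture: hom background with controllable inserts
hom_chrom <- function(m, spacing = 10000L) {
  toy_dataset(matrix(0L, 1, m), spacing = spacing)
}

test_that("window fractions are 1 on all-homozygous and 0 on all-heterozygous data", {
  p <- roh_params()
  expect_equal(window_homozygosity_calls(rep(0L, 200), p), rep(1, 200))
  expect_equal(window_homozygosity_calls(rep(1L, 200), p), rep(0, 200))
  ## one het inside a long homozygous stretch stays fully eligible
  calls <- rep(0L, 300); calls[150] <- 1L
  frac <- window_homozygosity_calls(calls, p)
  expect_true(all(frac >= p$window_threshold))
  ## two adjacent hets break the windows that span both
  calls2 <- rep(0L, 300); calls2[150:151] <- 1L
  frac2 <- window_homozygosity_calls(calls2, p)
  expect_lt(min(frac2), p$window_threshold)
  ## short chromosomes use the truncated window
  expect_equal(window_homozygosity_calls(rep(0L, 10), p), rep(1, 10))
})

test_that("final segment filters enforce the SNP, length, and density floors", {
  ## 60 hom markers at 10 kb -> ~590 kb, 60 SNPs: reported
  ds <- hom_chrom(600)
  ds$calls[1, ] <- 1L
  ds$calls[1, 301:360] <- 0L
  segs <- call_roh(ds)
  expect_identical(nrow(segs), 1L)
  ## all-heterozygous flanks make the outermost tract marker ineligible
  ## (only 2 of its 50 covering windows stay clean), trimming one marker a side
  expect_gte(segs$n_snps, 58L)
  expect_lte(segs$n_snps, 60L)

  ## a 400-kb homozygous stretch is too short
  ds2 <- toy_dataset(matrix(1L, 1, 600), spacing = 5000L)   # 5 kb spacing
  ds2$calls[1, 301:380] <- 0L                               # 80 SNPs, ~395 kb
  expect_identical(nrow(call_roh(ds2)), 0L)

  ## 25 homozygous markers are too few even when long enough
  ds3 <- toy_dataset(matrix(1L, 1, 200), spacing = 25000L)
  ds3$calls[1, 100:124] <- 0L                               # 25 SNPs, 600 kb
  expect_identical(nrow(call_roh(ds3)), 0L)

  ## all-heterozygous control: nothing called
  expect_identical(nrow(call_roh(toy_dataset(matrix(1L, 3, 500)))), 0L)
})

test_that("sparse segments fail the density rule and large gaps split runs", {
  ## 40 hom SNPs at 60 kb spacing: 2,340 kb / 40 = 58.5 kb per SNP > 50
  ds <- toy_dataset(matrix(1L, 1, 100), spacing = 60000L)
  ds$calls[1, 30:69] <- 0L
  expect_identical(nrow(call_roh(ds)), 0L)

  ## gap above 1000 kb splits an otherwise contiguous run
  m <- toy_markers(120, spacing = 10000L)
  m$pos_bp[61:120] <- m$pos_bp[61:120] + 2000000L
  ds2 <- genotype_dataset(matrix(0L, 1, 120), toy_samples(1), m)
  segs <- call_roh(ds2)
  expect_identical(nrow(segs), 2L)
  expect_true(all(segs$n_snps == 60L))
})

test_that("length classes use (low, high] boundaries", {
  segs <- data.frame(length_kb = c(1900, 2000, 3000, 4000, 8000, 16000, 16100))
  cl <- classify_roh(segs)$length_class
  expect_identical(as.character(cl),
                   c("<2 Mb", "<2 Mb", "2-4 Mb", "2-4 Mb", "4-8 Mb",
                     "8-16 Mb", ">16 Mb"))
})

test_that("the population summary counts zero-segment individuals", {
  samples <- toy_samples(3)
  samples$population <- "P1"
  segs <- data.frame(sample_id = c("s001", "s001"), population = "P1",
                     chrom = "1", start_bp = c(1e6, 5e6), end_bp = c(2e6, 6e6),
                     n_snps = 50L, length_kb = 1000)
  s <- roh_summary(segs, samples)
  expect_identical(s$min_count, 0L)
  expect_identical(s$max_count, 2L)
  expect_equal(s$mean_count, 2 / 3)
  empty <- roh_summary(segs[0, ], samples)
  expect_identical(empty$total, 0L)
  expect_identical(empty$min_count, 0L)
  expect_equal(empty$mean_count, 0)
})

test_that("chromosome coverage averages per-individual interval unions", {
  ds <- random_dataset(10, 20, seed = 40, spacing = 500000L)  # 10 Mb chromosome
  segs0 <- data.frame(sample_id = character(0), population = character(0),
                      chrom = character(0), start_bp = integer(0),
                      end_bp = integer(0), n_snps = integer(0),
                      length_kb = numeric(0))
  expect_equal(chromosome_coverage(segs0, ds)$mean_coverage, 0)

  ## one 1-Mb segment in 1 of 10 individuals on a 10-Mb chromosome -> 1%
  segs1 <- data.frame(sample_id = "s001", population = "P1", chrom = "1",
                      start_bp = 1e6, end_bp = 2e6 - 1, n_snps = 50L,
                      length_kb = 1000)
  expect_equal(chromosome_coverage(segs1, ds)$mean_coverage, 0.01)

  ## overlapping segments in one individual count once (union, not sum)
  segs2 <- rbind(segs1,
                 data.frame(sample_id = "s001", population = "P1", chrom = "1",
                            start_bp = 1.5e6, end_bp = 2.5e6 - 1, n_snps = 50L,
                            length_kb = 1000))
  expect_equal(chromosome_coverage(segs2, ds)$mean_coverage, 0.015)
})

test_that("islands require the frequency threshold and recompute idempotently", {
  ds <- random_dataset(10, 300, seed = 41, spacing = 10000L)
  mkseg <- function(ids) data.frame(
    sample_id = ids, population = "P1", chrom = "1",
    start_bp = 1000000, end_bp = 1600000, n_snps = 61L, length_kb = 600)

  isl6 <- roh_islands(mkseg(sprintf("s%03d", 1:6)), ds)    # 60% of population
  expect_identical(nrow(isl6), 1L)
  expect_equal(isl6$start_bp, ds$markers$pos_bp[min(which(ds$markers$pos_bp >= 1e6))])
  expect_equal(isl6$peak_frequency, 0.6)

  isl4 <- roh_islands(mkseg(sprintf("s%03d", 1:4)), ds)    # 40%: below threshold
  expect_identical(nrow(isl4), 0L)

  ## threshold 0 floods every covered run into one island
  isl0 <- roh_islands(mkseg("s001"), ds, freq_threshold = 0)
  expect_identical(nrow(isl0), 1L)
  expect_identical(isl0$n_markers, nrow(ds$markers))

  ## idempotence: recomputing frequencies from the same segments reproduces calls
  f1 <- roh_marker_frequency(mkseg(sprintf("s%03d", 1:6)), ds)
  f2 <- roh_marker_frequency(mkseg(sprintf("s%03d", 1:6)), ds)
  expect_identical(f1, f2)
  expect_equal(sort(unique(f1)), c(0, 0.6))
})

test_that("planted autozygous tracts are recovered with tract-exact boundaries", {
  cfg <- sim_config(n_populations = 1, n_per_population = 20, n_markers = 3000,
                    chromosome_lengths_bp = rep(15e6, 2),
                    founder_pool_size = 60, seed = 42)
  ds <- draw_population(make_founder_pool(cfg), cfg, 1)
  plan <- data.frame(sample_id = ds$samples$sample_id[c(1, 5, 9)],
                     chrom = c("1", "2", "1"),
                     start_bp = c(2e6, 4e6, 8e6))
  plan$length_bp <- c(1.2e6, 3e6, 2.2e6)
  plan$end_bp <- plan$start_bp + plan$length_bp
  ds2 <- plant_autozygosity(ds, plan, seed = 43)
  truth <- attr(ds2, "planted_roh")
  expect_identical(nrow(truth), 3L)

  ## every marker inside a planted interval is homozygous
  for (r in 1:3) {
    si <- match(truth$sample_id[r], ds2$samples$sample_id)
    inside <- ds2$markers$chrom == truth$chrom[r] &
      ds2$markers$pos_bp >= truth$start_bp[r] &
      ds2$markers$pos_bp <= truth$end_bp[r]
    expect_true(all(ds2$calls[si, inside] != 1L))
  }

  segs <- call_roh(ds2)
  max_gap <- max(diff(ds2$markers$pos_bp[ds2$markers$chrom == "1"]))
  for (r in 1:3) {
    tract <- observable_tract(ds2, truth$sample_id[r], truth$chrom[r],
                              truth$start_bp[r], truth$end_bp[r])
    hit <- segs[segs$sample_id == truth$sample_id[r] &
                  segs$chrom == truth$chrom[r] &
                  segs$start_bp <= truth$end_bp[r] &
                  segs$end_bp >= truth$start_bp[r], ]
    expect_identical(nrow(hit), 1L)
    expect_lte(abs(hit$start_bp - tract["start_bp"]), max_gap)
    expect_lte(abs(hit$end_bp - tract["end_bp"]), max_gap)
  }

  ## every reported segment satisfies the filters on independent re-check
  p <- roh_params()
  for (r in seq_len(nrow(segs))) {
    idx <- which(ds2$markers$chrom == segs$chrom[r] &
                   ds2$markers$pos_bp >= segs$start_bp[r] &
                   ds2$markers$pos_bp <= segs$end_bp[r])
    expect_gte(length(idx), p$min_snps)
    len_kb <- (segs$end_bp[r] - segs$start_bp[r] + 1) / 1000
    expect_gte(len_kb, p$min_length_kb)
    expect_lte(len_kb / length(idx), p$max_density_kb_per_snp)
    expect_identical(length(idx), segs$n_snps[r])
  }

  ## an empty plan leaves the dataset untouched
  ds3 <- plant_autozygosity(ds, data.frame(), seed = 1)
  expect_identical(ds3$calls, ds$calls)
})
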