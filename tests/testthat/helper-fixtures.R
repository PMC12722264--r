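## Small programmatic fixtures shared across the suite.

toy_markers <- function(m, chrom = "1", spacing = 1000L, a1 = "A", a2 = "C") {
  data.frame(marker_id = sprintf("m%03d", seq_len(m)),
             chrom = rep_len(chrom, m),
             pos_bp = as.integer(seq_len(m) * spacing),
             a1 = rep_len(a1, m), a2 = rep_len(a2, m),
             stringsAsFactors = FALSE)
}

toy_samples <- function(n, population = "P1") {
  data.frame(sample_id = sprintf("s%03d", seq_len(n)), population = population,
             stringsAsFactors = FALSE)
}

## calls given as a samples x markers matrix (possibly with NA)
toy_dataset <- function(calls, population = "P1", chrom = "1",
                        spacing = 1000L) {
  calls <- as.matrix(calls)
  genotype_dataset(calls, toy_samples(nrow(calls), population),
                   toy_markers(ncol(calls), chrom = chrom, spacing = spacing))
}

random_dataset <- function(n, m, seed = 1, missing_rate = 0,
                           population = "P1", spacing = 1000L) {
  set.seed(seed)
  p <- runif(m, 0.1, 0.9)
  calls <- matrix(rbinom(n * m, 2L, rep(p, each = n)), n, m)
  if (missing_rate > 0) {
    calls[runif(n * m) < missing_rate] <- NA_integer_
  }
  toy_dataset(calls, population = population, spacing = spacing)
}

## brute-force HWE enumeration oracle: probability of each heterozygote count
## given fixed allele counts, by direct multinomial enumeration
hwe_oracle <- function(n_hom1, n_het, n_hom2) {
  n <- n_hom1 + n_het + n_hom2
  nA <- 2 * n_hom1 + n_het
  hs <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  logp <- vapply(hs, function(h) {
    a <- (nA - h) / 2          # hom1 count
    b <- n - a - h             # hom2 count
    lfactorial(n) - lfactorial(a) - lfactorial(h) - lfactorial(b) + h * log(2)
  }, numeric(1))
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- prob[match(n_het, hs)]
  sum(prob[prob <= obs * (1 + 1e-12)])
}

## random additive tree generator: random topology + exponential branch
## lengths; returns the ape tree and its exact path-length matrix
random_additive_tree <- function(n_taxa, seed) {
  set.seed(seed)
  tree <- ape::rtree(n_taxa, rooted = FALSE,
                     br = function(n) stats::rexp(n, 5) + 0.05)
  list(tree = tree, d = ape::cophenetic.phylo(tree))
}
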