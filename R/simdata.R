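## Multi-population genotype simulator.
##
## Linkage disequilibrium arises from a finite founder haplotype pool:
## individual haplotypes are mosaics of pool haplotypes with template switches
## at a configurable rate (a Li-Stephens-style copying model). Population
## divergence follows the Balding-Nichols model: per-marker population
## frequencies are Beta draws with mean equal to the founder frequency and
## variance F * p * (1 - p), and copied alleles are resampled to the population
## frequency through a maximal coupling that preserves the shared haplotype
## background (and hence cross-population gametic phase).

#' Simulation configuration
#'
#' Holds every knob of the synthetic genotype generator. Defaults emulate
#' medium-density array data from closely related livestock populations:
#' a handful of populations with pairwise divergence on the 0.004-0.15 scale,
#' LD decaying over tens of kb to 1 Mb, and birth years spanning 1961-2024.
#'
#' @param n_populations Number of populations.
#' @param n_per_population Individuals per population.
#' @param n_markers Total markers, spread evenly over the chromosomes.
#' @param chromosome_lengths_bp Integer vector of chromosome lengths.
#' @param founder_pool_size Haplotypes in the founder pool; smaller pools give
#'   stronger LD (background r2 is roughly 1/pool size).
#' @param recombination_rate Expected template switches per Mb when copying a
#'   haplotype from the pool; controls the LD decay scale.
#' @param divergence_fst Target pairwise fixation index between populations
#'   (Balding-Nichols F), in [0, 1).
#' @param maf_floor Minimum founder minor allele frequency.
#' @param birth_year_range Length-2 integer vector (first, last year).
#' @param polygenic_pve Target proportion of birth-year variance explained by
#'   genome-wide relatedness, in [0, 1).
#' @param seed Integer seed; mandatory, every draw is reproducible from it.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(n_populations = 2, n_per_population = 200,
                       n_markers = 5000,
                       chromosome_lengths_bp = rep(20e6, 5),
                       founder_pool_size = 10, recombination_rate = 2,
                       divergence_fst = 0.05, maf_floor = 0.05,
                       birth_year_range = c(1961, 2024),
                       polygenic_pve = 0.5, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_populations >= 1, n_per_population >= 2, n_markers >= 2,
            founder_pool_size >= 2, divergence_fst >= 0, divergence_fst < 1,
            maf_floor > 0, maf_floor <= 0.5, polygenic_pve >= 0,
            polygenic_pve < 1, length(birth_year_range) == 2)
  structure(list(n_populations = n_populations,
                 n_per_population = n_per_population,
                 n_markers = n_markers,
                 chromosome_lengths_bp = as.numeric(chromosome_lengths_bp),
                 founder_pool_size = founder_pool_size,
                 recombination_rate = recombination_rate,
                 divergence_fst = divergence_fst,
                 maf_floor = maf_floor,
                 birth_year_range = as.integer(birth_year_range),
                 polygenic_pve = polygenic_pve,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Build the founder haplotype pool
#'
#' Founder allele frequencies are uniform on \code{[maf_floor, 1 - maf_floor]};
#' pool haplotypes carry independent Bernoulli draws at each marker, so
#' association between nearby markers in simulated individuals arises purely
#' from the finite pool. Markers are evenly spaced along each chromosome.
#'
#' @param config A \code{\link{sim_config}}.
#' @param template Optional existing \code{founder_pool}: its marker maps are
#'   reused (same array positions) while frequencies and haplotypes are drawn
#'   afresh -- for building genuinely unrelated populations typed on the same
#'   markers.
#' @return List of class \code{founder_pool} with per-chromosome marker maps,
#'   founder frequencies, and haplotype matrices (markers x pool size).
#' @export
make_founder_pool <- function(config, template = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_chr <- length(config$chromosome_lengths_bp)
  per_chr <- diff(round(seq(0, config$n_markers, length.out = n_chr + 1)))
  chrs <- vector("list", n_chr)
  for (c in seq_len(n_chr)) {
    if (!is.null(template)) {
      pos <- template$chromosomes[[c]]$pos_bp
      len <- template$chromosomes[[c]]$length_bp
      m <- length(pos)
    } else {
      m <- per_chr[c]
      len <- config$chromosome_lengths_bp[c]
      spacing <- len / (m + 1)
      ## jittered grid (+/- 40% of spacing): keeps order strictly increasing
      ## while spreading pair distances over all decay bins
      pos <- as.integer(round(seq_len(m) * spacing +
                                runif(m, -0.4, 0.4) * spacing))
      pos <- unique(pmax(1L, pos))
      m <- length(pos)
    }
    p <- runif(m, config$maf_floor, 1 - config$maf_floor)
    hap <- matrix(rbinom(m * config$founder_pool_size, 1L, rep(p, config$founder_pool_size)),
                  nrow = m, ncol = config$founder_pool_size)
    chrs[[c]] <- list(chrom = as.character(c), pos_bp = pos, freq = p,
                      haplotypes = hap, length_bp = len)
  }
  structure(list(chromosomes = chrs, config = config), class = "founder_pool")
}

## One mosaic haplotype: per-marker template indices, then pool alleles.
copy_mosaic <- function(pos_bp, length_bp, pool_hap, rate_per_mb) {
  m <- length(pos_bp)
  H <- ncol(pool_hap)
  n_switch <- rpois(1, rate_per_mb * length_bp / 1e6)
  if (n_switch == 0L) {
    tmpl <- rep.int(sample.int(H, 1), m)
  } else {
    cuts <- sort(runif(n_switch, 0, length_bp))
    seg <- findInterval(pos_bp, cuts) + 1L
    tmpl <- sample.int(H, n_switch + 1L, replace = TRUE)[seg]
  }
  pool_hap[cbind(seq_len(m), tmpl)]
}

## Maximal coupling of Bernoulli(p_founder) onto Bernoulli(q_pop): marginal
## frequency becomes q while retaining maximal correlation with the founder
## allele, so phase information shared through the pool is preserved.
resample_to_freq <- function(allele, p, q) {
  u <- runif(length(allele))
  up <- pmin(1, q / p)
  down <- pmax(0, (q - p) / (1 - p))
  ifelse(allele == 1L, as.integer(u < up), as.integer(u < down))
}

#' Draw one population from the founder pool
#'
#' Population allele frequencies are Balding-Nichols Beta draws around the
#' founder frequencies at the configured divergence F (degenerate at the
#' founder frequency when F = 0); individuals are built by mosaic copying of
#' pool haplotypes followed by frequency resampling, and the genotype is the
#' sum of two haplotypes.
#'
#' @param pool A \code{\link{make_founder_pool}} result.
#' @param config A \code{\link{sim_config}}.
#' @param population_index Integer; also seeds this population's draws.
#' @param label Population label for the sample table.
#' @return A \code{genotype_dataset} with haplotypes retained in attribute
#'   \code{"haplotypes"} and realized population frequencies in attribute
#'   \code{"pop_freq"}.
#' @export
draw_population <- function(pool, config = pool$config, population_index = 1,
                            label = paste0("POP", population_index)) {
  stopifnot(inherits(pool, "founder_pool"))
  set.seed(config$seed + 1000L * as.integer(population_index))
  n <- config$n_per_population
  F <- config$divergence_fst

  maps <- lapply(pool$chromosomes, function(ch) {
    data.frame(chrom = ch$chrom, pos_bp = ch$pos_bp, stringsAsFactors = FALSE)
  })
  markers <- do.call(rbind, maps)
  markers$marker_id <- paste0("snp_", markers$chrom, "_", markers$pos_bp)
  markers$a1 <- "A"; markers$a2 <- "C"
  m_tot <- nrow(markers)

  hap1 <- matrix(0L, n, m_tot); hap2 <- matrix(0L, n, m_tot)
  qs <- numeric(m_tot)
  off <- 0L
  for (ch in pool$chromosomes) {
    m <- length(ch$pos_bp)
    p <- ch$freq
    q <- if (F > 0) {
      a <- p * (1 - F) / F; b <- (1 - p) * (1 - F) / F
      pmin(0.99, pmax(0.01, rbeta(m, a, b)))
    } else p
    idx <- off + seq_len(m)
    qs[idx] <- q
    for (i in seq_len(n)) {
      h1 <- copy_mosaic(ch$pos_bp, ch$length_bp, ch$haplotypes, config$recombination_rate)
      h2 <- copy_mosaic(ch$pos_bp, ch$length_bp, ch$haplotypes, config$recombination_rate)
      if (F > 0) {
        h1 <- resample_to_freq(h1, p, q)
        h2 <- resample_to_freq(h2, p, q)
      }
      hap1[i, idx] <- h1
      hap2[i, idx] <- h2
    }
    off <- off + m
  }

  samples <- data.frame(sample_id = sprintf("%s_%04d", label, seq_len(n)),
                        population = label, stringsAsFactors = FALSE)
  ds <- genotype_dataset(hap1 + hap2, samples,
                         markers[, c("marker_id", "chrom", "pos_bp", "a1", "a2")],
                         sort_markers = FALSE)
  attr(ds, "haplotypes") <- list(hap1 = hap1, hap2 = hap2)
  attr(ds, "pop_freq") <- qs
  ds
}

#' Plant autozygous segments
#'
#' For each planned segment, one haplotype is copied onto the other across the
#' interval, making every spanned marker homozygous. Interval bounds are
#' snapped to marker positions and recorded exactly in the returned truth
#' table.
#'
#' @param ds A \code{genotype_dataset} carrying a \code{"haplotypes"}
#'   attribute (as produced by \code{\link{draw_population}}).
#' @param plan Data frame with columns \code{length_bp} and \code{fraction}
#'   (of individuals receiving the segment at one shared location), and
#'   optionally \code{chrom} and \code{start_bp}; or columns
#'   \code{sample_id}, \code{chrom}, \code{start_bp}, \code{end_bp} for fully
#'   explicit placement.
#' @param seed Integer seed for random placement.
#' @return The modified dataset, with the truth table (one row per planted
#'   segment per individual: sample_id, chrom, start_bp, end_bp, n_markers)
#'   in attribute \code{"planted_roh"}.
#' @export
plant_autozygosity <- function(ds, plan, seed = 1) {
  stopifnot(inherits(ds, "genotype_dataset"))
  if (is.null(plan) || nrow(plan) == 0) {
    attr(ds, "planted_roh") <- data.frame()
    return(ds)
  }
  set.seed(seed)
  haps <- attr(ds, "haplotypes")
  truth <- list()

  explicit <- all(c("sample_id", "chrom", "start_bp", "end_bp") %in% names(plan))
  chr_levels <- unique(ds$markers$chrom)
  chr_len <- tapply(ds$markers$pos_bp, ds$markers$chrom, max)

  for (r in seq_len(nrow(plan))) {
    if (explicit) {
      rows <- plan[r, , drop = FALSE]
    } else {
      len <- plan$length_bp[r]
      chrom <- if ("chrom" %in% names(plan) && !is.na(plan$chrom[r]))
        as.character(plan$chrom[r]) else {
          ok <- chr_levels[chr_len[chr_levels] > len]
          if (!length(ok)) stop("segment of ", len, " bp longer than every chromosome")
          sample(ok, 1)
        }
      if (len >= chr_len[[chrom]]) stop("segment longer than chromosome ", chrom)
      start <- if ("start_bp" %in% names(plan) && !is.na(plan$start_bp[r]))
        plan$start_bp[r] else floor(runif(1, 1, chr_len[[chrom]] - len))
      n_carrier <- max(1L, round(plan$fraction[r] * nrow(ds$samples)))
      carriers <- sample(ds$samples$sample_id, n_carrier)
      rows <- data.frame(sample_id = carriers, chrom = chrom,
                         start_bp = start, end_bp = start + len,
                         stringsAsFactors = FALSE)
    }
    for (j in seq_len(nrow(rows))) {
      si <- match(rows$sample_id[j], ds$samples$sample_id)
      in_seg <- which(ds$markers$chrom == as.character(rows$chrom[j]) &
                        ds$markers$pos_bp >= rows$start_bp[j] &
                        ds$markers$pos_bp <= rows$end_bp[j])
      if (length(in_seg) < 2) next
      if (!is.null(haps)) {
        haps$hap2[si, in_seg] <- haps$hap1[si, in_seg]
        ds$calls[si, in_seg] <- haps$hap1[si, in_seg] + haps$hap2[si, in_seg]
      } else {
        g <- ds$calls[si, in_seg]
        het <- which(g == 1L)
        g[het] <- 2L * rbinom(length(het), 1L, 0.5)
        ds$calls[si, in_seg] <- g
      }
      truth[[length(truth) + 1L]] <- data.frame(
        sample_id = rows$sample_id[j], chrom = as.character(rows$chrom[j]),
        start_bp = ds$markers$pos_bp[in_seg[1]],
        end_bp = ds$markers$pos_bp[in_seg[length(in_seg)]],
        n_markers = length(in_seg), stringsAsFactors = FALSE)
    }
  }
  attr(ds, "haplotypes") <- haps
  attr(ds, "planted_roh") <- do.call(rbind, truth)
  ds
}

#' Bounds of the observable autozygous tract around a planted segment
#'
#' Markers flanking a planted segment that are homozygous by chance are
#' indistinguishable by state from the planted tract; the observable tract is
#' the maximal run of non-heterozygous markers containing the planted
#' interval. Used as the ground truth for boundary-recovery checks.
#'
#' @param ds A \code{genotype_dataset}.
#' @param sample_id,chrom,start_bp,end_bp Planted segment coordinates.
#' @return Named numeric vector \code{c(start_bp, end_bp)}.
#' @export
observable_tract <- function(ds, sample_id, chrom, start_bp, end_bp) {
  si <- match(sample_id, ds$samples$sample_id)
  on_chr <- which(ds$markers$chrom == as.character(chrom))
  pos <- ds$markers$pos_bp[on_chr]
  g <- ds$calls[si, on_chr]
  i0 <- which(pos >= start_bp)[1]
  i1 <- max(which(pos <= end_bp))
  while (i0 > 1 && !isTRUE(g[i0 - 1] == 1L)) i0 <- i0 - 1
  while (i1 < length(pos) && !isTRUE(g[i1 + 1] == 1L)) i1 <- i1 + 1
  c(start_bp = pos[i0], end_bp = pos[i1])
}

#' Assign birth years with optional selection trends and polygenic structure
#'
#' Birth years are assigned uniformly over the range. When
#' \code{polygenic_pve > 0}, a genome-wide polygenic score (random marker
#' effects through the centered genotype matrix) plus independent noise is
#' rank-mapped onto the uniform year grid, so the proportion of year variance
#' captured by genomic relatedness matches the target in expectation (the
#' monotone rank mapping attenuates it by a few percent). For each trend
#' marker, genotypes are then re-drawn per individual from frequency
#' \code{p0 + slope * (year - first year)}, clipped to [0.01, 0.99] --
#' emulating an allele under sustained directional selection.
#'
#' @param ds A \code{genotype_dataset}.
#' @param trend_plan Data frame with columns \code{marker} (index or id) and
#'   \code{slope_per_year}, optional \code{p0} (defaults to the current
#'   frequency); \code{NULL} for no trends.
#' @param birth_year_range Length-2 integer vector.
#' @param polygenic_pve Target proportion of variance, in [0, 1).
#' @param seed Integer seed.
#' @return The dataset with birth years filled in; attribute
#'   \code{"selected_markers"} records marker ids, p0 and slope (with a
#'   \code{clipped} flag where the trend left (0,1) before clipping).
#' @export
assign_birth_years <- function(ds, trend_plan = NULL,
                               birth_year_range = c(1961, 2024),
                               polygenic_pve = 0, seed = 1) {
  stopifnot(inherits(ds, "genotype_dataset"))
  set.seed(seed)
  n <- nrow(ds$samples)
  y0 <- birth_year_range[1]; y1 <- birth_year_range[2]
  grid <- sort(round(seq(y0, y1, length.out = n)))

  if (polygenic_pve > 0) {
    W <- center_impute(ds$calls)
    g <- as.vector(W %*% rnorm(ncol(W)))
    g <- g / stats::sd(g)
    z <- rnorm(n)
    latent <- sqrt(polygenic_pve) * g + sqrt(1 - polygenic_pve) * z
    years <- grid[rank(latent, ties.method = "first")]
  } else {
    years <- sample(grid)
  }
  ds$samples$birth_year <- as.integer(years)

  sel <- NULL
  if (!is.null(trend_plan) && nrow(trend_plan) > 0) {
    sel <- data.frame(marker_id = character(0), p0 = numeric(0),
                      slope_per_year = numeric(0), clipped = logical(0))
    for (r in seq_len(nrow(trend_plan))) {
      mk <- trend_plan$marker[r]
      mi <- if (is.character(mk)) match(mk, ds$markers$marker_id) else as.integer(mk)
      if (is.na(mi) || mi < 1 || mi > nrow(ds$markers)) stop("trend marker not found: ", mk)
      p0 <- if ("p0" %in% names(trend_plan) && !is.na(trend_plan$p0[r]))
        trend_plan$p0[r] else mean(ds$calls[, mi], na.rm = TRUE) / 2
      slope <- trend_plan$slope_per_year[r]
      p_t <- p0 + slope * (years - y0)
      clipped <- any(p_t < 0.01) || any(p_t > 0.99)
      p_t <- pmin(0.99, pmax(0.01, p_t))
      ds$calls[, mi] <- rbinom(n, 2L, p_t)
      sel <- rbind(sel, data.frame(marker_id = ds$markers$marker_id[mi],
                                   p0 = p0, slope_per_year = slope,
                                   clipped = clipped))
    }
  }
  attr(ds, "selected_markers") <- sel
  ds
}

#' Simulate a complete multi-population study
#'
#' Convenience wrapper: founder pool, one dataset per population, optional
#' planted autozygosity and birth-year trends, all merged into a single
#' dataset with population labels.
#'
#' @param config A \code{\link{sim_config}}.
#' @param roh_plan Passed to \code{\link{plant_autozygosity}} per population
#'   (\code{NULL} to skip).
#' @param trend_plan Passed to \code{\link{assign_birth_years}} per population
#'   (\code{NULL} for no trend markers).
#' @return List with \code{datasets} (one per population), \code{merged}
#'   (single dataset with population labels), and \code{truth} (planted
#'   segments and selected markers per population).
#' @export
simulate_study <- function(config, roh_plan = NULL, trend_plan = NULL) {
  pool <- make_founder_pool(config)
  datasets <- vector("list", config$n_populations)
  truth <- list(planted_roh = list(), selected_markers = list())
  for (k in seq_len(config$n_populations)) {
    d <- draw_population(pool, config, k)
    if (!is.null(roh_plan)) {
      d <- plant_autozygosity(d, roh_plan, seed = config$seed + 7000L + k)
      truth$planted_roh[[k]] <- attr(d, "planted_roh")
    }
    d <- assign_birth_years(d, trend_plan, config$birth_year_range,
                            config$polygenic_pve, seed = config$seed + 9000L + k)
    truth$selected_markers[[k]] <- attr(d, "selected_markers")
    datasets[[k]] <- d
  }
  names(datasets) <- vapply(datasets, function(d) d$samples$population[1], "")
  merged <- datasets[[1]]
  if (length(datasets) > 1) {
    samples <- do.call(rbind, lapply(datasets, `[[`, "samples"))
    calls <- do.call(rbind, lapply(datasets, `[[`, "calls"))
    merged <- genotype_dataset(calls, samples, datasets[[1]]$markers,
                               sort_markers = FALSE)
  }
  list(datasets = datasets, merged = merged, truth = truth, pool = pool)
}

## Center genotypes at 2p and mean-impute missing calls to 0 after centering.
center_impute <- function(calls, p = NULL) {
  if (is.null(p)) p <- colMeans(calls, na.rm = TRUE) / 2
  W <- sweep(calls, 2, 2 * p)
  W[is.na(W)] <- 0
  W
}
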