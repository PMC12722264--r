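## Tiered quality control.
##
## Two profiles mirror common practice for array data: the "roh" profile keeps
## low-frequency and out-of-equilibrium markers (call-rate filters only, since
## homozygosity runs are depleted by MAF filtering), while the "full" profile
## adds autosome, MAF and Hardy-Weinberg filters for relationship, diversity,
## LD and association work.

#' Filter samples and markers on call rate
#'
#' Samples below the animal threshold are removed first; marker call rates are
#' then recomputed on the remaining samples.
#'
#' @param ds A \code{genotype_dataset}.
#' @param animal_min,marker_min Minimum call-rate fractions (default 0.95).
#' @return List: \code{ds} (filtered), \code{removed_samples},
#'   \code{removed_markers} (counts).
#' @export
filter_call_rate <- function(ds, animal_min = 0.95, marker_min = 0.95) {
  stopifnot(animal_min >= 0, animal_min <= 1, marker_min >= 0, marker_min <= 1)
  cr_s <- rowMeans(!is.na(ds$calls))
  keep_s <- cr_s >= animal_min
  ds2 <- subset_dataset(ds, samples = which(keep_s))
  cr_m <- colMeans(!is.na(ds2$calls))
  keep_m <- cr_m >= marker_min
  ds3 <- subset_dataset(ds2, markers = which(keep_m))
  list(ds = ds3, removed_samples = sum(!keep_s), removed_markers = sum(!keep_m))
}

#' Keep only autosomal markers
#'
#' @param ds A \code{genotype_dataset}.
#' @param autosome_labels Chromosome labels to keep (default \code{1:29},
#'   cattle autosomes).
#' @return List: \code{ds}, \code{removed_markers}.
#' @export
filter_autosomes <- function(ds, autosome_labels = as.character(1:29)) {
  keep <- ds$markers$chrom %in% as.character(autosome_labels)
  list(ds = subset_dataset(ds, markers = which(keep)),
       removed_markers = sum(!keep))
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided conditional exact test: given the allele counts, the p-value is
#' the summed probability of all heterozygote counts no more probable than the
#' observed one (plain p, no mid-p correction).
#'
#' @param n_hom1,n_het,n_hom2 Genotype counts (A1A1, A1A2, A2A2).
#' @return The exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_hom1, n_het, n_hom2) {
  stopifnot(n_hom1 >= 0, n_het >= 0, n_hom2 >= 0)
  n <- n_hom1 + n_het + n_hom2
  if (n < 1) stop("at least one genotype required")
  nA <- 2 * n_hom1 + n_het          # count of the first allele
  r <- min(nA, 2 * n - nA)          # rarer allele count
  if (r == 0) return(1)
  hs <- seq(r %% 2, r, by = 2)      # feasible heterozygote counts
  ## log P(h | n, r) up to a constant: 2^h / ((r-h)/2)! h! (n-(r+h)/2)!
  logp <- hs * log(2) - lfactorial((r - hs) / 2) - lfactorial(hs) -
    lfactorial(n - (r + hs) / 2)
  logp <- logp - max(logp)
  prob <- exp(logp) / sum(exp(logp))
  obs <- prob[match(n_het, hs)]
  sum(prob[prob <= obs * (1 + 1e-12)])
}

## Vectorized over markers: matrix with columns n_hom1, n_het, n_hom2.
hwe_exact_many <- function(counts) {
  apply(counts, 1, function(x) hwe_exact_test(x[1], x[2], x[3]))
}

#' Run a tiered quality-control profile
#'
#' Filters are applied sequentially -- animal call rate, genotype (marker)
#' call rate, non-autosomal, MAF, HWE -- and an attrition report accounts for
#' every removal. The \code{"roh"} profile stops after the call-rate filters;
#' the \code{"full"} profile applies all five. HWE is tested within each
#' population separately (a marker fails if it fails in the population being
#' filtered; for a multi-population dataset each population's markers are
#' assessed on its own samples and a marker is removed where it fails in that
#' population -- with \code{per_population = FALSE} the whole sample is pooled).
#'
#' @param ds A \code{genotype_dataset}.
#' @param profile \code{"full"} or \code{"roh"}.
#' @param animal_min,marker_min Call-rate thresholds (default 0.95).
#' @param maf_min Minimum minor allele frequency kept (default 0.05; markers
#'   with MAF < 0.05 are removed, MAF exactly 0.05 is kept).
#' @param hwe_min Minimum HWE exact p kept (default 1e-6).
#' @param autosome_labels Passed to \code{\link{filter_autosomes}}.
#' @param per_population Test HWE within populations. Default TRUE when
#'   population labels are present.
#' @return List: \code{ds} (filtered) and \code{report}, a data.frame with
#'   one row per criterion (removed counts; \code{NA} where a criterion is
#'   not part of the profile) plus final sample and marker counts.
#' @export
run_qc <- function(ds, profile = c("full", "roh"),
                   animal_min = 0.95, marker_min = 0.95,
                   maf_min = 0.05, hwe_min = 1e-6,
                   autosome_labels = as.character(1:29),
                   per_population = NULL) {
  profile <- match.arg(profile)
  n0 <- nrow(ds$samples); m0 <- nrow(ds$markers)
  if (is.null(per_population)) {
    per_population <- any(!is.na(ds$samples$population)) &&
      length(unique(ds$samples$population)) > 1
  }

  cr <- filter_call_rate(ds, animal_min, marker_min)
  ds <- cr$ds
  if (nrow(ds$samples) == 0) stop("no samples left after animal call-rate filter")
  if (nrow(ds$markers) == 0) stop("no markers left after genotype call-rate filter")
  rem <- c(animal_call_rate = cr$removed_samples,
           genotype_call_rate = cr$removed_markers,
           non_autosomal = NA, maf = NA, hwe = NA)

  if (profile == "full") {
    au <- filter_autosomes(ds, autosome_labels)
    ds <- au$ds
    rem["non_autosomal"] <- au$removed_markers
    if (nrow(ds$markers) == 0) stop("no markers left after non-autosomal filter")

    maf <- marker_maf(ds)
    keep <- !is.na(maf) & maf >= maf_min
    rem["maf"] <- sum(!keep)
    ds <- subset_dataset(ds, markers = which(keep))
    if (nrow(ds$markers) == 0) stop("no markers left after MAF filter")

    fail <- rep(FALSE, nrow(ds$markers))
    groups <- if (per_population) split(seq_len(nrow(ds$samples)), ds$samples$population)
    else list(all = seq_len(nrow(ds$samples)))
    for (idx in groups) {
      g <- ds$calls[idx, , drop = FALSE]
      cnt <- cbind(colSums(g == 2L, na.rm = TRUE),
                   colSums(g == 1L, na.rm = TRUE),
                   colSums(g == 0L, na.rm = TRUE))
      p <- hwe_exact_many(cnt)
      fail <- fail | (p < hwe_min)
    }
    rem["hwe"] <- sum(fail)
    ds <- subset_dataset(ds, markers = which(!fail))
    if (nrow(ds$markers) == 0) stop("no markers left after HWE filter")
  }

  report <- data.frame(criterion = c("animal_call_rate", "genotype_call_rate",
                                     "non_autosomal", "maf", "hwe"),
                       removed = as.integer(rem),
                       axis = c("samples", "markers", "markers", "markers", "markers"),
                       stringsAsFactors = FALSE)
  attr(report, "profile") <- profile
  attr(report, "initial") <- c(samples = n0, markers = m0)
  attr(report, "final") <- c(samples = nrow(ds$samples), markers = nrow(ds$markers))
  list(ds = ds, report = report)
}

#' Write a QC attrition report shaped like a per-population summary table
#'
#' @param reports Named list of QC reports (one per population).
#' @param path Output TSV path.
#' @return Invisibly, the assembled data.frame.
#' @export
write_qc_report <- function(reports, path) {
  crit <- reports[[1]]$criterion
  out <- data.frame(criterion = c(crit, "final_samples", "final_markers"))
  for (nm in names(reports)) {
    rep <- reports[[nm]]
    fin <- attr(rep, "final")
    out[[nm]] <- c(rep$removed, fin["samples"], fin["markers"])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
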