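## Genomic relationships, principal components, diversity and differentiation.

#' VanRaden genomic relationship matrix
#'
#' First-method construction: with M the samples x markers matrix of allele-A1
#' counts and P the matrix of per-marker frequencies p_i,
#' G = (M - 2P)(M - 2P)' / (2 * sum(p_i (1 - p_i))). Missing calls are
#' mean-imputed to 2 p_i before centering. With
#' \code{method = "per_snp"} each centered marker is instead divided by its
#' own standard deviation sqrt(2 p_i (1 - p_i)) and the cross-product scaled
#' by the marker count (the per-SNP standardized variant used for PCA).
#'
#' @param ds A \code{genotype_dataset}.
#' @param allele_freqs Optional fixed frequencies; default estimated from the
#'   data.
#' @param method \code{"vanraden"} (default) or \code{"per_snp"}.
#' @return Object of class \code{grm}: list with \code{values} (n x n),
#'   \code{allele_freqs}, \code{n_markers}, \code{method}.
#' @export
grm_vanraden <- function(ds, allele_freqs = NULL, method = c("vanraden", "per_snp")) {
  method <- match.arg(method)
  stopifnot(inherits(ds, "genotype_dataset"))
  p <- if (is.null(allele_freqs)) marker_freq_a1(ds) else allele_freqs
  if (any(is.nan(p))) stop("all-missing marker: frequencies undefined")
  het <- 2 * p * (1 - p)
  if (sum(het) <= 0) stop("all markers monomorphic: zero denominator")
  W <- center_impute(ds$calls, p)
  if (method == "vanraden") {
    G <- tcrossprod(W) / sum(het)
  } else {
    poly <- het > 0
    Ws <- sweep(W[, poly, drop = FALSE], 2, sqrt(het[poly]), "/")
    G <- tcrossprod(Ws) / sum(poly)
  }
  dimnames(G) <- list(ds$samples$sample_id, ds$samples$sample_id)
  structure(list(values = G, allele_freqs = p, n_markers = nrow(ds$markers),
                 method = method), class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat("grm (", x$method, "): ", nrow(x$values), " x ", ncol(x$values),
      " from ", x$n_markers, " markers; mean diagonal ",
      sprintf("%.3f", mean(diag(x$values))), "\n", sep = "")
  invisible(x)
}

#' Principal components from a genomic relationship matrix
#'
#' Eigendecomposition of G; scores are eigenvectors scaled by the square root
#' of their eigenvalues, and each component's explained fraction is its
#' eigenvalue over the trace.
#'
#' @param grm A \code{\link{grm_vanraden}} result (or plain symmetric matrix).
#' @param k Number of components (default 10, capped at n).
#' @return List of class \code{grm_pca}: \code{scores} (n x k),
#'   \code{explained_fraction}, \code{eigenvalues}.
#' @export
pca_from_grm <- function(grm, k = 10) {
  G <- if (inherits(grm, "grm")) grm$values else as.matrix(grm)
  if (!all(is.finite(G))) stop("non-finite entries in relationship matrix")
  n <- nrow(G)
  k <- min(k, n)
  eg <- eigen(G, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  tr <- sum(diag(G))
  scores <- eg$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(lam[seq_len(k)]), k, k)
  rownames(scores) <- rownames(G)
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(scores = scores,
                 explained_fraction = if (tr > 0) lam[seq_len(k)] / tr else rep(0, k),
                 eigenvalues = lam[seq_len(k)]),
            class = "grm_pca")
}

#' Observed and expected heterozygosity
#'
#' Observed heterozygosity per individual is the heterozygous count over the
#' non-missing genotype count; expected heterozygosity is the mean over
#' markers of 2 p (1 - p) with p estimated from the population. Individuals
#' with no non-missing calls are flagged and excluded from the summary means.
#'
#' @param ds A \code{genotype_dataset}.
#' @return List: \code{ho} (data.frame sample_id, ho), \code{he} (scalar),
#'   \code{he_per_marker}, and \code{summary} (mean and SD of HO, HE).
#' @export
heterozygosity <- function(ds) {
  non_miss <- rowSums(!is.na(ds$calls))
  het <- rowSums(ds$calls == 1L, na.rm = TRUE)
  ho <- ifelse(non_miss > 0, het / non_miss, NA_real_)
  p <- marker_freq_a1(ds)
  he_m <- 2 * p * (1 - p)
  he <- mean(he_m, na.rm = TRUE)
  list(ho = data.frame(sample_id = ds$samples$sample_id, ho = ho,
                       stringsAsFactors = FALSE),
       he = he, he_per_marker = he_m,
       summary = c(ho_mean = mean(ho, na.rm = TRUE), ho_sd = stats::sd(ho[!is.na(ho)]),
                   he_mean = he, he_sd = stats::sd(he_m[!is.na(he_m)])))
}

#' Proportion of polymorphic markers
#'
#' @param ds A \code{genotype_dataset}.
#' @param maf_threshold Markers with MAF strictly above this count as
#'   polymorphic (default 0.05).
#' @return Fraction in [0, 1].
#' @export
polymorphic_proportion <- function(ds, maf_threshold = 0.05) {
  maf <- marker_maf(ds)
  mean(maf > maf_threshold, na.rm = TRUE)
}

#' Pairwise allele-sharing statistic between individuals
#'
#' For each pair, over mutually non-missing loci, the shared proportion
#' s = (IBS2 + 0.5 IBS1) / m, where IBS2 and IBS1 count loci with two and one
#' shared alleles. Equivalently s = 1 - mean(|x_i - x_j|) / 2. Both the
#' shared proportion and its complement 1 - s (a genetic distance) are
#' reported; the literature uses both under the same name, so neither is
#' privileged.
#'
#' @param ds A \code{genotype_dataset} (apply LD pruning upstream when
#'   following array-panel convention).
#' @return List: \code{shared} and \code{distance} (\code{dist} objects), and
#'   \code{summary} with mean and SD over pairs of both quantities.
#' @export
pairwise_shared_distance <- function(ds) {
  stopifnot(nrow(ds$samples) >= 2)
  d <- stats::dist(ds$calls, method = "manhattan")   # NA pairs excluded, rescaled
  if (any(is.na(d))) warning("pair(s) with no mutually non-missing loci excluded")
  shared <- 1 - (d / 2) / nrow(ds$markers)
  distance <- 1 - shared
  list(shared = shared, distance = distance,
       summary = c(shared_mean = mean(shared, na.rm = TRUE),
                   shared_sd = stats::sd(shared[!is.na(shared)]),
                   distance_mean = mean(distance, na.rm = TRUE),
                   distance_sd = stats::sd(distance[!is.na(distance)])))
}

#' Two-population fixation index
#'
#' Per-marker Weir & Cockerham (1984) theta from genotype counts (the
#' variance-components estimator with the heterozygosity correction), with
#' negative per-marker values retained in the unweighted mean. Markers
#' monomorphic across both populations are excluded and counted. Two
#' summaries are returned: the per-marker mean with its SD (the form usually
#' tabulated alongside per-SNP scans), and \code{theta_overall}, the
#' multi-locus ratio-of-sums combination Weir & Cockerham prescribe
#' (sum of a over sum of a + b + c) -- the consistent estimator of the
#' divergence parameter; the per-marker mean sits systematically below it
#' because each marker's ratio is noisy and skewed. A Hudson estimator
#' (Hudson et al. 1992 form) is available for sensitivity checks.
#'
#' @param ds_a,ds_b Two \code{genotype_dataset} objects on harmonized shared
#'   markers.
#' @param estimator \code{"wc"} (default) or \code{"hudson"}.
#' @return List of class \code{fst_result}: \code{per_marker} (data.frame),
#'   \code{mean}, \code{sd}, \code{theta_overall}, \code{n_excluded},
#'   \code{estimator}.
#' @export
fst_pairwise <- function(ds_a, ds_b, estimator = c("wc", "hudson")) {
  estimator <- match.arg(estimator)
  stopifnot(identical(ds_a$markers$marker_id, ds_b$markers$marker_id))
  ga <- ds_a$calls; gb <- ds_b$calls
  n1 <- colSums(!is.na(ga)); n2 <- colSums(!is.na(gb))
  p1 <- colMeans(ga, na.rm = TRUE) / 2; p2 <- colMeans(gb, na.rm = TRUE) / 2
  h1 <- colMeans(ga == 1L, na.rm = TRUE); h2 <- colMeans(gb == 1L, na.rm = TRUE)

  usable <- n1 >= 2 & n2 >= 2
  pbar_all <- (n1 * p1 + n2 * p2) / (n1 + n2)
  poly <- usable & pbar_all > 0 & pbar_all < 1
  n_excluded <- sum(!poly)

  theta <- rep(NA_real_, length(p1))
  if (estimator == "wc") {
    r <- 2
    nb <- (n1 + n2) / r
    nc <- (r * nb - (n1^2 + n2^2) / (r * nb)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nb)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nb)
    hbar <- (n1 * h1 + n2 * h2) / (r * nb)
    a <- (nb / nc) * (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nb - 1))
    b <- (nb / (nb - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r -
                              hbar * (2 * nb - 1) / (4 * nb))
    cc <- hbar / 2
    denom <- a + b + cc
    th <- ifelse(denom != 0, a / denom, NA_real_)
    overall <- sum(a[poly & denom != 0]) / sum(denom[poly & denom != 0])
  } else {
    ## Hudson: (p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1), over
    ## p1(1-p2) + p2(1-p1); allele-count sample sizes 2n.
    num <- (p1 - p2)^2 - p1 * (1 - p1) / (2 * n1 - 1) - p2 * (1 - p2) / (2 * n2 - 1)
    den <- p1 * (1 - p2) + p2 * (1 - p1)
    th <- ifelse(den > 0, num / den, NA_real_)
    overall <- sum(num[poly & den > 0]) / sum(den[poly & den > 0])
  }
  theta[poly] <- th[poly]
  ok <- !is.na(theta)
  structure(list(per_marker = data.frame(marker_id = ds_a$markers$marker_id,
                                         theta = theta, stringsAsFactors = FALSE),
                 mean = mean(theta[ok]), sd = stats::sd(theta[ok]),
                 theta_overall = overall,
                 n_used = sum(ok), n_excluded = n_excluded,
                 estimator = estimator),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("fst_result (%s): mean theta %.4f +/- %.4f; combined %.4f over %d markers (%d excluded)\n",
              x$estimator, x$mean, x$sd, x$theta_overall, x$n_used, x$n_excluded))
  invisible(x)
}

#' Pairwise F_ST matrix over a list of populations
#'
#' @param datasets Named list of harmonized \code{genotype_dataset} objects.
#' @param estimator Passed to \code{\link{fst_pairwise}}.
#' @return List: \code{mean} and \code{sd} matrices (populations x
#'   populations).
#' @export
fst_matrix <- function(datasets, estimator = "wc") {
  k <- length(datasets)
  nms <- names(datasets)
  mu <- matrix(NA_real_, k, k, dimnames = list(nms, nms))
  sdm <- mu
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    f <- fst_pairwise(datasets[[i]], datasets[[j]], estimator)
    mu[i, j] <- mu[j, i] <- f$mean
    sdm[i, j] <- sdm[j, i] <- f$sd
  }
  diag(mu) <- 0; diag(sdm) <- 0
  list(mean = mu, sd = sdm)
}
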