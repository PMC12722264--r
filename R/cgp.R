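## Consistency of gametic phase between populations: per-distance-bin Pearson
## correlation of signed sqrt(r2) over SNP pairs shared by the two
## populations' LD tables.

#' Signed square root of r2
#'
#' sqrt(r2) carrying the sign of the gametic covariance D (from the EM
#' haplotype frequencies); sign(0) = 0. Pairs with undefined r2 are NA.
#'
#' @param pairs An \code{\link{ld_scan}} table with a \code{D} column.
#' @return Numeric vector aligned with \code{pairs}.
#' @export
signed_root_ld <- function(pairs) {
  if (is.null(pairs$D)) stop("pairs table lacks D; run ld_scan(with_em = TRUE)")
  sqrt(pairs$r2) * sign(pairs$D)
}

#' Consistency-of-gametic-phase curve for one population pair
#'
#' Both LD tables must come from the same harmonized marker set, with LD (and
#' hence the sign of D) computed within each population separately. Within
#' every distance bin of the decay scheme, the Pearson correlation of the two
#' populations' signed sqrt(r2) values is taken over the SNP pairs present
#' (with defined LD) in both tables; incomplete pairs are dropped and
#' counted.
#'
#' @param pairs_a,pairs_b \code{\link{ld_scan}} tables (with EM) for the two
#'   populations.
#' @param min_pairs Bins with fewer shared pairs are flagged (default 50).
#' @return Data frame of class \code{cgp_curve}: bin bounds, correlation,
#'   n_shared_pairs, reliable.
#' @export
cgp_curve <- function(pairs_a, pairs_b, min_pairs = 50) {
  key_a <- paste(pairs_a$marker_i, pairs_a$marker_j)
  key_b <- paste(pairs_b$marker_i, pairs_b$marker_j)
  ia <- match(key_b, key_a)
  shared_b <- which(!is.na(ia))
  a_idx <- ia[shared_b]

  sa <- signed_root_ld(pairs_a)[a_idx]
  sb <- signed_root_ld(pairs_b)[shared_b]
  dist_bp <- pairs_b$distance_bp[shared_b]
  ok <- !is.na(sa) & !is.na(sb)

  idx <- ld_bin_assign(dist_bp)
  bounds <- attr(idx, "bounds")
  out <- data.frame(bin_low_kb = bounds$low_kb, bin_high_kb = bounds$high_kb,
                    correlation = NA_real_, n_shared_pairs = 0L,
                    reliable = FALSE)
  for (b in seq_len(nrow(bounds))) {
    sel <- which(!is.na(idx) & idx == b & ok)
    out$n_shared_pairs[b] <- length(sel)
    if (length(sel) >= 2 && stats::sd(sa[sel]) > 0 && stats::sd(sb[sel]) > 0) {
      out$correlation[b] <- stats::cor(sa[sel], sb[sel])
    }
    out$reliable[b] <- length(sel) >= min_pairs
  }
  class(out) <- c("cgp_curve", "data.frame")
  out
}

#' Gametic-phase consistency for every population pair
#'
#' @param datasets Named list of harmonized \code{genotype_dataset} objects.
#' @param max_distance_bp Scan limit passed to \code{\link{ld_scan}}.
#' @param min_pairs Passed to \code{\link{cgp_curve}}.
#' @return Named list (\code{"A|B"}) of \code{cgp_curve} data frames.
#' @export
cgp_all_pairs <- function(datasets, max_distance_bp = 1e6, min_pairs = 50) {
  tables <- lapply(datasets, ld_scan, max_distance_bp = max_distance_bp,
                   with_em = TRUE)
  nms <- names(datasets)
  out <- list()
  for (i in seq_along(datasets)[-length(datasets)]) {
    for (j in (i + 1):length(datasets)) {
      out[[paste(nms[i], nms[j], sep = "|")]] <-
        cgp_curve(tables[[i]], tables[[j]], min_pairs)
    }
  }
  out
}
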