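## Two-locus linkage disequilibrium: genotypic r2, EM haplotype frequencies
## (D, D'), a distance-limited genome scan, decay binning, and the two marker
## pruning procedures (pairwise r2 and variance-inflation-factor).

#' Genotypic r-squared between two markers
#'
#' Squared Pearson correlation of the 0/1/2 allele-count vectors over
#' mutually non-missing individuals (the composite, phase-free LD measure).
#'
#' @param calls_i,calls_j Integer vectors of genotype calls.
#' @return r2 in [0, 1]; \code{NA} if fewer than 2 complete pairs or either
#'   marker has zero variance on the joint sample.
#' @export
genotype_r2 <- function(calls_i, calls_j) {
  ok <- !is.na(calls_i) & !is.na(calls_j)
  if (sum(ok) < 2) return(NA_real_)
  x <- calls_i[ok]; y <- calls_j[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

## EM over the 9-cell genotype table, vectorized across pairs.
## cells: matrix L x 9, columns n_g1g2 for (g1,g2) in
## (2,2),(2,1),(2,0),(1,2),(1,1),(1,0),(0,2),(0,1),(0,0); g = allele-A1 count.
em_cells <- function(cells, tol = 1e-10, max_iter = 1000) {
  n22 <- cells[, 1]; n21 <- cells[, 2]; n20 <- cells[, 3]
  n12 <- cells[, 4]; n11 <- cells[, 5]; n10 <- cells[, 6]
  n02 <- cells[, 7]; n01 <- cells[, 8]; n00 <- cells[, 9]
  N2 <- 2 * rowSums(cells)

  ## fixed haplotype contributions
  cAB <- 2 * n22 + n21 + n12
  cAb <- 2 * n20 + n21 + n10
  caB <- 2 * n02 + n12 + n01
  cab <- 2 * n00 + n10 + n01

  ## start from one E-step with double heterozygotes split evenly; exact
  ## (counting) solution wherever there are no double heterozygotes
  fAB <- (cAB + 0.5 * n11) / N2
  fAb <- (cAb + 0.5 * n11) / N2
  faB <- (caB + 0.5 * n11) / N2
  fab <- (cab + 0.5 * n11) / N2
  L <- length(N2)
  converged <- rep(FALSE, L)
  active <- which(n11 > 0)           # pairs without double hets are exact already
  converged[n11 == 0] <- TRUE
  iter <- 0L
  while (length(active) && iter < max_iter) {
    iter <- iter + 1L
    aAB <- fAB[active]; aAb <- fAb[active]; aaB <- faB[active]; aab <- fab[active]
    denom <- aAB * aab + aAb * aaB
    w <- ifelse(denom > 0, aAB * aab / denom, 0.5)
    h11 <- n11[active]; hN2 <- N2[active]
    nAB <- (cAB[active] + w * h11) / hN2
    nAb <- (cAb[active] + (1 - w) * h11) / hN2
    naB <- (caB[active] + (1 - w) * h11) / hN2
    nab <- (cab[active] + w * h11) / hN2
    delta <- pmax(abs(nAB - aAB), abs(nAb - aAb), abs(naB - aaB), abs(nab - aab))
    fAB[active] <- nAB; fAb[active] <- nAb; faB[active] <- naB; fab[active] <- nab
    done <- delta < tol
    converged[active[done]] <- TRUE
    active <- active[!done]
  }
  fA <- fAB + fAb; fB <- fAB + faB
  D <- fAB - fA * fB
  dmax <- ifelse(D >= 0, pmin(fA * (1 - fB), (1 - fA) * fB),
                 pmin(fA * fB, (1 - fA) * (1 - fB)))
  dprime <- ifelse(dmax > 0, D / dmax, 0)
  list(fAB = fAB, fAb = fAb, faB = faB, fab = fab,
       freq_a1_i = fA, freq_a1_j = fB, D = D, Dprime = dprime,
       converged = converged, n_iter = iter)
}

#' EM haplotype frequencies for one marker pair
#'
#' Maximum-likelihood two-locus haplotype frequencies from unphased
#' genotypes: double heterozygotes are split between the two phase
#' configurations by their current odds and the expectation step is iterated
#' to convergence (|change| < 1e-10, cap 1000 iterations). D is the gametic
#' covariance f(AB) - f(A) f(B) and D' its value scaled by the maximum
#' attainable at the observed allele frequencies.
#'
#' @param calls_i,calls_j Integer genotype vectors.
#' @return List: \code{fAB}, \code{fAb}, \code{faB}, \code{fab}, \code{D},
#'   \code{Dprime}, \code{converged}.
#' @export
em_haplotype_freqs <- function(calls_i, calls_j) {
  ok <- !is.na(calls_i) & !is.na(calls_j)
  x <- calls_i[ok]; y <- calls_j[ok]
  if (!length(x)) stop("no mutually non-missing calls")
  cells <- matrix(0, 1, 9)
  k <- 0L
  for (g1 in c(2L, 1L, 0L)) for (g2 in c(2L, 1L, 0L)) {
    k <- k + 1L
    cells[1, k] <- sum(x == g1 & y == g2)
  }
  res <- em_cells(cells)
  lapply(res, function(v) v[1])
}

#' Distance-limited intra-chromosomal LD scan
#'
#' Computes genotypic r2 (and, optionally, EM haplotype frequencies with
#' signed D and D') for every pair of markers on the same chromosome within
#' \code{max_distance_bp}. No r2 floor is applied. Pairs where either marker
#' is monomorphic on the joint sample are dropped with a count recorded in
#' attribute \code{"n_skipped"}.
#'
#' @param ds A \code{genotype_dataset} (map sorted).
#' @param max_distance_bp Maximum pair distance (default 1e6).
#' @param with_em Also run the EM to obtain D and D' (default TRUE).
#' @param chunk_size Pairs per processing block (memory knob).
#' @return Data frame: marker_i, marker_j, chrom, distance_bp, r2,
#'   freq_a1_i, freq_a1_j, and (with EM) D, Dprime.
#' @export
ld_scan <- function(ds, max_distance_bp = 1e6, with_em = TRUE,
                    chunk_size = 20000) {
  map <- ds$markers
  ii <- integer(0); jj <- integer(0)
  for (chr in unique(map$chrom)) {
    idx <- which(map$chrom == chr)
    pos <- map$pos_bp[idx]
    m <- length(idx)
    if (m < 2) next
    for (k in seq_len(m - 1)) {
      i <- seq_len(m - k)
      keep <- pos[i + k] - pos[i] <= max_distance_bp
      if (!any(keep)) break
      ii <- c(ii, idx[i[keep]]); jj <- c(jj, idx[i[keep] + k])
    }
  }
  L <- length(ii)
  out <- vector("list", max(1, ceiling(L / chunk_size)))
  n_skipped <- 0L
  if (L) {
    blocks <- split(seq_len(L), ceiling(seq_len(L) / chunk_size))
    for (b in seq_along(blocks)) {
      sel <- blocks[[b]]
      xi <- ds$calls[, ii[sel], drop = FALSE]
      xj <- ds$calls[, jj[sel], drop = FALSE]
      ok <- !is.na(xi) & !is.na(xj)
      x0 <- ifelse(ok, xi, 0L); y0 <- ifelse(ok, xj, 0L)
      n <- colSums(ok)
      sx <- colSums(x0); sy <- colSums(y0)
      sxx <- colSums(x0 * x0); syy <- colSums(y0 * y0); sxy <- colSums(x0 * y0)
      vx <- sxx - sx^2 / n; vy <- syy - sy^2 / n
      cxy <- sxy - sx * sy / n
      r2 <- ifelse(n >= 2 & vx > 0 & vy > 0, cxy^2 / (vx * vy), NA_real_)

      df <- data.frame(marker_i = map$marker_id[ii[sel]],
                       marker_j = map$marker_id[jj[sel]],
                       chrom = map$chrom[ii[sel]],
                       distance_bp = map$pos_bp[jj[sel]] - map$pos_bp[ii[sel]],
                       r2 = r2, stringsAsFactors = FALSE)
      if (with_em) {
        cells <- matrix(0, length(sel), 9)
        k <- 0L
        for (g1 in c(2L, 1L, 0L)) for (g2 in c(2L, 1L, 0L)) {
          k <- k + 1L
          cells[, k] <- colSums((xi == g1) & (xj == g2), na.rm = TRUE)
        }
        em <- em_cells(cells)
        df$D <- em$D; df$Dprime <- em$Dprime
        df$freq_a1_i <- em$freq_a1_i; df$freq_a1_j <- em$freq_a1_j
      } else {
        df$freq_a1_i <- sx / (2 * n); df$freq_a1_j <- sy / (2 * n)
      }
      keep <- !is.na(df$r2)
      n_skipped <- n_skipped + sum(!keep)
      out[[b]] <- df[keep, , drop = FALSE]
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(marker_i = character(0), marker_j = character(0),
                      chrom = character(0), distance_bp = integer(0),
                      r2 = numeric(0), freq_a1_i = numeric(0),
                      freq_a1_j = numeric(0))
  }
  rownames(res) <- NULL
  attr(res, "n_skipped") <- n_skipped
  res
}

#' Distance-bin assignment for LD decay
#'
#' Bins span [10 kb, 1 Mb]: half-open 10-kb bins [10,20) ... [90,100) kb,
#' then 100-kb bins [100,200) ... [900,1000) kb, the final bin closed at
#' 1000 kb. Distances below 10 kb or above 1 Mb fall outside the table.
#'
#' @param distance_bp Numeric vector of pair distances.
#' @return Integer bin index (1-18), \code{NA} outside the range. Bin bounds
#'   are in attribute \code{"bounds"} (kb, low inclusive, high exclusive
#'   except the last).
#' @export
ld_bin_assign <- function(distance_bp) {
  lows <- c(seq(10, 90, 10), seq(100, 900, 100))
  highs <- c(seq(20, 100, 10), seq(200, 1000, 100))
  kb <- distance_bp / 1000
  idx <- findInterval(kb, c(lows, 1000), rightmost.closed = TRUE)
  idx[kb < 10 | kb > 1000] <- NA_integer_
  structure(idx, bounds = data.frame(low_kb = lows, high_kb = highs))
}

#' Mean r2 per distance bin
#'
#' @param pairs An \code{\link{ld_scan}} table.
#' @param min_pairs Bins with fewer pairs are flagged unreliable (default 50).
#' @return Data frame: bin_low_kb, bin_high_kb, mean_r2, n_pairs, reliable.
#' @export
bin_ld_decay <- function(pairs, min_pairs = 50) {
  idx <- ld_bin_assign(pairs$distance_bp)
  bounds <- attr(idx, "bounds")
  n <- tabulate(idx, nbins = nrow(bounds))
  sums <- rep(0, nrow(bounds))
  ok <- !is.na(idx) & !is.na(pairs$r2)
  if (any(ok)) {
    agg <- tapply(pairs$r2[ok], idx[ok], sum)
    sums[as.integer(names(agg))] <- agg
    n <- tabulate(idx[ok], nbins = nrow(bounds))
  } else n <- rep(0L, nrow(bounds))
  data.frame(bin_low_kb = bounds$low_kb, bin_high_kb = bounds$high_kb,
             mean_r2 = ifelse(n > 0, sums / n, NA_real_),
             n_pairs = n, reliable = n >= min_pairs)
}

## Centered, mean-imputed genotype block for pruning regressions.
prune_block <- function(calls) {
  W <- center_impute(calls)
  W[, apply(W, 2, stats::sd) > 0, drop = FALSE]
}

#' Prune markers on pairwise r2
#'
#' Greedy windowed pruning: within each 50-marker window (sliding by 5), the
#' later marker of any pair with r2 above the threshold is dropped; window
#' positions advance over the original map so every close pair is examined.
#' Deterministic map-order tie-breaking makes runs reproducible.
#'
#' @param ds A \code{genotype_dataset}.
#' @param r2_max Threshold (default 0.8; pairs with r2 > r2_max conflict).
#' @param window_snps,step_snps Window geometry (defaults 50 and 5).
#' @return Character vector of kept marker ids.
#' @export
prune_r2 <- function(ds, r2_max = 0.8, window_snps = 50, step_snps = 5) {
  map <- ds$markers
  kept <- rep(TRUE, nrow(map))
  repeat {
    changed <- FALSE
    for (chr in unique(map$chrom)) {
      idx <- which(map$chrom == chr & kept)   # windows slide over survivors
      m <- length(idx)
      if (m < 2) next
      starts <- seq(1, max(1, m - 1), by = step_snps)
      for (s in starts) {
        win <- idx[s:min(m, s + window_snps - 1)]
        win <- win[kept[win]]
        if (length(win) < 2) next
        g <- ds$calls[, win, drop = FALSE]
        cm <- suppressWarnings(stats::cor(center_impute(g)))
        cm[is.na(cm)] <- 0
        k <- length(win)
        for (a in seq_len(k - 1)) {
          if (!kept[win[a]]) next
          for (b in (a + 1):k) {
            if (kept[win[b]] && cm[a, b]^2 > r2_max) {
              kept[win[b]] <- FALSE
              changed <- TRUE
            }
          }
        }
      }
    }
    if (!changed) break
  }
  map$marker_id[kept]
}

#' Prune markers on variance inflation factor
#'
#' Within each window, the marker with the highest VIF -- 1 / (1 - R2) of its
#' regression on the window's other markers -- is removed until all VIF are at
#' or below the cap. Exact duplicates (singular fits) count as infinite VIF
#' and go first, later map position breaking ties.
#'
#' @param ds A \code{genotype_dataset}.
#' @param window_snps,step_snps Window geometry (defaults 50 and 5).
#' @param vif_max VIF cap (default 2).
#' @return Character vector of kept marker ids.
#' @export
prune_vif <- function(ds, window_snps = 50, step_snps = 5, vif_max = 2) {
  map <- ds$markers
  kept <- rep(TRUE, nrow(map))
  repeat {
   changed <- FALSE
   for (chr in unique(map$chrom)) {
    idx_all <- which(map$chrom == chr & kept)  # windows slide over survivors
    m <- length(idx_all)
    if (m < 2) next
    starts <- seq(1, max(1, m - 1), by = step_snps)
    for (s in starts) {
      idx <- idx_all
      repeat {
        win <- idx[s:min(m, s + window_snps - 1)]
        win <- win[!is.na(win) & kept[win]]
        if (length(win) < 2) break
        W <- center_impute(ds$calls[, win, drop = FALSE])
        sds <- apply(W, 2, stats::sd)
        if (any(sds == 0)) {   # monomorphic: uninformative, VIF undefined -> drop
          kept[win[which(sds == 0)[1]]] <- FALSE
          changed <- TRUE
          next
        }
        R <- stats::cor(W)
        up <- which(upper.tri(R) & abs(R) > 1 - 1e-9, arr.ind = TRUE)
        if (nrow(up)) {        # exact duplicate: infinite VIF, drop later marker
          kept[win[max(up[1, ])]] <- FALSE
          changed <- TRUE
          next
        }
        vif <- tryCatch(diag(solve(R)), error = function(e) NULL)
        if (is.null(vif)) {    # collinear beyond a single pair
          kept[win[length(win)]] <- FALSE
          changed <- TRUE
          next
        }
        if (max(vif) <= vif_max) break
        worst <- which(vif == max(vif))
        kept[win[worst[length(worst)]]] <- FALSE
        changed <- TRUE
      }
    }
   }
   if (!changed) break
  }
  map$marker_id[kept]
}
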