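## Generation Proxy Selection Mapping.
##
## Birth year (a generation proxy) is regressed on each SNP in a linear mixed
## model, y = mu + x_i b_i + g + e, with g ~ N(0, G sigma_g^2) controlling for
## genome-wide relatedness through the VanRaden G and e ~ N(0, I sigma_e^2).
## Variance components are estimated once by REML under the null (no SNP) via
## the eigendecomposition of G, then held fixed for a generalized
## least-squares Wald scan over markers (the standard mixed-model-association
## strategy; the candidate marker stays in G, no leave-one-chromosome-out).
## Markers significant after Bonferroni correction indicate alleles whose
## frequency has drifted systematically with birth year -- ongoing selection.

#' REML variance components for the null model
#'
#' Fits y = mu + g + e with g ~ N(0, K sigma_g^2), e ~ N(0, I sigma_e^2) by
#' restricted maximum likelihood, profiling over the variance ratio on the
#' eigenbasis of K (one eigendecomposition, then 1-D optimization).
#'
#' @param y Numeric response (birth years; centered internally).
#' @param K Relationship matrix or \code{grm} object.
#' @return List of class \code{gpsm_vc}: \code{sigma2_g}, \code{sigma2_e},
#'   \code{pve}, \code{log_likelihood}, \code{boundary} (TRUE if the genetic
#'   variance was pinned at zero), and the eigendecomposition for reuse.
#' @export
reml_null <- function(y, K) {
  if (inherits(K, "grm")) K <- K$values
  n <- length(y)
  stopifnot(nrow(K) == n)
  if (stats::var(y) == 0) stop("response has zero variance")
  eg <- eigen(K, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  yt <- crossprod(eg$vectors, y - mean(y))
  xt <- crossprod(eg$vectors, rep(1, n))

  prof <- function(h2) {
    phi <- h2 / (1 - h2)                  # sigma_g^2 / sigma_e^2
    w <- phi * d + 1
    xwx <- sum(xt^2 / w)
    beta <- sum(xt * yt / w) / xwx
    r <- yt - xt * beta
    rwr <- sum(r^2 / w)
    s2e <- rwr / (n - 1)
    ll <- -0.5 * ((n - 1) * log(s2e) + sum(log(w)) + log(xwx) + (n - 1))
    list(ll = ll, s2e = s2e, phi = phi, beta = beta)
  }
  opt <- stats::optimize(function(h) prof(h)$ll, c(1e-6, 1 - 1e-6),
                         maximum = TRUE, tol = 1e-9)
  h2 <- opt$maximum
  fit <- prof(h2)
  boundary <- FALSE
  ## compare against the h2 -> 0 boundary (pure-noise model)
  fit0 <- prof(1e-12)
  if (fit0$ll >= fit$ll) {
    h2 <- 0; fit <- fit0; boundary <- TRUE
  }
  s2e <- fit$s2e
  s2g <- fit$phi * s2e
  structure(list(sigma2_g = s2g, sigma2_e = s2e, pve = s2g / (s2g + s2e),
                 log_likelihood = fit$ll, boundary = boundary,
                 eigen_values = d, eigen_vectors = eg$vectors,
                 y_rotated = yt, ones_rotated = xt, mean_y = mean(y)),
            class = "gpsm_vc")
}

## Direct-inversion REML log-likelihood at given variance components; the
## independent check of the eigendecomposition path (same constant
## convention: -0.5 [log|V| + log|X'V^-1 X| + r' V^-1 r]).
reml_loglik_direct <- function(y, K, sigma2_g, sigma2_e) {
  if (inherits(K, "grm")) K <- K$values
  n <- length(y)
  X <- matrix(1, n, 1)
  V <- sigma2_g * K + diag(sigma2_e, n)
  Vi <- solve(V)
  xvx <- drop(t(X) %*% Vi %*% X)
  beta <- drop(t(X) %*% Vi %*% y) / xvx
  r <- y - X %*% beta
  ld <- determinant(V, logarithm = TRUE)$modulus
  -0.5 * (as.numeric(ld) + log(xvx) + drop(t(r) %*% Vi %*% r))
}

## Eigen-path REML log-likelihood at arbitrary components, matching the
## direct convention above.
reml_loglik_eigen <- function(vc, sigma2_g, sigma2_e) {
  w <- sigma2_g * vc$eigen_values + sigma2_e
  xwx <- sum(vc$ones_rotated^2 / w)
  beta <- sum(vc$ones_rotated * vc$y_rotated / w) / xwx
  r <- vc$y_rotated - vc$ones_rotated * beta
  -0.5 * (sum(log(w)) + log(xwx) + sum(r^2 / w))
}

#' Mixed-model association scan
#'
#' Generalized least squares of the response on (intercept, genotype) for
#' every marker, with V = sigma_g^2 G + sigma_e^2 I fixed at the null REML
#' estimates; Wald chi-square with 1 df. Missing genotypes are mean-imputed;
#' monomorphic markers are skipped.
#'
#' @param ds A \code{genotype_dataset}.
#' @param y Response vector (defaults to the sample table's birth years).
#' @param vc A \code{\link{reml_null}} fit on the same samples.
#' @return Data frame: marker_id, chrom, pos_bp, freq_a1, effect, se, chisq,
#'   p_value.
#' @export
mlma_scan <- function(ds, y = ds$samples$birth_year, vc) {
  stopifnot(inherits(vc, "gpsm_vc"))
  n <- nrow(ds$samples)
  stopifnot(length(y) == n)
  U <- vc$eigen_vectors
  w <- vc$sigma2_g * vc$eigen_values + vc$sigma2_e
  iw <- 1 / w

  p <- marker_freq_a1(ds)
  X <- center_impute(ds$calls, p)          # centered, imputed genotypes
  Xt <- crossprod(U, X)                    # rotate into the eigenbasis
  yt <- crossprod(U, y - mean(y))
  ot <- crossprod(U, rep(1, n))            # rotated intercept

  S11 <- sum(ot^2 * iw)
  S1y <- sum(ot * yt * iw)
  S1x <- drop(crossprod(Xt * iw, ot))
  Sxx <- colSums(Xt^2 * iw)
  Sxy <- drop(crossprod(Xt * iw, yt))

  det2 <- S11 * Sxx - S1x^2
  mono <- p <= 0 | p >= 1 | det2 <= 1e-12
  b <- ifelse(mono, NA_real_, (S11 * Sxy - S1x * S1y) / det2)
  var_b <- ifelse(mono, NA_real_, S11 / det2)
  chisq <- b^2 / var_b
  pval <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)

  data.frame(marker_id = ds$markers$marker_id, chrom = ds$markers$chrom,
             pos_bp = ds$markers$pos_bp, freq_a1 = p,
             effect = b, se = sqrt(var_b), chisq = chisq, p_value = pval,
             stringsAsFactors = FALSE)
}

#' Bonferroni significance level
#'
#' @param n_markers Number of tests.
#' @param alpha Family-wise error rate (default 0.05).
#' @return alpha / n_markers.
#' @export
bonferroni_threshold <- function(n_markers, alpha = 0.05) {
  stopifnot(n_markers >= 1)
  alpha / n_markers
}

#' Quantile-quantile data and genomic inflation factor
#'
#' Expected quantiles are -log10((i - 0.5) / M) against the sorted observed
#' -log10 p; the inflation factor is the median association chi-square over
#' the null median (0.4549).
#'
#' @param p_values Vector of p-values in (0, 1]; zeros are clamped to the
#'   smallest positive double with a warning.
#' @return List: \code{expected}, \code{observed} (sorted, ascending),
#'   \code{lambda}.
#' @export
qq_data <- function(p_values) {
  p <- p_values[!is.na(p_values)]
  if (any(p <= 0)) {
    warning("p-values of 0 clamped to .Machine$double.xmin")
    p[p <= 0] <- .Machine$double.xmin
  }
  M <- length(p)
  obs <- sort(-log10(p))
  expd <- sort(-log10((seq_len(M) - 0.5) / M))
  lambda <- stats::median(stats::qchisq(p, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1)
  list(expected = expd, observed = obs, lambda = lambda)
}

#' Generation-proxy selection mapping
#'
#' The one-stop fitting function: builds (or reuses) the VanRaden G, runs
#' REML under the null, scans all markers with the mixed model, and applies
#' the Bonferroni threshold.
#'
#' @param ds A \code{genotype_dataset} with birth years (after full QC).
#' @param y Response override (default birth years).
#' @param grm Optional precomputed \code{grm}; default built from \code{ds}.
#' @return Object of class \code{gpsm}: list with \code{results} (per-marker
#'   table with \code{significant} flag), \code{vc}, \code{threshold},
#'   \code{qq}, \code{n_markers}, \code{n_samples}.
#' @export
gpsm <- function(ds, y = ds$samples$birth_year, grm = NULL) {
  if (anyNA(y)) stop("response contains missing values; drop those samples first")
  if (is.null(grm)) grm <- grm_vanraden(ds)
  vc <- reml_null(y, grm)
  res <- mlma_scan(ds, y, vc)
  thr <- bonferroni_threshold(sum(!is.na(res$p_value)))
  res$significant <- !is.na(res$p_value) & res$p_value < thr
  structure(list(results = res, vc = vc, threshold = thr,
                 qq = qq_data(res$p_value),
                 n_markers = sum(!is.na(res$p_value)),
                 n_samples = nrow(ds$samples)),
            class = "gpsm")
}

#' @export
print.gpsm <- function(x, ...) {
  cat("Generation-proxy selection mapping\n")
  cat(sprintf("  samples: %d, markers tested: %d\n", x$n_samples, x$n_markers))
  cat(sprintf("  PVE (sigma_g^2 / total): %.3f  [sigma_g^2 = %.3f, sigma_e^2 = %.3f]\n",
              x$vc$pve, x$vc$sigma2_g, x$vc$sigma2_e))
  cat(sprintf("  Bonferroni threshold: %.3e;  significant markers: %d\n",
              x$threshold, sum(x$results$significant, na.rm = TRUE)))
  cat(sprintf("  genomic inflation factor: %.3f\n", x$qq$lambda))
  invisible(x)
}

#' @method summary gpsm
#' @export
summary.gpsm <- function(object, ...) {
  print(object)
  sig <- object$results[which(object$results$significant), ]
  if (nrow(sig)) {
    cat("\nSignificant markers:\n")
    print(sig[order(sig$p_value),
              c("marker_id", "chrom", "pos_bp", "effect", "se", "p_value")],
          row.names = FALSE)
  }
  invisible(object)
}

#' Manhattan / Q-Q plot for a GPSM fit
#'
#' @param x A \code{gpsm} object.
#' @param type \code{"manhattan"} or \code{"qq"}.
#' @param ... Passed to \code{plot}.
#' @method plot gpsm
#' @export
plot.gpsm <- function(x, type = c("manhattan", "qq"), ...) {
  type <- match.arg(type)
  r <- x$results[!is.na(x$results$p_value), ]
  if (type == "manhattan") {
    chr <- factor(r$chrom, levels = unique(r$chrom))
    offs <- c(0, cumsum(tapply(r$pos_bp, chr, max)))
    xpos <- r$pos_bp + offs[as.integer(chr)]
    plot(xpos, -log10(r$p_value), pch = 20, cex = 0.5,
         col = c("grey30", "steelblue")[1 + as.integer(chr) %% 2],
         xlab = "genome position", ylab = expression(-log[10](p)), ...)
    abline(h = -log10(x$threshold), col = "red", lty = 2)
  } else {
    plot(x$qq$expected, x$qq$observed, pch = 20, cex = 0.5,
         xlab = expression(Expected ~ -log[10](p)),
         ylab = expression(Observed ~ -log[10](p)), ...)
    abline(0, 1, col = "red")
  }
  invisible(x)
}
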