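## Runs of homozygosity: sliding-window detection, length classes, summary
## statistics, chromosome coverage, and population-frequency islands.

#' ROH detection parameters
#'
#' Defaults follow the standard array-density parameter set: 50-SNP sliding
#' windows tolerating one heterozygous and one missing call, a 5% window
#' threshold for marker eligibility, and final segments of at least 30 SNPs
#' and 500 kb with at most 50 kb per SNP and a 1000-kb gap cap.
#'
#' @param window_snps Window size in SNPs.
#' @param window_het_max,window_missing_max Per-window tolerances.
#' @param window_threshold Minimum fraction of covering windows that must be
#'   homozygous for a marker to be ROH-eligible.
#' @param min_snps,min_length_kb Final segment floors.
#' @param max_density_kb_per_snp Maximum segment kb per SNP.
#' @param max_gap_kb Split runs at inter-marker gaps above this.
#' @param boundary \code{"hom_run"} (default) snaps each called run to its
#'   longest heterozygote-free stretch; \code{"window"} reports the raw
#'   eligible-run bounds (which systematically overshoot into flanking
#'   heterozygosity).
#' @return List of class \code{roh_params}.
#' @export
roh_params <- function(window_snps = 50, window_het_max = 1,
                       window_missing_max = 1, window_threshold = 0.05,
                       min_snps = 30, min_length_kb = 500,
                       max_density_kb_per_snp = 50, max_gap_kb = 1000,
                       boundary = c("hom_run", "window")) {
  boundary <- match.arg(boundary)
  stopifnot(window_snps >= 1, window_het_max >= 0, window_missing_max >= 0,
            window_threshold > 0, window_threshold <= 1, min_snps >= 1,
            min_length_kb > 0, max_density_kb_per_snp > 0, max_gap_kb > 0)
  structure(as.list(environment()), class = "roh_params")
}

#' Per-marker homozygous-window fraction for one individual
#'
#' For every marker on a chromosome, the fraction of the overlapping 50-SNP
#' windows that are homozygous (at most \code{window_het_max} heterozygotes
#' and \code{window_missing_max} missing calls). On chromosomes shorter than
#' one window the single truncated window spanning the chromosome is used, so
#' termini are not spuriously ineligible.
#'
#' @param calls Integer vector: one individual's calls along one sorted
#'   chromosome.
#' @param params A \code{\link{roh_params}}.
#' @return Numeric vector of fractions in [0, 1], one per marker.
#' @export
window_homozygosity_calls <- function(calls, params = roh_params()) {
  m <- length(calls)
  w <- min(params$window_snps, m)
  het <- as.integer(!is.na(calls) & calls == 1L)
  mis <- as.integer(is.na(calls))
  ch <- c(0L, cumsum(het)); cm <- c(0L, cumsum(mis))
  n_win <- m - w + 1L
  starts <- seq_len(n_win)
  ok <- (ch[starts + w] - ch[starts]) <= params$window_het_max &
    (cm[starts + w] - cm[starts]) <= params$window_missing_max
  cok <- c(0L, cumsum(as.integer(ok)))
  ## windows covering marker k start in [k - w + 1, k], clipped to [1, n_win]
  lo <- pmax(1L, seq_len(m) - w + 1L)
  hi <- pmin(n_win, seq_len(m))
  (cok[hi + 1L] - cok[lo]) / (hi - lo + 1L)
}

## Longest heterozygote-free stretch (missing allowed) within calls[lo:hi].
## Returns c(lo', hi') in the same index space, or NULL if none.
longest_hom_stretch <- function(calls, lo, hi) {
  seg <- calls[lo:hi]
  het <- !is.na(seg) & seg == 1L
  if (!any(het)) return(c(lo, hi))
  r <- rle(!het)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  good <- which(r$values)
  if (!length(good)) return(NULL)
  best <- good[which.max(r$lengths[good])]
  c(lo + starts[best] - 1L, lo + ends[best] - 1L)
}

#' Call runs of homozygosity
#'
#' Markers are flagged ROH-eligible where their homozygous-window fraction
#' meets the threshold; maximal runs of eligible markers are split at
#' inter-marker gaps above the gap cap, snapped to their longest
#' heterozygote-free stretch (default boundary rule), and reported when they
#' hold at least \code{min_snps} markers, span at least \code{min_length_kb},
#' and have at most \code{max_density_kb_per_snp} kb per SNP. Coordinates are
#' the first and last marker positions (1-based, inclusive).
#'
#' @param ds A \code{genotype_dataset} (apply call-rate-only QC upstream).
#' @param params A \code{\link{roh_params}}.
#' @return Data frame: sample_id, population, chrom, start_bp, end_bp,
#'   n_snps, length_kb, length_class.
#' @export
call_roh <- function(ds, params = roh_params()) {
  stopifnot(inherits(ds, "genotype_dataset"))
  segs <- list()
  chrs <- unique(ds$markers$chrom)
  chr_idx <- lapply(chrs, function(ch) which(ds$markers$chrom == ch))
  names(chr_idx) <- chrs
  for (s in seq_len(nrow(ds$samples))) {
    for (ch in chrs) {
      idx <- chr_idx[[ch]]
      pos <- ds$markers$pos_bp[idx]
      calls <- ds$calls[s, idx]
      frac <- window_homozygosity_calls(calls, params)
      elig <- frac >= params$window_threshold
      if (!any(elig)) next
      ## runs of eligible markers, split at large gaps
      gap_break <- c(FALSE, diff(pos) > params$max_gap_kb * 1000)
      grp <- cumsum(!elig | gap_break)
      for (run in split(which(elig), grp[elig])) {
        lo <- run[1]; hi <- run[length(run)]
        if (params$boundary == "hom_run") {
          b <- longest_hom_stretch(calls, lo, hi)
          if (is.null(b)) next
          lo <- b[1]; hi <- b[2]
        }
        n_snps <- hi - lo + 1L
        length_kb <- (pos[hi] - pos[lo] + 1) / 1000
        if (n_snps < params$min_snps) next
        if (length_kb < params$min_length_kb) next
        if (length_kb / n_snps > params$max_density_kb_per_snp) next
        segs[[length(segs) + 1L]] <- data.frame(
          sample_id = ds$samples$sample_id[s],
          population = ds$samples$population[s],
          chrom = ch, start_bp = pos[lo], end_bp = pos[hi],
          n_snps = n_snps, length_kb = length_kb,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(segs)) do.call(rbind, segs) else
    data.frame(sample_id = character(0), population = character(0),
               chrom = character(0), start_bp = integer(0),
               end_bp = integer(0), n_snps = integer(0),
               length_kb = numeric(0), stringsAsFactors = FALSE)
  classify_roh(out)
}

#' Assign ROH length classes
#'
#' Classes at 2/4/8/16 Mb with half-open (low, high] boundaries: a 16.0-Mb
#' segment is "8-16 Mb", 16.1 Mb is ">16 Mb".
#'
#' @param segments A segment table with a \code{length_kb} column.
#' @return The table with a \code{length_class} factor added.
#' @export
classify_roh <- function(segments) {
  lv <- c("<2 Mb", "2-4 Mb", "4-8 Mb", "8-16 Mb", ">16 Mb")
  segments$length_class <- cut(segments$length_kb / 1000,
                               breaks = c(-Inf, 2, 4, 8, 16, Inf),
                               labels = lv, right = TRUE)
  segments
}

#' Per-population ROH summary
#'
#' Counts per individual (including individuals with zero segments), total
#' segment count, and segment-length summaries.
#'
#' @param segments A \code{\link{call_roh}} table.
#' @param samples The sample table the segments were called on.
#' @return Data frame, one row per population: n_individuals, total,
#'   min/max/mean/sd per-individual count, mean/sd length (kb).
#' @export
roh_summary <- function(segments, samples) {
  pops <- unique(samples$population)
  out <- lapply(pops, function(p) {
    ids <- samples$sample_id[samples$population %in% p]
    seg <- segments[segments$sample_id %in% ids, , drop = FALSE]
    counts <- table(factor(seg$sample_id, levels = ids))
    data.frame(population = if (is.na(p)) "all" else p,
               n_individuals = length(ids),
               total = nrow(seg),
               min_count = min(counts), max_count = max(counts),
               mean_count = mean(counts), sd_count = stats::sd(as.numeric(counts)),
               mean_length_kb = if (nrow(seg)) mean(seg$length_kb) else 0,
               sd_length_kb = if (nrow(seg) > 1) stats::sd(seg$length_kb) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Chromosome coverage by ROH
#'
#' Per chromosome, the mean over individuals of the fraction of the
#' chromosome covered by the union of that individual's segments. Chromosome
#' length defaults to the last marker position.
#'
#' @param segments A \code{\link{call_roh}} table.
#' @param ds The dataset the segments were called on.
#' @param chrom_lengths Optional named vector of physical lengths (bp).
#' @return Data frame: chrom, length_bp, mean_coverage (fraction).
#' @export
chromosome_coverage <- function(segments, ds, chrom_lengths = NULL) {
  chrs <- unique(ds$markers$chrom)
  n_ind <- nrow(ds$samples)
  out <- lapply(chrs, function(ch) {
    len <- if (!is.null(chrom_lengths) && ch %in% names(chrom_lengths))
      chrom_lengths[[ch]] else max(ds$markers$pos_bp[ds$markers$chrom == ch])
    seg <- segments[segments$chrom == ch, , drop = FALSE]
    cov <- 0
    if (nrow(seg)) {
      per_ind <- vapply(split(seg, seg$sample_id), function(s) {
        ir <- IRanges::reduce(IRanges::IRanges(s$start_bp, s$end_bp))
        sum(IRanges::width(ir))
      }, numeric(1))
      cov <- sum(per_ind) / (n_ind * len)
    }
    data.frame(chrom = ch, length_bp = len, mean_coverage = cov,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' In-ROH frequency per marker
#'
#' Fraction of individuals whose segment set covers each marker.
#'
#' @param segments A \code{\link{call_roh}} table.
#' @param ds The dataset the segments were called on.
#' @return Numeric vector aligned with the marker map.
#' @export
roh_marker_frequency <- function(segments, ds) {
  n_ind <- nrow(ds$samples)
  freq <- numeric(nrow(ds$markers))
  if (!nrow(segments) || !n_ind) return(freq)
  for (ch in unique(segments$chrom)) {
    idx <- which(ds$markers$chrom == ch)
    pos <- ds$markers$pos_bp[idx]
    seg <- segments[segments$chrom == ch, , drop = FALSE]
    cnt <- numeric(length(idx))
    for (r in seq_len(nrow(seg))) {
      inside <- pos >= seg$start_bp[r] & pos <= seg$end_bp[r]
      cnt[inside] <- cnt[inside] + 1
    }
    freq[idx] <- cnt / n_ind
  }
  freq
}

#' Call ROH islands
#'
#' Maximal runs of consecutive markers whose in-ROH frequency meets the
#' threshold (default: at least half the population) are reported with bp
#' bounds, member markers, and peak frequency.
#'
#' @param segments A \code{\link{call_roh}} table for the full population.
#' @param ds The dataset the segments were called on.
#' @param freq_threshold Minimum in-ROH frequency (default 0.5).
#' @return Data frame: chrom, start_bp, end_bp, n_markers, peak_frequency,
#'   marker_ids (comma-separated).
#' @export
roh_islands <- function(segments, ds, freq_threshold = 0.5) {
  freq <- roh_marker_frequency(segments, ds)
  out <- list()
  for (ch in unique(ds$markers$chrom)) {
    idx <- which(ds$markers$chrom == ch)
    hot <- freq[idx] >= freq_threshold
    if (!any(hot)) next
    grp <- cumsum(!hot)
    for (run in split(idx[hot], grp[hot])) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch,
        start_bp = ds$markers$pos_bp[run[1]],
        end_bp = ds$markers$pos_bp[run[length(run)]],
        n_markers = length(run),
        peak_frequency = max(freq[run]),
        marker_ids = paste(ds$markers$marker_id[run], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), start_bp = integer(0), end_bp = integer(0),
               n_markers = integer(0), peak_frequency = numeric(0),
               marker_ids = character(0), stringsAsFactors = FALSE)
}

#' Write ROH islands as BED
#'
#' BED uses 0-based half-open intervals; the 1-based inclusive bounds of the
#' island table are converted accordingly.
#'
#' @param islands A \code{\link{roh_islands}} table.
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
write_islands_bed <- function(islands, path) {
  bed <- data.frame(chrom = islands$chrom, start = islands$start_bp - 1L,
                    end = islands$end_bp,
                    name = sprintf("island_%d", seq_len(nrow(islands))),
                    score = round(1000 * islands$peak_frequency))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
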