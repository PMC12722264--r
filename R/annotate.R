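## Windowing of candidate markers, overlap with user-supplied gene/QTL
## interval tables, and hypergeometric enrichment of QTL categories.
## Annotation sources are always files supplied by the user -- database
## versions drift, so no live lookups.

#' Read a feature interval table
#'
#' Accepts a TSV with header columns \code{feature_id}, \code{chrom},
#' \code{start_bp}, \code{end_bp} and optional \code{category} (1-based,
#' inclusive), or a GFF3 file (via \code{rtracklayer}; the \code{type} field
#' becomes the category, the \code{ID}/\code{Name} attribute the id).
#'
#' @param path Input file.
#' @param format \code{"tsv"} or \code{"gff3"}.
#' @return Data frame: feature_id, chrom, start_bp, end_bp, category.
#' @export
read_feature_table <- function(path, format = c("tsv", "gff3")) {
  format <- match.arg(format)
  if (format == "tsv") {
    ft <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, quote = "")
    needed <- c("feature_id", "chrom", "start_bp", "end_bp")
    miss <- setdiff(needed, names(ft))
    if (length(miss)) stop("feature table missing columns: ",
                           paste(miss, collapse = ", "))
    ft$chrom <- as.character(ft$chrom)
    if (!"category" %in% names(ft)) ft$category <- NA_character_
  } else {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      stop("GFF3 import requires the rtracklayer package")
    }
    gr <- rtracklayer::import(path, format = "gff3")
    md <- S4Vectors::mcols(gr)
    id <- if ("ID" %in% names(md)) as.character(md$ID) else
      if ("Name" %in% names(md)) as.character(md$Name) else
        paste0("feat_", seq_along(gr))
    ft <- data.frame(feature_id = id,
                     chrom = as.character(GenomicRanges::seqnames(gr)),
                     start_bp = GenomicRanges::start(gr),
                     end_bp = GenomicRanges::end(gr),
                     category = as.character(md$type),
                     stringsAsFactors = FALSE)
  }
  bad <- ft$start_bp > ft$end_bp
  if (any(bad)) stop(sum(bad), " feature(s) with start > end")
  ft
}

#' Flanked windows around candidate markers
#'
#' Each marker gets the interval [position - flank, position + flank],
#' clipped at 1; overlapping or adjacent windows on the same chromosome are
#' merged.
#'
#' @param markers Data frame with \code{chrom} and \code{pos_bp} (e.g. the
#'   significant rows of a \code{gpsm} result, or island marker rows).
#' @param flank_bp Flank on each side (default 100 kb).
#' @return Data frame: window_id, chrom, start_bp, end_bp.
#' @export
windows_from_markers <- function(markers, flank_bp = 1e5) {
  stopifnot(all(c("chrom", "pos_bp") %in% names(markers)))
  if (!nrow(markers)) {
    return(data.frame(window_id = character(0), chrom = character(0),
                      start_bp = integer(0), end_bp = integer(0)))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(markers$chrom),
    ranges = IRanges::IRanges(start = pmax(1, markers$pos_bp - flank_bp),
                              end = markers$pos_bp + flank_bp))
  merged <- GenomicRanges::reduce(gr)
  data.frame(window_id = sprintf("win_%d", seq_along(merged)),
             chrom = as.character(GenomicRanges::seqnames(merged)),
             start_bp = GenomicRanges::start(merged),
             end_bp = GenomicRanges::end(merged),
             stringsAsFactors = FALSE)
}

#' Features overlapping candidate windows
#'
#' Reports every feature overlapping any window by at least 1 bp, with the
#' window that hit it.
#'
#' @param windows A \code{\link{windows_from_markers}} table.
#' @param features A \code{\link{read_feature_table}} table.
#' @return Data frame: window_id, feature_id, chrom, start_bp, end_bp,
#'   category.
#' @export
overlap_features <- function(windows, features) {
  if (!nrow(windows) || !nrow(features)) {
    return(data.frame(window_id = character(0), feature_id = character(0),
                      chrom = character(0), start_bp = integer(0),
                      end_bp = integer(0), category = character(0)))
  }
  gw <- GenomicRanges::GRanges(windows$chrom,
                               IRanges::IRanges(windows$start_bp, windows$end_bp))
  gf <- GenomicRanges::GRanges(features$chrom,
                               IRanges::IRanges(features$start_bp, features$end_bp))
  hits <- GenomicRanges::findOverlaps(gf, gw)
  fi <- S4Vectors::queryHits(hits); wi <- S4Vectors::subjectHits(hits)
  data.frame(window_id = windows$window_id[wi],
             feature_id = features$feature_id[fi],
             chrom = features$chrom[fi],
             start_bp = features$start_bp[fi],
             end_bp = features$end_bp[fi],
             category = features$category[fi],
             stringsAsFactors = FALSE)
}

#' Hypergeometric enrichment of QTL categories
#'
#' Per category, the upper-tail hypergeometric probability of observing at
#' least the hit count among the selection, drawn from the background
#' (over-representation only), with Benjamini-Hochberg adjustment across
#' categories.
#'
#' @param hit_categories Character vector: category of each selected feature.
#' @param background_categories Character vector: category of each background
#'   feature (the selection must be a subset).
#' @return Data frame: category, hits_in_selection, hits_in_background,
#'   selection_size, background_size, p_value, fdr_adjusted_p.
#' @export
qtl_enrichment <- function(hit_categories, background_categories) {
  hit_categories <- hit_categories[!is.na(hit_categories)]
  background_categories <- background_categories[!is.na(background_categories)]
  cats <- unique(hit_categories)
  absent <- setdiff(cats, unique(background_categories))
  if (length(absent)) stop("categories absent from background: ",
                           paste(absent, collapse = ", "))
  N <- length(background_categories)
  n <- length(hit_categories)
  out <- lapply(cats, function(ct) {
    K <- sum(background_categories == ct)
    k <- sum(hit_categories == ct)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(category = ct, hits_in_selection = k, hits_in_background = K,
               selection_size = n, background_size = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$fdr_adjusted_p <- stats::p.adjust(out$p_value, method = "BH")
  out[order(out$p_value), ]
}

#' Write windows as BED (0-based half-open)
#'
#' @param windows A \code{\link{windows_from_markers}} table.
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
write_windows_bed <- function(windows, path) {
  bed <- data.frame(chrom = windows$chrom, start = windows$start_bp - 1L,
                    end = windows$end_bp, name = windows$window_id)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
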