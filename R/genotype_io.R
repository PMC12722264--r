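## PLINK 1 binary (bed/bim/fam) codec, SNP-major layout.
##
## bed 2-bit encoding per sample, little-endian within each byte:
##   00 -> homozygous A1 (2 copies of A1)   10 -> heterozygous (1 copy)
##   11 -> homozygous A2 (0 copies)         01 -> missing
## One byte packs 4 samples; each marker starts on a byte boundary.

BED_MAGIC <- as.raw(c(0x6c, 0x1b, 0x01))

## 256 x 4 lookup: byte value -> allele-A1 counts of the 4 packed samples.
bed_decode_table <- function() {
  tab <- matrix(NA_integer_, 256, 4)
  code2count <- c(`0` = 2L, `1` = NA_integer_, `2` = 1L, `3` = 0L)
  for (b in 0:255) {
    for (k in 0:3) {
      code <- bitwAnd(bitwShiftR(b, 2L * k), 3L)
      tab[b + 1L, k + 1L] <- code2count[[as.character(code)]]
    }
  }
  tab
}
.bed_env <- new.env(parent = emptyenv())
get_bed_tab <- function() {
  if (is.null(.bed_env$tab)) .bed_env$tab <- bed_decode_table()
  .bed_env$tab
}

#' Read PLINK 1 binary genotypes
#'
#' Reads a \code{.bed}/\code{.bim}/\code{.fam} triplet (SNP-major, v1.00
#' magic) into a \code{\link{genotype_dataset}}, decoding calls to counts of
#' the bim A1 allele. Sample and marker order are preserved from the fam and
#' bim files. Population labels and birth years are not part of the PLINK
#' format; supply them with \code{\link{read_sample_metadata}}.
#'
#' @param prefix Path prefix; \code{<prefix>.bed} etc. must exist.
#' @param metadata Optional path to a sidecar metadata TSV (columns
#'   \code{sample_id}, \code{population}, \code{birth_year}) merged by
#'   sample_id.
#' @return A \code{genotype_dataset}.
#' @export
read_plink <- function(prefix, metadata = NULL) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  for (p in paths) if (!file.exists(p)) stop("file not found: ", p)

  fam <- utils::read.table(paths[3], header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  bim <- if (file.info(paths[2])$size == 0) {
    data.frame(V1 = character(0), V2 = character(0), V3 = numeric(0),
               V4 = integer(0), V5 = character(0), V6 = character(0))
  } else {
    utils::read.table(paths[2], header = FALSE, stringsAsFactors = FALSE,
                      colClasses = c("character", "character", "numeric",
                                     "integer", "character", "character"))
  }
  n <- nrow(fam); m <- nrow(bim)

  samples <- data.frame(sample_id = fam[[2]], stringsAsFactors = FALSE)
  markers <- data.frame(marker_id = bim[[2]], chrom = bim[[1]],
                        pos_bp = bim[[4]], a1 = bim[[5]], a2 = bim[[6]],
                        stringsAsFactors = FALSE)

  bytes_per_marker <- (n + 3L) %/% 4L
  expected <- 3L + bytes_per_marker * m
  sz <- file.info(paths[1])$size
  raw <- readBin(paths[1], "raw", n = expected + 1L)
  if (length(raw) < 3L || !identical(raw[1:3], BED_MAGIC)) {
    stop("bad magic bytes in ", paths[1], ": not a PLINK 1 SNP-major bed file")
  }
  if (sz != expected) {
    stop("size mismatch in ", paths[1], ": expected ", expected,
         " bytes for ", n, " samples x ", m, " markers, found ", sz)
  }
  body <- as.integer(raw[-(1:3)]) + 1L
  tab <- get_bed_tab()
  ## decode all bytes to a (4*bytes_per_marker) x m matrix, then crop to n rows
  counts <- matrix(t(tab[body, , drop = FALSE]), nrow = 4L * bytes_per_marker,
                   ncol = m)
  calls <- counts[seq_len(n), , drop = FALSE]

  ds <- genotype_dataset(calls, samples, markers, sort_markers = FALSE)
  if (!is.null(metadata)) ds <- read_sample_metadata(ds, metadata)
  ds
}

#' Write PLINK 1 binary genotypes
#'
#' Writes the dataset as a SNP-major \code{.bed}/\code{.bim}/\code{.fam}
#' triplet readable by \code{\link{read_plink}} with bit-identical calls.
#' A zero-marker dataset yields a valid bed file containing only the magic
#' bytes.
#'
#' @param ds A \code{genotype_dataset}.
#' @param prefix Output path prefix.
#' @param metadata Also write the sidecar metadata TSV
#'   (\code{<prefix>.meta.tsv}) with population and birth year. Default TRUE.
#' @return Invisibly, the vector of paths written.
#' @export
write_plink <- function(ds, prefix, metadata = TRUE) {
  stopifnot(inherits(ds, "genotype_dataset"))
  n <- nrow(ds$samples); m <- nrow(ds$markers)
  dir <- dirname(prefix)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)

  fam <- data.frame(fid = ds$samples$sample_id, iid = ds$samples$sample_id,
                    pat = 0L, mat = 0L,
                    sex = ifelse(is.na(ds$samples$sex), 0L,
                                 match(ds$samples$sex, c("M", "F"), nomatch = 0L)),
                    phe = -9L)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  bim <- data.frame(chrom = ds$markers$chrom, id = ds$markers$marker_id,
                    cm = rep(0, m), pos = ds$markers$pos_bp,
                    a1 = ds$markers$a1, a2 = ds$markers$a2)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  ## counts -> 2-bit codes: 2->00, NA->01, 1->10, 0->11
  codes <- matrix(3L, nrow = n, ncol = m)
  if (n && m) {
    codes[which(ds$calls == 2L)] <- 0L
    codes[which(ds$calls == 1L)] <- 2L
    codes[which(is.na(ds$calls))] <- 1L
  }
  bytes_per_marker <- (n + 3L) %/% 4L
  pad <- 4L * bytes_per_marker - n
  if (pad > 0L && m > 0L) codes <- rbind(codes, matrix(0L, pad, m))
  payload <- raw(0)
  if (m > 0L && bytes_per_marker > 0L) {
    shifted <- codes * rep(c(1L, 4L, 16L, 64L), times = bytes_per_marker)
    grp <- rep(seq_len(bytes_per_marker), each = 4L)
    bytes <- rowsum(shifted, grp, reorder = FALSE)   # bytes_per_marker x m
    payload <- as.raw(as.vector(bytes))
  }
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(BED_MAGIC, con)
  if (length(payload)) writeBin(payload, con)

  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  if (metadata) {
    meta <- ds$samples[, c("sample_id", "population", "birth_year")]
    mp <- paste0(prefix, ".meta.tsv")
    utils::write.table(meta, mp, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, mp)
  }
  invisible(paths)
}

#' Attach sample metadata from a sidecar TSV
#'
#' The fam format has no population or birth-year field; this package carries
#' them in a tab-separated sidecar keyed by \code{sample_id}.
#'
#' @param ds A \code{genotype_dataset}.
#' @param path TSV with header columns \code{sample_id}, \code{population},
#'   \code{birth_year}.
#' @return The dataset with its sample table updated.
#' @export
read_sample_metadata <- function(ds, path) {
  meta <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(meta)) stop("metadata needs a sample_id column")
  idx <- match(ds$samples$sample_id, as.character(meta$sample_id))
  if ("population" %in% names(meta)) {
    ds$samples$population <- meta$population[idx]
  }
  if ("birth_year" %in% names(meta)) {
    ds$samples$birth_year <- as.integer(meta$birth_year[idx])
  }
  ds
}

## Strand-ambiguous allele pairs cannot be oriented across datasets.
is_ambiguous_pair <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize allele coding and intersect marker sets across datasets
#'
#' Restricts every dataset to the markers present in all of them, makes the A1
#' allele identical across datasets (flipping genotypes 0<->2 where A1/A2 are
#' swapped relative to the first dataset), and drops markers whose allele
#' pairs cannot be reconciled -- including strand-ambiguous A/T and C/G pairs,
#' whose orientation (and hence the sign of D in phase comparisons) is
#' undecidable.
#'
#' @param datasets List of two or more \code{genotype_dataset} objects.
#' @param drop_ambiguous Drop A/T and C/G markers. Default TRUE.
#' @return The list of harmonized datasets, with a \code{"report"} attribute:
#'   a data.frame of kept/flipped/dropped counts per dataset.
#' @export
harmonize_and_intersect <- function(datasets, drop_ambiguous = TRUE) {
  stopifnot(length(datasets) >= 2)
  ids <- Reduce(intersect, lapply(datasets, function(d) d$markers$marker_id))
  if (!length(ids)) stop("no markers shared by all datasets")

  ref <- datasets[[1]]$markers
  ref <- ref[match(ids, ref$marker_id), ]
  keep <- rep(TRUE, length(ids))
  if (drop_ambiguous) keep <- keep & !is_ambiguous_pair(ref$a1, ref$a2)

  flips <- vector("list", length(datasets))
  for (k in seq_along(datasets)) {
    mk <- datasets[[k]]$markers
    mk <- mk[match(ids, mk$marker_id), ]
    same <- mk$a1 == ref$a1 & mk$a2 == ref$a2
    swap <- mk$a1 == ref$a2 & mk$a2 == ref$a1
    keep <- keep & (same | swap)
    flips[[k]] <- swap
  }

  ids_kept <- ids[keep]
  if (!length(ids_kept)) stop("no markers shared by all datasets after allele reconciliation")
  out <- vector("list", length(datasets))
  report <- data.frame(dataset = seq_along(datasets),
                       kept = NA_integer_, flipped = NA_integer_,
                       dropped = NA_integer_)
  for (k in seq_along(datasets)) {
    d <- subset_dataset(datasets[[k]], markers = ids_kept)
    fl <- flips[[k]][keep]
    if (any(fl)) {
      d$calls[, fl] <- 2L - d$calls[, fl, drop = FALSE]
      mi <- match(ids_kept[fl], d$markers$marker_id)
      a1 <- d$markers$a1[mi]
      d$markers$a1[mi] <- d$markers$a2[mi]
      d$markers$a2[mi] <- a1
    }
    report$kept[k] <- length(ids_kept)
    report$flipped[k] <- sum(fl)
    report$dropped[k] <- length(ids) - length(ids_kept)
    out[[k]] <- d
  }
  names(out) <- names(datasets)
  attr(out, "report") <- report
  out
}
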