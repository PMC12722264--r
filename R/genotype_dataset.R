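#' Construct a genotype dataset
#'
#' The central container of the package: a sample table, a marker map, and a
#' samples x markers matrix of allele-A1 counts (0, 1, 2, or \code{NA} for a
#' missing call). All analysis stages consume and return this class.
#'
#' @param calls Integer matrix, samples in rows and markers in columns; entries
#'   must be 0, 1, 2 or \code{NA}.
#' @param samples Data frame with at least a \code{sample_id} column; optional
#'   \code{population}, \code{birth_year} and \code{sex} columns. Missing
#'   optional columns are added as \code{NA}.
#' @param markers Data frame with columns \code{marker_id}, \code{chrom},
#'   \code{pos_bp}, \code{a1}, \code{a2}. Positions are 1-based base pairs.
#' @param sort_markers Sort the marker map by chromosome and position (and the
#'   call matrix with it). Default \code{TRUE}; map order is load-bearing for
#'   windowed analyses (LD, ROH).
#'
#' @return An object of class \code{genotype_dataset}: a list with elements
#'   \code{samples}, \code{markers}, \code{calls}.
#' @export
genotype_dataset <- function(calls, samples, markers, sort_markers = TRUE) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)

  if (!"sample_id" %in% names(samples)) stop("samples needs a 'sample_id' column")
  for (col in c("population", "birth_year", "sex")) {
    if (!col %in% names(samples)) samples[[col]] <- NA
  }
  needed <- c("marker_id", "chrom", "pos_bp", "a1", "a2")
  miss <- setdiff(needed, names(markers))
  if (length(miss)) stop("markers is missing columns: ", paste(miss, collapse = ", "))

  samples$sample_id <- as.character(samples$sample_id)
  markers$marker_id <- as.character(markers$marker_id)
  markers$chrom <- as.character(markers$chrom)
  markers$pos_bp <- as.integer(markers$pos_bp)

  if (anyDuplicated(samples$sample_id)) stop("duplicate sample_id in sample table")
  if (anyDuplicated(markers$marker_id)) stop("duplicate marker_id in marker map")
  if (nrow(calls) != nrow(samples) || ncol(calls) != nrow(markers)) {
    stop("calls is ", nrow(calls), " x ", ncol(calls), " but tables describe ",
         nrow(samples), " samples and ", nrow(markers), " markers")
  }
  bad <- calls[!is.na(calls)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) {
    stop("genotype calls must be 0, 1, 2 or NA")
  }
  ok_alleles <- c("A", "C", "G", "T", "0")
  if (!all(markers$a1 %in% ok_alleles) || !all(markers$a2 %in% ok_alleles)) {
    stop("alleles must be one of A, C, G, T, 0")
  }
  yr <- samples$birth_year[!is.na(samples$birth_year)]
  if (length(yr) && (min(yr) < 1900 || max(yr) > 2100)) {
    stop("birth_year outside plausible range 1900-2100")
  }

  if (sort_markers) {
    ord <- order(suppressWarnings(as.numeric(markers$chrom)), markers$chrom,
                 markers$pos_bp)
    markers <- markers[ord, , drop = FALSE]
    calls <- calls[, ord, drop = FALSE]
    rownames(markers) <- NULL
  }
  by_chr <- split(markers$pos_bp, markers$chrom)
  if (any(vapply(by_chr, function(p) any(diff(p) <= 0), logical(1)))) {
    stop("marker positions must be strictly increasing within a chromosome")
  }

  dimnames(calls) <- list(samples$sample_id, markers$marker_id)
  structure(list(samples = samples, markers = markers, calls = calls),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  npop <- length(unique(x$samples$population[!is.na(x$samples$population)]))
  cat("genotype_dataset: ", nrow(x$samples), " samples x ", nrow(x$markers),
      " markers, ", length(unique(x$markers$chrom)), " chromosome(s)",
      if (npop) paste0(", ", npop, " population(s)") else "", "\n", sep = "")
  miss <- mean(is.na(x$calls))
  cat(sprintf("missing call rate: %.4f\n", miss))
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$calls)

#' Subset a genotype dataset
#'
#' @param ds A \code{genotype_dataset}.
#' @param samples Logical/integer/character index into the sample table.
#' @param markers Logical/integer/character index into the marker map.
#' @return The restricted \code{genotype_dataset}.
#' @export
subset_dataset <- function(ds, samples = NULL, markers = NULL) {
  stopifnot(inherits(ds, "genotype_dataset"))
  si <- if (is.null(samples)) seq_len(nrow(ds$samples)) else samples
  if (is.character(si)) si <- match(si, ds$samples$sample_id)
  mi <- if (is.null(markers)) seq_len(nrow(ds$markers)) else markers
  if (is.character(mi)) mi <- match(mi, ds$markers$marker_id)
  s <- ds$samples[si, , drop = FALSE]; rownames(s) <- NULL
  m <- ds$markers[mi, , drop = FALSE]; rownames(m) <- NULL
  genotype_dataset(ds$calls[si, mi, drop = FALSE], s, m, sort_markers = FALSE)
}

#' Split a dataset by population label
#'
#' @param ds A \code{genotype_dataset} with a \code{population} column.
#' @return Named list of \code{genotype_dataset}, one per population.
#' @export
split_populations <- function(ds) {
  stopifnot(inherits(ds, "genotype_dataset"))
  pops <- unique(ds$samples$population)
  pops <- pops[!is.na(pops)]
  out <- lapply(pops, function(p) subset_dataset(ds, ds$samples$population == p))
  names(out) <- pops
  out
}

## Allele-A1 frequency per marker over non-missing calls; NA where all missing.
marker_freq_a1 <- function(ds) {
  colMeans(ds$calls, na.rm = TRUE) / 2
}

#' Per-marker minor allele frequency
#'
#' @param ds A \code{genotype_dataset}.
#' @return Numeric vector, \code{min(p, 1 - p)} of the allele-A1 frequency over
#'   non-missing calls; \code{NaN} for all-missing markers.
#' @export
marker_maf <- function(ds) {
  p <- marker_freq_a1(ds)
  pmin(p, 1 - p)
}
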