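## Population-level identity-by-state tree: mean genotypes per population,
## an IBS distance matrix, and Neighbor-Joining (Saitou & Nei) through ape.

#' Population mean genotypes
#'
#' Per population and marker, the mean of the non-missing 0/1/2 calls.
#' Markers where any population has zero non-missing calls are dropped from
#' all populations (logged via attribute \code{"dropped_markers"}).
#'
#' @param datasets Named list of harmonized \code{genotype_dataset} objects,
#'   or one dataset with population labels.
#' @return Matrix populations x markers of mean allele-A1 counts.
#' @export
population_mean_genotypes <- function(datasets) {
  if (inherits(datasets, "genotype_dataset")) datasets <- split_populations(datasets)
  stopifnot(length(datasets) >= 1)
  ids <- datasets[[1]]$markers$marker_id
  means <- t(vapply(datasets, function(d) {
    stopifnot(identical(d$markers$marker_id, ids))
    colMeans(d$calls, na.rm = TRUE)
  }, numeric(length(ids))))
  rownames(means) <- names(datasets)
  colnames(means) <- ids
  bad <- apply(means, 2, function(x) any(is.nan(x)))
  out <- means[, !bad, drop = FALSE]
  attr(out, "dropped_markers") <- ids[bad]
  out
}

#' Identity-by-state distance between population mean genotypes
#'
#' distance(j, k) = mean over markers of |mean_j - mean_k| / 2: the mean
#' allele-sharing mismatch, bounded in [0, 1] (0 for identical populations, 1
#' for populations fixed for opposite alleles everywhere).
#'
#' @param means Matrix from \code{\link{population_mean_genotypes}}.
#' @param method \code{"ibs"} (default) or \code{"euclidean"} (on mean
#'   genotypes scaled by 2, for sensitivity).
#' @return A symmetric \code{matrix} with zero diagonal.
#' @export
ibs_distance_matrix <- function(means, method = c("ibs", "euclidean")) {
  method <- match.arg(method)
  if (anyNA(means)) stop("means matrix must be complete")
  d <- if (method == "ibs") {
    as.matrix(stats::dist(means, method = "manhattan")) / (2 * ncol(means))
  } else {
    as.matrix(stats::dist(means / 2)) / sqrt(ncol(means))
  }
  diag(d) <- 0
  d
}

#' Neighbor-Joining tree from a distance matrix
#'
#' Standard agglomerative Neighbor-Joining; additive (tree-metric) inputs are
#' recovered exactly. Negative branch lengths -- a known NJ artifact on
#' non-additive inputs -- are clamped to zero with the deficit transferred to
#' the adjacent edge, and each clamp is recorded in attribute
#' \code{"clamped"}. The tree is left unrooted.
#'
#' @param d Symmetric distance matrix (>= 3 labels) or \code{dist}.
#' @param clamp_negative Clamp negative branch lengths (default TRUE).
#' @return An \code{ape} \code{phylo} tree.
#' @export
neighbor_joining <- function(d, clamp_negative = TRUE) {
  dm <- as.matrix(d)
  if (nrow(dm) < 3) stop("at least 3 labels required")
  if (!isSymmetric(unname(dm), tol = 1e-8)) stop("distance matrix must be symmetric")
  tree <- ape::nj(stats::as.dist(dm))
  n_clamped <- 0L
  if (clamp_negative && any(tree$edge.length < 0)) {
    for (e in which(tree$edge.length < 0)) {
      deficit <- tree$edge.length[e]
      tree$edge.length[e] <- 0
      parent <- tree$edge[e, 1]
      sib <- setdiff(which(tree$edge[, 1] == parent), e)
      if (length(sib)) {
        tree$edge.length[sib[1]] <- tree$edge.length[sib[1]] + deficit
      }
      n_clamped <- n_clamped + 1L
    }
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  attr(tree, "clamped") <- n_clamped
  tree
}

#' Write (and read back) Newick trees
#'
#' Thin wrappers over \code{ape}; labels with spaces are quoted per the
#' Newick convention by \code{ape} itself.
#'
#' @param tree A \code{phylo} tree.
#' @param path Output file.
#' @return \code{write_newick}: invisibly, the path. \code{read_newick}: a
#'   \code{phylo} tree.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}

#' Build the population tree in one step
#'
#' @param datasets Harmonized datasets (list or labeled single dataset).
#' @param method Distance method, see \code{\link{ibs_distance_matrix}}.
#' @return List: \code{means}, \code{distances}, \code{tree}.
#' @export
population_tree <- function(datasets, method = "ibs") {
  means <- population_mean_genotypes(datasets)
  d <- ibs_distance_matrix(means, method)
  list(means = means, distances = d, tree = neighbor_joining(d))
}
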