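# Phylogeny of gland mutation profiles: binary presence/absence profiles,
# pairwise Hamming distances, neighbor-joining trees and the Fitch
# parsimony score.

#' Binary mutation profiles from a MAF matrix
#'
#' @param matrix Site-by-gland MAF matrix.
#' @param presence_maf Presence threshold (default 0.25).
#' @return Integer 0/1 matrix, rows = glands (taxa), columns = sites.
#' @export
binary_profiles <- function(matrix, presence_maf = 0.25) {
  t(matrix >= presence_maf) * 1L
}

#' Pairwise Hamming distances between binary profiles
#'
#' @param profiles Binary matrix, rows = taxa, columns = characters (equal
#'   length for all taxa by construction).
#' @return Symmetric numeric matrix of Hamming distances with zero diagonal.
#' @export
hamming_matrix <- function(profiles) {
  if (is.null(dim(profiles))) stop("`profiles` must be a matrix", call. = FALSE)
  if (!all(profiles %in% c(0, 1))) stop("profiles must be binary", call. = FALSE)
  as.matrix(dist(profiles, method = "manhattan"))
}

#' Neighbor-joining tree
#'
#' Classic neighbor joining (Q-matrix selection with the standard
#' branch-length formulas, via `ape::nj()`); for additive distance matrices
#' the topology and branch lengths are exact. Negative branch lengths, which
#' NJ can produce on non-additive input, are clamped to zero with a warning.
#'
#' @param d Symmetric distance matrix (or `dist`) over >= 3 taxa.
#' @param labels Optional taxon labels overriding `dimnames`.
#' @return An `ape::phylo` unrooted tree.
#' @export
nj_tree <- function(d, labels = NULL) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("need at least 3 taxa", call. = FALSE)
  if (!is.null(labels)) dimnames(d) <- list(labels, labels)
  tree <- ape::nj(stats::as.dist(d))
  if (any(tree$edge.length < 0)) {
    warning("negative branch lengths clamped to zero")
    tree$edge.length <- pmax(tree$edge.length, 0)
  }
  tree
}

#' Fitch parsimony score
#'
#' Minimum number of character changes over the tree, summed across binary
#' characters (small-parsimony scoring via `phangorn::fitch()`).
#'
#' @param tree An `ape::phylo` whose tip labels match the profile rows.
#' @param profiles Binary matrix, rows = taxa.
#' @return Integer: the parsimony score.
#' @export
parsimony_score <- function(tree, profiles) {
  if (!setequal(tree$tip.label, rownames(profiles))) {
    stop("tree tips and profile rows do not match", call. = FALSE)
  }
  dat <- phangorn::phyDat(profiles[tree$tip.label, , drop = FALSE],
                          type = "USER", levels = c(0, 1))
  as.integer(phangorn::fitch(tree, dat))
}
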