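#' Neighbor-joining tree from a distance matrix
#'
#' Applies the classic Saitou-Nei neighbor-joining algorithm (via
#' \pkg{ape}) to a symmetric distance matrix with zero diagonal. For an
#' additive matrix the generating topology and branch lengths are recovered
#' exactly. Neighbor joining can produce negative branch lengths on noisy
#' input; these are kept as computed unless `clampNegative = TRUE` sets
#' them to zero.
#'
#' @param x a [SpacedDistanceMatrix-class] or a symmetric numeric matrix
#'   with taxon dimnames.
#' @param clampNegative set negative branch lengths to 0 (default `FALSE`).
#' @return an unrooted `ape::phylo` tree.
#' @export
#' @examples
#' d <- matrix(c(0,3,5,6, 3,0,6,7, 5,6,0,7, 6,7,7,0), 4, 4,
#'             dimnames = list(LETTERS[1:4], LETTERS[1:4]))
#' neighborJoining(d)
neighborJoining <- function(x, clampNegative = FALSE) {
  m <- if (is(x, "SpacedDistanceMatrix")) distances(x) else as.matrix(x)
  if (nrow(m) < 3L) stop("neighbor joining needs at least 3 taxa")
  if (!isTRUE(all.equal(m, t(m)))) stop("distance matrix must be symmetric")
  tr <- ape::nj(stats::as.dist(m))
  if (clampNegative) tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Robinson-Foulds comparison of two trees
#'
#' Counts the symmetric difference of the non-trivial bipartitions of two
#' unrooted trees over the same leaf set (via \pkg{phangorn}), and reports
#' it together with the maximum possible value \eqn{2n - 6} for \eqn{n}
#' shared leaves and the relative RF distance \eqn{\mathrm{rf}/(2n-6)}.
#' Multifurcating trees are compared as-is (polytomies are not resolved);
#' the symmetric difference definition applies unchanged.
#'
#' @param tree1,tree2 `ape::phylo` trees with identical leaf label sets.
#' @return list: `n`, `rf`, `max_rf`, `relative_rf`.
#' @export
#' @examples
#' t1 <- ape::read.tree(text = "((A:1,B:1):1,C:1,D:1);")
#' t2 <- ape::read.tree(text = "((A:1,C:1):1,B:1,D:1);")
#' rfDistance(t1, t2) # rf 2 of max 2
rfDistance <- function(tree1, tree2) {
  if (!setequal(tree1$tip.label, tree2$tip.label)) {
    stop("trees have different leaf sets")
  }
  n <- length(tree1$tip.label)
  rf <- as.numeric(phangorn::RF.dist(ape::unroot(tree1), ape::unroot(tree2),
                                     check.labels = TRUE))
  max_rf <- 2 * n - 6
  list(n = n, rf = rf, max_rf = max_rf,
       relative_rf = if (max_rf > 0) rf / max_rf else NA_real_)
}

#' Relative Robinson-Foulds distance from printed table values
#'
#' The relative RF distance of an absolute RF value for `n` taxa is
#' \eqn{\mathrm{rf}/(2n-6)}; published tables render it rounded half up to
#' two decimals, which this helper reproduces.
#'
#' @param rf absolute RF distance (may be a non-integer average over runs).
#' @param n number of taxa.
#' @param digits decimals for rounding (default 2; `NULL` for unrounded).
#' @return relative RF value.
#' @export
#' @examples
#' relativeRF(4, 29)  # 0.08
#' relativeRF(6, 19)  # 0.19
relativeRF <- function(rf, n, digits = 2) {
  stopifnot(n >= 4)
  val <- rf / (2 * n - 6)
  if (is.null(digits)) val else roundHalfUp(val, digits)
}

#' Newick tree input and output
#'
#' Thin wrappers over \pkg{ape}'s Newick parser and writer; unrooted trees
#' are serialized with a trifurcating root, and round-tripping preserves
#' topology and branch lengths to the writer's precision.
#'
#' @param path file path.
#' @return `readNewick` returns an `ape::phylo`; `writeNewick` returns
#'   `path` invisibly.
#' @export
readNewick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("malformed Newick file: ", path)
  if (anyDuplicated(tr$tip.label)) stop("duplicate leaf labels in ", path)
  tr
}

#' @rdname readNewick
#' @param tree an `ape::phylo`.
#' @export
writeNewick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
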