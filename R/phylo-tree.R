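#' Read and write phylogenies in Newick format
#'
#' Thin wrappers around ape's Newick parser that validate what the
#' comparative machinery needs: branch lengths present, non-negative, and no
#' duplicated tip labels.
#'
#' @param file Path to a Newick file (one or several trees).
#' @param text Newick string, used instead of `file` when given.
#' @return An `ape::phylo` (single tree) or `multiPhylo` (several).
#' @export
read_newick <- function(file = NULL, text = NULL) {
  tr <- if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(file)
  if (is.null(tr)) abort("malformed Newick input.")
  check_tree <- function(t) {
    if (anyDuplicated(t$tip.label)) abort("duplicate tip labels.")
    if (is.null(t$edge.length)) abort("tree has no branch lengths.")
    if (any(t$edge.length < 0)) abort("negative branch lengths.")
    t
  }
  if (inherits(tr, "multiPhylo")) {
    structure(lapply(tr, check_tree), class = "multiPhylo")
  } else {
    check_tree(tr)
  }
}

#' @rdname read_newick
#' @param tree A `phylo` or `multiPhylo` object.
#' @param digits Significant digits for branch lengths.
#' @return `write_newick()` returns the Newick string invisibly (and writes
#'   to `file` when given).
#' @export
write_newick <- function(tree, file = "", digits = 10) {
  out <- ape::write.tree(tree, file = file, digits = digits)
  invisible(out)
}

#' Brownian-motion covariance matrix of a tree
#'
#' Entry (i, j) is the shared path length from the root to the most recent
#' common ancestor of tips i and j; the diagonal holds each tip's root-to-tip
#' distance. Under Brownian motion with rate `sigma2`, trait covariances are
#' `sigma2 * C`.
#'
#' @param tree An `ape::phylo` tree with branch lengths.
#' @return A symmetric positive semidefinite matrix with tip labels as
#'   dimnames.
#' @export
phylo_vcv <- function(tree) {
  ape::vcv.phylo(tree)
}

#' Pagel's lambda transform of a Brownian covariance matrix
#'
#' Multiplies the off-diagonal entries of `C` by `lambda`, leaving the
#' diagonal unchanged: `lambda = 1` is Brownian motion, `lambda = 0` a star
#' phylogeny with independent tips.
#'
#' @param C Covariance matrix from [phylo_vcv()].
#' @param lambda Signal strength in `[0, 1]`.
#' @return The transformed matrix.
#' @export
lambda_transform <- function(C, lambda) {
  if (!is.matrix(C) || nrow(C) != ncol(C)) abort("`C` must be square.")
  if (!is.finite(lambda) || lambda < 0 || lambda > 1) {
    abort("`lambda` must lie in [0, 1].")
  }
  V <- C * lambda
  diag(V) <- diag(C)
  V
}

# Tree is ultrametric when all root-to-tip distances agree.
is_ultrametric <- function(tree, tol = 1e-8) {
  d <- diag(ape::vcv.phylo(tree))
  diff(range(d)) < tol * max(d)
}
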