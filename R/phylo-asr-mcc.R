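#' Ancestral state reconstruction under Brownian motion
#'
#' Maximum-likelihood (equivalently GLS) estimates of a continuous trait at
#' every internal node. The root estimate is the GLS grand mean; other nodes
#' are the conditional expectations of the Brownian process given the tip
#' values, using the shared-path-length covariances between nodes and tips.
#'
#' @param tree An `ape::phylo` tree with branch lengths.
#' @param tip_values Named numeric vector of tip states (names = tip
#'   labels), or unnamed in tip order.
#' @return A named numeric vector of states for internal nodes, names being
#'   ape's node numbers (`n_tips + 1` is the root).
#' @export
asr_bm <- function(tree, tip_values) {
  n <- length(tree$tip.label)
  m <- tree$Nnode
  if (!is.null(names(tip_values))) {
    if (!setequal(names(tip_values), tree$tip.label)) {
      abort("tip value names must match the tree's tips.")
    }
    y <- tip_values[tree$tip.label]
  } else {
    if (length(tip_values) != n) abort("need one value per tip.")
    y <- setNames(tip_values, tree$tip.label)
  }
  C <- phylo_vcv(tree)[tree$tip.label, tree$tip.label]
  one <- rep(1, n)
  Ci_y <- solve(C, y)
  Ci_1 <- solve(C, one)
  mu <- sum(Ci_y) / sum(Ci_1)
  # covariance of each internal node with each tip: depth of their MRCA
  depth <- ape::node.depth.edgelength(tree)
  mr <- ape::mrca(tree, full = TRUE)
  Cnt <- matrix(depth[mr[n + seq_len(m), seq_len(n)]], m, n)
  anc <- mu + drop(Cnt %*% solve(C, y - mu))
  setNames(anc, as.character(n + seq_len(m)))
}

#' Maximum clade credibility tree from a tree sample
#'
#' Scores every tree in the sample by the sum over its clades of the log
#' frequency with which that clade occurs in the sample, and returns the
#' highest-scoring tree. Node heights on the returned tree are replaced by
#' the mean height of each clade across the sample trees that contain it
#' (edges clamped at zero length if the averaged heights are locally
#' inconsistent).
#'
#' @param trees A `multiPhylo` (or list of `phylo`) sharing one tip set.
#' @return The MCC tree (`phylo`) with attributes `log_credibility` (its
#'   score) and `scores` (per-tree log credibilities).
#' @export
mcc_tree <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!length(trees)) abort("empty tree sample.")
  tipsets <- purrr::map(trees, function(t) sort(t$tip.label))
  if (length(unique(tipsets)) != 1) abort("trees must share one tip set.")
  n_trees <- length(trees)
  clades <- purrr::map(trees, tree_clades)
  counts <- table(unlist(purrr::map(clades, names)))
  scores <- purrr::map_dbl(clades, function(cl) {
    sum(log(as.numeric(counts[names(cl)]) / n_trees))
  })
  best <- which.max(scores)
  out <- trees[[best]]
  # mean clade heights across trees containing the clade
  height_sum <- new.env(parent = emptyenv())
  for (cl in clades) {
    for (key in names(cl)) {
      prev <- height_sum[[key]] %||% c(0, 0)
      height_sum[[key]] <- prev + c(cl[[key]], 1)
    }
  }
  best_clades <- clades[[best]]
  node_height <- purrr::map_dbl(names(best_clades), function(key) {
    s <- height_sum[[key]]
    s[1] / s[2]
  })
  n <- length(out$tip.label)
  heights <- c(rep(0, n), rep(NA_real_, out$Nnode))
  node_ids <- attr(best_clades, "node_ids")
  heights[node_ids] <- node_height
  el <- heights[out$edge[, 1]] - heights[out$edge[, 2]]
  out$edge.length <- pmax(el, 0)
  attr(out, "log_credibility") <- scores[best]
  attr(out, "scores") <- scores
  out
}

# Named list of clade heights, one entry per internal node; names are
# canonical sorted tip-label keys, attribute `node_ids` maps to ape node
# numbers in the same order.
tree_clades <- function(tree) {
  n <- length(tree$tip.label)
  pp <- ape::prop.part(tree)
  labels <- attr(pp, "labels")
  depth <- ape::node.depth.edgelength(tree)
  total <- max(depth)
  node_ids <- n + seq_len(tree$Nnode)
  keys <- purrr::map_chr(pp, function(idx) {
    paste(sort(labels[idx]), collapse = "|")
  })
  heights <- total - depth[node_ids]
  out <- setNames(as.list(heights), keys)
  attr(out, "node_ids") <- node_ids
  out
}

#' Log clade-credibility score of each tree in a sample
#'
#' @inheritParams mcc_tree
#' @return Numeric vector of per-tree scores (sum of log clade frequencies).
#' @export
mcc_scores <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  n_trees <- length(trees)
  clades <- purrr::map(trees, tree_clades)
  counts <- table(unlist(purrr::map(clades, names)))
  purrr::map_dbl(clades, function(cl) {
    sum(log(as.numeric(counts[names(cl)]) / n_trees))
  })
}
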