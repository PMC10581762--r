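#' Simulation-based phylogenetic ANOVA
#'
#' Tests a whole grouping factor on a continuous trait while accounting for
#' phylogeny. The observed statistic is the ordinary one-way ANOVA F on the
#' raw tip values. Its null distribution is generated by simulating the
#' trait under Brownian motion on the tree (rate and grand mean estimated
#' from the data by ML) and recomputing F with the same group labels; the
#' p-value is `(count of simulated F >= observed + 1) / (n_sims + 1)`.
#'
#' The F statistic itself does not depend on the tree; the tree enters only
#' through the null distribution, which is what makes the test phylogenetic.
#'
#' @param data Species-keyed data frame.
#' @param response Name of the trait column.
#' @param group Name of the grouping column (>= 2 levels).
#' @param tree An `ape::phylo` tree.
#' @param n_sims Number of Brownian simulations (default 1000).
#' @param seed Seed for the simulations (mandatory, for reproducibility).
#' @param species_col Name of the species identifier column.
#' @return An object of class `phylo_anova`: `F`, `df_between`, `df_within`,
#'   `p_sim`, `n_sims`, `seed`, group sizes, and the estimated BM rate.
#' @export
phylo_anova <- function(data, response, group, tree, n_sims = 1000, seed,
                        species_col = "species") {
  if (missing(seed)) abort("`seed` is mandatory for phylo_anova().")
  al <- align_tree_data(data, tree, species_col)
  y <- al$data[[response]]
  g <- factor(al$data[[group]])
  if (nlevels(g) < 2) abort("`group` needs at least 2 levels.")
  n <- length(y)
  k <- nlevels(g)
  Fobs <- anova_F(matrix(y, ncol = 1), g)
  if (!is.finite(Fobs)) {
    warn("zero within-group variance: F is infinite.")
  }
  # BM rate and grand mean by ML on the tree
  C <- al$C
  one <- rep(1, n)
  Ci_y <- solve(C, y)
  Ci_1 <- solve(C, one)
  mu <- sum(one * Ci_y) / sum(one * Ci_1)
  r <- y - mu
  sigma2 <- drop(crossprod(r, solve(C, r))) / n
  if (sigma2 <= 1e-300) {
    warn("trait is constant on the tree: simulation null is degenerate.")
    p_sim <- 1
  } else {
    set.seed(as.integer(seed))
    Ysim <- rmvn_chol(n_sims, rep(mu, n), sigma2 * C)
    Fsim <- anova_F(Ysim, g)
    p_sim <- (sum(Fsim >= Fobs) + 1) / (n_sims + 1)
  }
  structure(
    list(F = Fobs, df_between = k - 1, df_within = n - k, p_sim = p_sim,
         n_sims = n_sims, seed = seed, sigma2 = sigma2,
         group_sizes = table(g)),
    class = "phylo_anova"
  )
}

# One-way ANOVA F for each column of Y (n x m), shared group labels.
anova_F <- function(Y, g) {
  n <- nrow(Y)
  k <- nlevels(g)
  counts <- tabulate(g, nbins = k)
  # group means: k x m
  M <- rowsum(Y, g) / counts
  grand <- colMeans(Y)
  ssb <- colSums(counts * sweep(M, 2, grand)^2)
  sst <- colSums(sweep(Y, 2, grand)^2)
  ssw <- sst - ssb
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  f[ssb <= 0] <- 0 # no between-group variation: F is zero by convention
  drop(f)
}

#' @export
print.phylo_anova <- function(x, ...) {
  cat(sprintf(
    "Phylogenetic ANOVA (BM simulation null)\nF(%d, %d) = %.3f, p_sim = %.4g (%d simulations, seed %s)\n",
    x$df_between, x$df_within, x$F, x$p_sim, x$n_sims, format(x$seed)
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.phylo_anova <- function(x, ...) {
  tibble::tibble(
    statistic = x$F, df = x$df_between, df.residual = x$df_within,
    p.value = x$p_sim, n_sims = x$n_sims
  )
}

#' @exportS3Method generics::glance
glance.phylo_anova <- function(x, ...) tidy(x)
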