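test_that("Newick round-trips preserve topology and branch lengths", {
  tr <- read_newick(text = "((A:1,B:1):1,C:2);")
  expect_s3_class(tr, "phylo")
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  C <- phylo_vcv(tr)
  expect_equal(C["A", "B"], 1)
  expect_equal(C["A", "C"], 0)
  expect_equal(diag(C), c(A = 2, B = 2, C = 2))

  for (seed in 1:5) {
    t1 <- random_coal_tree(8, seed)
    t2 <- read_newick(text = write_newick(t1))
    expect_same_topology(t1, t2)
    expect_equal(sort(phylo_vcv(t1)[t2$tip.label, t2$tip.label]),
                 sort(phylo_vcv(t2)), tolerance = 1e-9, ignore_attr = TRUE)
  }

  expect_error(suppressWarnings(read_newick(text = "(A:1")))
  expect_error(read_newick(text = "((A:1,A:1):1,C:2);"), "duplicate")
})

test_that("lambda transform scales only the off-diagonal", {
  C <- phylo_vcv(random_coal_tree(6, 2))
  expect_identical(lambda_transform(C, 1), C)
  expect_equal(lambda_transform(C, 0), diag(diag(C)), ignore_attr = TRUE)
  half <- lambda_transform(C, 0.5)
  off <- row(C) != col(C)
  expect_equal(half[off], C[off] / 2)
  expect_equal(diag(half), diag(C))
  expect_error(lambda_transform(C, 1.2), "\\[0, 1\\]")

  # PSD across the lambda range on ultrametric trees
  for (lam in seq(0, 1, 0.25)) {
    ev <- eigen(lambda_transform(C, lam), symmetric = TRUE,
                only.values = TRUE)$values
    expect_true(all(ev > -1e-8))
  }
})

test_that("PGLS reduces to ordinary least squares without phylogenetic structure", {
  set.seed(31)
  tr <- random_coal_tree(20, 31)
  dat <- tibble::tibble(
    species = tr$tip.label,
    x = rnorm(20),
    y = 1 + 2 * rnorm(20)
  )
  dat$y <- 1 + 0.5 * dat$x + rnorm(20)

  # lambda fixed at 0: identical to OLS
  fit0 <- pgls_fit(dat, y ~ x, tr, lambda = 0)
  ols <- lm(y ~ x, dat)
  expect_equal(unname(fit0$coefficients$estimate), unname(coef(ols)),
               tolerance = 1e-8)
  expect_equal(unname(fit0$coefficients$std.error),
               unname(summary(ols)$coefficients[, 2]), tolerance = 1e-8)
  expect_equal(unname(fit0$coefficients$p.value),
               unname(summary(ols)$coefficients[, 4]), tolerance = 1e-8)

  # star tree: GLS equals OLS for any lambda
  star <- ape::stree(20, "star")
  star$tip.label <- dat$species
  star$edge.length <- rep(1, 20)
  fit_star <- pgls_fit(dat, y ~ x, star, lambda = 0.7)
  expect_equal(unname(fit_star$coefficients$estimate), unname(coef(ols)),
               tolerance = 1e-8)
})

test_that("ML lambda matches independent implementations", {
  set.seed(77)
  tr <- random_coal_tree(40, 77)
  y <- drop(simulate_bm(tr, 1, sd = 1, lambda = 0.7, mean = 5))
  names(y) <- tr$tip.label

  # intercept-only ML lambda against phytools
  skip_if_not_installed("phytools")
  ps <- phytools::phylosig(tr, y, method = "lambda")
  mine <- phylo_signal_lambda(y, tree = tr)
  expect_equal(mine$lambda, ps$lambda, tolerance = 1e-4)
  expect_equal(mine$logLik, ps$logL, tolerance = 1e-6)

  # regression at fixed lambda against nlme::gls (lambda held at our ML
  # estimate; the log-likelihood is invariant to the correlation scaling)
  skip_if_not_installed("nlme")
  x <- rnorm(40)
  dat <- tibble::tibble(species = tr$tip.label, y = unname(y) + 0.3 * x,
                        x = x)
  fit <- pgls_fit(dat, y ~ x, tr)
  df <- as.data.frame(dat)
  rownames(df) <- df$species
  g <- nlme::gls(y ~ x, data = df, method = "ML",
                 correlation = ape::corPagel(fit$lambda, tr, form = ~species,
                                             fixed = TRUE))
  expect_equal(unname(fit$coefficients$estimate), unname(coef(g)),
               tolerance = 1e-6)
  expect_equal(unname(fit$coefficients$std.error),
               unname(summary(g)$tTable[, 2]), tolerance = 1e-6)
  expect_equal(fit$logLik, as.numeric(stats::logLik(g)), tolerance = 1e-6)
})

test_that("the profile-likelihood optimum dominates a lambda grid", {
  set.seed(13)
  tr <- random_coal_tree(25, 13)
  dat <- tibble::tibble(species = tr$tip.label,
                        y = drop(simulate_bm(tr, 1, sd = 2, lambda = 0.6)))
  fit <- pgls_fit(dat, y ~ 1, tr)
  grid_ll <- vapply(seq(0, 1, length.out = 101), function(l) {
    pgls_fit(dat, y ~ 1, tr, lambda = l)$logLik
  }, numeric(1))
  expect_gte(fit$logLik, max(grid_ll) - 1e-6)
  expect_equal(fit$AIC, -2 * fit$logLik + 2 * 3)
})

test_that("phylogenetic signal recovery distinguishes white noise from Brownian motion", {
  tr <- random_coal_tree(100, 991)
  n_rep <- 50
  set.seed(992)
  lam_noise <- vapply(seq_len(n_rep), function(i) {
    y <- setNames(rnorm(100), tr$tip.label)
    phylo_signal_lambda(y, tree = tr)$lambda
  }, numeric(1))
  expect_gte(mean(lam_noise < 0.1), 0.9)

  set.seed(993)
  lam_bm <- vapply(seq_len(n_rep), function(i) {
    y <- drop(simulate_bm(tr, 1, sd = 1, lambda = 1))
    phylo_signal_lambda(y, tree = tr)$lambda
  }, numeric(1))
  expect_gte(mean(lam_bm > 0.8), 0.9)

  expect_warning(
    out <- phylo_signal_lambda(
      tibble::tibble(species = tr$tip.label, y = 1), "y", tr),
    "constant"
  )
  expect_true(is.na(out$lambda))
})

test_that("stepwise selection finds strong effects and resists pure noise", {
  tr <- random_coal_tree(23, 55)
  set.seed(55)
  dat <- tibble::tibble(
    species = tr$tip.label,
    x1 = rnorm(23), x2 = rnorm(23), x3 = rnorm(23),
    y = 10 * rnorm(23)
  )
  dat$y <- 3 + 8 * dat$x1 + rnorm(23)
  st <- phylostep(dat, "y", c("x1", "x2", "x3"), tr)
  expect_true("x1" %in% st$selected)
  # AIC decreases weakly along every accepted move
  expect_true(all(diff(st$trace$AIC) <= 0))

  # pure-noise candidates: intercept-only wins most of the time
  set.seed(56)
  keeps <- vapply(1:30, function(i) {
    d <- tibble::tibble(species = tr$tip.label, a = rnorm(23),
                        b = rnorm(23), y = rnorm(23))
    length(phylostep(d, "y", c("a", "b"), tr)$selected) == 0
  }, logical(1))
  expect_gt(mean(keeps), 0.5)
})

test_that("observed phylogenetic-ANOVA F matches textbook ANOVA and ignores the tree", {
  tr <- random_coal_tree(6, 3)
  dat <- tibble::tibble(species = tr$tip.label,
                        y = c(1, 2, 3, 4, 5, 6),
                        g = rep(c("a", "b"), each = 3))
  pa <- phylo_anova(dat, "y", "g", tr, n_sims = 99, seed = 4)
  expect_equal(pa$F, 13.5)
  expect_equal(pa$df_between, 1)
  expect_equal(pa$df_within, 4)
  expect_equal(pa$F, anova_F_oracle(dat$y, factor(dat$g)))

  # a different tree changes only the simulation p-value, never F
  tr2 <- random_coal_tree(6, 99)
  pa2 <- phylo_anova(dat, "y", "g", tr2, n_sims = 99, seed = 4)
  expect_equal(pa2$F, pa$F)

  # constant response: identical group means give F = 0
  datc <- tibble::tibble(species = tr$tip.label, y = rep(2, 6),
                         g = rep(c("a", "b"), 3))
  expect_warning(pac <- phylo_anova(datc, "y", "g", tr, n_sims = 99, seed = 1),
                 "constant")
  expect_equal(pac$F, 0)

  # p-value resolution is 1/(n_sims + 1) and the same seed reproduces it
  pa3 <- phylo_anova(dat, "y", "g", tr, n_sims = 99, seed = 4)
  expect_identical(pa3$p_sim, pa$p_sim)
  expect_equal((pa$p_sim * 100) %% 1, 0, tolerance = 1e-12)
})

test_that("Brownian ancestral states satisfy exact identities and match phytools", {
  # constant tips: every ancestor is that constant
  tr <- random_coal_tree(10, 8)
  a_const <- asr_bm(tr, setNames(rep(3.5, 10), tr$tip.label))
  expect_equal(unname(a_const), rep(3.5, tr$Nnode))

  # two tips, equal branches: root at the midpoint
  two <- read_newick(text = "(A:1,B:1);")
  expect_equal(unname(asr_bm(two, c(A = 0, B = 10))), 5)

  # root equals the intercept-only GLS mean at lambda = 1
  tr2 <- random_coal_tree(20, 9)
  set.seed(10)
  y <- setNames(rnorm(20, 10, 3), tr2$tip.label)
  a <- asr_bm(tr2, y)
  fit <- pgls_fit(tibble::tibble(species = names(y), y = unname(y)),
                  y ~ 1, tr2, lambda = 1)
  expect_equal(unname(a["21"]), unname(fit$coefficients$estimate[1]),
               tolerance = 1e-8)

  skip_if_not_installed("phytools")
  fa <- phytools::fastAnc(tr2, y)
  expect_equal(unname(a), unname(as.numeric(fa)), tolerance = 1e-6)
})

test_that("MCC tree selection agrees with majority intuition and phangorn", {
  # 9 identical topologies out of 10 win
  base <- random_coal_tree(6, 20)
  other <- random_coal_tree(6, 21)
  sample10 <- c(rep(list(base), 9), list(other))
  m <- mcc_tree(sample10)
  expect_same_topology(m, base)

  # single input returns that tree
  expect_same_topology(mcc_tree(list(base)), base)

  # per-tree scores match an independently written oracle
  set.seed(22)
  samp <- lapply(1:10, function(i) random_coal_tree(5, 200 + i %% 4))
  expect_equal(mcc_scores(samp), mcc_scores_oracle(samp), tolerance = 1e-10)

  skip_if_not_installed("phangorn")
  ph <- phangorn::maxCladeCred(do.call(c, samp), tree = FALSE, rooted = TRUE)
  expect_equal(mcc_scores(samp), unname(ph), tolerance = 1e-8)

  expect_error(mcc_tree(list()), "empty")
})

test_that("MCC node heights average clade heights across the sample", {
  t1 <- read_newick(text = "((A:1,B:1):1,C:2);")
  t2 <- read_newick(text = "((A:2,B:2):2,C:4);")
  m <- mcc_tree(list(t1, t2))
  H <- phylo_vcv(m)
  # AB clade height: mean(1, 2); root height: mean(2, 4)
  expect_equal(unname(diag(H)[1]), 3)
  expect_equal(unname(H["A", "B"]), 3 - 1.5)
})
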