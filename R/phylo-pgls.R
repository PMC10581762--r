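#' Phylogenetic generalized least squares with Pagel's lambda
#'
#' Fits the regression `formula` by generalized least squares with error
#' covariance `sigma2 * C_lambda`, where `C` is the Brownian-motion
#' covariance of the tree and `C_lambda` its Pagel's-lambda transform.
#' `lambda` may be fixed or estimated by maximum likelihood: the profile
#' log-likelihood is scanned on a 101-point grid over `[0, 1]` (to avoid
#' local optima) and refined with a bounded one-dimensional optimizer around
#' the best grid point. The likelihood is full ML under a Gaussian model;
#' `sigma2` is profiled out analytically.
#'
#' The AIC counts the regression coefficients plus `sigma2` plus `lambda` as
#' parameters. Coefficient standard errors use the unbiased residual
#' variance `RSS_gls / (n - p)` and t statistics are referred to a
#' t distribution with `n - p` degrees of freedom.
#'
#' @param data A data frame with one row per species, containing a `species`
#'   column matching the tree's tip labels and every variable in `formula`.
#' @param formula A model formula, e.g. `max_overlap ~ diet + habitat`.
#' @param tree An `ape::phylo` tree covering all species in `data` (extra
#'   tips are pruned).
#' @param lambda `"ML"` (default) or a fixed value in `[0, 1]`.
#' @param species_col Name of the species identifier column.
#' @return An object of class `pgls` with coefficient table, `lambda`,
#'   `sigma2` (ML), `logLik`, `AIC`, the lambda profile grid, and the
#'   aligned model ingredients.
#' @export
pgls_fit <- function(data, formula, tree, lambda = "ML",
                     species_col = "species") {
  al <- align_tree_data(data, tree, species_col)
  mf <- droplevels(stats::model.frame(formula, al$data))
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  n <- length(y)
  p <- ncol(X)
  if (n <= p + 1) abort("too few species for the requested model.")
  # column-normalized rank check, insensitive to covariate scale
  Xn <- sweep(X, 2, pmax(sqrt(colSums(X^2)), 1e-300), `/`)
  if (qr(Xn)$rank < p) abort("singular design: collinear predictors.")
  C <- al$C

  profile <- NULL
  if (identical(lambda, "ML")) {
    opt <- profile_lambda(y, X, C)
    lam <- opt$lambda
    profile <- opt$profile
  } else {
    if (!is.numeric(lambda) || lambda < 0 || lambda > 1) {
      abort('`lambda` must be "ML" or a number in [0, 1].')
    }
    lam <- lambda
  }
  fit <- gls_core(y, X, lambda_transform(C, lam))
  se <- sqrt(diag(fit$cov_beta))
  tval <- fit$beta / se
  pval <- 2 * pt(-abs(tval), n - p)
  k_par <- p + 2 # betas + sigma2 + lambda
  structure(
    list(
      response = deparse(formula[[2]]),
      formula = formula,
      coefficients = tibble::tibble(
        term = colnames(X), estimate = unname(fit$beta),
        std.error = unname(se), statistic = unname(tval),
        p.value = unname(pval)
      ),
      lambda = lam,
      lambda_estimated = identical(lambda, "ML"),
      lambda_profile = profile,
      sigma2 = fit$sigma2_ml,
      logLik = fit$logLik,
      AIC = -2 * fit$logLik + 2 * k_par,
      n = n, df.residual = n - p, n_param = k_par,
      species = al$data[[species_col]],
      y = y, X = X, C = C
    ),
    class = "pgls"
  )
}

# Align a species-keyed data frame with a tree: prune extra tips, order the
# covariance matrix to the data rows.
align_tree_data <- function(data, tree, species_col = "species") {
  data <- tibble::as_tibble(data)
  if (!species_col %in% names(data)) {
    abort(sprintf("`data` needs a `%s` column.", species_col))
  }
  sp <- as.character(data[[species_col]])
  if (anyDuplicated(sp)) abort("one row per species required.")
  missing_sp <- setdiff(sp, tree$tip.label)
  if (length(missing_sp)) {
    abort(paste0("species absent from the tree: ",
                 paste(missing_sp, collapse = ", ")))
  }
  extra <- setdiff(tree$tip.label, sp)
  if (length(extra)) tree <- ape::keep.tip(tree, sp)
  C <- phylo_vcv(tree)[sp, sp]
  list(data = data, tree = tree, C = C)
}

# GLS estimates and Gaussian ML log-likelihood for fixed V (unit-rate
# covariance); sigma2 is profiled analytically.
gls_core <- function(y, X, V) {
  n <- length(y)
  p <- ncol(X)
  L <- chol(V)
  logdetV <- 2 * sum(log(diag(L)))
  # whiten: solve L' z = v  =>  z = (L')^{-1} v, with V = L'L
  wy <- backsolve(L, y, transpose = TRUE)
  wX <- backsolve(L, X, transpose = TRUE)
  XtX <- crossprod(wX)
  beta <- drop(solve(XtX, crossprod(wX, wy)))
  r <- wy - wX %*% beta
  rss <- drop(crossprod(r))
  sigma2_ml <- rss / n
  logLik <- -0.5 * (n * log(2 * pi * sigma2_ml) + logdetV + n)
  sigma2_err <- rss / (n - p)
  list(beta = setNames(beta, colnames(X)), sigma2_ml = sigma2_ml,
       logLik = logLik, cov_beta = sigma2_err * solve(XtX),
       rss = rss, logdetV = logdetV)
}

# Profile log-likelihood over lambda: 101-point grid pre-scan, then bounded
# refinement around the best grid point; boundary values are kept eligible.
profile_lambda <- function(y, X, C) {
  grid <- seq(0, 1, length.out = 101)
  ll <- vapply(grid, function(l) gls_core(y, X, lambda_transform(C, l))$logLik,
               numeric(1))
  i <- which.max(ll)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- optimize(function(l) gls_core(y, X, lambda_transform(C, l))$logLik,
                  interval = c(lo, hi), maximum = TRUE, tol = 1e-8)
  cand <- c(opt$maximum, grid[i])
  cand_ll <- c(opt$objective, ll[i])
  best <- which.max(cand_ll)
  list(lambda = cand[best], logLik = cand_ll[best],
       profile = tibble::tibble(lambda = grid, logLik = ll))
}

#' Phylogenetic signal of a trait (Pagel's lambda)
#'
#' Maximum-likelihood lambda for an intercept-only model: the strength with
#' which trait covariances follow the Brownian expectation on the tree.
#' Estimates at the boundary of `[0, 1]` are reported as such.
#'
#' @param data Data frame with `species` and the trait column, or a named
#'   numeric vector keyed by species.
#' @param trait Name of the trait column (ignored for a named vector).
#' @param tree An `ape::phylo` tree.
#' @param species_col Name of the species identifier column.
#' @return A one-row tibble: `trait`, `lambda`, `logLik`, `at_boundary`.
#' @export
phylo_signal_lambda <- function(data, trait = NULL, tree,
                                species_col = "species") {
  if (is.numeric(data) && !is.null(names(data))) {
    data <- tibble::tibble(species = names(data), .y = unname(data))
    trait <- ".y"
    species_col <- "species"
  }
  if (is.null(trait)) abort("`trait` must name a column of `data`.")
  y <- data[[trait]]
  if (length(unique(y)) < 2) {
    warn("trait is constant: phylogenetic signal undefined.")
    return(tibble::tibble(trait = trait, lambda = NA_real_,
                          logLik = NA_real_, at_boundary = NA))
  }
  f <- stats::as.formula(paste0("`", trait, "` ~ 1"))
  fit <- pgls_fit(data, f, tree, lambda = "ML", species_col = species_col)
  tibble::tibble(
    trait = trait, lambda = fit$lambda, logLik = fit$logLik,
    at_boundary = fit$lambda < 1e-4 || fit$lambda > 1 - 1e-4
  )
}

#' @export
print.pgls <- function(x, ...) {
  cat(sprintf("Phylogenetic GLS: %s\n", deparse(x$formula)))
  cat(sprintf("n = %d species, lambda = %.4g%s, sigma2 = %.4g\n",
              x$n, x$lambda,
              if (x$lambda_estimated) " (ML)" else " (fixed)", x$sigma2))
  cat(sprintf("logLik = %.3f, AIC = %.3f\n", x$logLik, x$AIC))
  print(as.data.frame(x$coefficients), digits = 4)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pgls <- function(x, ...) {
  x$coefficients
}

#' @exportS3Method generics::glance
glance.pgls <- function(x, ...) {
  tibble::tibble(
    lambda = x$lambda, sigma2 = x$sigma2, logLik = x$logLik, AIC = x$AIC,
    nobs = x$n, df.residual = x$df.residual
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.pgls <- function(object, ...) {
  if (is.null(object$lambda_profile)) {
    abort("no lambda profile stored (lambda was fixed).")
  }
  ggplot2::ggplot(object$lambda_profile,
                  ggplot2::aes(x = .data$lambda, y = .data$logLik)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$lambda, linetype = 2) +
    ggplot2::labs(x = "Pagel's lambda", y = "profile log-likelihood") +
    ggplot2::theme_minimal()
}
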