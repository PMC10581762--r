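#' Principal component analysis of elliptic Fourier coefficients
#'
#' Builds the coefficient matrix (one row per outline), drops columns with
#' essentially zero variance (e.g. entries fixed by normalization), centres
#' the remainder and performs an eigendecomposition of its covariance. The
#' resulting scores are the shape space in which outlines are compared.
#'
#' @param coeff_list A named list of `eft_coefficients` (one per outline,
#'   equal harmonic counts and normalization), or a numeric matrix /
#'   data frame whose rows are flattened coefficient vectors.
#' @return An object of class `shape_pca`: `scores` (tibble with `outline`
#'   id and `PC1..PCk`), `eigenvalues`, `proportion` of variance, `center`,
#'   `rotation` (loadings), `dropped` (constant columns and their values)
#'   and `n_harmonics`.
#' @export
pca_shapes <- function(coeff_list) {
  if (is.list(coeff_list) && !is.data.frame(coeff_list) &&
      all(purrr::map_lgl(coeff_list, inherits, "eft_coefficients"))) {
    Ns <- unique(purrr::map_int(coeff_list, function(z) z$n_harmonics))
    if (length(Ns) != 1) abort("all outlines must share one harmonic count.")
    norms <- unique(purrr::map_lgl(coeff_list, function(z) z$normalized))
    if (length(norms) != 1) abort("mixed normalization across outlines.")
    X <- do.call(rbind, purrr::map(coeff_list, coef_vector))
    if (is.null(rownames(X))) rownames(X) <- names(coeff_list)
    n_harm <- Ns
  } else {
    X <- as.matrix(coeff_list)
    n_harm <- ncol(X) %/% 4L
  }
  if (nrow(X) < 3) abort("need at least 3 outlines for a shape space.")
  if (is.null(rownames(X))) rownames(X) <- paste0("outline_", seq_len(nrow(X)))
  sds <- apply(X, 2, sd)
  tol <- 1e-10 * max(sds, 1e-300)
  keep <- sds > max(tol, 1e-12)
  if (!any(keep)) {
    abort("all coefficient columns are constant: shapes are identical.",
          class = "owlfield_degenerate_pca")
  }
  if (any(!keep)) {
    warn(sprintf("dropping %d zero-variance coefficient column(s).",
                 sum(!keep)))
  }
  dropped <- colMeans(X[, !keep, drop = FALSE])
  pc <- prcomp(X[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
  eig <- pc$sdev^2
  scores <- tibble::as_tibble(pc$x)
  scores <- dplyr::bind_cols(tibble::tibble(outline = rownames(X)), scores)
  structure(
    list(scores = scores, eigenvalues = eig, proportion = eig / sum(eig),
         center = pc$center, rotation = pc$rotation, dropped = dropped,
         n_harmonics = n_harm),
    class = "shape_pca"
  )
}

#' @export
print.shape_pca <- function(x, ...) {
  k <- min(4, length(x$proportion))
  cat(sprintf("Shape space over %d outlines, %d harmonics\n",
              nrow(x$scores), x$n_harmonics))
  cat("Variance proportions:",
      paste0(sprintf("PC%d %.1f%%", seq_len(k), 100 * x$proportion[1:k]),
             collapse = ", "), "\n")
  invisible(x)
}

#' Reconstruct the outline at a position in shape space
#'
#' Takes the mean coefficient vector, displaces it along one principal
#' component by the requested score, restores any constant columns dropped
#' before the PCA, and inverts the Fourier series. Used to visualise what a
#' component encodes (e.g. the mean shape at score 0, or shapes at +/- 2
#' standard deviations).
#'
#' @param space A `shape_pca` object.
#' @param pc Component index.
#' @param score Score along that component.
#' @param k Points in the reconstructed outline.
#' @return A closed outline tibble.
#' @export
shape_at_pc <- function(space, pc = 1, score = 0, k = 200) {
  stopifnot(inherits(space, "shape_pca"))
  if (pc > ncol(space$rotation)) abort("component not computed.")
  kept <- space$center + score * space$rotation[, pc]
  full <- c(kept, space$dropped)
  coeffs_from_vector(full, space$n_harmonics) |> eft_inverse(k)
}

# Rebuild an eft_coefficients object from a flattened (possibly reordered)
# named coefficient vector.
coeffs_from_vector <- function(v, n_harmonics) {
  N <- n_harmonics
  grab <- function(letter) {
    unname(v[paste0(letter, 1:N)])
  }
  structure(
    list(a = grab("a"), b = grab("b"), c = grab("c"), d = grab("d"),
         a0 = 0, c0 = 0, n_harmonics = N, scale = 1,
         normalized = TRUE, rotated = FALSE),
    class = "eft_coefficients"
  )
}

#' Project a coefficient vector onto an existing shape space
#'
#' @param space A `shape_pca` object.
#' @param coeffs An `eft_coefficients` object or flattened coefficient
#'   vector.
#' @return A numeric vector of scores on the space's components.
#' @export
project_shape <- function(space, coeffs) {
  stopifnot(inherits(space, "shape_pca"))
  v <- if (inherits(coeffs, "eft_coefficients")) coef_vector(coeffs) else coeffs
  kept <- v[names(space$center)]
  drop((kept - space$center) %*% space$rotation)
}

#' @exportS3Method generics::tidy
tidy.shape_pca <- function(x, ...) {
  tibble::tibble(
    component = paste0("PC", seq_along(x$eigenvalues)),
    eigenvalue = x$eigenvalues,
    proportion = x$proportion,
    cumulative = cumsum(x$proportion)
  )
}

#' @exportS3Method generics::glance
glance.shape_pca <- function(x, ...) {
  tibble::tibble(
    n_outlines = nrow(x$scores),
    n_components = length(x$eigenvalues),
    pc1_proportion = x$proportion[1],
    pc2_proportion = if (length(x$proportion) > 1) x$proportion[2] else NA_real_
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.shape_pca <- function(object, colour = NULL, ...) {
  df <- object$scores
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$proportion[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$proportion[2])
    ) +
    ggplot2::theme_minimal()
  p
}
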