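#' Resample a closed outline to equally spaced points
#'
#' Standardizes an outline before elliptic Fourier analysis: the traversal is
#' restarted at the topmost vertex (ties broken toward the smallest x) and
#' `k` points are placed at equal arc-length intervals along the polygon,
#' preserving orientation.
#'
#' @param outline Closed outline tibble (`x`, `y`, first vertex repeated
#'   last) or an open vertex list, which is closed implicitly.
#' @param k Number of sample points (>= 8).
#' @return A closed outline tibble with `k + 1` rows.
#' @export
resample_outline <- function(outline, k) {
  if (k < 8) abort("`k` must be at least 8.")
  v <- outline_vertices(outline)
  # start at the topmost vertex, ties toward smallest x
  top <- which(v$y == max(v$y))
  start <- top[which.min(v$x[top])]
  idx <- c(start:nrow(v), seq_len(start - 1))
  x <- v$x[idx]
  y <- v$y[idx]
  x <- c(x, x[1])
  y <- c(y, y[1])
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  per <- sum(seg)
  if (per <= 0) abort("degenerate outline: zero perimeter.")
  s <- c(0, cumsum(seg))
  target <- seq(0, per, length.out = k + 1)[-(k + 1)]
  xi <- stats::approx(s, x, xout = target, ties = "ordered")$y
  yi <- stats::approx(s, y, xout = target, ties = "ordered")$y
  tibble::tibble(x = c(xi, xi[1]), y = c(yi, yi[1]))
}

# Distinct vertices of a closed outline, duplicate closing vertex removed.
outline_vertices <- function(outline) {
  o <- tibble::as_tibble(outline)
  if (!all(c("x", "y") %in% names(o))) abort("an outline needs `x` and `y`.")
  n <- nrow(o)
  if (n >= 2 && o$x[1] == o$x[n] && o$y[1] == o$y[n]) o <- o[-n, ]
  if (nrow(o) < 3) abort("an outline needs at least 3 distinct vertices.")
  o
}

#' Elliptic Fourier transform of a closed outline
#'
#' Decomposes a closed outline, traversed as a piecewise-linear curve
#' parameterized by arc length, into two truncated Fourier series, one for
#' each coordinate: harmonic `n` contributes
#' `a_n cos(2 pi n t / T) + b_n sin(2 pi n t / T)` to x and
#' `c_n cos(...) + d_n sin(...)` to y. Coefficients are the exact integrals
#' for the piecewise-linear curve (Kuhl-Giardina formulation), so no prior
#' resampling is strictly required, though [resample_outline()] standardizes
#' the start point.
#'
#' By default the coefficients are normalized for position (translation terms
#' removed) and size (all coefficients divided by the semi-major axis of the
#' first-harmonic ellipse). Rotation alignment is off by default: the
#' elevation axis of a visual field is biologically meaningful and the
#' Cartesian projection preserves it. Set `rotate = TRUE` for the full
#' first-ellipse alignment used when shapes must also be rotation-invariant.
#'
#' @param outline Closed outline tibble (`x`, `y`).
#' @param n_harmonics Number of harmonics to compute.
#' @param normalize Remove translation and scale (default `TRUE`).
#' @param rotate Also align the first-harmonic ellipse with the x axis
#'   (default `FALSE`).
#' @return An object of class `eft_coefficients`: harmonic coefficient
#'   vectors `a`, `b`, `c`, `d`, translation terms `a0`, `c0`, the `scale`
#'   divided out, and normalization metadata.
#' @export
eft_forward <- function(outline, n_harmonics, normalize = TRUE,
                        rotate = FALSE) {
  v <- outline_vertices(outline)
  o <- tibble::as_tibble(outline)
  if (!(o$x[1] == o$x[nrow(o)] && o$y[1] == o$y[nrow(o)])) {
    abort("outline must be closed (first vertex repeated last).")
  }
  if (n_harmonics < 1) abort("`n_harmonics` must be >= 1.")
  x <- c(v$x, v$x[1])
  y <- c(v$y, v$y[1])
  dx <- diff(x)
  dy <- diff(y)
  dt <- sqrt(dx^2 + dy^2)
  keep <- dt > 0
  dx <- dx[keep]; dy <- dy[keep]; dt <- dt[keep]
  Tt <- sum(dt)
  t1 <- cumsum(dt)
  t0 <- c(0, t1[-length(t1)])
  N <- n_harmonics
  n <- seq_len(N)
  # outer products: rows segments, cols harmonics
  phi1 <- outer(t1, 2 * pi * n / Tt)
  phi0 <- outer(t0, 2 * pi * n / Tt)
  dcos <- cos(phi1) - cos(phi0)
  dsin <- sin(phi1) - sin(phi0)
  const <- Tt / (2 * pi^2 * n^2)
  a <- const * colSums((dx / dt) * dcos)
  b <- const * colSums((dx / dt) * dsin)
  cc <- const * colSums((dy / dt) * dcos)
  d <- const * colSums((dy / dt) * dsin)
  # translation: mean of the piecewise-linear curve over arc length
  xm <- (x[-length(x)] + x[-1])[keep] / 2
  ym <- (y[-length(y)] + y[-1])[keep] / 2
  a0 <- sum(xm * dt) / Tt
  c0 <- sum(ym * dt) / Tt
  scale <- 1
  if (rotate) {
    rot <- align_first_ellipse(a, b, cc, d)
    a <- rot$a; b <- rot$b; cc <- rot$c; d <- rot$d
  }
  if (normalize) {
    scale <- first_ellipse_scale(a[1], b[1], cc[1], d[1])
    if (scale <= 0) abort("degenerate first harmonic: cannot normalize scale.")
    a <- a / scale; b <- b / scale; cc <- cc / scale; d <- d / scale
  }
  structure(
    list(a = a, b = b, c = cc, d = d, a0 = a0, c0 = c0,
         n_harmonics = N, scale = scale,
         normalized = normalize, rotated = rotate),
    class = "eft_coefficients"
  )
}

# Semi-major axis of the first-harmonic ellipse: the largest singular value
# of the 2x2 linear map [a1 b1; c1 d1].
first_ellipse_scale <- function(a1, b1, c1, d1) {
  M <- matrix(c(a1, c1, b1, d1), 2, 2)
  svd(M)$d[1]
}

# Kuhl-Giardina first-ellipse alignment: a parameter phase shift theta puts
# the semi-major axis at t = 0, then a spatial rotation psi lays it on the
# x axis. Applied to every harmonic.
align_first_ellipse <- function(a, b, cc, d) {
  theta <- 0.5 * atan2(2 * (a[1] * b[1] + cc[1] * d[1]),
                       a[1]^2 + cc[1]^2 - b[1]^2 - d[1]^2)
  n <- seq_along(a)
  ct <- cos(n * theta); st <- sin(n * theta)
  a2 <- a * ct + b * st
  b2 <- -a * st + b * ct
  c2 <- cc * ct + d * st
  d2 <- -cc * st + d * ct
  psi <- atan2(c2[1], a2[1])
  cp <- cos(psi); sp <- sin(psi)
  list(a = cp * a2 + sp * c2, b = cp * b2 + sp * d2,
       c = -sp * a2 + cp * c2, d = -sp * b2 + cp * d2)
}

#' Reconstruct an outline from elliptic Fourier coefficients
#'
#' Evaluates the truncated Fourier series at `k` equally spaced parameter
#' values. Normalized coefficients reconstruct the centred, unit-scale
#' shape; unnormalized ones include the translation terms.
#'
#' @param coeffs An `eft_coefficients` object.
#' @param k Number of evaluation points.
#' @param n_harmonics Evaluate only the first harmonics (default: all
#'   available).
#' @return A closed outline tibble.
#' @export
eft_inverse <- function(coeffs, k = 200, n_harmonics = NULL) {
  stopifnot(inherits(coeffs, "eft_coefficients"))
  N <- n_harmonics %||% coeffs$n_harmonics
  if (N > coeffs$n_harmonics) abort("more harmonics requested than stored.")
  t <- seq(0, 1, length.out = k + 1)[-(k + 1)]
  n <- seq_len(N)
  C <- cos(2 * pi * outer(t, n))
  S <- sin(2 * pi * outer(t, n))
  x <- C %*% coeffs$a[n] + S %*% coeffs$b[n]
  y <- C %*% coeffs$c[n] + S %*% coeffs$d[n]
  if (!coeffs$normalized) {
    x <- x + coeffs$a0
    y <- y + coeffs$c0
  }
  tibble::tibble(x = c(x, x[1]), y = c(y, y[1]))
}

#' Harmonic power spectrum and harmonic-count selection
#'
#' The power carried by harmonic `n` is
#' `(a_n^2 + b_n^2 + c_n^2 + d_n^2) / 2`, the mean squared contribution of
#' that harmonic to the outline. The cumulative fraction of total power is
#' the usual criterion for choosing how many harmonics to retain; the
#' smallest count reaching `threshold` is reported.
#'
#' @param coeffs An `eft_coefficients` object computed to a generous number
#'   of harmonics.
#' @param threshold Cumulative power fraction to reach (default 0.99).
#' @return A list with `spectrum` (tibble: `harmonic`, `power`,
#'   `cumulative_fraction`) and `n_selected`.
#' @export
harmonic_power <- function(coeffs, threshold = 0.99) {
  stopifnot(inherits(coeffs, "eft_coefficients"))
  if (threshold <= 0 || threshold > 1) abort("`threshold` must be in (0, 1].")
  p <- (coeffs$a^2 + coeffs$b^2 + coeffs$c^2 + coeffs$d^2) / 2
  cf <- cumsum(p) / sum(p)
  # threshold 1 means "keep everything": do not let rounding drop harmonics
  sel <- if (threshold >= 1) coeffs$n_harmonics else which(cf >= threshold)
  tibble_out <- tibble::tibble(
    harmonic = seq_along(p), power = p, cumulative_fraction = cf
  )
  list(
    spectrum = tibble_out,
    n_selected = if (length(sel)) min(sel) else coeffs$n_harmonics,
    threshold = threshold
  )
}

#' Mean reconstruction error at increasing harmonic counts
#'
#' Euclidean distance between corresponding points of the outline
#' reconstructed with `n` harmonics and the best available reconstruction
#' (all stored harmonics), averaged over points, for `n = 1, ...`. By
#' Parseval's relation this error is non-increasing in `n`; it is the
#' second, distance-based criterion for choosing a harmonic count.
#'
#' @param coeffs An `eft_coefficients` object.
#' @param k Number of evaluation points.
#' @return A tibble with `harmonics` and `mean_distance`.
#' @export
reconstruction_error <- function(coeffs, k = 200) {
  stopifnot(inherits(coeffs, "eft_coefficients"))
  best <- eft_inverse(coeffs, k)
  purrr::map_dfr(seq_len(coeffs$n_harmonics), function(n) {
    rec <- eft_inverse(coeffs, k, n_harmonics = n)
    tibble::tibble(
      harmonics = n,
      mean_distance = mean(sqrt((rec$x - best$x)^2 + (rec$y - best$y)^2))
    )
  })
}

#' @export
print.eft_coefficients <- function(x, ...) {
  cat(sprintf(
    "Elliptic Fourier coefficients: %d harmonics%s%s\n",
    x$n_harmonics,
    if (x$normalized) ", normalized (translation + scale)" else ", raw",
    if (x$rotated) ", first-ellipse aligned" else ""
  ))
  invisible(x)
}

#' Flatten elliptic Fourier coefficients to a named numeric vector
#'
#' Column order is `a1..aN, b1..bN, c1..cN, d1..dN`, the layout expected by
#' [pca_shapes()].
#'
#' @param coeffs An `eft_coefficients` object.
#' @return A named numeric vector of length `4 * n_harmonics`.
#' @export
coef_vector <- function(coeffs) {
  stopifnot(inherits(coeffs, "eft_coefficients"))
  N <- coeffs$n_harmonics
  setNames(
    c(coeffs$a, coeffs$b, coeffs$c, coeffs$d),
    c(paste0("a", 1:N), paste0("b", 1:N), paste0("c", 1:N), paste0("d", 1:N))
  )
}
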