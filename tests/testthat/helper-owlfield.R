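# Fixtures and independent oracles shared across the suite.

# --- outline fixtures -------------------------------------------------------

make_circle <- function(R = 1, m = 256, x0 = 0, y0 = 0) {
  t <- seq(0, 2 * pi, length.out = m + 1)[-(m + 1)]
  tibble::tibble(x = x0 + R * cos(t), y = y0 + R * sin(t)) |> close_outline()
}

make_ellipse <- function(a = 2, b = 1, m = 512) {
  t <- seq(0, 2 * pi, length.out = m + 1)[-(m + 1)]
  tibble::tibble(x = a * cos(t), y = b * sin(t)) |> close_outline()
}

make_square <- function(side = 1) {
  tibble::tibble(
    x = c(0, side, side, 0),
    y = c(0, 0, side, side)
  ) |> close_outline()
}

close_outline <- function(o) dplyr::bind_rows(o, o[1, ])

make_tent_outline <- function(widths = c(0, 15, 40, 55, 35, 10, 0)) {
  e <- seq(-30, by = 10, length.out = length(widths))
  outline_from_profile(make_tent_profile(e, widths))
}

rotate_outline <- function(o, deg) {
  th <- deg * pi / 180
  tibble::tibble(x = cos(th) * o$x - sin(th) * o$y,
                 y = sin(th) * o$x + cos(th) * o$y)
}

# Semi-major axis of the first-harmonic ellipse.
first_scale <- function(cf) {
  svd(matrix(c(cf$a[1], cf$c[1], cf$b[1], cf$d[1]), 2, 2))$d[1]
}

# --- profile fixtures -------------------------------------------------------

# Tent-shaped profile touching zero on the grid.
make_tent_profile <- function(elevations = seq(-30, 30, 10),
                              widths = c(0, 20, 50, 60, 50, 20, 0)) {
  tibble::tibble(
    species = "toy", individual = "toy_i1",
    elevation = elevations,
    left_margin = widths / 2, right_margin = -widths / 2,
    binocular_width = widths,
    interpolated = FALSE, estimated_lower_bound = FALSE
  )
}

# --- oracles ----------------------------------------------------------------

# 2-D ray tracing: direction from the eye to the ophthalmoscope viewing
# point, computed with explicit vector geometry (no shared code path with
# correct_to_infinity beyond base trig).
ray_trace_azimuth <- function(theta_deg, eye, r, s) {
  th <- theta_deg * pi / 180
  view <- c(r * sin(th), r * cos(th))
  eye_pos <- c(if (eye == "right") s / 2 else -s / 2, 0)
  d <- view - eye_pos
  atan2(d[1], d[2]) * 180 / pi
}

# Brute-force Fourier integration of a piecewise-linear closed curve:
# a_n = (2/T) int x(t) cos(2 pi n t / T) dt via a dense trapezoid rule.
eft_quadrature_oracle <- function(outline, n_harmonics, n_grid = 2e5) {
  x <- outline$x
  y <- outline$y
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  Tt <- sum(seg)
  s <- c(0, cumsum(seg))
  tg <- seq(0, Tt, length.out = n_grid + 1)
  xi <- stats::approx(s, x, xout = tg, ties = "ordered")$y
  yi <- stats::approx(s, y, xout = tg, ties = "ordered")$y
  h <- Tt / n_grid
  trap <- function(f) (sum(f) - (f[1] + f[length(f)]) / 2) * h
  res <- lapply(seq_len(n_harmonics), function(n) {
    cn <- cos(2 * pi * n * tg / Tt)
    sn <- sin(2 * pi * n * tg / Tt)
    c(a = 2 / Tt * trap(xi * cn), b = 2 / Tt * trap(xi * sn),
      c = 2 / Tt * trap(yi * cn), d = 2 / Tt * trap(yi * sn))
  })
  do.call(rbind, res)
}

# One-way ANOVA F recomputed through R's linear-model machinery.
anova_F_oracle <- function(y, g) {
  unname(anova(lm(y ~ g))$`F value`[1])
}

# Independent log clade-credibility scores via sorted tip-label keys,
# written without reference to the package implementation.
mcc_scores_oracle <- function(trees) {
  clade_keys <- function(tr) {
    n <- length(tr$tip.label)
    unlist(lapply((n + 1):(n + tr$Nnode), function(node) {
      tips <- ape::extract.clade(tr, node)$tip.label
      paste(sort(tips), collapse = "|")
    }))
  }
  keys <- lapply(trees, clade_keys)
  freq <- table(unlist(keys)) / length(trees)
  vapply(keys, function(k) sum(log(as.numeric(freq[k]))), numeric(1))
}

# Random ultrametric tree with reproducible labels.
random_coal_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rcoal(n)
  tr$tip.label <- sprintf("sp%02d", seq_len(n))
  tr
}

expect_closed <- function(o) {
  expect_equal(unlist(o[1, c("x", "y")]), unlist(o[nrow(o), c("x", "y")]))
}

expect_same_topology <- function(t1, t2) {
  d <- suppressWarnings(ape::dist.topo(t1, t2))
  expect_equal(as.numeric(d), 0)
}
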