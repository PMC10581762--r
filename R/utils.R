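deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

check_finite <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    abort(sprintf("`%s` must be finite and numeric.", name))
  }
  invisible(x)
}

# Draw n x m standard normals and colour them with the Cholesky factor of V,
# so each column is one MVN(mu, V) sample. Uses the current RNG stream.
rmvn_chol <- function(m, mu, V) {
  n <- length(mu)
  L <- chol(V)
  Z <- matrix(rnorm(n * m), n, m)
  sweep(crossprod(L, Z), 1, mu, `+`)
}
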