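# Independent oracle helpers shared across test files. Everything here is
# deliberately naive (explicit inverses, exhaustive loops) so that the fast
# projection-based paths in the package are checked against a different route.

cth <- function(x) Conj(t(x))

rcomplex_mat <- function(n, m) {
  matrix(complex(real = rnorm(n * m), imaginary = rnorm(n * m)), n, m)
}

# Random orthonormal complex basis via SVD of a Gaussian matrix.
runitary_basis <- function(n_t, n_c) {
  svd(rcomplex_mat(n_t, max(n_c, 2L)), nu = n_c)$u[, seq_len(n_c), drop = FALSE]
}

# sigma^2 * diag(F^-1) through an explicit Fisher-matrix inverse.
fisher_crb_oracle <- function(j, sigma = 1) {
  sigma^2 * Re(diag(solve(cth(j) %*% j)))
}

# Explicit normal-equations projector (I - Ji (Ji' Ji)^-1 Ji') ji.
projector_oracle <- function(j, i) {
  ji <- j[, -i, drop = FALSE]
  as.vector(j[, i] - ji %*% solve(cth(ji) %*% ji, cth(ji) %*% j[, i]))
}

# Largest principal angle between equal-rank subspaces, as the spectral norm
# of the residual of one basis projected off the other.
max_principal_angle_sin <- function(u1, u2) {
  resid <- u2 - u1 %*% (cth(u1) %*% u2)
  max(svd(resid, nu = 0, nv = 0)$d)
}

expect_rel_equal <- function(actual, expected, rtol) {
  expect_lt(max(abs(actual - expected)) / max(abs(expected), .Machine$double.eps),
            rtol)
}

cnorm2_test <- function(x) sum(Mod(x)^2)

toy_wm_theta <- function() parameter_vector(r1 = 1 / 0.810, r2 = 1 / 0.025)
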