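new_subspace_basis <- function(u, lambda, singular_values, provenance = list()) {
  u <- fix_column_phase(as_complex_matrix(u))
  structure(
    list(u = u, lambda = lambda, n_c = ncol(u),
         singular_values = singular_values, provenance = provenance),
    class = "subspace_basis"
  )
}

#' Extract the orthonormal matrix of a basis
#'
#' @param basis A `subspace_basis` or a bare (orthonormal) complex matrix.
#' @return Complex `N_T x N_c` matrix.
#' @export
basis_matrix <- function(basis) {
  if (inherits(basis, "subspace_basis")) basis$u else as_complex_matrix(basis)
}

#' @export
print.subspace_basis <- function(x, ...) {
  cat("<subspace_basis> ", nrow(x$u), "time points x", x$n_c,
      "components, lambda =", x$lambda, "\n")
  invisible(x)
}

#' Traditional SVD subspace basis
#'
#' The classical energy-optimal temporal basis: the first `n_c` left singular
#' vectors of the fingerprint dictionary, i.e. the minimizer of
#' `||S - U U^H S||_F^2` over orthonormal `U` of rank `n_c`.
#'
#' @param s A `fingerprint_dictionary` or complex signal matrix
#'   (`N_T x N_s`).
#' @param n_c Subspace rank, `1 <= n_c <= min(N_T, N_s)`.
#' @return A `subspace_basis` with `lambda = 0` and the full singular-value
#'   spectrum of the dictionary as provenance.
#' @export
traditional_svd <- function(s, n_c) {
  sm <- if (inherits(s, "fingerprint_dictionary")) s$signals else as_complex_matrix(s)
  if (n_c < 1 || n_c > min(dim(sm))) abort("n_c out of range")
  sv <- svd(sm, nu = n_c, nv = 0)
  new_subspace_basis(sv$u, lambda = 0, singular_values = sv$d,
                     provenance = list(method = "traditional_svd"))
}

#' CRB-SVD subspace basis
#'
#' Computes the basis that trades signal-energy preservation against
#' preservation of the (approximate compressed) Cramer-Rao bound: the first
#' `n_c` left singular vectors of the horizontally concatenated matrix
#' `D = [(1 - lambda) * S, lambda * J_perp]`, where `J_perp` holds the
#' unit-normalized orthogonalized derivatives of the parameters of interest
#' for every fingerprint. `lambda = 0` recovers the traditional SVD basis;
#' `lambda = 1` drops the signal term entirely and is permitted with a
#' warning (poor signal fidelity).
#'
#' @param s A `fingerprint_dictionary` or complex signal matrix. Fingerprint
#'   columns enter at their simulated scale; set `normalize_signals = TRUE`
#'   to give each fingerprint unit energy first.
#' @param ortho An [build_ortho_set()] result (or a complex matrix of
#'   unit-norm orthogonalized derivatives).
#' @param lambda CRB weighting in `[0, 1]`.
#' @param n_c Subspace rank; must not exceed the numerical rank of `D`.
#' @param normalize_signals Normalize each fingerprint column to unit energy
#'   before concatenation (default `FALSE`).
#' @param tol Relative singular-value tolerance for the numerical rank.
#' @return A `subspace_basis` carrying `lambda` and the full singular-value
#'   spectrum of `D`.
#' @export
crb_svd <- function(s, ortho, lambda, n_c, normalize_signals = FALSE,
                    tol = 1e-10) {
  stopifnot(lambda >= 0, lambda <= 1)
  sm <- if (inherits(s, "fingerprint_dictionary")) s$signals else as_complex_matrix(s)
  jp <- if (inherits(ortho, "ortho_deriv_set")) ortho$matrix else as_complex_matrix(ortho)
  if (nrow(sm) != nrow(jp)) abort("signal and derivative matrices disagree in N_T")
  if (lambda == 1) warn("lambda = 1 drops the signal-energy term; expect poor signal fidelity")
  if (normalize_signals) {
    sm <- sweep(sm, 2, sqrt(colSums(Mod(sm)^2)), "/")
  }
  d <- cbind((1 - lambda) * sm, lambda * jp)
  sv <- svd(d, nu = min(n_c, nrow(d)), nv = 0)
  rank_d <- sum(sv$d > tol * sv$d[1L])
  if (n_c > rank_d) abort("requested rank exceeds numerical rank")
  new_subspace_basis(sv$u[, seq_len(n_c), drop = FALSE], lambda = lambda,
                     singular_values = sv$d,
                     provenance = list(method = "crb_svd",
                                       normalize_signals = normalize_signals))
}

#' Identity basis
#'
#' The trivial rank-`N_T` basis (no compression); useful as the uncompressed
#' reference in Monte-Carlo studies.
#'
#' @param n_t Number of time points.
#' @return A `subspace_basis` with `U = I`.
#' @export
identity_basis <- function(n_t) {
  new_subspace_basis(diag(n_t) + 0i, lambda = 0,
                     singular_values = rep(1, n_t),
                     provenance = list(method = "identity"))
}

#' Compress a fingerprint into subspace coefficients
#'
#' `c = U^H s`; because `U` is orthonormal the coefficient energy plus the
#' projection-residual energy equals the fingerprint energy.
#'
#' @param f Complex fingerprint vector (or matrix of fingerprints, one per
#'   column).
#' @param basis A `subspace_basis` or orthonormal matrix.
#' @return Complex coefficient vector of length `N_c` (or `N_c x N_s`
#'   matrix).
#' @export
compress <- function(f, basis) {
  u <- basis_matrix(basis)
  out <- ct(u) %*% as_complex_matrix(f)
  if (ncol(out) == 1L) as.vector(out) else out
}

#' Project a fingerprint onto a subspace
#'
#' `U U^H s`: idempotent orthogonal projection onto the basis span; the
#' residual is orthogonal to every basis column.
#'
#' @inheritParams compress
#' @return Projected fingerprint(s), same shape as the input.
#' @export
project <- function(f, basis) {
  u <- basis_matrix(basis)
  out <- u %*% (ct(u) %*% as_complex_matrix(f))
  if (ncol(out) == 1L) as.vector(out) else out
}

#' Compress a dictionary for matching
#'
#' Precomputes `U^H S` and per-column norms for maximum-correlation
#' dictionary matching on compressed coefficients.
#'
#' @param d A `fingerprint_dictionary`.
#' @param basis A `subspace_basis`.
#' @return Object of class `"compressed_dictionary"` with fields
#'   `coefficients` (`N_c x N_s`), `norms`, `theta`.
#' @export
compress_dictionary <- function(d, basis) {
  coef <- compress(d$signals, basis)
  if (is.null(dim(coef))) coef <- matrix(coef, ncol = n_fingerprints(d))
  structure(
    list(coefficients = coef,
         norms = sqrt(colSums(Mod(coef)^2)),
         theta = d$theta),
    class = "compressed_dictionary"
  )
}

# ---------------------------------------------------------------------------
# broom-style accessors

#' @export
tidy.subspace_basis <- function(x, ...) {
  d <- x$singular_values
  tibble(component = seq_along(d), singular_value = d,
         energy_fraction = d^2 / sum(d^2),
         retained = seq_along(d) <= x$n_c)
}

#' @export
glance.subspace_basis <- function(x, ...) {
  d2 <- x$singular_values^2
  tibble(n_t = nrow(x$u), n_c = x$n_c, lambda = x$lambda,
         captured_energy = sum(d2[seq_len(min(x$n_c, length(d2)))]) / sum(d2))
}

#' Scree-style plot of a subspace basis spectrum
#'
#' @param object A `subspace_basis`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.subspace_basis <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$component, y = .data$singular_value,
                                   colour = .data$retained)) +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "component", y = "singular value",
                  title = sprintf("Subspace spectrum (lambda = %.2f, Nc = %d)",
                                  object$lambda, object$n_c))
}
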