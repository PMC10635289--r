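#' Orthogonalized signal derivative
#'
#' Projects the derivative of the signal with respect to parameter `i` onto
#' the orthogonal complement of the span of all other parameters'
#' derivatives. Writing `J_i` for the Jacobian without column `i` and `P` for
#' the orthogonal projector onto its range, the result is
#' `(I - P) j_i`. Its squared Hermitian norm is inversely proportional to the
#' parameter's Cramer-Rao bound, which is what makes this vector the central
#' object of the whole basis-design problem. The result is *not* normalized.
#'
#' The projector is computed through a rank-revealing SVD of `J_i` with
#' relative singular-value tolerance `tol` (pseudo-inverse semantics for
#' near-degenerate complements).
#'
#' @param j Complex Jacobian matrix (`N_T x N_p`), columns ordered as in
#'   [parameter_vector()].
#' @param i Column index of the parameter of interest.
#' @param tol Relative rank tolerance; if the projected derivative has norm
#'   below `tol * ||j_i||` the parameter is unidentifiable and an error is
#'   raised.
#' @return Complex vector of length `N_T`.
#' @export
orthogonalized_derivative <- function(j, i, tol = 1e-10) {
  j <- as_complex_matrix(j)
  stopifnot(i >= 1, i <= ncol(j))
  ji <- j[, i]
  others <- j[, -i, drop = FALSE]
  if (ncol(others) > 0L) {
    q <- orthonormal_range(others, tol)
    jperp <- ji - q %*% (ct(q) %*% ji)
    jperp <- as.vector(jperp)
  } else {
    jperp <- ji
  }
  if (cnorm(jperp) < tol * cnorm(ji)) {
    abort(paste0("derivative degenerate within span of other parameters",
                 " (parameter column ", i, ")"))
  }
  jperp
}

# Order-dependent variant: sequential QR (Gram-Schmidt) sweep, where each
# derivative is orthogonalized only against the columns preceding it.
joint_qr_derivatives <- function(j, tol = 1e-10) {
  j <- as_complex_matrix(j)
  out <- vector("list", ncol(j))
  basis <- matrix(0 + 0i, nrow(j), 0)
  for (i in seq_len(ncol(j))) {
    v <- j[, i]
    if (ncol(basis) > 0L) v <- v - basis %*% (ct(basis) %*% v)
    v <- as.vector(v)
    out[[i]] <- v
    nv <- cnorm(v)
    if (nv > tol * cnorm(j[, i])) basis <- cbind(basis, v / nv)
  }
  out
}

#' Build the orthogonalized-derivative set of a dictionary
#'
#' For each fingerprint and each parameter of interest, computes the
#' orthogonalized derivative (nuisance parameters participate in the
#' projection but contribute no columns) and normalizes it to unit energy.
#' The normalized columns are what enters the CRB-SVD concatenation; the
#' pre-normalization norms are retained because the approximate compressed
#' CRB needs them.
#'
#' @param jacobians List of per-fingerprint Jacobian matrices sharing shape
#'   and column order.
#' @param interest Character names of the parameters of interest (columns of
#'   the Jacobians); all remaining columns are nuisance parameters.
#' @param method `"complement"` (default) uses the order-independent
#'   complement projector; `"qr"` uses a sequential one-pass QR sweep in
#'   column order, kept for comparison.
#' @param tol Rank tolerance passed to [orthogonalized_derivative()].
#' @param ids Optional fingerprint identifiers (default sequential).
#' @return Object of class `"ortho_deriv_set"`: fields `matrix` (complex
#'   `N_T x (N_s * N_pi)`, unit-norm columns), `index_map` (tibble with
#'   `column`, `fingerprint`, `parameter`), `norms` (pre-normalization
#'   norms), `n_pi`.
#' @export
build_ortho_set <- function(jacobians, interest = c("r1", "r2"),
                            method = c("complement", "qr"),
                            tol = 1e-10, ids = NULL) {
  method <- match.arg(method)
  stopifnot(length(jacobians) >= 1)
  cn <- colnames(jacobians[[1L]]) %||% param_names()
  idx_int <- match(interest, cn)
  if (anyNA(idx_int)) abort("interest parameters not found in Jacobian columns")
  ids <- ids %||% seq_along(jacobians)

  cols <- vector("list", length(jacobians) * length(idx_int))
  norms <- numeric(length(cols))
  k <- 0L
  map <- vector("list", length(cols))
  for (f in seq_along(jacobians)) {
    j <- jacobians[[f]]
    seq_perp <- if (method == "qr") joint_qr_derivatives(j, tol) else NULL
    for (p in seq_along(idx_int)) {
      jperp <- tryCatch(
        if (method == "qr") seq_perp[[idx_int[p]]] else
          orthogonalized_derivative(j, idx_int[p], tol),
        error = function(e) abort(paste0("fingerprint ", ids[f], ": ",
                                         conditionMessage(e)))
      )
      k <- k + 1L
      norms[k] <- cnorm(jperp)
      cols[[k]] <- jperp / norms[k]
      map[[k]] <- tibble(column = k, fingerprint = ids[f],
                         parameter = interest[p])
    }
  }
  structure(
    list(matrix = as_complex_matrix(do.call(cbind, cols)),
         index_map = dplyr::bind_rows(map),
         norms = norms, n_pi = length(idx_int), interest = interest),
    class = "ortho_deriv_set"
  )
}

#' @export
print.ortho_deriv_set <- function(x, ...) {
  cat("<ortho_deriv_set> ", nrow(x$matrix), "time points x", ncol(x$matrix),
      "unit-norm orthogonalized derivatives (", x$n_pi, "per fingerprint )\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# CRB variants

#' Uncompressed Cramer-Rao bound
#'
#' Per-parameter CRB of the uncompressed fingerprint under white Gaussian
#' noise, computed through the geometric route
#' `B_u(theta_i) = sigma^2 / ||j_perp_i||^2` where `j_perp_i` is the
#' [orthogonalized_derivative()]. Equivalent to `sigma^2` times the diagonal
#' of the inverse Fisher matrix `(J^H J)^{-1}`, but requires no matrix
#' inverse.
#'
#' @param j Complex Jacobian (`N_T x N_p`).
#' @param sigma Noise standard deviation per real/imaginary component
#'   (default 1; all shipped loss metrics are sigma-invariant ratios).
#' @param tol Rank tolerance; a rank-deficient Jacobian (infinite CRB) is an
#'   error.
#' @return Named numeric vector of bounds, one per Jacobian column (nuisance
#'   parameters included).
#' @export
crb_uncompressed <- function(j, sigma = 1, tol = 1e-10) {
  j <- as_complex_matrix(j)
  vapply(seq_len(ncol(j)), function(i) {
    jperp <- tryCatch(orthogonalized_derivative(j, i, tol),
                      error = function(e) {
                        abort(paste0("rank-deficient Jacobian, CRB infinite: ",
                                     conditionMessage(e)))
                      })
    sigma^2 / cnorm2(jperp)
  }, numeric(1), USE.NAMES = FALSE) |>
    stats::setNames(colnames(j))
}

#' Exact compressed Cramer-Rao bound
#'
#' CRB when the subspace coefficients `c = U^H s` are the measurements:
#' the uncompressed formula applied to the compressed Jacobian `U^H J`. If
#' compression collapses a parameter's derivative into the span of the
#' others, the bound is infinite and an error is raised.
#'
#' @inheritParams crb_uncompressed
#' @param basis A [subspace_basis][traditional_svd()] or an orthonormal
#'   complex matrix `U`.
#' @return Named numeric vector of per-parameter bounds.
#' @export
crb_exact_compressed <- function(j, basis, sigma = 1, tol = 1e-10) {
  u <- basis_matrix(basis)
  jc <- ct(u) %*% as_complex_matrix(j)
  tryCatch(crb_uncompressed(jc, sigma, tol),
           error = function(e) abort(paste0(
             "parameter unidentifiable in subspace: ", conditionMessage(e))))
}

#' Approximate compressed Cramer-Rao bound
#'
#' The approximation that makes SVD-based basis optimization possible: the
#' orthogonal complement is taken *before* compression, giving
#' `B_ac(theta_i) = sigma^2 / ||U^H j_perp_i||^2` with the un-normalized
#' orthogonalized derivative `j_perp_i`. It always lies between the
#' uncompressed and exact compressed bounds,
#' `B_u <= B_ac <= B_ec`.
#'
#' @inheritParams crb_exact_compressed
#' @param jperp Optional precomputed list/matrix of un-normalized
#'   orthogonalized derivatives (one column per Jacobian column); computed
#'   from `j` when omitted.
#' @return Named numeric vector of per-parameter bounds.
#' @export
crb_approx_compressed <- function(j, basis, sigma = 1, tol = 1e-10, jperp = NULL) {
  u <- basis_matrix(basis)
  j <- as_complex_matrix(j)
  if (is.null(jperp)) {
    jperp <- lapply(seq_len(ncol(j)), function(i)
      orthogonalized_derivative(j, i, tol))
  }
  if (is.matrix(jperp)) jperp <- lapply(seq_len(ncol(jperp)), function(i) jperp[, i])
  vapply(seq_along(jperp), function(i) {
    e <- cnorm2(ct(u) %*% jperp[[i]])
    if (e < (tol * cnorm(jperp[[i]]))^2) {
      abort("approximate compressed CRB infinite: subspace orthogonal to derivative")
    }
    sigma^2 / e
  }, numeric(1), USE.NAMES = FALSE) |>
    stats::setNames(colnames(j)[seq_along(jperp)])
}

#' Per-fingerprint CRB table
#'
#' Evaluates the three CRB variants for every fingerprint and every
#' parameter of interest against a given basis, returning a tidy table (one
#' row per fingerprint-parameter pair) from which the loss metrics and the
#' optimality ratio are derived.
#'
#' @param jacobians List of per-fingerprint Jacobians.
#' @param basis A subspace basis (or orthonormal matrix).
#' @param sigma Noise standard deviation (default 1).
#' @param interest Parameters of interest (Jacobian column names).
#' @param ids Optional fingerprint identifiers.
#' @param tol Rank tolerance.
#' @return A tibble of class `"crb_table"` with columns `fingerprint`,
#'   `parameter`, `b_u`, `b_ac`, `b_ec`, `sigma`.
#' @export
crb_table <- function(jacobians, basis, sigma = 1, interest = c("r1", "r2"),
                      ids = NULL, tol = 1e-10) {
  u <- basis_matrix(basis)
  ids <- ids %||% seq_along(jacobians)
  cn <- colnames(jacobians[[1L]]) %||% param_names()
  idx_int <- match(interest, cn)
  rows <- purrr::map(seq_along(jacobians), function(f) {
    j <- jacobians[[f]]
    jperp <- lapply(seq_len(ncol(j)), function(i)
      orthogonalized_derivative(j, i, tol))
    b_u <- sigma^2 / vapply(jperp, cnorm2, numeric(1))
    b_ac <- crb_approx_compressed(j, u, sigma, tol, jperp = jperp)
    b_ec <- crb_exact_compressed(j, u, sigma, tol)
    tibble(fingerprint = ids[f], parameter = cn[idx_int],
           b_u = b_u[idx_int], b_ac = b_ac[idx_int], b_ec = b_ec[idx_int],
           sigma = sigma)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("crb_table", class(out))
  out
}

#' CRB compression losses
#'
#' Aggregates a [crb_table()] into the approximate and exact CRB losses
#' `sum_i (1 - B_u_i / B_ac_i)` and `sum_i (1 - B_u_i / B_ec_i)` over all
#' fingerprint-parameter pairs, together with per-parameter mean losses. The
#' approximate loss equals the squared Frobenius residual of the
#' unit-normalized orthogonalized-derivative set under projection onto the
#' basis, which is exactly the quantity the CRB-SVD minimizes.
#'
#' @param table A [crb_table()].
#' @return List of class `"crb_losses"`: `delta_b_ac`, `delta_b_ec`
#'   (scalars), `per_parameter` (tibble of mean losses per parameter) and
#'   `n_rows`.
#' @export
crb_losses <- function(table) {
  stopifnot(all(c("b_u", "b_ac", "b_ec") %in% names(table)))
  per <- table |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(
      mean_loss_ac = mean(1 - .data$b_u / .data$b_ac),
      mean_loss_ec = mean(1 - .data$b_u / .data$b_ec),
      .groups = "drop"
    )
  structure(
    list(delta_b_ac = sum(1 - table$b_u / table$b_ac),
         delta_b_ec = sum(1 - table$b_u / table$b_ec),
         per_parameter = per, n_rows = nrow(table)),
    class = "crb_losses"
  )
}

#' @export
print.crb_losses <- function(x, ...) {
  cat("<crb_losses>  delta_B_ac =", format(x$delta_b_ac),
      " delta_B_ec =", format(x$delta_b_ec), " over", x$n_rows, "rows\n")
  print(x$per_parameter)
  invisible(x)
}

#' Basis optimality ratio
#'
#' Mean over all fingerprint-parameter pairs of `B_ac / B_ec`, a proxy for
#' how close an SVD-derived basis (which is optimal for the approximate
#' bound) is to optimal for the exact compressed bound; `R <= 1`, with
#' `R` near 1 certifying near-optimality.
#'
#' @param table A [crb_table()].
#' @return Scalar ratio.
#' @export
optimality_ratio <- function(table) mean(table$b_ac / table$b_ec)

#' Relative signal energy loss under compression
#'
#' `||S - U U^H S||_F^2 / ||S||_F^2`, the fraction of dictionary signal
#' energy not representable in the subspace.
#'
#' @param s A `fingerprint_dictionary` or complex signal matrix.
#' @param basis A subspace basis or orthonormal matrix.
#' @return Scalar in `[0, 1]`.
#' @export
signal_energy_loss <- function(s, basis) {
  sm <- if (inherits(s, "fingerprint_dictionary")) s$signals else as_complex_matrix(s)
  u <- basis_matrix(basis)
  total <- sum(Mod(sm)^2)
  if (total == 0) abort("zero-energy dictionary")
  res <- sm - u %*% (ct(u) %*% sm)
  sum(Mod(res)^2) / total
}
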