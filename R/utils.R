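#' @importFrom tibble tibble as_tibble
#' @importFrom rlang abort warn .data
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

# Conjugate (Hermitian) transpose. All transposes in the CRB formulas are
# conjugate transposes; plain t() silently drops the conjugation for complex
# input, so every inner product in the package goes through this helper.
ct <- function(x) Conj(t(x))

# Squared Hermitian l2 norm; Re() drops the numerically-zero imaginary part.
cnorm2 <- function(x) sum(Re(Conj(x) * x))

cnorm <- function(x) sqrt(cnorm2(x))

# Orthonormal basis of range(A) via a rank-revealing SVD.
# Columns with singular value <= tol * sigma_max are treated as null.
orthonormal_range <- function(a, tol = 1e-10) {
  if (is.null(dim(a))) a <- matrix(a, ncol = 1L)
  if (ncol(a) == 0L || all(Mod(a) == 0)) {
    return(matrix(0 + 0i, nrow = nrow(a), ncol = 0L))
  }
  sv <- svd(a)
  keep <- sv$d > tol * sv$d[1L]
  sv$u[, keep, drop = FALSE]
}

# Rotate each column so its largest-magnitude entry is real and positive.
# SVD phases are arbitrary; this makes every basis reproducible bit-for-bit.
fix_column_phase <- function(u) {
  for (k in seq_len(ncol(u))) {
    j <- which.max(Mod(u[, k]))
    m <- Mod(u[j, k])
    if (m > 0) u[, k] <- u[, k] * Conj(u[j, k]) / m
  }
  u
}

as_complex_matrix <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  storage.mode(x) <- "complex"
  x
}

`%||%` <- function(x, y) if (is.null(x)) y else x
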