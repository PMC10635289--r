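#' Parameter grid specification
#'
#' Describes a Cartesian grid over tissue parameters in the
#' `min:step:max` style used for fingerprinting dictionaries (e.g. T1 from
#' 500 to 1500 ms in steps of 2 ms). Each axis is given either as
#' `c(min, step, max)` or as an explicit vector of values; the grid is the
#' cross-product of the axes in declaration order.
#'
#' @param ... Named axes. Ranges are interpreted in the *rate* convention of
#'   [parameter_vector()] (`r1`, `r2` in 1/s) unless the name is `t1` or
#'   `t2`, in which case values are relaxation times in milliseconds and are
#'   converted to rates.
#' @param .explicit Named list of axes that are explicit value vectors rather
#'   than `c(min, step, max)` triples.
#' @return An object of class `"parameter_grid"`.
#' @examples
#' g <- parameter_grid(t1 = c(500, 2, 1500), t2 = c(10, 0.38, 200))
#' @export
parameter_grid <- function(..., .explicit = list()) {
  ranges <- list(...)
  stopifnot(length(ranges) + length(.explicit) > 0)
  axes <- c(lapply(ranges, function(r) {
    stopifnot(length(r) == 3)
    if (r[2] <= 0) abort("grid step must be > 0")
    if (r[1] > r[3]) abort("grid min must be <= max")
    seq(r[1], r[3], by = r[2])
  }), .explicit)
  if (any(lengths(axes) < 1L)) abort("empty grid range")
  structure(list(axes = axes), class = "parameter_grid")
}

#' Expand a parameter grid into a parameter table
#'
#' Returns one row per grid point, ordered lexicographically over the axes in
#' declaration order (first axis varies slowest). Time axes `t1`/`t2`
#' (milliseconds) are converted to the rate columns `r1`/`r2` (1/s); the
#' original time values are retained as `t1_ms`/`t2_ms` columns.
#'
#' @param grid A [parameter_grid()].
#' @return A tibble with columns `r1`, `r2` (and `t1_ms`, `t2_ms` when the
#'   grid was specified in times).
#' @export
build_grid <- function(grid) {
  stopifnot(inherits(grid, "parameter_grid"))
  tab <- rev(expand.grid(rev(grid$axes), KEEP.OUT.ATTRS = FALSE))
  tab <- as_tibble(tab)
  if ("t1" %in% names(tab)) {
    tab$t1_ms <- tab$t1
    tab$r1 <- 1000 / tab$t1
    tab$t1 <- NULL
  }
  if ("t2" %in% names(tab)) {
    tab$t2_ms <- tab$t2
    tab$r2 <- 1000 / tab$t2
    tab$t2 <- NULL
  }
  tab
}

#' Simulate a fingerprint dictionary
#'
#' Evaluates the model at every grid point with `m0 = 1` (dictionary
#' matching estimates the scale separately) and stacks the fingerprints
#' column-wise.
#'
#' @param model A model object ([toy_model()] / [fisp_model()]).
#' @param grid A [parameter_grid()] or a parameter table as returned by
#'   [build_grid()].
#' @return An object of class `"fingerprint_dictionary"` with fields
#'   `signals` (complex `N_T x N_s` matrix), `theta` (parameter table) and
#'   `provenance`.
#' @export
simulate_dictionary <- function(model, grid) {
  theta <- if (inherits(grid, "parameter_grid")) build_grid(grid) else as_tibble(grid)
  if (anyDuplicated(theta[c("r1", "r2")])) abort("duplicated grid points")
  signals <- model_signal_batch(model, theta)
  bad <- which(!apply(is.finite(Re(signals)) & is.finite(Im(signals)), 2, all))
  if (length(bad)) {
    abort(paste0("non-finite simulation output at grid point(s) ",
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  new_dictionary(signals, theta,
                 provenance = list(model = class(model)[1L],
                                   spec = model$spec, n_s = ncol(signals)))
}

new_dictionary <- function(signals, theta, provenance = list()) {
  signals <- as_complex_matrix(signals)
  stopifnot(ncol(signals) == nrow(theta))
  structure(list(signals = signals, theta = as_tibble(theta),
                 provenance = provenance),
            class = "fingerprint_dictionary")
}

#' @export
print.fingerprint_dictionary <- function(x, ...) {
  cat("<fingerprint_dictionary> ", nrow(x$signals), "time points x",
      ncol(x$signals), "fingerprints\n")
  invisible(x)
}

#' Number of fingerprints / time points in a dictionary
#' @param d A `fingerprint_dictionary`.
#' @return Integer count.
#' @export
n_fingerprints <- function(d) ncol(d$signals)

#' @rdname n_fingerprints
#' @export
n_timepoints <- function(d) nrow(d$signals)

#' Augment a dictionary with complex conjugates
#'
#' Appends the complex conjugate of every fingerprint as an extra column so
#' that conjugation symmetry of the signal model is represented exactly in
#' the dictionary span, which in turn yields real-valued subspace bases for
#' conjugation-symmetric models. The parameter table is duplicated with a
#' logical `conjugate` flag. Applying the augmentation twice doubles the
#' columns again (no deduplication is attempted).
#'
#' @param d A `fingerprint_dictionary`.
#' @return The augmented dictionary with `2 * N_s` columns.
#' @export
augment_conjugate <- function(d) {
  theta <- d$theta
  if (!"conjugate" %in% names(theta)) theta$conjugate <- FALSE
  theta2 <- theta
  theta2$conjugate <- TRUE
  new_dictionary(cbind(d$signals, Conj(d$signals)),
                 dplyr::bind_rows(theta, theta2),
                 provenance = c(d$provenance, list(conjugate_augmented = TRUE)))
}

#' Split a dictionary into basis-estimation and test sets
#'
#' Random disjoint column partition by a seeded permutation, in the spirit of
#' holding out a third of the fingerprints to evaluate a basis on signals it
#' was not computed from.
#'
#' @param d A `fingerprint_dictionary`.
#' @param fraction Proportion of fingerprints in the first (training) part,
#'   strictly between 0 and 1. Default `0.67`.
#' @param seed Integer seed making the partition reproducible.
#' @return List with elements `train` and `test`, both dictionaries.
#' @export
split_train_test <- function(d, fraction = 0.67, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1)
  n <- n_fingerprints(d)
  n_train <- round(fraction * n)
  if (n_train < 1L || n_train >= n) abort("split fraction yields an empty part")
  perm <- withr::with_seed(seed, sample.int(n))
  idx_train <- sort(perm[seq_len(n_train)])
  idx_test <- sort(perm[-seq_len(n_train)])
  subset_dict <- function(idx) {
    new_dictionary(d$signals[, idx, drop = FALSE], d$theta[idx, , drop = FALSE],
                   provenance = c(d$provenance, list(split_seed = seed)))
  }
  list(train = subset_dict(idx_train), test = subset_dict(idx_test))
}
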