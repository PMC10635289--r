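#' Basis-quality sweep over lambda and subspace size
#'
#' Runs the full basis-design pipeline on one dictionary: splits the
#' fingerprints into basis-estimation and held-out test sets, builds the
#' orthogonalized-derivative set of the training fingerprints, computes one
#' CRB-SVD decomposition per `lambda`, truncates it at every requested
#' `N_c`, and evaluates signal energy loss, the approximate and exact CRB
#' losses, and the optimality ratio on the held-out test set.
#'
#' @param model A signal model object.
#' @param grid A [parameter_grid()] or parameter table.
#' @param lambdas CRB weightings to sweep (default 10 evenly spaced values
#'   in `[0, 1)`).
#' @param n_cs Subspace sizes to sweep.
#' @param fraction Training fraction of the fingerprint split (default
#'   0.67).
#' @param seed Integer seed for the split.
#' @param sigma Noise standard deviation entering the CRB formulas (the
#'   reported losses and ratio are sigma-invariant).
#' @param interest Parameters of interest.
#' @param h_rel Finite-difference step for model Jacobians.
#' @return A tibble of class `"sweep_report"`, one row per
#'   `(lambda, n_c)`: `signal_energy_loss`, `delta_b_ac`, `delta_b_ec`,
#'   `r_opt` and per-row mean losses.
#' @export
sweep_report <- function(model, grid, lambdas = seq(0, 0.9, by = 0.1),
                         n_cs = 3:10, fraction = 0.67, seed = 1L, sigma = 1,
                         interest = c("r1", "r2"), h_rel = 1e-5) {
  dict <- if (inherits(grid, "fingerprint_dictionary")) grid else
    simulate_dictionary(model, grid)
  parts <- split_train_test(dict, fraction = fraction, seed = seed)

  jac_train <- model_jacobian_batch(model, parts$train$theta, h_rel = h_rel)
  jac_test <- model_jacobian_batch(model, parts$test$theta, h_rel = h_rel)
  ortho_train <- build_ortho_set(jac_train, interest = interest)

  rows <- purrr::map(lambdas, function(lam) {
    sv_needed <- max(n_cs)
    basis_full <- crb_svd(parts$train, ortho_train, lambda = lam, n_c = sv_needed)
    purrr::map(n_cs, function(nc) {
      basis <- new_subspace_basis(basis_full$u[, seq_len(nc), drop = FALSE],
                                  lambda = lam,
                                  singular_values = basis_full$singular_values)
      tab <- crb_table(jac_test, basis, sigma = sigma, interest = interest)
      losses <- crb_losses(tab)
      tibble(lambda = lam, n_c = nc,
             signal_energy_loss = signal_energy_loss(parts$test, basis),
             delta_b_ac = losses$delta_b_ac,
             delta_b_ec = losses$delta_b_ec,
             mean_loss_ac = losses$delta_b_ac / losses$n_rows,
             mean_loss_ec = losses$delta_b_ec / losses$n_rows,
             r_opt = optimality_ratio(tab))
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  class(rows) <- c("sweep_report", class(rows))
  attr(rows, "seed") <- seed
  attr(rows, "fraction") <- fraction
  rows
}

#' Plot a basis-quality sweep
#'
#' Signal energy loss, CRB losses and the optimality ratio against lambda,
#' one line per subspace size.
#'
#' @param object A [sweep_report()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sweep_report <- function(object, ...) {
  d <- tidyr::pivot_longer(
    as_tibble(object),
    c("signal_energy_loss", "mean_loss_ac", "mean_loss_ec", "r_opt"),
    names_to = "metric", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$lambda, y = .data$value,
                                  colour = factor(.data$n_c))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(colour = "Nc", y = NULL,
                  title = "Basis quality vs CRB weighting")
}
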