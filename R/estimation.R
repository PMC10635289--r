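#' White complex Gaussian noise model
#'
#' `sigma` is the noise standard deviation **per real/imaginary component**;
#' the signal-to-noise ratio is defined per time point as
#' `SNR = |m0| / sigma`. One of `sigma` or `snr` must be given. Because the
#' basis is orthonormal, noise added to the coefficients has the same
#' covariance as compressed uncompressed-domain noise, which is what permits
#' simulating directly in the coefficient domain.
#'
#' @param snr Signal-to-noise ratio `|m0| / sigma` (default 50).
#' @param m0 Reference scale (default 1).
#' @param sigma Noise standard deviation per component; derived from `snr`
#'   when omitted.
#' @param seed Optional integer seed used by [add_coefficient_noise()].
#' @return Object of class `"noise_model"`.
#' @export
noise_model <- function(snr = 50, m0 = 1 + 0i, sigma = NULL, seed = NULL) {
  if (is.null(sigma)) sigma <- Mod(m0) / snr
  stopifnot(sigma >= 0)
  structure(list(sigma = sigma, snr = Mod(m0) / max(sigma, .Machine$double.xmin),
                 m0 = as.complex(m0), seed = seed),
            class = "noise_model")
}

#' Add circular complex Gaussian noise to coefficients
#'
#' Adds i.i.d. noise with standard deviation `sigma` per real and imaginary
#' component to each coefficient. With a `seed` in the noise model the draw
#' is reproducible and does not disturb the caller's RNG state.
#'
#' @param c Complex coefficient vector.
#' @param noise A [noise_model()].
#' @return Noisy coefficient vector.
#' @export
add_coefficient_noise <- function(c, noise) {
  draw <- function() {
    n <- length(c)
    c + complex(real = stats::rnorm(n, 0, noise$sigma),
                imaginary = stats::rnorm(n, 0, noise$sigma))
  }
  if (!is.null(noise$seed)) withr::with_seed(noise$seed, draw()) else draw()
}

#' Dictionary matching on compressed coefficients
#'
#' Maximum-correlation search: the matched entry maximizes
#' `|d_k^H c| / ||d_k||` over the compressed dictionary; the scale estimate
#' is `m0_hat = d_k^H c / ||d_k||^2`. Ties break to the lowest index.
#'
#' @param c Complex coefficient vector (`N_c`).
#' @param cdict A [compress_dictionary()] result.
#' @return Object of class `"match_result"`: `theta_hat` (matched parameter
#'   row), `m0_hat`, `index`, `objective` (the matched correlation).
#' @export
dictionary_match <- function(c, cdict) {
  if (length(cdict$norms) == 0L) abort("empty dictionary")
  inner <- as.vector(ct(cdict$coefficients) %*% c)
  scores <- Mod(inner) / cdict$norms
  k <- which.max(scores)
  structure(
    list(theta_hat = cdict$theta[k, , drop = FALSE],
         m0_hat = inner[k] / cdict$norms[k]^2,
         index = k, objective = scores[k], converged = NA),
    class = "match_result"
  )
}

#' Nonlinear least-squares fit in the compressed domain
#'
#' Minimizes `||U^H s(theta, m0) - c||^2` over `(m0, r1, r2)` with the
#' Levenberg-Marquardt algorithm, the residual stacked over real and
#' imaginary parts. The relaxation rates are fitted in log-space to keep
#' them positive; `m0` is fitted jointly as two real components.
#'
#' @param c Complex coefficient vector.
#' @param basis A `subspace_basis`.
#' @param model A signal model object.
#' @param theta0 Initial [parameter_vector()].
#' @param max_iter Maximum Levenberg-Marquardt iterations (default 500).
#' @return Object of class `"nlls_result"`: `theta_hat`, `m0_hat`,
#'   `objective`, `iterations`, `converged`.
#' @export
nlls_fit <- function(c, basis, model, theta0, max_iter = 500L) {
  u <- basis_matrix(basis)
  resid_fun <- function(par) {
    th <- parameter_vector(m0 = complex(real = par[1], imaginary = par[2]),
                           r1 = exp(par[3]), r2 = exp(par[4]),
                           interest = theta0$interest)
    r <- as.vector(ct(u) %*% model_signal(model, th)) - c
    c(Re(r), Im(r))
  }
  par0 <- c(Re(theta0$m0), Im(theta0$m0), log(theta0$r1), log(theta0$r2))
  fit <- minpack.lm::nls.lm(par = par0, fn = resid_fun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = as.integer(max_iter)))
  par <- fit$par
  structure(
    list(theta_hat = parameter_vector(
           m0 = complex(real = par[1], imaginary = par[2]),
           r1 = exp(par[3]), r2 = exp(par[4]), interest = theta0$interest),
         m0_hat = complex(real = par[1], imaginary = par[2]),
         objective = fit$deviance,
         iterations = fit$niter,
         converged = fit$info %in% 1:4),
    class = "nlls_result"
  )
}

#' Monte-Carlo bias/variance study of an estimator
#'
#' Simulates the true compressed coefficients `c* = U^H s(theta_true)`, adds
#' seeded coefficient-domain noise per repetition, runs the chosen estimator
#' and summarizes per-parameter normalized bias and standard deviation
#' alongside the square-root uncompressed and exact-compressed CRB
#' references.
#'
#' @param model A signal model object.
#' @param theta_true True [parameter_vector()].
#' @param basis A `subspace_basis`.
#' @param noise A [noise_model()].
#' @param n_reps Number of noisy repetitions (`>= 2`).
#' @param estimator `"match"` or `"nlls"`.
#' @param seed Integer seed for the noise stream.
#' @param cdict Compressed dictionary (required for `estimator = "match"`),
#'   compressed with the *same* basis.
#' @param max_iter NLLS iteration cap.
#' @return Object of class `"monte_carlo_report"` with fields `summary`
#'   (tibble: parameter, truth, bias_norm, std_norm, variance, crb refs),
#'   `estimates` (per-rep tibble), `n_failed`, `estimator`, `basis_lambda`.
#' @export
monte_carlo <- function(model, theta_true, basis, noise, n_reps = 1000L,
                        estimator = c("match", "nlls"), seed = 1L,
                        cdict = NULL, max_iter = 500L) {
  estimator <- match.arg(estimator)
  stopifnot(n_reps >= 2)
  if (estimator == "match" && is.null(cdict)) abort("matching requires a compressed dictionary")
  c_star <- compress(model_signal(model, theta_true), basis)

  run_rep <- function(ci) {
    if (estimator == "match") {
      m <- dictionary_match(ci, cdict)
      c(r1 = m$theta_hat$r1[[1]], r2 = m$theta_hat$r2[[1]], m0_mod = Mod(m$m0_hat))
    } else {
      fit <- nlls_fit(ci, basis, model, theta_true, max_iter = max_iter)
      c(r1 = fit$theta_hat$r1, r2 = fit$theta_hat$r2, m0_mod = Mod(fit$m0_hat))
    }
  }

  est <- withr::with_seed(seed, {
    t(vapply(seq_len(n_reps), function(r) {
      ci <- add_coefficient_noise(c_star, noise_model(sigma = noise$sigma))
      tryCatch(run_rep(ci), error = function(e) c(r1 = NA_real_, r2 = NA_real_,
                                                  m0_mod = NA_real_))
    }, numeric(3)))
  })
  ok <- stats::complete.cases(est)
  n_failed <- sum(!ok)
  est_ok <- est[ok, , drop = FALSE]

  j <- model_jacobian(model, theta_true)
  b_u <- crb_uncompressed(j, noise$sigma)
  b_ec <- tryCatch(crb_exact_compressed(j, basis, noise$sigma),
                   error = function(e) stats::setNames(rep(NA_real_, ncol(j)),
                                                       colnames(j)))
  truth <- c(r1 = theta_true$r1, r2 = theta_true$r2)
  pars <- c("r1", "r2")
  mean_est <- unname(colMeans(est_ok)[pars])
  sd_est <- unname(apply(est_ok, 2, stats::sd)[pars])
  var_est <- unname(apply(est_ok, 2, stats::var)[pars])
  tr <- unname(truth[pars])
  bu <- unname(b_u[pars])
  bec <- unname(b_ec[pars])
  summary <- tibble(
    parameter = pars,
    truth = tr,
    mean_estimate = mean_est,
    bias_norm = (mean_est - tr) / tr,
    std_norm = sd_est / tr,
    variance = var_est,
    b_u = bu,
    b_ec = bec,
    sqrt_b_u_norm = sqrt(bu) / tr,
    sqrt_b_ec_norm = sqrt(bec) / tr
  )
  structure(
    list(summary = summary,
         estimates = as_tibble(est_ok) |> dplyr::mutate(rep = dplyr::row_number()),
         n_reps = n_reps, n_failed = n_failed, estimator = estimator,
         basis_lambda = if (inherits(basis, "subspace_basis")) basis$lambda else NA_real_,
         sigma = noise$sigma, seed = seed),
    class = "monte_carlo_report"
  )
}

#' @export
print.monte_carlo_report <- function(x, ...) {
  cat("<monte_carlo_report> ", x$estimator, "estimator,", x$n_reps, "reps (",
      x$n_failed, "failed ), sigma =", format(x$sigma), "\n")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.monte_carlo_report <- function(x, ...) x$summary

#' @export
glance.monte_carlo_report <- function(x, ...) {
  tibble(estimator = x$estimator, n_reps = x$n_reps, n_failed = x$n_failed,
         sigma = x$sigma, basis_lambda = x$basis_lambda,
         worst_std_norm = max(x$summary$std_norm))
}

#' Bias/std summary plot of a Monte-Carlo report
#'
#' Normalized bias and standard deviation per parameter, with the
#' square-root CRB references.
#'
#' @param object A `monte_carlo_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.monte_carlo_report <- function(object, ...) {
  d <- object$summary |>
    tidyr::pivot_longer(c("bias_norm", "std_norm"),
                        names_to = "metric", values_to = "value")
  refs <- object$summary |>
    dplyr::transmute(.data$parameter, metric = "std_norm",
                     ref = .data$sqrt_b_ec_norm)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$parameter, y = abs(.data$value))) +
    ggplot2::geom_col() +
    ggplot2::geom_point(data = refs, ggplot2::aes(y = .data$ref),
                        colour = "red", shape = 4, size = 3) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(y = "|normalized value|",
                  title = sprintf("Monte-Carlo %s (lambda = %.2f)",
                                  object$estimator, object$basis_lambda))
}
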