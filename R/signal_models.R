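#' Biophysical parameter vector
#'
#' Bundles the parameters of the single-compartment relaxometry models used
#' throughout the package: a complex scale `m0`, the longitudinal relaxation
#' rate `r1` (1/s, i.e. 1/T1) and the transverse relaxation rate `r2` (1/s,
#' i.e. 1/T2). Each parameter is flagged either as a *parameter of interest*
#' or as a *nuisance* parameter; nuisance parameters take part in every
#' Fisher-information computation but contribute no columns to the
#' orthogonalized-derivative set used for basis design.
#'
#' @param m0 Complex (or real) scale, `|m0| > 0`. Default `1`.
#' @param r1 Longitudinal relaxation rate in 1/s, `> 0`.
#' @param r2 Transverse relaxation rate in 1/s, `> 0`.
#' @param interest Character vector naming the parameters of interest among
#'   `c("m0", "r1", "r2")`. Default treats `m0` as nuisance and `r1`, `r2`
#'   as the parameters of interest.
#' @return An object of class `"parameter_vector"`.
#' @examples
#' theta_wm <- parameter_vector(r1 = 1 / 0.810, r2 = 1 / 0.025)
#' @export
parameter_vector <- function(m0 = 1 + 0i, r1, r2, interest = c("r1", "r2")) {
  m0 <- as.complex(m0)
  if (!is.finite(Mod(m0)) || Mod(m0) == 0) abort("|m0| must be positive and finite")
  if (!is.numeric(r1) || r1 <= 0) abort("r1 must be > 0")
  if (!is.numeric(r2) || r2 <= 0) abort("r2 must be > 0")
  interest <- match.arg(interest, c("m0", "r1", "r2"), several.ok = TRUE)
  structure(
    list(m0 = m0, r1 = as.numeric(r1), r2 = as.numeric(r2),
         interest = interest),
    class = "parameter_vector"
  )
}

#' @export
print.parameter_vector <- function(x, ...) {
  cat("<parameter_vector>  m0 =", format(x$m0),
      " r1 =", format(x$r1), "/s  (T1 =", format(1000 / x$r1), "ms)",
      " r2 =", format(x$r2), "/s  (T2 =", format(1000 / x$r2), "ms)\n")
  cat("  parameters of interest:", paste(x$interest, collapse = ", "), "\n")
  invisible(x)
}

param_names <- function() c("m0", "r1", "r2")

interest_mask <- function(theta) param_names() %in% theta$interest

#' Two-segment inversion-recovery/decay toy model specification
#'
#' An analytically tractable fingerprint model used for oracle testing and
#' fast demonstrations. The fingerprint has two consecutive segments:
#' an inversion-recovery segment sampling `m0 * (1 - 2 * exp(-t * r1))` at
#' `t = dt_ir, 2*dt_ir, ...` and a decay segment sampling
#' `m0 * exp(-tau * r2)` at `tau = dt_decay, 2*dt_decay, ...`. The first
#' segment encodes `r1` only, the second `r2` only, so the analytic Jacobian
#' has disjoint-support relaxation-rate columns.
#'
#' @param n_ir Number of inversion-recovery samples (`>= 1`).
#' @param dt_ir Spacing of the IR samples in seconds (`> 0`).
#' @param n_decay Number of decay samples (`>= 1`).
#' @param dt_decay Spacing of the decay samples in seconds (`> 0`).
#' @return An object of class `"toy_ir_spec"`; fingerprint length is
#'   `n_ir + n_decay`.
#' @export
toy_ir_spec <- function(n_ir = 12L, dt_ir = 0.1, n_decay = 12L, dt_decay = 0.01) {
  stopifnot(n_ir >= 1, n_decay >= 1, dt_ir > 0, dt_decay > 0)
  structure(
    list(n_ir = as.integer(n_ir), dt_ir = dt_ir,
         n_decay = as.integer(n_decay), dt_decay = dt_decay),
    class = "toy_ir_spec"
  )
}

#' FISP fingerprinting sequence specification
#'
#' Sequence timing and excitation train for the inversion-recovery FISP
#' fingerprinting simulator ([fisp_signal()]): adiabatic inversion, delay
#' `ti`, then one excitation per entry of `flip_train` with repetition time
#' `tr` and echo time `te`. Gradient spoiling is modeled by a deterministic
#' ensemble of `n_isochromats` isochromats dephased by `2*pi*j/n_isochromats`
#' per TR; the recorded signal is the complex ensemble average of the
#' transverse magnetization at the echo time.
#'
#' @param flip_train Flip angles in radians, one per excitation, each in
#'   `[0, pi]`. See [default_flip_train()].
#' @param tr Repetition time in seconds (default 0.010).
#' @param te Echo time in seconds (default 0.005), `0 < te < tr`.
#' @param ti Inversion time in seconds (default 0.020), `>= 0`.
#' @param inv_efficiency Inversion efficiency in `[0, 1]` (default 1).
#' @param n_isochromats Size of the dephasing ensemble (default 64).
#' @return An object of class `"fisp_spec"`.
#' @export
fisp_spec <- function(flip_train = default_flip_train(), tr = 0.010, te = 0.005,
                      ti = 0.020, inv_efficiency = 1, n_isochromats = 64L) {
  if (length(flip_train) == 0L) abort("empty sequence")
  stopifnot(te > 0, te < tr, ti >= 0,
            inv_efficiency >= 0, inv_efficiency <= 1, n_isochromats >= 1)
  if (any(flip_train < 0 | flip_train > pi)) abort("flip angles must lie in [0, pi]")
  structure(
    list(flip_train = as.numeric(flip_train), tr = tr, te = te, ti = ti,
         inv_efficiency = inv_efficiency,
         n_isochromats = as.integer(n_isochromats)),
    class = "fisp_spec"
  )
}

#' Default synthetic flip-angle train
#'
#' A smooth variable-flip-angle train made of consecutive sinusoidal lobes,
#' the shape commonly used in FISP fingerprinting. Peak amplitudes default to
#' 35, 70, 50, 60 and 45 degrees over five lobes of 100 pulses each (500
#' pulses total, flip angles between 0 and 70 degrees).
#'
#' @param n_pulses Total train length.
#' @param amplitudes_deg Peak flip angle of each lobe, degrees.
#' @return Numeric vector of flip angles in radians.
#' @export
default_flip_train <- function(n_pulses = 500L,
                               amplitudes_deg = c(35, 70, 50, 60, 45)) {
  n_lobes <- length(amplitudes_deg)
  per <- ceiling(n_pulses / n_lobes)
  ang <- unlist(lapply(amplitudes_deg, function(a) {
    a * sin(pi * seq_len(per) / (per + 1))
  }))
  ang[seq_len(n_pulses)] * pi / 180
}

# ---------------------------------------------------------------------------
# Toy model

#' Evaluate the toy inversion-recovery/decay fingerprint
#'
#' @param theta A [parameter_vector()].
#' @param spec A [toy_ir_spec()].
#' @return Complex fingerprint vector of length `n_ir + n_decay`.
#' @export
toy_signal <- function(theta, spec) {
  t_ir <- seq_len(spec$n_ir) * spec$dt_ir
  t_de <- seq_len(spec$n_decay) * spec$dt_decay
  theta$m0 * c(1 - 2 * exp(-t_ir * theta$r1), exp(-t_de * theta$r2))
}

#' Analytic Jacobian of the toy model
#'
#' Columns are the derivatives of [toy_signal()] with respect to
#' `(m0, r1, r2)` in that order. The `m0` column equals `s / m0`; the `r1`
#' and `r2` columns are supported on the IR and decay segments respectively.
#'
#' @inheritParams toy_signal
#' @return Complex matrix with columns named `m0`, `r1`, `r2`.
#' @export
toy_jacobian <- function(theta, spec) {
  t_ir <- seq_len(spec$n_ir) * spec$dt_ir
  t_de <- seq_len(spec$n_decay) * spec$dt_decay
  j_m0 <- c(1 - 2 * exp(-t_ir * theta$r1), exp(-t_de * theta$r2))
  j_r1 <- theta$m0 * c(2 * t_ir * exp(-t_ir * theta$r1), numeric(spec$n_decay))
  j_r2 <- theta$m0 * c(numeric(spec$n_ir), -t_de * exp(-t_de * theta$r2))
  j <- cbind(m0 = j_m0, r1 = j_r1, r2 = j_r2)
  as_complex_matrix(j)
}

# ---------------------------------------------------------------------------
# FISP isochromat simulator

# Batch Bloch simulation over many (r1, r2) pairs at m0 = 1.
# State matrices have one row per parameter set and one column per
# isochromat, so per-parameter relaxation factors recycle down columns.
fisp_batch_unit <- function(r1, r2, spec) {
  np <- length(r1)
  nt <- length(spec$flip_train)
  n_iso <- spec$n_isochromats
  e2te <- exp(-spec$te * r2)
  e2tr <- exp(-(spec$tr - spec$te) * r2)
  e1te <- exp(-spec$te * r1)
  e1tr <- exp(-(spec$tr - spec$te) * r1)

  mp <- matrix(0 + 0i, np, n_iso)
  mz <- matrix(-spec$inv_efficiency, np, n_iso)
  mz <- 1 + (mz - 1) * exp(-spec$ti * r1)
  spoil <- matrix(exp(2i * pi * seq_len(n_iso) / n_iso), np, n_iso, byrow = TRUE)

  a <- spec$flip_train
  c2 <- cos(a / 2)^2; s2 <- sin(a / 2)^2; sa <- sin(a); ca <- cos(a)
  sig <- matrix(0 + 0i, np, nt)
  for (t in seq_len(nt)) {
    # rotation by a[t] about a fixed transverse axis, complex-transverse form
    mp_new <- mp * c2[t] + Conj(mp) * s2[t] - 1i * sa[t] * mz
    mz <- sa[t] * Im(mp) + ca[t] * mz
    mp <- mp_new
    mp <- mp * e2te
    mz <- 1 + (mz - 1) * e1te
    sig[, t] <- rowMeans(mp)
    mp <- mp * e2tr
    mz <- 1 + (mz - 1) * e1tr
    mp <- mp * spoil
  }
  sig
}

#' Simulate a FISP fingerprint
#'
#' Isochromat-ensemble Bloch simulation of the inversion-recovery FISP
#' sequence: thermal-equilibrium start, inversion with the specified
#' efficiency, relaxation for `ti`, then per excitation a rotation about a
#' fixed transverse axis, relaxation to the echo time where the complex
#' isochromat-averaged transverse magnetization is recorded, relaxation for
#' the rest of the TR, and deterministic spoiler dephasing
#' `2*pi*j/n_isochromats` about the longitudinal axis. The signal is linear
#' in `m0`, and multiplying `m0` by a phase rotates the whole fingerprint by
#' that phase.
#'
#' @param theta A [parameter_vector()].
#' @param spec A [fisp_spec()].
#' @return Complex fingerprint of length `length(flip_train)`.
#' @export
fisp_signal <- function(theta, spec) {
  if (length(spec$flip_train) == 0L) abort("empty sequence")
  theta$m0 * as.vector(fisp_batch_unit(theta$r1, theta$r2, spec))
}

# ---------------------------------------------------------------------------
# Model objects: a uniform (signal, jacobian) surface for downstream code.

#' Signal model objects
#'
#' `toy_model()` and `fisp_model()` wrap a sequence specification into a
#' model object with a uniform surface: [model_signal()] evaluates one
#' fingerprint, [model_signal_batch()] evaluates a whole parameter table
#' (vectorized over grid points for the FISP simulator), and
#' [model_jacobian()] returns the fingerprint Jacobian with respect to
#' `(m0, r1, r2)` — analytic for the toy model, central finite differences
#' for FISP.
#'
#' @param spec A [toy_ir_spec()] or [fisp_spec()].
#' @return A model object of class `"toy_model"` or `"fisp_model"`, both
#'   inheriting from `"signal_model"`.
#' @export
toy_model <- function(spec = toy_ir_spec()) {
  structure(list(spec = spec), class = c("toy_model", "signal_model"))
}

#' @rdname toy_model
#' @export
fisp_model <- function(spec = fisp_spec()) {
  structure(list(spec = spec), class = c("fisp_model", "signal_model"))
}

#' Evaluate a signal model
#'
#' @param model A model from [toy_model()] or [fisp_model()].
#' @param theta A [parameter_vector()].
#' @return Complex fingerprint vector.
#' @export
model_signal <- function(model, theta) UseMethod("model_signal")

#' @export
model_signal.toy_model <- function(model, theta) toy_signal(theta, model$spec)

#' @export
model_signal.fisp_model <- function(model, theta) fisp_signal(theta, model$spec)

#' Evaluate a model over a parameter table
#'
#' @param model A model object.
#' @param theta_table Tibble/data frame with numeric columns `r1`, `r2` and
#'   optionally a complex `m0` column (default 1).
#' @return Complex matrix, one column per table row (`N_T x N_s`).
#' @export
model_signal_batch <- function(model, theta_table) UseMethod("model_signal_batch")

batch_m0 <- function(theta_table) {
  if ("m0" %in% names(theta_table)) as.complex(theta_table$m0) else
    rep(1 + 0i, nrow(theta_table))
}

#' @export
model_signal_batch.toy_model <- function(model, theta_table) {
  s <- vapply(seq_len(nrow(theta_table)), function(i) {
    toy_signal(parameter_vector(m0 = batch_m0(theta_table)[i],
                                r1 = theta_table$r1[i], r2 = theta_table$r2[i]),
               model$spec)
  }, complex(model$spec$n_ir + model$spec$n_decay))
  as_complex_matrix(s)
}

#' @export
model_signal_batch.fisp_model <- function(model, theta_table) {
  sig <- fisp_batch_unit(theta_table$r1, theta_table$r2, model$spec)
  s <- t(sig) * rep(batch_m0(theta_table), each = length(model$spec$flip_train))
  as_complex_matrix(s)
}

#' Model Jacobian with respect to (m0, r1, r2)
#'
#' @inheritParams model_signal
#' @param h_rel Relative finite-difference step (finite-difference backends).
#' @return Complex `N_T x 3` matrix with columns `m0`, `r1`, `r2`.
#' @export
model_jacobian <- function(model, theta, h_rel = 1e-5) UseMethod("model_jacobian")

#' @export
model_jacobian.toy_model <- function(model, theta, h_rel = 1e-5) {
  toy_jacobian(theta, model$spec)
}

#' @export
model_jacobian.fisp_model <- function(model, theta, h_rel = 1e-5) {
  finite_diff_jacobian(function(th) model_signal(model, th), theta, h_rel)
}

#' Central finite-difference Jacobian of a signal model
#'
#' Differentiates a fingerprint model with respect to `(m0, r1, r2)` using
#' central differences with per-parameter step
#' `h_p = h_rel * max(|theta_p|, theta_scale_p)`. The complex scale `m0` is
#' treated as a single complex parameter (the models are linear in `m0`, so a
#' real-axis step recovers the exact complex derivative `s / m0`).
#'
#' @param model_fun Function mapping a [parameter_vector()] to a fingerprint.
#' @param theta A [parameter_vector()].
#' @param h_rel Relative step size (`> 0`).
#' @param theta_scale Per-parameter floor for the absolute step, recycled to
#'   length 3; guards parameters near zero.
#' @return Complex matrix with columns `m0`, `r1`, `r2`.
#' @export
finite_diff_jacobian <- function(model_fun, theta, h_rel = 1e-5, theta_scale = 1) {
  stopifnot(h_rel > 0)
  theta_scale <- rep_len(theta_scale, 3L)
  vals <- c(Mod(theta$m0), theta$r1, theta$r2)
  h <- h_rel * pmax(abs(vals), theta_scale)
  if (any(vals + h == vals)) abort("finite-difference step underflow")

  shift <- function(which, delta) {
    th <- theta
    th[[which]] <- th[[which]] + delta
    th
  }
  cols <- lapply(seq_along(param_names()), function(p) {
    nm <- param_names()[p]
    (model_fun(shift(nm, h[p])) - model_fun(shift(nm, -h[p]))) / (2 * h[p])
  })
  j <- do.call(cbind, cols)
  colnames(j) <- param_names()
  as_complex_matrix(j)
}

# Batch Jacobians for every row of a parameter table: 6 batch evaluations
# for the rate derivatives plus the exact m0 column s / m0.
model_jacobian_batch <- function(model, theta_table, h_rel = 1e-5,
                                 theta_scale = 1) {
  s <- model_signal_batch(model, theta_table)
  m0 <- batch_m0(theta_table)
  n_t <- nrow(s)
  perturbed <- function(par, sgn) {
    tab <- theta_table
    h <- h_rel * pmax(abs(tab[[par]]), theta_scale)
    tab[[par]] <- tab[[par]] + sgn * h
    list(sig = model_signal_batch(model, tab), h = h)
  }
  jr <- lapply(c("r1", "r2"), function(par) {
    up <- perturbed(par, +1)
    dn <- perturbed(par, -1)
    (up$sig - dn$sig) / rep(up$h + dn$h, each = n_t)
  })
  lapply(seq_len(nrow(theta_table)), function(i) {
    j <- cbind(m0 = s[, i] / m0[i], r1 = jr[[1L]][, i], r2 = jr[[2L]][, i])
    as_complex_matrix(j)
  })
}
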