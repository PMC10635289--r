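# The committed FISP study scenario: a scaled-down three-tissue dictionary
# (GM+WM, fat, CSF blocks) driven by the default 500-pulse flip train, a
# 67/33 basis/test split, rank-3 bases at several CRB weightings, and a fine
# white-matter matching grid. Built lazily and cached for the session
# because several test files evaluate different facets of the same scenario.

.scenario_cache <- new.env(parent = emptyenv())

scenario_theta_table <- function() {
  dplyr::bind_rows(
    build_grid(parameter_grid(t1 = c(500, 40, 1460), t2 = c(10, 10, 180))),
    build_grid(parameter_grid(t1 = c(250, 75, 550), t2 = c(60, 20, 140))),
    build_grid(parameter_grid(t1 = c(3000, 500, 5000), t2 = c(1500, 250, 2500)))
  )
}

fisp_scenario <- function() {
  if (!is.null(.scenario_cache$s)) return(.scenario_cache$s)
  model <- fisp_model(fisp_spec())
  dict <- simulate_dictionary(model, scenario_theta_table())
  parts <- split_train_test(dict, fraction = 0.67, seed = 101L)
  jac_train <- crbsvd:::model_jacobian_batch(model, parts$train$theta)
  jac_test <- crbsvd:::model_jacobian_batch(model, parts$test$theta)
  ortho_train <- build_ortho_set(jac_train)
  bases <- lapply(c(0, 0.3, 0.5), function(lam)
    crb_svd(parts$train, ortho_train, lambda = lam, n_c = 3))
  names(bases) <- c("l0", "l03", "l05")
  truth <- toy_wm_theta()
  .scenario_cache$s <- list(
    model = model, dict = dict, train = parts$train, test = parts$test,
    jac_train = jac_train, jac_test = jac_test, ortho_train = ortho_train,
    bases = bases, truth = truth,
    j_truth = model_jacobian(model, truth),
    noise = noise_model(snr = 50)
  )
  .scenario_cache$s
}

# Fine white-matter matching dictionary (step below the expected parameter
# noise at SNR 50).
fisp_matching_dictionary <- function() {
  if (!is.null(.scenario_cache$mdict)) return(.scenario_cache$mdict)
  sc <- fisp_scenario()
  .scenario_cache$mdict <- simulate_dictionary(
    sc$model, parameter_grid(t1 = c(600, 5, 1050), t2 = c(10, 1, 60)))
  .scenario_cache$mdict
}

# Full lambda x Nc quality sweep of the scenario dictionary.
fisp_scenario_sweep <- function() {
  if (!is.null(.scenario_cache$sweep)) return(.scenario_cache$sweep)
  sc <- fisp_scenario()
  .scenario_cache$sweep <- sweep_report(sc$model, sc$dict,
                                        lambdas = seq(0, 0.9, by = 0.1),
                                        n_cs = 3:10, seed = 101L)
  .scenario_cache$sweep
}

# Seeded Monte-Carlo arm of the scenario under a given basis.
fisp_scenario_mc <- function(basis, n_reps = 200L) {
  sc <- fisp_scenario()
  cdict <- compress_dictionary(fisp_matching_dictionary(), basis)
  monte_carlo(sc$model, sc$truth, basis, sc$noise, n_reps = n_reps,
              estimator = "match", seed = 7L, cdict = cdict)
}

# Three-region phantom on scenario grid points, shared by the recon tests.
scenario_phantom_spec <- function(side = 32L) {
  reg <- function(shape, theta_ms, ...) {
    c(list(shape = shape,
           theta = parameter_vector(r1 = 1000 / theta_ms[1],
                                    r2 = 1000 / theta_ms[2])),
      list(...))
  }
  phantom_spec(side, list(
    reg("disc", c(700, 60), center = c(12, 12), radius = 7),
    reg("disc", c(1100, 90), center = c(22, 21), radius = 6),
    reg("rect", c(860, 30), xlim = c(6, 14), ylim = c(22, 28))
  ))
}
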