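toy_test_dictionary <- function() {
  model <- toy_model()
  tab <- build_grid(parameter_grid(.explicit = list(
    r1 = seq(0.6, 2.0, length.out = 5), r2 = seq(8, 100, length.out = 5))))
  list(model = model, dict = simulate_dictionary(model, tab), theta = tab)
}

test_that("traditional SVD basis captures signal energy optimally", {
  # rank-1 dictionary: the single basis vector is the normalized fingerprint
  s1 <- matrix(rep(c(1, 2i, -1), 4), 3, 4)
  b1 <- traditional_svd(s1, 1)
  fp <- c(1, 2i, -1) / sqrt(6)
  phase <- b1$u[which.max(Mod(b1$u)), 1] / fp[which.max(Mod(fp))]
  expect_rel_equal(b1$u[, 1], fp * phase, 1e-10)

  withr::with_seed(61, {
    s <- rcomplex_mat(20, 50)
    b5 <- traditional_svd(s, 5)
    # captured energy vs brute-force eigendecomposition of the Gram matrix
    ev <- sort(Re(eigen(s %*% cth(s), symmetric = TRUE)$values), decreasing = TRUE)
    expect_rel_equal(sum(b5$singular_values[1:5]^2) / sum(b5$singular_values^2),
                     sum(ev[1:5]) / sum(ev), 1e-10)
    # full-rank basis represents the dictionary exactly
    b20 <- traditional_svd(s, 20)
    expect_lt(signal_energy_loss(s, b20), 1e-10)
  })
  expect_error(traditional_svd(s1, 0), "n_c")
  expect_error(traditional_svd(s1, 9), "n_c")
})

test_that("CRB-SVD reduces to the traditional SVD at lambda = 0", {
  tt <- toy_test_dictionary()
  jacs <- crbsvd:::model_jacobian_batch(tt$model, tt$theta)
  os <- build_ortho_set(jacs)
  for (nc in c(3, 6)) {
    b_tr <- traditional_svd(tt$dict, nc)
    b_crb <- crb_svd(tt$dict, os, lambda = 0, n_c = nc)
    expect_lt(max_principal_angle_sin(b_tr$u, b_crb$u), 1e-8)
  }
})

test_that("CRB-SVD matches a brute-force Gram eigendecomposition", {
  withr::with_seed(62, {
    s <- rcomplex_mat(12, 6)
    jp <- rcomplex_mat(12, 4)
    jp <- sweep(jp, 2, sqrt(colSums(Mod(jp)^2)), "/")
    lam <- 0.4
    b <- crb_svd(s, jp, lambda = lam, n_c = 5)
    d <- cbind((1 - lam) * s, lam * jp)
    eg <- eigen(d %*% cth(d))
    for (k in 1:5) {
      v <- eg$vectors[, k]
      # align phases before comparison
      ph <- sum(Conj(v) * b$u[, k])
      ph <- ph / Mod(ph)
      expect_rel_equal(b$u[, k], v * ph, 1e-8)
    }
    # singular values consistent with Gram eigenvalues
    expect_rel_equal(b$singular_values[1:5]^2, Re(eg$values[1:5]), 1e-8)
  })
})

test_that("CRB-SVD guards rank, warns at lambda = 1, and scales freely", {
  withr::with_seed(63, {
    s <- rcomplex_mat(10, 3)
    jp <- rcomplex_mat(10, 2)
    expect_error(crb_svd(s, jp, lambda = 0.5, n_c = 8), "numerical rank")
    expect_warning(crb_svd(s, jp, lambda = 1, n_c = 2), "lambda = 1")

    # scaling property: D and [S, lambda/(1-lambda) Jp] share left singular vectors
    lam <- 0.3
    b <- crb_svd(s, jp, lambda = lam, n_c = 4)
    b2 <- svd(cbind(s, (lam / (1 - lam)) * jp), nu = 4)$u
    expect_lt(max_principal_angle_sin(b$u, b2), 1e-8)
  })
})

test_that("near-full-rank CRB-SVD basis is lossless on its generating set", {
  tt <- toy_test_dictionary()
  parts <- split_train_test(tt$dict, 0.67, seed = 3)
  jacs <- crbsvd:::model_jacobian_batch(tt$model, parts$train$theta)
  os <- build_ortho_set(jacs)
  # smooth exponential families are numerically rank deficient: truncate at
  # the numerical rank of D rather than N_T
  probe <- crb_svd(parts$train, os, lambda = 0.5, n_c = 1)
  rank_d <- sum(probe$singular_values > 1e-10 * probe$singular_values[1])
  b <- crb_svd(parts$train, os, lambda = 0.5, n_c = rank_d)
  expect_lt(signal_energy_loss(parts$train, b), 1e-9)
  tab <- crb_table(jacs, b)
  losses <- crb_losses(tab)
  expect_lt(abs(losses$delta_b_ac), 1e-9)
  expect_lt(abs(losses$delta_b_ec), 1e-9)
})

test_that("compression and projection satisfy the orthonormal-basis identities", {
  withr::with_seed(64, {
    u <- runitary_basis(15, 4)
    b <- crbsvd:::new_subspace_basis(u, lambda = 0, singular_values = rep(1, 4))
    s <- as.vector(rcomplex_mat(15, 1))

    # basis column maps to a unit coordinate vector
    ck <- compress(b$u[, 2], b)
    expect_rel_equal(ck, c(0, 1, 0, 0) + 0i, 1e-10)

    # orthogonal input annihilates
    s_orth <- s - b$u %*% (cth(b$u) %*% s)
    expect_lt(max(Mod(compress(s_orth, b))), 1e-10)

    # Pythagoras: coefficient energy + residual energy = signal energy
    c1 <- compress(s, b)
    resid <- s - project(s, b)
    expect_rel_equal(sum(Mod(c1)^2) + sum(Mod(resid)^2), sum(Mod(s)^2), 1e-10)

    # projection is idempotent, fixes points of the span, orthogonal residual
    p1 <- project(s, b)
    expect_rel_equal(project(p1, b), p1, 1e-12)
    expect_rel_equal(project(b$u[, 1], b), b$u[, 1], 1e-12)
    expect_lt(max(Mod(cth(b$u) %*% resid)), 1e-10)
  })
})

test_that("basis computation is deterministic under the phase convention", {
  tt <- toy_test_dictionary()
  jacs <- crbsvd:::model_jacobian_batch(tt$model, tt$theta)
  os <- build_ortho_set(jacs)
  b1 <- crb_svd(tt$dict, os, lambda = 0.3, n_c = 5)
  b2 <- crb_svd(tt$dict, os, lambda = 0.3, n_c = 5)
  expect_identical(b1$u, b2$u)
  # phase convention: largest entry of every column real positive
  for (k in 1:5) {
    top <- b1$u[which.max(Mod(b1$u[, k])), k]
    expect_lt(abs(Arg(top)), 1e-12)
  }
})

test_that("lambda sweep endpoints show the energy/CRB trade-off", {
  tt <- toy_test_dictionary()
  parts <- split_train_test(tt$dict, 0.67, seed = 5)
  jac_train <- crbsvd:::model_jacobian_batch(tt$model, parts$train$theta)
  jac_test <- crbsvd:::model_jacobian_batch(tt$model, parts$test$theta)
  os <- build_ortho_set(jac_train)
  nc <- 4
  metrics <- lapply(c(0, 0.5, 0.9), function(lam) {
    b <- crb_svd(parts$train, os, lambda = lam, n_c = nc)
    list(loss = signal_energy_loss(parts$test, b),
         dbec = crb_losses(crb_table(jac_test, b))$delta_b_ec)
  })
  # signal loss grows from the lambda = 0 endpoint to lambda = 0.9
  expect_lte(metrics[[1]]$loss, metrics[[3]]$loss)
  # the CRB loss at lambda = 0.5 improves on the traditional basis
  expect_lt(metrics[[2]]$dbec, metrics[[1]]$dbec)
})

test_that("tidy and glance summarize a basis", {
  tt <- toy_test_dictionary()
  b <- traditional_svd(tt$dict, 3)
  td <- tidy(b)
  expect_s3_class(td, "tbl_df")
  expect_equal(sum(td$retained), 3L)
  expect_equal(sum(td$energy_fraction), 1, tolerance = 1e-12)
  gl <- glance(b)
  expect_equal(gl$n_c, 3L)
  expect_gt(gl$captured_energy, 0.99)  # toy dictionary is highly compressible
})
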