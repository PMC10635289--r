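test_that("orthogonalized derivative agrees with hand and normal-equations projections", {
  # hand example: remove the component of (1,1,0) along (0,1,0)
  j <- cbind(c(1, 1, 0), c(0, 1, 0)) + 0i
  expect_equal(orthogonalized_derivative(j, 1), c(1, 0, 0) + 0i, tolerance = 1e-12)

  # mutually orthogonal columns pass through unchanged
  jo <- cbind(c(1, 0, 0, 0), c(0, 2, 0, 0), c(0, 0, 3i, 0))
  for (i in 1:3) {
    expect_equal(orthogonalized_derivative(jo, i), jo[, i], tolerance = 1e-12)
  }

  # explicit projector oracle on random complex Jacobians
  withr::with_seed(11, {
    for (rep in 1:5) {
      j <- rcomplex_mat(12, 4)
      for (i in 1:4) {
        expect_rel_equal(orthogonalized_derivative(j, i),
                         projector_oracle(j, i), 1e-10)
      }
    }
  })

  # duplicated column makes the parameter unidentifiable
  jd <- cbind(c(1, 2, 3), c(1, 2, 3)) + 0i
  expect_error(orthogonalized_derivative(jd, 1), "degenerate")
})

test_that("ortho set bookkeeping: unit norms, nuisance projection, index map", {
  model <- toy_model(toy_ir_spec(n_ir = 6, n_decay = 6))
  tab <- tibble::tibble(r1 = seq(0.6, 1.4, 0.2), r2 = seq(15, 55, 10))
  jacs <- lapply(seq_len(5), function(i)
    model_jacobian(model, parameter_vector(r1 = tab$r1[i], r2 = tab$r2[i])))
  os <- build_ortho_set(jacs, interest = c("r1", "r2"))

  expect_equal(dim(os$matrix), c(12L, 10L))
  expect_true(all(abs(sqrt(colSums(Mod(os$matrix)^2)) - 1) < 1e-9))
  expect_equal(nrow(os$index_map), 10L)
  expect_false(anyDuplicated(os$index_map[c("fingerprint", "parameter")]) > 0)

  # every column is orthogonal to its fingerprint's other derivatives,
  # in particular to the m0 (signal) direction
  for (k in seq_len(10)) {
    f <- os$index_map$fingerprint[k]
    s <- model_signal(model, parameter_vector(r1 = tab$r1[f], r2 = tab$r2[f]))
    expect_lt(Mod(sum(Conj(s / sqrt(cnorm2_test(s))) * os$matrix[, k])), 1e-8)
  }

  # degenerate fingerprint is reported by id
  jac_bad <- jacs
  jac_bad[[3]][, "r1"] <- jac_bad[[3]][, "m0"]
  expect_error(build_ortho_set(jac_bad), "fingerprint 3")
})

test_that("sequential-QR orthogonalization variant stays consistent", {
  withr::with_seed(4, {
    j <- rcomplex_mat(10, 3)
    colnames(j) <- c("m0", "r1", "r2")
    os_qr <- build_ortho_set(list(j), method = "qr")
    expect_true(all(abs(sqrt(colSums(Mod(os_qr$matrix)^2)) - 1) < 1e-9))
    # last column agrees with the complement projector (same complement)
    os_c <- build_ortho_set(list(j), method = "complement")
    expect_rel_equal(os_qr$matrix[, 2], os_c$matrix[, 2], 1e-8)
  })
  # orthogonal Jacobian: both variants reduce to plain normalization
  jo <- cbind(m0 = c(1, 0, 0, 0), r1 = c(0, 2, 0, 0), r2 = c(0, 0, 5, 0)) + 0i
  expect_equal(build_ortho_set(list(jo), method = "qr")$matrix,
               build_ortho_set(list(jo), method = "complement")$matrix,
               tolerance = 1e-12)
})

test_that("uncompressed CRB equals the Fisher-inverse route", {
  # orthonormal columns give sigma^2 exactly
  j <- cbind(c(1, 0, 0), c(0, 1, 0)) + 0i
  expect_equal(unname(crb_uncompressed(j, sigma = 0.5)), c(0.25, 0.25),
               tolerance = 1e-12)

  # single-parameter model: sigma^2 / ||j||^2
  j1 <- matrix(c(1, 2i, 2), ncol = 1)
  expect_equal(unname(crb_uncompressed(j1)), 1 / 9, tolerance = 1e-12)

  withr::with_seed(21, {
    j <- rcomplex_mat(16, 4)
    expect_rel_equal(unname(crb_uncompressed(j, sigma = 0.7)),
                     fisher_crb_oracle(j, 0.7), 1e-8)
  })

  expect_error(crb_uncompressed(cbind(c(1, 1), c(1, 1)) + 0i), "rank-deficient")
})

test_that("exact compressed CRB equals the compressed Fisher route", {
  withr::with_seed(22, {
    j <- rcomplex_mat(16, 3)
    u <- runitary_basis(16, 5)
    expect_rel_equal(unname(crb_exact_compressed(j, u, sigma = 1.3)),
                     fisher_crb_oracle(cth(u) %*% j, 1.3), 1e-8)

    # basis spanning the Jacobian leaves the CRB unchanged
    uj <- svd(j)$u
    expect_rel_equal(unname(crb_exact_compressed(j, uj)),
                     unname(crb_uncompressed(j)), 1e-10)
  })

  # lossless 2-column example
  j2 <- cbind(c(1, 0, 0), c(0, 1, 0)) + 0i
  expect_equal(unname(crb_exact_compressed(j2, j2, sigma = 0.5)), c(0.25, 0.25),
               tolerance = 1e-12)

  # compression that collapses the two derivatives together
  jc <- cbind(c(1, 0, 0), c(0, 1, 0)) + 0i
  u1 <- matrix(c(1, 1, 0) / sqrt(2), ncol = 1) + 0i
  expect_error(crb_exact_compressed(jc, u1), "unidentifiable")
})

test_that("approximate compressed CRB brackets between B_u and B_ec", {
  withr::with_seed(23, {
    j <- rcomplex_mat(20, 3)
    uj <- svd(j)$u
    expect_rel_equal(unname(crb_approx_compressed(j, uj)),
                     unname(crb_uncompressed(j)), 1e-10)

    # subspace orthogonal to the derivative -> infinite bound
    null_dir <- svd(j)$u  # span of J
    u_orth <- svd(diag(20) - null_dir %*% cth(null_dir))$u[, 1:4]
    expect_error(crb_approx_compressed(j[, 1, drop = FALSE], u_orth), "infinite")

    for (rep in 1:25) {
      j <- rcomplex_mat(16, 3)
      u <- runitary_basis(16, 6)
      b_u <- crb_uncompressed(j)
      b_ac <- crb_approx_compressed(j, u)
      b_ec <- crb_exact_compressed(j, u)
      expect_true(all(b_u <= b_ac * (1 + 1e-8)))
      expect_true(all(b_ac <= b_ec * (1 + 1e-8)))
    }
  })
})

test_that("toy-model CRB matches a hand-summed 3x3 Fisher inverse", {
  spec <- toy_ir_spec(n_ir = 4, dt_ir = 0.3, n_decay = 5, dt_decay = 0.02)
  th <- parameter_vector(r1 = 1.1, r2 = 35)
  j <- toy_jacobian(th, spec)
  # explicit real 3x3 Fisher matrix assembled element by element
  f <- matrix(0, 3, 3)
  for (a in 1:3) for (b in 1:3) f[a, b] <- Re(sum(Conj(j[, a]) * j[, b]))
  expect_rel_equal(unname(crb_uncompressed(j, sigma = 2)),
                   4 * diag(solve(f)), 1e-10)
})

test_that("CRB losses, Frobenius identity and optimality ratio", {
  model <- toy_model(toy_ir_spec(n_ir = 8, n_decay = 8))
  tab <- tibble::tibble(r1 = c(0.7, 1.0, 1.5), r2 = c(20, 35, 60))
  jacs <- lapply(seq_len(3), function(i)
    model_jacobian(model, parameter_vector(r1 = tab$r1[i], r2 = tab$r2[i])))
  os <- build_ortho_set(jacs)

  # lossless basis: all ratios one
  u_full <- svd(cbind(do.call(cbind, jacs)))$u
  tab_full <- crb_table(jacs, u_full)
  losses_full <- crb_losses(tab_full)
  expect_lt(abs(losses_full$delta_b_ac), 1e-9)
  expect_lt(abs(losses_full$delta_b_ec), 1e-9)
  expect_equal(optimality_ratio(tab_full), 1, tolerance = 1e-9)

  # lossy basis: inequality and the Frobenius-residual identity
  u3 <- withr::with_seed(31, runitary_basis(16, 3))
  ct3 <- crb_table(jacs, u3)
  losses <- crb_losses(ct3)
  expect_lte(losses$delta_b_ac, losses$delta_b_ec + 1e-10)
  frob <- sum(Mod(os$matrix - u3 %*% (cth(u3) %*% os$matrix))^2)
  expect_rel_equal(losses$delta_b_ac, frob, 1e-8)
  expect_lte(optimality_ratio(ct3), 1 + 1e-10)

  # hand-built ratio arithmetic
  hand <- tibble::tibble(fingerprint = 1:3, parameter = "r1",
                         b_u = c(1, 2, 3) / 2, b_ac = c(1, 2, 3),
                         b_ec = c(2, 2, 6), sigma = 1)
  expect_equal(optimality_ratio(hand), 2 / 3, tolerance = 1e-14)
})

test_that("compressed bounds are invariant to unitary mixing of the basis", {
  withr::with_seed(41, {
    j <- rcomplex_mat(18, 3)
    u <- runitary_basis(18, 5)
    q <- svd(rcomplex_mat(5, 5))$u  # random unitary
    uq <- u %*% q
    expect_rel_equal(unname(crb_approx_compressed(j, uq)),
                     unname(crb_approx_compressed(j, u)), 1e-8)
    expect_rel_equal(unname(crb_exact_compressed(j, uq)),
                     unname(crb_exact_compressed(j, u)), 1e-8)
  })
})

test_that("bounds are non-increasing in subspace size for nested SVD bases", {
  model <- toy_model()
  tab <- tibble::tibble(r1 = c(0.8, 1.2, 1.8), r2 = c(25, 40, 80))
  d <- simulate_dictionary(model, tab)
  jacs <- lapply(seq_len(3), function(i)
    model_jacobian(model, parameter_vector(r1 = tab$r1[i], r2 = tab$r2[i])))
  os <- build_ortho_set(jacs)
  full <- crb_svd(d, os, lambda = 0.4, n_c = 8)
  prev <- NULL
  for (nc in 3:8) {
    u <- full$u[, seq_len(nc), drop = FALSE]
    ct_nc <- crb_table(jacs, u)
    if (!is.null(prev)) {
      expect_true(all(ct_nc$b_ec <= prev$b_ec * (1 + 1e-10)))
      expect_true(all(ct_nc$b_ac <= prev$b_ac * (1 + 1e-10)))
    }
    prev <- ct_nc
  }
})

test_that("signal energy loss obeys the Pythagorean identity", {
  withr::with_seed(51, {
    s <- rcomplex_mat(14, 9)
    u <- runitary_basis(14, 4)
    loss <- signal_energy_loss(s, u)
    expect_rel_equal(loss, 1 - sum(Mod(cth(u) %*% s)^2) / sum(Mod(s)^2), 1e-10)
    expect_gte(loss, 0); expect_lte(loss, 1)

    # span of the dictionary -> no loss; orthogonal complement -> total loss
    us <- svd(s)$u
    expect_lt(signal_energy_loss(s, us), 1e-12)
    u_orth <- svd(diag(14) - us %*% cth(us))$u[, 1:3]
    expect_equal(signal_energy_loss(s, u_orth), 1, tolerance = 1e-10)
  })
  expect_error(signal_energy_loss(matrix(0 + 0i, 4, 2), runitary_basis(4, 1)),
               "zero-energy")
})
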