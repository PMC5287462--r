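# Effective connectivity, parameter sensitivities, and the eigenmode
# decomposition of the predicted fixed-point shift.

test_that("zero recurrent connectivity gives a zero effective connectivity", {
  net <- network_model(K = matrix(0, 2, 2), J = matrix(87.8, 2, 2),
                       K_ext = 140, J_ext = 87.8, nu_ext = 40)
  fp <- find_stable_fixed_point(net)
  lr <- effective_connectivity(net, fp)
  expect_equal(lr$M, matrix(0, 2, 2), ignore_attr = TRUE)
  expect_equal(Re(lr$lambdas), c(0, 0), ignore_attr = TRUE)
  expect_equal(Im(lr$lambdas), c(0, 0), ignore_attr = TRUE)
})

test_that("M equals the finite-difference Jacobian of the gain map", {
  net <- build_single_pop()
  for (fp in enumerate_fixed_points(net)[c(2, 3)]) {
    lr <- effective_connectivity(net, fp, residual_tol = 1e-6)
    J_fd <- fd_jacobian(net, fp$nu_star)
    expect_lt(max(abs(lr$M - J_fd)) / max(abs(J_fd)), 1e-4)
  }
  net10 <- build_random_multipop(6, seed = 3)
  fp <- find_stable_fixed_point(net10, nu0 = rep(400, 6))
  lr <- effective_connectivity(net10, fp)
  J_fd <- fd_jacobian(net10, fp$nu_star)
  expect_lt(max(abs(lr$M - J_fd)) / max(abs(J_fd)), 1e-4)
})

test_that("stability labels agree with the spectrum of M", {
  net <- build_single_pop()
  fps <- enumerate_fixed_points(net)
  res <- vapply(fps, function(fp) {
    lr <- effective_connectivity(net, fp)
    max(Re(lr$lambdas))
  }, numeric(1))
  expect_lt(res[1], 1)   # LA
  expect_gt(res[2], 1)   # separatrix
  expect_lt(res[3], 1)   # HA
})

test_that("eigenpairs are bi-orthogonal, complete, and sorted", {
  net <- build_random_multipop(10, seed = 1)
  fp <- find_stable_fixed_point(net, nu0 = rep(400, 10))
  lr <- effective_connectivity(net, fp)
  N <- 10
  expect_lt(max(Mod(t(lr$V) %*% lr$U - diag(N))), 1e-10)
  comp <- matrix(0 + 0i, N, N)
  for (l in seq_len(N)) comp <- comp + lr$U[, l] %o% lr$V[, l]
  expect_lt(max(Mod(comp - diag(N))), 1e-8)
  expect_true(all(diff(Re(lr$lambdas)) <= 1e-12))
})

test_that("delta_bar vanishes for a zero perturbation and supports all kinds", {
  net <- build_random_multipop(4, seed = 2)
  fp <- find_stable_fixed_point(net, nu0 = rep(400, 4))
  for (kind in c("nu_ext", "K_ext", "K", "J")) {
    db <- delta_bar(net, fp, param_spec(kind))
    P <- switch(kind, nu_ext = 1L, K_ext = 4L, K = 16L, J = 16L)
    expect_identical(dim(db), c(4L, P))
    expect_equal(as.vector(db %*% rep(0, P)), rep(0, 4))
  }
})

test_that("indegree sensitivity is block sparse over target rows", {
  net <- build_random_multipop(3, seed = 5)
  fp <- find_stable_fixed_point(net, nu0 = rep(400, 3))
  db <- delta_bar(net, fp, param_spec("K"))
  N <- 3
  for (i in seq_len(N)) for (l in seq_len(N * N)) {
    in_row_block <- l > (i - 1) * N && l <= i * N
    if (!in_row_block)
      expect_identical(db[i, l], 0)
  }
  # within-block entries match finite differences of the gain map
  h <- 1e-7
  for (i in seq_len(N)) for (j in seq_len(N)) {
    net2 <- net
    net2$K[i, j] <- net$K[i, j] + h
    net3 <- net
    net3$K[i, j] <- net$K[i, j] - h
    fd <- (phi_network(fp$nu_star, net2) -
           phi_network(fp$nu_star, net3)) / (2 * h)
    expect_lt(max(abs(db[, (i - 1) * N + j] - fd)), 1e-5)
  }
})

test_that("external-rate sensitivity matches a finite difference", {
  net <- build_random_multipop(4, seed = 2)
  fp <- find_stable_fixed_point(net, nu0 = rep(400, 4))
  db <- delta_bar(net, fp, param_spec("nu_ext"))
  h <- 1e-5
  net2 <- net
  net2$nu_ext <- net$nu_ext + h
  net3 <- net
  net3$nu_ext <- net$nu_ext - h
  fd <- (phi_network(fp$nu_star, net2) - phi_network(fp$nu_star, net3)) / (2 * h)
  expect_lt(max(abs(db[, 1] - fd)) / max(abs(fd)), 1e-6)
})

test_that("mode contributions are real, complete, and sum to one", {
  net <- build_random_multipop(10, seed = 1)
  for (nu0 in list(NULL, rep(400, 10))) {
    fp <- find_stable_fixed_point(net, nu0 = nu0)
    lr <- effective_connectivity(net, fp)
    db <- delta_bar(net, fp, param_spec("nu_ext"))
    sh <- predict_shift(lr, db, 0.01 * net$nu_ext)
    expect_lt(abs(sum(sh$eta, na.rm = TRUE) - 1), 1e-8)
    expect_true(all(is.na(sh$eta) | abs(Im(sh$eta)) == 0))
    # representative entries cover every conjugate pair exactly once
    expect_identical(sum(is.na(sh$eta)), sum(sh$pair > 0) %/% 2L)
  }
})

test_that("a single mode carries the whole shift in one dimension", {
  net <- build_single_pop()
  fp <- find_stable_fixed_point(net)
  lr <- effective_connectivity(net, fp)
  sh <- predict_shift(lr, delta_bar(net, fp, param_spec("nu_ext")), 1)
  expect_equal(sh$eta, 1, tolerance = 1e-12)
})

test_that("predicted shifts converge quadratically to nonlinear re-solves", {
  net <- build_hetero_two_pop()
  u0 <- middle_root(net)
  lr <- effective_connectivity(net, u0)
  db <- delta_bar(net, u0, param_spec("nu_ext"))
  errs <- vapply(c(0.4, 0.2, 0.1), function(d) {
    predicted <- u0$nu_star + as.vector(solve(diag(2) - lr$M, db %*% d))
    actual <- middle_root(build_hetero_two_pop(nu_ext = 30 + d))$nu_star
    sqrt(sum((predicted - actual)^2))
  }, numeric(1))
  ratios <- errs[-length(errs)] / errs[-1]
  expect_true(all(ratios > 3 & ratios < 5))  # halving reduces error ~4x
})

test_that("degenerate shift inputs are rejected", {
  net <- build_single_pop()
  fp <- find_stable_fixed_point(net)
  lr <- effective_connectivity(net, fp)
  db <- delta_bar(net, fp, param_spec("nu_ext"))
  expect_error(predict_shift(lr, db, 0), "zero")
  expect_error(predict_shift(lr, db, c(1, 2)), "length")
  expect_error(effective_connectivity(net, middle_root(net)$nu_star * 1.5 + 3),
               NA)  # bare vectors are allowed as evaluation points
})
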