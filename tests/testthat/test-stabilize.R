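# Compensating parameter changes, eigenmode-restricted indegree
# modifications, constraints, and the iterative stabilization loop.

test_that("the one-population compensation reduces to the closed form", {
  net <- build_single_pop()
  u0 <- middle_root(net)
  d_nu <- 1
  dK <- compensate_scalar(net, u0, param_spec("nu_ext", d_nu),
                          param_spec("K"))
  closed <- -net$K_ext * d_nu / u0$nu_star
  expect_lt(abs(dK - closed) / abs(closed), 1e-8)
  # zero perturbation, zero compensation
  dK0 <- compensate_scalar(net, u0, param_spec("nu_ext", 0),
                           param_spec("K"))
  expect_equal(as.vector(dK0), 0)
})

test_that("compensation preserves the unstable point to second order", {
  net <- build_hetero_two_pop()
  u0 <- middle_root(net)
  resids <- vapply(c(1, 0.5, 0.25), function(d) {
    shifted <- build_hetero_two_pop(nu_ext = 30 + d)
    raw_shift <- mean(abs(middle_root(shifted)$nu_star - u0$nu_star))
    dK <- compensate_scalar(net, u0, param_spec("nu_ext", d),
                            param_spec("K"))
    comp <- shifted
    comp$K <- net$K + dK
    resid <- mean(abs(middle_root(comp)$nu_star - u0$nu_star))
    expect_lt(resid, 0.1 * raw_shift)
    resid
  }, numeric(1))
  ratios <- resids[-length(resids)] / resids[-1]
  expect_true(all(ratios > 3 & ratios < 5))  # quadratic in the perturbation
})

test_that("compensation restores the basin while the LA rate rises", {
  net <- build_single_pop(nu_ext = 42)  # LA clearly away from zero
  u0 <- middle_root(net)
  la0 <- enumerate_fixed_points(net)[[1]]
  d <- 0.5
  dK <- compensate_scalar(net, u0, param_spec("nu_ext", d),
                          param_spec("K"))
  comp <- build_single_pop(nu_ext = 42 + d)
  comp$K <- net$K + dK
  fps <- enumerate_fixed_points(comp)
  expect_length(fps, 3)
  expect_lt(abs(fps[[2]]$nu_star - u0$nu_star), 1e-6)  # separatrix pinned
  expect_gt(fps[[1]]$nu_star, la0$nu_star)             # LA rate increased
})

test_that("mode-restricted modifications satisfy the substitution identity", {
  net <- build_random_multipop(10, seed = 1)
  fp <- find_stable_fixed_point(net, nu0 = rep(400, 10))
  lr <- effective_connectivity(net, fp)
  a_spec <- param_spec("nu_ext", 1)
  db_k <- delta_bar(net, fp, param_spec("K"))
  nu_hat <- as.vector(t(lr$V) %*% lr$nu)
  set.seed(11)
  mode_sets <- c(list(1L, seq_len(10)),
                 replicate(4, sort(sample(10, sample(2:6, 1))),
                           simplify = FALSE))
  for (modes in mode_sets) {
    plan <- suppressWarnings(
      indegree_mode_solution(net, fp, lr, a_spec, modes = modes))
    lhs <- as.vector(db_k %*% vectorize(plan$delta_K))
    sel <- plan$modes
    rhs <- Re(lr$U[, sel, drop = FALSE] %*%
              (plan$epsilons[sel] * nu_hat[sel]))
    expect_lt(max(abs(lhs - rhs)), 1e-8)
  }
  # no selected modes, no modification
  p0 <- indegree_mode_solution(net, fp, lr, a_spec, modes = integer(0))
  expect_equal(p0$delta_K, matrix(0, 10, 10))
})

test_that("a single real mode yields a rank-one change up to the row factor", {
  net <- build_two_pop()
  u0 <- middle_root(net)
  lr <- effective_connectivity(net, u0)
  plan <- indegree_mode_solution(net, u0, lr, param_spec("nu_ext", 1),
                                 modes = 1L)
  ew <- effective_weight_matrices(net)
  tm <- net$par$tau_m * 1e-3
  rowfac <- tm * (lr$S_vec * ew$w_mV + lr$T_vec * ew$w_mV^2)
  num <- plan$delta_K * rowfac
  expect_lt(svd(num)$d[2] / svd(num)$d[1], 1e-10)
})

test_that("critical-mode selection follows the unstable eigendirection", {
  net <- build_single_pop()
  u0 <- middle_root(net)
  lr_u <- effective_connectivity(net, u0)
  expect_identical(select_critical_mode(lr_u), 1L)
  expect_gt(Re(lr_u$lambdas[1]), 1)
  la <- enumerate_fixed_points(net)[[1]]
  lr_s <- effective_connectivity(net, la)
  expect_error(select_critical_mode(lr_s), "not unstable")
})

test_that("selection is by contribution when several modes are unstable", {
  # planted spectrum: diagonalizable M with two eigenvalues above 1
  U <- cbind(c(1, 0.2, 0), c(0.1, 1, 0.3), c(0, 0.2, 1))
  lam <- c(1.6, 1.2, 0.4)
  M <- U %*% diag(lam) %*% solve(U)
  lr <- structure(list(M = M, lambdas = as.complex(lam), U = U,
                       V = t(solve(U)), nu = c(10, 5, 2),
                       S_vec = rep(1, 3), T_vec = rep(0, 3)),
                  class = "linear_response")
  rhs <- c(1, 0, 0)
  dn <- solve(diag(3) - M, rhs)
  a_hat <- as.vector(t(lr$V) %*% rhs)
  eta <- Re((a_hat / (1 - lam)) * as.vector(dn %*% U) / sum(dn^2))
  sh <- structure(list(delta_nu_star = dn, eta = eta,
                       pair = integer(3), lambdas = as.complex(lam)),
                  class = "shift_prediction")
  sel <- suppressWarnings(select_critical_mode(lr, sh))
  expect_identical(sel, which.max(replace(eta, lam <= 1, -Inf)))
})

test_that("constraints zero forbidden entries and clip removals", {
  net <- build_layered_toy()
  # evaluate the linear response at a generic active working point
  nu_eval <- seq(2, 6, length.out = net$N)
  lr <- effective_connectivity(net, nu_eval)
  plan <- suppressWarnings(
    indegree_mode_solution(net, nu_eval, lr, param_spec("nu_ext", 5),
                           modes = 1:2))
  # all-permissive constraints change nothing
  p_id <- apply_constraints(plan, net, constraint_set(nonneg = FALSE),
                            lr = lr)
  expect_equal(p_id$delta_K, plan$delta_K)
  # anatomical rules: cross-area entries from inhibitory or layer-4
  # sources are frozen
  p_c <- apply_constraints(plan, net, cortical_constraints(), lr = lr)
  forb <- !p_c$mask
  expect_true(any(forb))
  expect_true(all(p_c$delta_K[forb] == 0))
  expect_true(all(net$K + p_c$delta_K >= -1e-12))
  lab <- net$labels
  cross <- outer(lab$area, lab$area, `!=`)
  bad_src <- matrix(lab$ei == "I" | startsWith(lab$layer, "4"),
                    net$N, net$N, byrow = TRUE)
  expect_identical(unname(forb), unname(cross & bad_src))
  # forced removal: an entry pushed below zero is clipped to exact removal
  plan2 <- plan
  plan2$delta_K <- matrix(0, net$N, net$N)
  plan2$delta_K[1, 2] <- -(net$K[1, 2] + 5)
  p_r <- apply_constraints(plan2, net, constraint_set())
  expect_equal(p_r$delta_K[1, 2], -net$K[1, 2])
  expect_true(p_r$removed[1, 2])
  expect_identical(sum(p_r$removed), 1L)
})

test_that("an already-stable network stabilizes in zero iterations", {
  net <- build_single_pop()
  res <- stabilize(net, kappa_target = 1.2, bisect_tol = 1e-4)
  expect_true(res$converged)
  expect_identical(res$iterations, 0L)
  expect_equal(res$network$K, net$K)
})

test_that("stabilization restores the LA basin at the target drive", {
  net <- build_two_pop()
  res <- stabilize(net, kappa_target = 1.7, localize_tol = 1e-8,
                   bisect_tol = 1e-5)
  expect_true(res$converged)
  expect_lte(res$iterations, 10L)
  expect_true(all(res$network$K >= 0))
  # flow from the inactive state at the target now reaches a low state
  tr <- integrate_flow(apply_drive_scaling(res$network,
                                           drive_scaling(1.7)))
  terminal <- tr$nu[nrow(tr$nu), ]
  expect_lt(mean(terminal), 100)
  # and its rates exceed the original LA rates
  la0 <- find_stable_fixed_point(net)
  expect_gt(mean(terminal), mean(la0$nu_star))
})

test_that("stabilization respects masked entries on a multi-population fixture", {
  net <- build_random_multipop(5, seed = 42)
  # freeze all indegree entries onto the first population
  frozen <- constraint_set(forbidden = function(labels) {
    N <- nrow(labels)
    m <- matrix(FALSE, N, N)
    m[1, ] <- TRUE
    m
  })
  res <- stabilize(net, kappa_target = 1.8, constraints = frozen,
                   localize_tol = 1e-8, bisect_tol = 1e-5)
  expect_true(res$converged)
  expect_lte(res$iterations, 10L)
  expect_equal(res$network$K[1, ], net$K[1, ])
  expect_true(all(res$network$K >= 0))
  tr <- integrate_flow(apply_drive_scaling(res$network,
                                           drive_scaling(1.8)))
  expect_lt(mean(tr$nu[nrow(tr$nu), ]), 100)
})
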