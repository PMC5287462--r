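# Independent oracles used across the suite. These deliberately avoid the
# package's own quadrature path: the reference rate integrates the raw
# integrand e^{x^2}(1 + erf(x)) with R's adaptive quadrature at tight
# tolerance, and root finding scans Phi(nu) - nu on a dense grid.

# High-precision reference for the stationary rate, valid while the raw
# integrand e^{x^2}(1 + erf(x)) = e^{x^2} erfc(-x) stays inside double
# range (integration bounds within about +-25). Adaptive Gauss-Kronrod on
# the unscaled product; the erfc form avoids the cancellation of 1 + erf
# at negative arguments.
siegert_oracle <- function(mu, sigma, params = neuron_params()) {
  tm <- params$tau_m * 1e-3
  tr <- params$tau_r * 1e-3
  shift <- abs(pracma::zeta(0.5)) / 2 * sqrt(params$tau_s / params$tau_m)
  a <- (params$V_r - mu) / sigma + shift
  b <- (params$theta - mu) / sigma + shift
  f <- function(x) exp(x^2) * pracma::erfc(-x)
  I <- stats::integrate(f, a, b, rel.tol = 1e-11, abs.tol = 0,
                        subdivisions = 2000L)$value
  1 / (tr + tm * sqrt(pi) * I)
}

# dense-grid root scan of the one-population self-consistency map
root_scan_1d <- function(network, n_grid = 4001L, nu_max = 499) {
  g <- function(nu) phi_network(nu, network) - nu
  nus <- seq(0, nu_max, length.out = n_grid)
  fv <- vapply(nus, g, numeric(1))
  idx <- which(fv[-1] * fv[-length(fv)] < 0)
  vapply(idx, function(i)
    stats::uniroot(g, c(nus[i], nus[i + 1]), tol = 1e-12)$root, numeric(1))
}

# central finite-difference Jacobian of the gain map at a rate vector
fd_jacobian <- function(network, nu, h = 1e-6) {
  N <- length(nu)
  J <- matrix(0, N, N)
  for (j in seq_len(N)) {
    e <- numeric(N)
    e[j] <- h
    J[, j] <- (phi_network(nu + e, network) - phi_network(nu - e, network)) / (2 * h)
  }
  J
}

# the unstable (middle) fixed point of a small network by enumeration
middle_root <- function(network) {
  fps <- enumerate_fixed_points(network)
  i <- which(vapply(fps, function(f) f$stability == "unstable", logical(1)))
  stopifnot(length(i) >= 1)
  fps[[i[1]]]
}

# two-population fixture with heterogeneous weights: compensation through
# the combined sensitivities is then genuinely first-order, so the
# residual shift of the unstable fixed point scales quadratically
build_hetero_two_pop <- function(nu_ext = 30) {
  network_model(
    K = matrix(c(80, 65, 55, 90), 2, 2, byrow = TRUE),
    J = matrix(c(87.8, 70, 62, 95), 2, 2, byrow = TRUE),
    K_ext = c(140, 130), J_ext = 87.8, nu_ext = nu_ext,
    labels = data.frame(pop = c("E1", "E2"), area = "A1", layer = "5E",
                        ei = "E"))
}
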