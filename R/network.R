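# Data model for multi-population LIF networks.

#' Multi-population LIF network model
#'
#' Bundles the population-level description consumed by all analyses: an
#' indegree matrix `K` (row = target population, column = source), a
#' synaptic weight matrix `J` of the same shape, per-population neuron
#' parameters, and an external Poisson drive (`K_ext`, `J_ext`, `nu_ext`).
#'
#' Weights are given in pA by default and converted internally to effective
#' post-synaptic potential amplitudes `w = J * tau_s / C_m` (mV), the
#' exponential-current convention in which the membrane resistance is
#' absorbed into the current. Set `weight_unit = "mV"` to supply effective
#' weights directly.
#'
#' @param K N x N indegree matrix (incoming synapses per target neuron);
#'   non-negative
#' @param J N x N synaptic weight matrix (pA unless `weight_unit = "mV"`);
#'   negative entries mark inhibitory sources
#' @param params a single [neuron_params()] shared by all populations, or a
#'   list of length N
#' @param K_ext external indegree per population (scalar recycled, or
#'   length-N vector)
#' @param J_ext external synaptic weight (same unit as `J`)
#' @param nu_ext rate of each external Poisson source (spikes/s)
#' @param labels optional data.frame with one row per population and any of
#'   the columns `pop`, `area`, `layer`, `ei`
#' @param pop_sizes optional neuron counts per population (needed for
#'   size-weighted area summaries)
#' @param ext_multiplier optional per-population multiplier on `K_ext`
#'   (e.g. for populations that receive enhanced external drive)
#' @param weight_unit `"pA"` (default) or `"mV"`
#' @return an object of class `network_model`
#' @examples
#' net <- build_single_pop()
#' net
#' @export
network_model <- function(K, J, params = neuron_params(), K_ext, J_ext,
                          nu_ext, labels = NULL, pop_sizes = NULL,
                          ext_multiplier = NULL,
                          weight_unit = c("pA", "mV")) {
  weight_unit <- match.arg(weight_unit)
  K <- as.matrix(K)
  J <- as.matrix(J)
  if (nrow(K) != ncol(K)) stop("network_model: K must be square")
  if (!identical(dim(K), dim(J)))
    stop("network_model: K and J must have identical shape")
  if (any(!is.finite(K)) || any(!is.finite(J)))
    stop("network_model: non-finite entries in K or J")
  if (any(K < 0)) stop("network_model: K must be non-negative")
  N <- nrow(K)
  if (inherits(params, "neuron_params")) params <- rep(list(params), N)
  if (!is.list(params) || length(params) != N ||
      !all(vapply(params, inherits, logical(1), "neuron_params")))
    stop("network_model: 'params' must be one neuron_params or a list of N")
  K_ext <- rep_len(as.numeric(K_ext), N)
  if (any(K_ext < 0)) stop("network_model: K_ext must be >= 0")
  if (length(nu_ext) != 1L || nu_ext < 0)
    stop("network_model: nu_ext must be a single non-negative rate")
  if (is.null(ext_multiplier)) ext_multiplier <- rep(1, N)
  ext_multiplier <- rep_len(as.numeric(ext_multiplier), N)
  if (is.null(labels)) labels <- data.frame(pop = paste0("p", seq_len(N)))
  if (!is.data.frame(labels) || nrow(labels) != N)
    stop("network_model: 'labels' must be a data.frame with N rows")
  if (is.null(labels$pop)) labels$pop <- paste0("p", seq_len(N))
  if (!is.null(pop_sizes)) {
    pop_sizes <- rep_len(as.numeric(pop_sizes), N)
    if (any(pop_sizes <= 0)) stop("network_model: pop_sizes must be positive")
  }
  dimnames(K) <- dimnames(J) <- list(labels$pop, labels$pop)
  # per-population parameter vectors, precomputed for fast access
  par <- lapply(c("tau_m", "tau_r", "tau_s", "C_m", "V_r", "theta", "E_L"),
                function(f) vapply(params, `[[`, numeric(1), f))
  names(par) <- c("tau_m", "tau_r", "tau_s", "C_m", "V_r", "theta", "E_L")
  structure(list(N = N, K = K, J = J, params = params, par = par,
                 K_ext = K_ext, J_ext = J_ext, nu_ext = nu_ext,
                 labels = labels, pop_sizes = pop_sizes,
                 ext_multiplier = ext_multiplier,
                 weight_unit = weight_unit),
            class = "network_model")
}

.check_network <- function(network) {
  if (!inherits(network, "network_model"))
    stop("expected a network_model object")
  network
}

#' @export
print.network_model <- function(x, ...) {
  cat(sprintf("LIF network model: %d population(s)\n", x$N))
  cat(sprintf("  nu_ext = %g spikes/s, J_ext = %g %s, K_ext in [%g, %g]\n",
              x$nu_ext, x$J_ext, x$weight_unit, min(x$K_ext), max(x$K_ext)))
  if (!is.null(x$labels$area))
    cat("  areas:", paste(unique(x$labels$area), collapse = ", "), "\n")
  invisible(x)
}

# conversion factor pA -> mV per target population (tau_s/C_m, ms/pF = mV/pA)
.w_factor <- function(net) {
  if (net$weight_unit == "mV") rep(1, net$N) else net$par$tau_s / net$par$C_m
}

#' Effective weight matrices
#'
#' Hadamard products `W = K * w` and `W2 = K * w * w`, where `w` is the
#' weight matrix in effective-mV units (converted from pA by the target
#' population's `tau_s / C_m` when needed). `W` carries the sign pattern of
#' `J`; `W2` is its elementwise product with `w` once more.
#'
#' @param network a [network_model()]
#' @return list with matrices `W` (mV), `W2` (mV^2) and the converted
#'   weight matrix `w_mV`
#' @export
effective_weight_matrices <- function(network) {
  net <- .check_network(network)
  w <- net$J * .w_factor(net)   # row-wise: target's conversion factor
  list(W = net$K * w, W2 = net$K * w * w, w_mV = w)
}

# effective external weight per target population (mV)
.w_ext <- function(net) net$J_ext * .w_factor(net)

# effective external indegree including per-population multipliers
.K_ext_eff <- function(net) net$K_ext * net$ext_multiplier

#' Input moments from connectivity and rates
#'
#' Mean and variance of the synaptic input per population:
#' \eqn{\mu_i = \tau_m [\sum_j K_{ij} w_{ij} \nu_j + K_{ext,i} w_{ext} \nu_{ext}]}
#' (mV) and the analogous sum with squared effective weights for
#' \eqn{\sigma_i^2} (mV^2). The returned `mu` is the synaptic mean; the
#' gain function evaluates it on the absolute membrane-potential scale by
#' adding the leak potential.
#'
#' @param nu rate vector (spikes/s), length N, non-negative
#' @param network a [network_model()]
#' @return object of class `input_moments`: list with `mu` (mV) and
#'   `sigma2` (mV^2)
#' @export
input_moments <- function(nu, network) {
  net <- .check_network(network)
  nu <- as.numeric(nu)
  if (length(nu) != net$N)
    stop("input_moments: 'nu' must have length ", net$N)
  if (any(!is.finite(nu)) || any(nu < 0))
    stop("input_moments: 'nu' must be finite and non-negative")
  ew <- effective_weight_matrices(net)
  tm <- net$par$tau_m * 1e-3
  wx <- .w_ext(net)
  kx <- .K_ext_eff(net)
  mu <- tm * (as.vector(ew$W %*% nu) + kx * wx * net$nu_ext)
  sigma2 <- tm * (as.vector(ew$W2 %*% nu) + kx * wx^2 * net$nu_ext)
  structure(list(mu = mu, sigma2 = sigma2), class = "input_moments")
}

#' Population gain map of a network
#'
#' Evaluates the self-consistency map \eqn{\Phi(\nu)}: the stationary rate
#' of every population given the input moments generated by rate vector
#' `nu`. This is the right-hand side (plus `nu`) of the pseudo-time flow
#' used for fixed-point search.
#'
#' @inheritParams input_moments
#' @return rate vector (spikes/s)
#' @export
phi_network <- function(nu, network) {
  net <- .check_network(network)
  .phi_fast(as.numeric(nu), .net_cache(net))
}

# precomputed quantities for repeated gain-map evaluation
.net_cache <- function(net) {
  ew <- effective_weight_matrices(net)
  tm <- net$par$tau_m * 1e-3
  kx <- .K_ext_eff(net)
  wx <- .w_ext(net)
  list(N = net$N,
       tmW = tm * ew$W, tmW2 = tm * ew$W2,
       mu_ext = tm * kx * wx * net$nu_ext,
       s2_ext = tm * kx * wx^2 * net$nu_ext,
       tau_m = net$par$tau_m, tau_r = net$par$tau_r,
       tau_s = net$par$tau_s, V_r = net$par$V_r,
       theta = net$par$theta, E_L = net$par$E_L)
}

.phi_fast <- function(nu, cache) {
  mu_abs <- cache$E_L + cache$mu_ext + as.vector(cache$tmW %*% nu)
  sigma2 <- cache$s2_ext + as.vector(cache$tmW2 %*% nu)
  .siegert_core_vec(mu_abs, sqrt(pmax(sigma2, 0)), cache$tau_m,
                    cache$tau_r, cache$tau_s, cache$V_r, cache$theta)
}
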