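# Stationary LIF gain function under the diffusion approximation and its
# derivatives with respect to the input moments.

#' Neuron and synapse parameters of a LIF population
#'
#' Container for the single-neuron parameters of one population of leaky
#' integrate-and-fire neurons with exponentially decaying postsynaptic
#' currents. Defaults are the standard cortical microcircuit values.
#'
#' @param tau_m membrane time constant (ms)
#' @param tau_r absolute refractory period (ms)
#' @param tau_s postsynaptic current time constant (ms)
#' @param C_m membrane capacitance (pF)
#' @param V_r reset potential (mV)
#' @param theta firing threshold (mV)
#' @param E_L leak (resting) potential (mV)
#' @return an object of class `neuron_params`
#' @examples
#' p <- neuron_params()
#' siegert_rate(-45, 5, p)
#' @export
neuron_params <- function(tau_m = 10, tau_r = 2, tau_s = 0.5, C_m = 250,
                          V_r = -65, theta = -50, E_L = -65) {
  p <- list(tau_m = tau_m, tau_r = tau_r, tau_s = tau_s, C_m = C_m,
            V_r = V_r, theta = theta, E_L = E_L)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]))
      stop("neuron_params: '", nm, "' must be a single finite number")
  }
  if (tau_m <= 0) stop("neuron_params: tau_m must be > 0")
  if (tau_s <= 0) stop("neuron_params: tau_s must be > 0")
  if (tau_r < 0) stop("neuron_params: tau_r must be >= 0")
  if (C_m <= 0) stop("neuron_params: C_m must be > 0")
  if (theta <= V_r) stop("neuron_params: theta must exceed V_r")
  structure(p, class = "neuron_params")
}

#' @export
print.neuron_params <- function(x, ...) {
  cat("LIF neuron parameters:\n")
  cat(sprintf("  tau_m = %g ms, tau_r = %g ms, tau_s = %g ms, C_m = %g pF\n",
              x$tau_m, x$tau_r, x$tau_s, x$C_m))
  cat(sprintf("  V_r = %g mV, theta = %g mV, E_L = %g mV\n",
              x$V_r, x$theta, x$E_L))
  invisible(x)
}

# |zeta(1/2)|/2, computed once at first use rather than hard-coded.
.gamma_zeta <- function() {
  if (is.null(.mf_cache$gamma_zeta))
    .mf_cache$gamma_zeta <- abs(pracma::zeta(0.5)) / 2
  .mf_cache$gamma_zeta
}

# Gauss-Legendre nodes/weights on [-1, 1], cached. 48 nodes resolve every
# bounded piece of the Siegert integrand to machine precision.
.gl_nodes <- function(n = 48L) {
  key <- paste0("gl", n)
  if (is.null(.mf_cache[[key]]))
    .mf_cache[[key]] <- pracma::gaussLegendre(n, -1, 1)
  .mf_cache[[key]]
}

# Scaled complementary error function exp(x^2) erfc(x) for x >= 0, with an
# asymptotic-series branch for large arguments where the direct product
# over/underflows. exp(x^2) erfc(x) = exp(x^2) 2 pnorm(-x sqrt(2)).
.erfcx_pos <- function(x) {
  out <- numeric(length(x))
  small <- x < 25
  if (any(small)) {
    xs <- x[small]
    out[small] <- exp(xs^2) * 2 * pnorm(-xs * sqrt(2))
  }
  if (any(!small)) {
    t <- x[!small]
    t2 <- t^2
    out[!small] <- (1 / (t * sqrt(pi))) *
      (1 - 0.5 / t2 + 0.75 / t2^2 - 1.875 / t2^3 + 6.5625 / t2^4)
  }
  out
}

# Vectorized stationary rate over populations given absolute-scale mean
# membrane potential mu_abs (mV), input std sigma (mV), and per-population
# parameter vectors (times in ms). sigma == 0 entries use the noiseless
# formula. Thin wrapper over the compiled kernel.
.siegert_core_vec <- function(mu_abs, sigma, tau_m, tau_r, tau_s, V_r,
                              theta) {
  gl <- .gl_nodes()
  .siegert_rates_cpp(mu_abs, sigma, tau_m, tau_r, tau_s, V_r, theta,
                     .gamma_zeta(), gl$x, gl$w)
}

.check_params <- function(params) {
  if (!inherits(params, "neuron_params"))
    stop("'params' must be a neuron_params object")
  params
}

# scalar core; mu is the mean membrane potential (mV, absolute scale,
# i.e. E_L plus the synaptic mean input), sigma the input std (mV)
.siegert1 <- function(mu, sigma, p) {
  .siegert_core_vec(mu, sigma, p$tau_m, p$tau_r, p$tau_s, p$V_r, p$theta)
}

#' Stationary firing rate of a LIF population (Siegert formula)
#'
#' Mean first-passage-time rate of the leaky integrate-and-fire neuron
#' driven by Gaussian white noise with mean `mu` and standard deviation
#' `sigma`, including the linear-order correction for exponentially
#' filtered synaptic currents: the integration boundaries are shifted by
#' \eqn{\gamma \sqrt{\tau_s/\tau_m}\,\sigma} with
#' \eqn{\gamma = |\zeta(1/2)|/2}.
#'
#' `mu` is the mean membrane potential on the absolute scale of the
#' threshold and reset (i.e. the leak potential plus the synaptic mean
#' input). For `sigma = 0` the noiseless limit [noiseless_rate()] is
#' returned.
#'
#' @param mu mean input (mV); may be a vector
#' @param sigma input standard deviation (mV); recycled against `mu`
#' @param params a [neuron_params()] object
#' @return stationary rate(s) in spikes/s, in `[0, 1000/tau_r)`
#' @examples
#' siegert_rate(-45, 5, neuron_params())
#' @export
siegert_rate <- function(mu, sigma, params) {
  p <- .check_params(params)
  if (!all(is.finite(mu)) || !all(is.finite(sigma)))
    stop("siegert_rate: non-finite 'mu' or 'sigma'")
  if (any(sigma < 0)) stop("siegert_rate: 'sigma' must be >= 0")
  n <- max(length(mu), length(sigma))
  mu <- rep_len(mu, n)
  sigma <- rep_len(sigma, n)
  rp <- function(x) rep_len(x, n)
  .siegert_core_vec(mu, sigma, rp(p$tau_m), rp(p$tau_r), rp(p$tau_s),
                    rp(p$V_r), rp(p$theta))
}

#' Noiseless LIF transfer function
#'
#' Deterministic (zero-noise) stationary rate of the LIF neuron:
#' zero for subthreshold mean input, and
#' \eqn{1/[\tau_r + \tau_m \log((\mu - V_r)/(\mu - \theta))]} above
#' threshold.
#'
#' @inheritParams siegert_rate
#' @return rate(s) in spikes/s
#' @export
noiseless_rate <- function(mu, params) {
  p <- .check_params(params)
  if (!all(is.finite(mu))) stop("noiseless_rate: non-finite 'mu'")
  tm <- p$tau_m * 1e-3
  tr <- p$tau_r * 1e-3
  ifelse(mu <= p$theta, 0,
         1 / (tr + tm * log((mu - p$V_r) / (mu - p$theta))))
}

# log of e^{y^2}(1 + erf(y)), stable for all y
.log_f_siegert <- function(y) {
  if (y >= 0) y^2 + log1p(pracma::erf(y)) else log(.erfcx_pos(-y))
}

# S_i and T_i at given scalar moments; returns c(S, T) in (spikes/s)/mV and
# (spikes/s)/mV^2. Computed analytically from the boundary terms of the
# Siegert integral, in log-magnitude arithmetic so the deep-subthreshold
# regime does not overflow.
.gain_deriv1 <- function(mu, sigma, p) {
  if (sigma <= 0) stop("gain_derivatives: sigma must be > 0 (degenerate input)")
  tm <- p$tau_m * 1e-3
  shift <- .gamma_zeta() * sqrt(p$tau_s / p$tau_m)
  a <- (p$V_r - mu) / sigma + shift
  b <- (p$theta - mu) / sigma + shift
  phi <- .siegert1(mu, sigma, p)
  if (phi <= 0) return(c(S = 0, T = 0))
  lphi <- log(phi)
  lfa <- .log_f_siegert(a)
  lfb <- .log_f_siegert(b)
  lc <- log(tm * sqrt(pi) / sigma)
  S <- exp(2 * lphi + lc + lfb) - exp(2 * lphi + lc + lfa)
  # dPhi/dsigma = phi^2 tm sqrt(pi)/sigma^2 [f(b)(theta-mu) - f(a)(V_r-mu)];
  # T = dPhi/dsigma / (2 sigma)
  lct <- log(tm * sqrt(pi)) - 3 * log(sigma) - log(2)
  term <- function(lf, x) if (x == 0) 0 else sign(x) * exp(2 * lphi + lct + lf + log(abs(x)))
  T <- term(lfb, p$theta - mu) - term(lfa, p$V_r - mu)
  c(S = S, T = T)
}

#' Sensitivities of the gain function at a network state
#'
#' Evaluates the diagonal sensitivity matrices `S` and `T` of the
#' population gain with respect to the input moments at rate vector `nu`:
#' \eqn{S_{ii} = \partial\Phi_i/\partial\mu_i} and
#' \eqn{T_{ii} = (\partial\Phi_i/\partial\sigma_i)/(2\sigma_i)}. Both
#' depend only on the target population. Populations with zero input
#' variance are rejected, since `T` divides by `sigma`.
#'
#' @param nu rate vector (spikes/s), length `N`
#' @param network a [network_model()]
#' @return list with diagonal matrices `S`, `T`, their diagonals as vectors
#'   `S_vec`, `T_vec`, and the input moments used
#' @export
gain_derivatives <- function(nu, network) {
  net <- .check_network(network)
  mom <- input_moments(nu, net)
  sig <- sqrt(mom$sigma2)
  if (any(sig == 0))
    stop("gain_derivatives: zero input variance in population(s) ",
         paste(which(sig == 0), collapse = ", "),
         "; T is undefined at sigma = 0")
  N <- net$N
  sv <- numeric(N)
  tv <- numeric(N)
  for (i in seq_len(N)) {
    d <- .gain_deriv1(net$par$E_L[i] + mom$mu[i], sig[i], net$params[[i]])
    sv[i] <- d[["S"]]
    tv[i] <- d[["T"]]
  }
  list(S = diag(sv, N), T = diag(tv, N), S_vec = sv, T_vec = tv,
       moments = mom)
}
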