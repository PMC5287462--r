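# Linear response around a fixed point: effective connectivity, its
# bi-orthogonal eigenmodes, parameter sensitivities, and per-mode
# contributions to the predicted fixed-point shift.

#' Perturbed-parameter specification
#'
#' Names the model parameter to perturb and the perturbation. Matrix-valued
#' parameters are vectorized row-major (see [vectorize()]).
#'
#' @param kind one of `"nu_ext"` (scalar external rate), `"K_ext"`
#'   (external indegrees, length-N), `"K"` (recurrent indegrees, N x N),
#'   `"J"` (synaptic weights, N x N, in the network's weight unit)
#' @param delta the perturbation in matching shape; may be `NULL` when the
#'   spec only names the compensating parameter
#' @return object of class `param_spec`
#' @export
param_spec <- function(kind = c("nu_ext", "K_ext", "K", "J"), delta = NULL) {
  kind <- match.arg(kind)
  structure(list(kind = kind, delta = delta), class = "param_spec")
}

.param_dim <- function(spec, net) {
  switch(spec$kind, nu_ext = 1L, K_ext = net$N, K = net$N^2, J = net$N^2)
}

.delta_vec <- function(spec, net) {
  if (is.null(spec$delta)) stop("param_spec '", spec$kind, "' has no delta")
  d <- spec$delta
  v <- if (is.matrix(d)) vectorize(d) else as.numeric(d)
  P <- .param_dim(spec, net)
  if (length(v) == 1L && P > 1L && spec$kind == "K_ext") v <- rep(v, P)
  if (length(v) != P)
    stop("param_spec '", spec$kind, "': delta has length ", length(v),
         ", expected ", P)
  v
}

#' Effective connectivity and its eigenmodes at a fixed point
#'
#' Builds \eqn{M = \tau_m (S W + T W_2)}, the Jacobian of the population
#' gain with respect to the rates, evaluated at a fixed point, together
#' with its eigendecomposition. Right eigenvectors come from the
#' eigensolver; left eigenvectors are the rows of the inverse of the
#' right-eigenvector matrix, which guarantees the bi-orthogonality
#' \eqn{v_l^T u_n = \delta_{ln}} and the completeness
#' \eqn{\sum_l u_l v_l^T = 1}. Eigenpairs are sorted by descending real
#' part, then descending imaginary part, so mode indices are reproducible.
#' A near-defective eigenbasis (condition number of `U` above `1e10`)
#' raises an error naming the clustered eigenvalues.
#'
#' @param network a [network_model()]
#' @param fp a `fixed_point` (or a bare rate vector)
#' @param residual_tol largest accepted fixed-point residual
#' @return object of class `linear_response` with fields `S`, `T`
#'   (diagonal matrices), `M`, `lambdas`, `U`, `V`, `nu`, `at`
#' @export
effective_connectivity <- function(network, fp, residual_tol = 1e-6) {
  net <- .check_network(network)
  if (inherits(fp, "fixed_point")) {
    if (fp$residual > residual_tol)
      stop("effective_connectivity: fixed-point residual ", fp$residual,
           " exceeds tolerance ", residual_tol)
    nu <- fp$nu_star
  } else {
    nu <- as.numeric(fp)
    fp <- NULL
  }
  gd <- gain_derivatives(nu, net)
  ew <- effective_weight_matrices(net)
  tm <- net$par$tau_m * 1e-3
  M <- (tm * gd$S_vec) * ew$W + (tm * gd$T_vec) * ew$W2
  ee <- eigen(M)
  ord <- order(-Re(ee$values), -Im(ee$values))
  lambdas <- ee$values[ord]
  U <- ee$vectors[, ord, drop = FALSE]
  sv <- svd(U, nu = 0, nv = 0)$d
  if (sv[length(sv)] <= 0 || sv[1] / sv[length(sv)] > 1e10) {
    cl <- signif(lambdas, 6)
    stop("effective_connectivity: eigenvector matrix is near-singular ",
         "(clustered eigenvalues: ", paste(cl, collapse = ", "), ")")
  }
  V <- t(solve(U))  # columns v_l; plain-transpose bi-orthogonal to U
  structure(list(S = gd$S, T = gd$T, S_vec = gd$S_vec, T_vec = gd$T_vec,
                 M = M, lambdas = lambdas, U = U, V = V, nu = nu, at = fp,
                 network = net),
            class = "linear_response")
}

#' @export
print.linear_response <- function(x, ...) {
  cat(sprintf("linear response at fixed point (%d modes)\n", length(x$lambdas)))
  cat("  leading eigenvalues:",
      paste(signif(x$lambdas[seq_len(min(4, length(x$lambdas)))], 5),
            collapse = ", "), "\n")
  invisible(x)
}

#' Direct parameter sensitivity of the gain
#'
#' The matrix \eqn{\bar\Delta_a = S \,\partial\mu/\partial a +
#' T \,\partial\sigma^2/\partial a} mapping a perturbation of parameter `a`
#' to the direct (pre-feedback) change of the gain, evaluated at a fixed
#' point. For matrix-valued parameters the columns follow the row-major
#' vectorization, and the indegree sensitivity is block-sparse: the input
#' moments of population `i` depend only on row `i` of the indegree
#' matrix.
#'
#' @inheritParams effective_connectivity
#' @param spec a [param_spec()] naming the parameter
#' @return an `N x P` matrix (`P` the parameter dimension)
#' @export
delta_bar <- function(network, fp, spec) {
  net <- .check_network(network)
  if (!inherits(spec, "param_spec")) stop("'spec' must be a param_spec")
  nu <- if (inherits(fp, "fixed_point")) fp$nu_star else as.numeric(fp)
  gd <- gain_derivatives(nu, net)
  ew <- effective_weight_matrices(net)
  tm <- net$par$tau_m * 1e-3
  N <- net$N
  Sv <- gd$S_vec
  Tv <- gd$T_vec
  switch(spec$kind,
    nu_ext = {
      kx <- .K_ext_eff(net)
      wx <- .w_ext(net)
      matrix(Sv * tm * kx * wx + Tv * tm * kx * wx^2, ncol = 1)
    },
    K_ext = {
      wx <- .w_ext(net)
      mult <- net$ext_multiplier
      diag(Sv * tm * mult * wx * net$nu_ext +
           Tv * tm * mult * wx^2 * net$nu_ext, N)
    },
    K = {
      out <- matrix(0, N, N^2)
      w <- ew$w_mV
      for (i in seq_len(N)) {
        cols <- (i - 1) * N + seq_len(N)
        out[i, cols] <- tm[i] * (Sv[i] * w[i, ] + Tv[i] * w[i, ]^2) * nu
      }
      out
    },
    J = {
      out <- matrix(0, N, N^2)
      w <- ew$w_mV
      cf <- .w_factor(net)  # d w / d J per target row
      for (i in seq_len(N)) {
        cols <- (i - 1) * N + seq_len(N)
        out[i, cols] <- tm[i] * (Sv[i] * net$K[i, ] * cf[i] +
                                 Tv[i] * net$K[i, ] * 2 * w[i, ] * cf[i]) * nu
      }
      out
    })
}

# match complex-conjugate eigenvalue pairs; returns an integer partner
# vector (0 for real modes)
.conj_pairs <- function(lambdas, tol = 1e-8) {
  n <- length(lambdas)
  partner <- integer(n)
  scale <- max(1, abs(lambdas))
  for (l in seq_len(n)) {
    if (partner[l] != 0 || abs(Im(lambdas[l])) < tol * scale) next
    cand <- which(partner == 0 & seq_len(n) != l &
                  abs(lambdas - Conj(lambdas[l])) < 1e-6 * scale)
    if (length(cand) > 0) {
      partner[l] <- cand[1]
      partner[cand[1]] <- l
    }
  }
  partner
}

#' Predicted fixed-point shift and per-mode contributions
#'
#' First-order prediction of the fixed-point displacement under a
#' parameter perturbation, \eqn{\delta\nu^* = (1 - M)^{-1} \bar\Delta_a
#' \delta a}, decomposed over the eigenmodes of the effective
#' connectivity. The projections are \eqn{\hat a_l = v_l^T \bar\Delta_a
#' \delta a} and each mode contributes
#' \eqn{\tilde\eta_l = \frac{\hat a_l}{1-\lambda_l}
#' \frac{\delta\nu^{*T} u_l}{\delta\nu^{*T}\delta\nu^*}}
#' to the shift (the expansion coefficients of the realized
#' \eqn{\delta\nu^*} itself); complex-conjugate pairs are combined
#' (\eqn{\eta_l = \tilde\eta_l + \tilde\eta_l^*}) so all reported
#' contributions are real and sum to 1 by construction. The sign
#' convention decomposes the realized shift itself; compensation-directed
#' signs enter only through the mode coefficients of
#' [indegree_mode_solution()].
#'
#' @param lr a [effective_connectivity()] result
#' @param db the `N x P` sensitivity matrix from [delta_bar()]
#' @param delta_a perturbation vector (length P, row-major for matrices)
#' @return object of class `shift_prediction`: `delta_nu_star`, `a_hat`,
#'   `eta_tilde` (complex, per mode), `eta` (real, conjugate pairs
#'   combined, indexed by representative mode), `pair`
#' @export
predict_shift <- function(lr, db, delta_a) {
  if (!inherits(lr, "linear_response")) stop("'lr' must be a linear_response")
  N <- length(lr$nu)
  delta_a <- if (is.matrix(delta_a)) vectorize(delta_a) else as.numeric(delta_a)
  if (ncol(db) != length(delta_a))
    stop("predict_shift: delta_a length does not match delta_bar columns")
  rhs <- as.vector(db %*% delta_a)
  if (any(abs(1 - lr$lambdas) < 1e-12))
    stop("predict_shift: an eigenvalue of M equals 1; the fixed point is ",
         "parabolic and the linear prediction is singular")
  dn <- solve(diag(N) - lr$M, rhs)
  if (sqrt(sum(dn^2)) < 1e-300)
    stop("predict_shift: predicted shift is zero; mode contributions are ",
         "undefined")
  a_hat <- as.vector(t(lr$V) %*% rhs)      # v_l^T rhs (plain transpose)
  proj <- as.vector(dn %*% lr$U)           # delta_nu^T u_l
  eta_tilde <- (a_hat / (1 - lr$lambdas)) * proj / sum(dn^2)
  partner <- .conj_pairs(lr$lambdas)
  eta <- numeric(length(eta_tilde))
  counted <- rep(FALSE, length(eta_tilde))
  for (l in seq_along(eta_tilde)) {
    if (counted[l]) next
    if (partner[l] == 0) {
      eta[l] <- Re(eta_tilde[l])
      counted[l] <- TRUE
    } else {
      eta[l] <- Re(eta_tilde[l] + eta_tilde[partner[l]])
      counted[l] <- counted[partner[l]] <- TRUE
      eta[partner[l]] <- NA_real_  # contribution carried by the representative
    }
  }
  structure(list(delta_nu_star = dn, delta_bar = db, delta_a = delta_a,
                 a_hat = a_hat, eta_tilde = eta_tilde, eta = eta,
                 pair = partner, lambdas = lr$lambdas),
            class = "shift_prediction")
}

#' @export
print.shift_prediction <- function(x, ...) {
  cat("predicted fixed-point shift (spikes/s):",
      paste(signif(x$delta_nu_star, 5), collapse = ", "), "\n")
  cat("  sum of mode contributions:",
      format(sum(x$eta, na.rm = TRUE), digits = 12), "\n")
  invisible(x)
}
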