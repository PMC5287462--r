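# Fixed points of the self-consistency map: pseudo-time integration,
# exhaustive enumeration for small systems, and localization of unstable
# fixed points by bisection of the external drive.

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("pseudo-time trajectory: %d samples, %d population(s)\n",
              length(x$s), ncol(x$nu)))
  cat(sprintf("  s in [%g, %g], final speed %.3g, converged: %s\n",
              x$s[1], x$s[length(x$s)], x$speed[length(x$speed)],
              x$converged))
  invisible(x)
}

# construct a fixed_point object
.fixed_point <- function(nu_star, residual, stability, label, provenance) {
  structure(list(nu_star = nu_star, residual = residual,
                 stability = stability, label = label,
                 provenance = provenance),
            class = "fixed_point")
}

#' @export
print.fixed_point <- function(x, ...) {
  cat(sprintf("fixed point [%s, %s]: residual %.3g\n",
              x$stability, x$label, x$residual))
  cat("  rates (spikes/s):", paste(signif(x$nu_star, 6), collapse = ", "),
      "\n")
  invisible(x)
}

# Jacobian of Phi at nu: M_ij = tau_m_i (S_i W_ij + T_i W2_ij)
.jac_phi <- function(nu, net) {
  gd <- gain_derivatives(nu, net)
  ew <- effective_weight_matrices(net)
  tm <- net$par$tau_m * 1e-3
  (tm * gd$S_vec) * ew$W + (tm * gd$T_vec) * ew$W2
}

.max_re_eig <- function(M) max(Re(eigen(M, only.values = TRUE)$values))

# stability classification via the spectrum of M; NULL when the moments are
# degenerate (e.g. a fully silent, undriven network)
.classify_stability <- function(nu, net) {
  M <- tryCatch(.jac_phi(nu, net), error = function(e) NULL)
  if (is.null(M)) return(NULL)
  ev <- Re(eigen(M, only.values = TRUE)$values)
  list(n_unstable = sum(ev > 1), max_re = max(ev))
}

#' Integrate the pseudo-time flow of the rate equations
#'
#' Classical fourth-order Runge-Kutta integration of
#' \eqn{\dot\nu = \Phi(\nu) - \nu} in the dimensionless pseudo-time `s`.
#' The state is clipped at zero from below after every step (transient
#' undershoot can occur with inhibition); the Euclidean norm of the
#' velocity is recorded at every step. Integration stops early once the
#' speed stays below `tol_conv` for `conv_steps` consecutive steps, unless
#' `stop_on_convergence = FALSE`.
#'
#' @param network a [network_model()]
#' @param nu0 initial rate vector (spikes/s); defaults to the inactive
#'   state
#' @param s_max maximal pseudo-time
#' @param h step size
#' @param tol_conv convergence threshold on the speed
#' @param conv_steps number of consecutive sub-threshold steps required
#' @param stop_on_convergence stop early once converged
#' @param stop_near optional matrix of reference states (one per row):
#'   integration also stops once the population-mean distance to any row
#'   drops below `stop_near_tol` (used to classify attractor outcomes
#'   without waiting for full convergence)
#' @param stop_near_tol proximity threshold (spikes/s)
#' @return object of class `trajectory` with fields `s`, `nu`
#'   (samples x populations), `speed`, `converged`, `clipped`
#' @export
integrate_flow <- function(network, nu0 = NULL, s_max = 100, h = 0.01,
                           tol_conv = 1e-10, conv_steps = 10L,
                           stop_on_convergence = TRUE, stop_near = NULL,
                           stop_near_tol = 0.25) {
  net <- .check_network(network)
  if (is.null(nu0)) nu0 <- rep(0, net$N)
  nu0 <- as.numeric(nu0)
  if (length(nu0) != net$N || any(!is.finite(nu0)) || any(nu0 < 0))
    stop("integrate_flow: 'nu0' must be a finite non-negative vector of length ",
         net$N)
  if (h <= 0 || s_max <= 0) stop("integrate_flow: h and s_max must be > 0")
  cache <- .net_cache(net)
  f <- function(x) .phi_fast(pmax(x, 0), cache) - x
  n_steps <- ceiling(s_max / h)
  S <- numeric(n_steps + 1)
  NU <- matrix(NA_real_, n_steps + 1, net$N)
  SP <- numeric(n_steps + 1)
  nu <- nu0
  NU[1, ] <- nu
  v <- f(nu)
  SP[1] <- sqrt(sum(v^2))
  clipped <- FALSE
  below <- 0L
  last <- n_steps + 1
  for (k in seq_len(n_steps)) {
    k1 <- f(nu)
    k2 <- f(nu + h / 2 * k1)
    k3 <- f(nu + h / 2 * k2)
    k4 <- f(nu + h * k3)
    nu_new <- nu + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (any(!is.finite(nu_new)))
      stop("integrate_flow: non-finite state at s = ", k * h,
           " (state: ", paste(signif(nu, 4), collapse = ", "), ")")
    if (any(nu_new < 0)) {
      clipped <- TRUE
      nu_new <- pmax(nu_new, 0)
    }
    nu <- nu_new
    S[k + 1] <- k * h
    NU[k + 1, ] <- nu
    sp <- sqrt(sum(f(nu)^2))
    SP[k + 1] <- sp
    below <- if (sp < tol_conv) below + 1L else 0L
    if (stop_on_convergence && below >= conv_steps) {
      last <- k + 1
      break
    }
    if (!is.null(stop_near) &&
        min(rowMeans(abs(sweep(stop_near, 2, nu)))) < stop_near_tol) {
      last <- k + 1
      break
    }
  }
  keep <- seq_len(last)
  structure(list(s = S[keep], nu = NU[keep, , drop = FALSE],
                 speed = SP[keep], converged = below >= conv_steps,
                 clipped = clipped),
            class = "trajectory")
}

#' Find a stable fixed point by pseudo-time integration
#'
#' Integrates the flow from `nu0` (default: the inactive state) until the
#' speed drops below `tol_conv`. The terminal state is labeled `stable`
#' only if the integration converged and all eigenvalues of the effective
#' connectivity at that point have real part below 1; otherwise the label
#' is `undetermined` — a non-converged run never fabricates a fixed point.
#'
#' @inheritParams integrate_flow
#' @param label_rule how to name a stable point: mean rate below
#'   `ha_threshold` gives `"LA"`, above gives `"HA"`
#' @param ha_threshold mean-rate boundary (spikes/s) between the LA and HA
#'   labels
#' @return a `fixed_point`
#' @export
find_stable_fixed_point <- function(network, nu0 = NULL, s_max = 100,
                                    h = 0.01, tol_conv = 1e-10,
                                    ha_threshold = 100,
                                    label_rule = TRUE) {
  net <- .check_network(network)
  tr <- integrate_flow(net, nu0 = nu0, s_max = s_max, h = h,
                       tol_conv = tol_conv)
  nu <- tr$nu[nrow(tr$nu), ]
  residual <- sqrt(sum((phi_network(nu, net) - nu)^2))
  stab <- "undetermined"
  if (tr$converged) {
    cl <- .classify_stability(nu, net)
    if (!is.null(cl) && cl$n_unstable == 0) stab <- "stable"
  }
  label <- if (stab == "stable" && isTRUE(label_rule)) {
    if (mean(nu) < ha_threshold) "LA" else "HA"
  } else "undetermined"
  .fixed_point(nu, residual, stab, label,
               provenance = list(method = "flow", nu0 = if (is.null(nu0)) rep(0, net$N) else nu0,
                                 s_final = tr$s[length(tr$s)],
                                 converged = tr$converged))
}

# damped quasi-Newton refinement of Phi(nu) - nu = 0
.newton_polish <- function(net, nu, tol = 1e-12, max_iter = 100L) {
  cache <- .net_cache(net)
  phi_c <- function(x) .phi_fast(x, cache)
  fval <- phi_c(nu) - nu
  res <- sqrt(sum(fval^2))
  for (it in seq_len(max_iter)) {
    if (res < tol) break
    J <- tryCatch(.jac_phi(nu, net) - diag(net$N), error = function(e) NULL)
    if (is.null(J)) break
    step <- tryCatch(solve(J, -fval), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    improved <- FALSE
    for (half in 1:25) {
      cand <- pmax(nu + lambda * step, 0)
      fc <- phi_c(cand) - cand
      rc <- sqrt(sum(fc^2))
      if (rc < res) {
        nu <- cand
        fval <- fc
        res <- rc
        improved <- TRUE
        break
      }
      lambda <- lambda / 2
    }
    if (!improved) break
  }
  list(nu = nu, residual = res, converged = res < tol)
}

#' Enumerate all fixed points of a small network
#'
#' Exhaustive fixed-point enumeration for one- or two-population networks.
#' In one dimension the map \eqn{\Phi(\nu) - \nu} is scanned on a dense
#' grid over `[0, 1/tau_r)`, sign changes are bracketed and polished with
#' [stats::uniroot()]; the scan is repeated at doubled resolution and a
#' persistent disagreement in the root count raises a resolution error. In
#' two dimensions a damped Newton iteration is started from a grid of
#' initial conditions and the converged roots are deduplicated. Each root
#' is classified by the eigenvalues of the effective connectivity; stable
#' roots are labeled LA/HA by rate ordering and unstable ones `separatrix`.
#'
#' @param network a [network_model()] with at most 2 populations
#' @param grid_n number of grid points per dimension in the initial scan
#' @param tol residual tolerance for accepted roots
#' @return list of `fixed_point` objects, ordered by mean rate
#' @export
enumerate_fixed_points <- function(network, grid_n = 2001L, tol = 1e-8) {
  net <- .check_network(network)
  if (net$N > 2)
    stop("enumerate_fixed_points: exhaustive enumeration supports N <= 2")
  nu_max <- 0.999 * 1000 / min(net$par$tau_r)
  roots <- if (net$N == 1L) .enumerate_1d(net, grid_n, nu_max)
           else .enumerate_2d(net, nu_max)
  fps <- lapply(roots, function(nu) {
    residual <- sqrt(sum((phi_network(nu, net) - nu)^2))
    cl <- .classify_stability(nu, net)
    stab <- if (is.null(cl)) "undetermined"
            else if (cl$n_unstable > 0) "unstable" else "stable"
    .fixed_point(nu, residual, stab, label = "undetermined",
                 provenance = list(method = "enumeration"))
  })
  fps <- fps[order(vapply(fps, function(f) mean(f$nu_star), numeric(1)))]
  stable_idx <- which(vapply(fps, function(f) f$stability == "stable",
                             logical(1)))
  if (length(stable_idx) > 0) {
    fps[[stable_idx[1]]]$label <- "LA"
    if (length(stable_idx) > 1)
      fps[[stable_idx[length(stable_idx)]]]$label <- "HA"
  }
  for (i in seq_along(fps))
    if (fps[[i]]$stability == "unstable") fps[[i]]$label <- "separatrix"
  fps
}

.scan_roots_1d <- function(g, grid_n, nu_max) {
  nus <- seq(0, nu_max, length.out = grid_n)
  fv <- vapply(nus, g, numeric(1))
  idx <- which(fv[-1] * fv[-length(fv)] < 0 | fv[-length(fv)] == 0)
  roots <- numeric(0)
  for (i in idx) {
    if (fv[i] == 0) {
      roots <- c(roots, nus[i])
    } else {
      r <- stats::uniroot(g, c(nus[i], nus[i + 1]), tol = 1e-12)
      roots <- c(roots, r$root)
    }
  }
  if (fv[length(fv)] == 0) roots <- c(roots, nus[length(fv)])
  sort(unique(roots))
}

.enumerate_1d <- function(net, grid_n, nu_max) {
  g <- function(nu) phi_network(nu, net) - nu
  r1 <- .scan_roots_1d(g, grid_n, nu_max)
  r2 <- .scan_roots_1d(g, 2L * grid_n, nu_max)
  if (length(r1) != length(r2)) {
    r3 <- .scan_roots_1d(g, 4L * grid_n, nu_max)
    if (length(r3) != length(r2))
      stop("enumerate_fixed_points: root count does not stabilize under grid ",
           "refinement; increase grid_n")
    r2 <- r3
  }
  lapply(r2, function(x) x)
}

.enumerate_2d <- function(net, nu_max, starts_n = 12L) {
  gr <- seq(0, nu_max, length.out = starts_n)
  roots <- list()
  for (x in gr) for (y in gr) {
    pol <- .newton_polish(net, c(x, y), tol = 1e-11, max_iter = 80L)
    if (!pol$converged) next
    if (any(pol$nu < -1e-9) || any(pol$nu > nu_max + 1)) next
    dup <- any(vapply(roots, function(r) sqrt(sum((r - pol$nu)^2)) < 1e-5,
                      logical(1)))
    if (!dup) roots[[length(roots) + 1]] <- pol$nu
  }
  roots
}

#' Localize an unstable fixed point by drive bisection
#'
#' Bisects the drive-scaling factor kappa between a value whose flow from
#' `nu0` reaches the low-activity attractor and one that reaches the
#' high-activity attractor. On the two bracketing trajectories the
#' critical pseudo-time `s_c` is the last strict local minimum of the
#' flow speed before the trajectories diverge (population-mean distance
#' exceeding `diverge_tol`); the state at `s_c` is refined by a damped
#' Newton iteration on \eqn{\Phi(\nu) - \nu = 0}. The result is labeled
#' `unstable` only if at least one eigenvalue of the effective
#' connectivity at that point has real part above 1. If the refinement
#' escapes toward a stable attractor the unpolished state is returned with
#' a warning.
#'
#' @param network a [network_model()]
#' @param scaling_lo,scaling_hi [drive_scaling()] objects sharing selectors,
#'   with `scaling_lo$kappa < scaling_hi$kappa`; the flow from `nu0` must
#'   reach distinct attractors at the two endpoints
#' @param nu0 initial condition (default: inactive state)
#' @param bisect_tol terminal bracket width in kappa
#' @param diverge_tol population-mean rate distance (spikes/s) defining
#'   trajectory divergence
#' @param ha_threshold population-mean rate (spikes/s) separating the LA
#'   from the HA outcome when classifying terminal states
#' @inheritParams integrate_flow
#' @return a `fixed_point` with provenance recording the kappa bracket and
#'   `s_c`
#' @export
locate_unstable_fixed_point <- function(network, scaling_lo, scaling_hi,
                                        nu0 = NULL, bisect_tol = 1e-9,
                                        diverge_tol = 1, s_max = 100,
                                        h = 0.01, tol_conv = 1e-10,
                                        ha_threshold = 100) {
  net <- .check_network(network)
  if (!inherits(scaling_lo, "drive_scaling") ||
      !inherits(scaling_hi, "drive_scaling"))
    stop("locate_unstable_fixed_point: scalings must be drive_scaling objects")
  if (scaling_lo$kappa >= scaling_hi$kappa)
    stop("locate_unstable_fixed_point: scaling_lo$kappa must be < scaling_hi$kappa")
  if (is.null(nu0)) nu0 <- rep(0, net$N)
  at_kappa <- function(kappa) {
    sc <- scaling_lo
    sc$kappa <- kappa
    apply_drive_scaling(net, sc)
  }
  run <- function(kappa, refs = NULL)
    integrate_flow(at_kappa(kappa), nu0 = nu0, s_max = s_max, h = h,
                   tol_conv = tol_conv, stop_near = refs,
                   stop_near_tol = diverge_tol / 4)
  term <- function(tr) tr$nu[nrow(tr$nu), ]
  ref_lo <- term(run(scaling_lo$kappa))
  ref_hi <- term(run(scaling_hi$kappa))
  if (mean(ref_lo) >= ha_threshold || mean(ref_hi) < ha_threshold)
    stop("locate_unstable_fixed_point: no separatrix crossing in range ",
         "(the endpoint flows do not reach distinct LA/HA attractors)")
  refs <- rbind(ref_lo, ref_hi)
  outcome <- function(nu) if (mean(nu) < ha_threshold) "LA" else "HA"
  k_lo <- scaling_lo$kappa
  k_hi <- scaling_hi$kappa
  while (k_hi - k_lo > bisect_tol) {
    k_m <- (k_lo + k_hi) / 2
    if (outcome(term(run(k_m, refs))) == "LA") k_lo <- k_m else k_hi <- k_m
  }
  tr_lo <- run(k_lo)
  tr_hi <- run(k_hi)
  n <- min(nrow(tr_lo$nu), nrow(tr_hi$nu))
  dist <- abs(rowMeans(tr_lo$nu[seq_len(n), , drop = FALSE]) -
              rowMeans(tr_hi$nu[seq_len(n), , drop = FALSE]))
  div_idx <- which(dist > diverge_tol)
  end <- if (length(div_idx) > 0) div_idx[1] else n
  sp <- tr_lo$speed[seq_len(end)]
  mins <- which(diff(sign(diff(sp))) > 0) + 1L
  mins <- mins[sp[mins] < sp[mins - 1] & sp[mins] < sp[mins + 1]]
  # an initial condition already next to the fixed point leaves it from the
  # first step: the boundary sample is then the speed minimum
  if (length(sp) > 1 && sp[1] < sp[2]) mins <- c(1L, mins)
  if (length(mins) == 0) {
    e <- simpleError(paste0("locate_unstable_fixed_point: no local speed ",
                            "minimum before divergence"))
    e$speed_trace <- sp
    stop(e)
  }
  s_c_idx <- mins[length(mins)]
  nu_c <- tr_lo$nu[s_c_idx, ]
  net_c <- at_kappa(k_lo)
  escapes <- function(p) mean(abs(p - ref_lo)) < diverge_tol ||
                         mean(abs(p - ref_hi)) < diverge_tol
  # refine from the LA-side critical state; if the iteration slides off to
  # a stable attractor, retry from the HA-side trajectory at the same time
  pol <- .newton_polish(net_c, nu_c, tol = 1e-12)
  if (escapes(pol$nu) && s_c_idx <= nrow(tr_hi$nu)) {
    alt <- .newton_polish(net_c, tr_hi$nu[s_c_idx, ], tol = 1e-12)
    if (!escapes(alt$nu)) pol <- alt
  }
  if (escapes(pol$nu)) {
    warning("locate_unstable_fixed_point: refinement escaped toward a ",
            "stable attractor; returning the unpolished critical state")
    pol <- list(nu = nu_c,
                residual = sqrt(sum((phi_network(nu_c, net_c) - nu_c)^2)),
                converged = FALSE)
  }
  cl <- .classify_stability(pol$nu, net_c)
  stab <- if (!is.null(cl) && cl$n_unstable >= 1) "unstable" else "undetermined"
  .fixed_point(pol$nu, pol$residual, stab,
               label = if (stab == "unstable") "separatrix" else "undetermined",
               provenance = list(method = "kappa_bisection",
                                 kappa_lo = k_lo, kappa_hi = k_hi,
                                 s_c = tr_lo$s[s_c_idx], nu0 = nu0,
                                 polished = pol$converged))
}
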