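# Compensating parameter changes (separatrix preservation) and the
# iterative, eigenmode-restricted indegree stabilization loop.

#' Connectivity constraint set
#'
#' Bundles the rules restricting which indegree entries a modification may
#' touch: a forbidden-entry predicate over the label table and the
#' non-negativity rule on the modified indegrees.
#'
#' @param forbidden `NULL` (nothing forbidden) or a function
#'   `function(labels)` returning an `N x N` logical matrix that is `TRUE`
#'   where changes are disallowed (row = target, column = source)
#' @param nonneg enforce `K + delta_K >= 0` by clipping (connection
#'   removal)
#' @return object of class `constraint_set`
#' @export
constraint_set <- function(forbidden = NULL, nonneg = TRUE) {
  structure(list(forbidden = forbidden, nonneg = nonneg),
            class = "constraint_set")
}

#' Anatomical constraint set for layered multi-area networks
#'
#' Standard cortical constraints on indegree modifications: cross-area
#' connections may not originate in inhibitory populations, nor in
#' granular layer-4 populations; indegrees stay non-negative. Areas come
#' from the `area` label column, inhibitory populations from `ei == "I"`,
#' and layer-4 populations from a `layer` label starting with `"4"`.
#'
#' @return a [constraint_set()]
#' @export
cortical_constraints <- function() {
  constraint_set(forbidden = function(labels) {
    N <- nrow(labels)
    area <- if (is.null(labels$area)) rep("A", N) else labels$area
    cross <- outer(area, area, `!=`)
    inh_src <- if (is.null(labels$ei)) rep(FALSE, N) else labels$ei == "I"
    l4_src <- if (is.null(labels$layer)) rep(FALSE, N)
              else startsWith(labels$layer, "4")
    cross & matrix(inh_src | l4_src, N, N, byrow = TRUE)
  })
}

.forbidden_mask <- function(constraints, net) {
  if (is.null(constraints) || is.null(constraints$forbidden))
    return(matrix(FALSE, net$N, net$N))
  m <- constraints$forbidden(net$labels)
  if (!is.matrix(m) || !identical(dim(m), c(net$N, net$N)) ||
      anyNA(m) || !is.logical(m))
    stop("constraint predicate must return a complete N x N logical matrix")
  m
}

#' Compensating parameter change at an unstable fixed point
#'
#' Solves the separatrix-preservation condition
#' \eqn{\bar\Delta_a \delta a = -\bar\Delta_b \delta b} for the
#' compensating change `delta_b`: the feedback factor \eqn{(1-M)^{-1}}
#' appears on both sides of the first-order shift and drops out, so only
#' the direct sensitivities enter. The system is solved exactly when
#' square and nonsingular, in the least-norm sense when underdetermined;
#' an inconsistent overdetermined system raises an error reporting the
#' residual rather than silently fitting.
#'
#' @param network a [network_model()]
#' @param ufp the unstable `fixed_point` whose position is to be preserved
#' @param a_spec [param_spec()] of the perturbation (with `delta`)
#' @param b_spec [param_spec()] naming the compensating parameter
#' @return `delta_b` in the natural shape of the parameter (scalar, vector
#'   or matrix), with the achieved residual as attribute `"residual"`
#' @export
compensate_scalar <- function(network, ufp, a_spec, b_spec) {
  net <- .check_network(network)
  da <- .delta_vec(a_spec, net)
  Da <- delta_bar(net, ufp, a_spec)
  Db <- delta_bar(net, ufp, b_spec)
  rhs <- -as.vector(Da %*% da)
  if (all(rhs == 0)) {
    db <- rep(0, ncol(Db))
  } else {
    sv <- svd(Db)
    tol <- max(dim(Db)) * .Machine$double.eps * sv$d[1]
    pos <- sv$d > tol
    db <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% rhs) / sv$d[pos])
    db <- as.vector(db)
    resid <- sqrt(sum((as.vector(Db %*% db) - rhs)^2))
    if (nrow(Db) > ncol(Db) && resid > 1e-8 * max(1, sqrt(sum(rhs^2))))
      stop("compensate_scalar: overdetermined system is inconsistent ",
           "(residual ", signif(resid, 4), "); no exact compensation exists")
    attr(db, "residual") <- resid
  }
  N <- net$N
  out <- switch(b_spec$kind,
    nu_ext = db[1],
    K_ext = db,
    K = devectorize(db, N, N),
    J = devectorize(db, N, N))
  attr(out, "residual") <- attr(db, "residual")
  out
}

#' Eigenmode-restricted indegree modification
#'
#' Realizes the compensation of a perturbation `a_spec` as an indegree
#' change confined to selected eigenmodes of the effective connectivity.
#' The mode coefficients are \eqn{\epsilon_l = -\hat a_l / \hat\nu_l} with
#' \eqn{\hat a_l = v_l^T \bar\Delta_a \delta a} and
#' \eqn{\hat\nu_l = v_l^T \nu}; the indegree change is assembled from the
#' rank-one terms as
#' \eqn{\delta K_{ij} = \sum_l \epsilon_l (u_l v_l^T)_{ij} /
#' [\tau_m (S_i w_{ij} + T_i w_{ij}^2)]},
#' which reproduces the mode expansion of the direct shift exactly upon
#' substitution. A selected complex mode is combined with its conjugate
#' partner (added to the selection with a warning if missing) so the
#' realized change is real. Entries with zero synaptic weight cannot carry
#' an indegree change (the row factor vanishes); they are left at zero and
#' reported in `residual_entries`.
#'
#' @inheritParams compensate_scalar
#' @param lr the [effective_connectivity()] at `ufp`
#' @param modes integer indices of the eigenmodes to use (possibly empty)
#' @param nu_hat_tol modes with `|v_l^T nu|` below this (relative to the
#'   rate norm) are rejected
#' @return object of class `modification_plan`
#' @export
indegree_mode_solution <- function(network, ufp, lr, a_spec,
                                   modes, nu_hat_tol = 1e-10) {
  net <- .check_network(network)
  if (!inherits(lr, "linear_response")) stop("'lr' must be a linear_response")
  N <- net$N
  modes <- sort(unique(as.integer(modes)))
  if (length(modes) > 0 && (min(modes) < 1 || max(modes) > N))
    stop("indegree_mode_solution: mode indices out of range")
  partner <- .conj_pairs(lr$lambdas)
  missing_partners <- setdiff(partner[modes][partner[modes] > 0], modes)
  if (length(missing_partners) > 0) {
    warning("indegree_mode_solution: adding conjugate partner mode(s) ",
            paste(missing_partners, collapse = ", "),
            " to keep the modification real")
    modes <- sort(c(modes, missing_partners))
  }
  da <- .delta_vec(a_spec, net)
  rhs <- as.vector(delta_bar(net, ufp, a_spec) %*% da)
  a_hat <- as.vector(t(lr$V) %*% rhs)
  nu_hat <- as.vector(t(lr$V) %*% lr$nu)
  eps <- complex(real = rep(0, N))
  if (length(modes) > 0) {
    bad <- modes[abs(nu_hat[modes]) < nu_hat_tol * max(1, sqrt(sum(lr$nu^2)))]
    if (length(bad) > 0)
      stop("indegree_mode_solution: mode(s) ", paste(bad, collapse = ", "),
           " have vanishing rate projection nu_hat; cannot realize them as ",
           "indegree changes")
    eps[modes] <- -a_hat[modes] / nu_hat[modes]
  }
  num <- matrix(0 + 0i, N, N)
  for (l in modes)
    num <- num + eps[l] * (lr$U[, l] %o% lr$V[, l])
  if (max(abs(Im(num))) > 1e-8 * max(1, max(abs(Re(num)))))
    warning("indegree_mode_solution: non-negligible imaginary part after ",
            "pair combination; taking the real part")
  num <- Re(num)
  ew <- effective_weight_matrices(net)
  tm <- net$par$tau_m * 1e-3
  rowfac <- tm * (lr$S_vec * ew$w_mV + lr$T_vec * ew$w_mV^2)
  delta_K <- matrix(0, N, N)
  ok <- ew$w_mV != 0
  delta_K[ok] <- num[ok] / rowfac[ok]
  residual_entries <- which(!ok & abs(num) > 0, arr.ind = TRUE)
  structure(list(delta_K = delta_K, epsilons = eps, modes = modes,
                 selected_mode = if (length(modes) == 1) modes else NA_integer_,
                 mask = matrix(TRUE, N, N),
                 residual_entries = residual_entries,
                 a_spec = a_spec, target_rhs = -rhs,
                 summaries = .plan_summaries(delta_K, net)),
            class = "modification_plan")
}

.plan_summaries <- function(delta_K, net) {
  ktot <- rowSums(net$K)
  per_target <- ifelse(ktot > 0, rowSums(delta_K) / ktot, NA_real_)
  rel <- matrix(NA_real_, net$N, net$N)
  nz <- net$K != 0
  rel[nz] <- delta_K[nz] / net$K[nz]
  list(per_target_rel = per_target, per_entry_rel = rel,
       mean_abs_per_target_rel = mean(abs(per_target), na.rm = TRUE))
}

#' @export
print.modification_plan <- function(x, ...) {
  cat(sprintf("indegree modification plan: modes {%s}\n",
              paste(x$modes, collapse = ", ")))
  cat(sprintf("  max |delta_K| = %.4g; mean |per-target relative change| = %.4g\n",
              max(abs(x$delta_K)),
              x$summaries$mean_abs_per_target_rel))
  invisible(x)
}

#' Select the critical eigenmode
#'
#' Returns the index of the unstable eigendirection (real part of the
#' eigenvalue above 1). If several modes are unstable the one with the
#' largest shift contribution `eta` is chosen (ties broken by largest real
#' part) with a warning; if none is unstable the fixed point is not
#' unstable and an error is raised.
#'
#' @param lr [effective_connectivity()] at the unstable fixed point
#' @param shift optional [predict_shift()] result used to rank multiple
#'   unstable modes
#' @return integer mode index
#' @export
select_critical_mode <- function(lr, shift = NULL) {
  if (!inherits(lr, "linear_response")) stop("'lr' must be a linear_response")
  unstable <- which(Re(lr$lambdas) > 1)
  if (length(unstable) == 0)
    stop("select_critical_mode: no eigenvalue with real part > 1; the ",
         "fixed point is not unstable")
  if (length(unstable) == 1) return(unstable)
  warning("select_critical_mode: ", length(unstable),
          " unstable eigendirections; selecting by largest contribution")
  if (!is.null(shift)) {
    eta <- shift$eta[unstable]
    eta[is.na(eta)] <- shift$eta[shift$pair[unstable][is.na(eta)]]
    best <- unstable[order(-eta, -Re(lr$lambdas[unstable]))]
    return(best[1])
  }
  unstable[order(-Re(lr$lambdas[unstable]))][1]
}

#' Apply connectivity constraints to a modification plan
#'
#' Projects the plan onto the admissible set: forbidden entries are zeroed
#' first, then entries that would drive an indegree negative are clipped
#' to exact removal (`K + delta_K = 0`). The direct shift achieved after
#' projection is re-estimated and stored next to the unconstrained target,
#' so the cost of the constraints is visible; the plan itself is not
#' re-solved — projection reporting keeps the linear theory honest.
#'
#' @param plan a [indegree_mode_solution()] result
#' @param network the [network_model()] the plan applies to
#' @param constraints a [constraint_set()]
#' @param lr optional [effective_connectivity()] to re-estimate the
#'   post-projection fixed-point shift
#' @return the projected `modification_plan`, with fields `mask`,
#'   `removed` (entries clipped to removal), and `projection_report`
#' @export
apply_constraints <- function(plan, network, constraints, lr = NULL) {
  net <- .check_network(network)
  if (!inherits(plan, "modification_plan"))
    stop("'plan' must be a modification_plan")
  if (!inherits(constraints, "constraint_set"))
    stop("'constraints' must be a constraint_set")
  forb <- .forbidden_mask(constraints, net)
  dk <- plan$delta_K
  dk[forb] <- 0
  removed <- matrix(FALSE, net$N, net$N)
  if (isTRUE(constraints$nonneg)) {
    neg <- net$K + dk < 0
    removed <- neg
    dk[neg] <- -net$K[neg]
  }
  plan$mask <- !forb
  plan$delta_K <- dk
  plan$removed <- removed
  plan$summaries <- .plan_summaries(dk, net)
  # achieved direct shift vs. the unconstrained target
  k_spec <- param_spec("K", delta = dk)
  nu_at <- if (!is.null(lr)) lr$nu else NULL
  report <- list(target_rhs = plan$target_rhs)
  if (!is.null(lr)) {
    achieved <- as.vector(delta_bar(net, lr$nu, k_spec) %*% vectorize(dk))
    report$achieved_rhs <- achieved
    report$rhs_residual <- sqrt(sum((achieved - plan$target_rhs)^2))
    sh <- tryCatch(predict_shift(lr, delta_bar(net, lr$nu, k_spec),
                                 vectorize(dk)),
                   error = function(e) NULL)
    if (!is.null(sh)) report$achieved_shift <- sh$delta_nu_star
  }
  plan$projection_report <- report
  plan
}

# apply a modification plan to a network
.apply_plan <- function(net, plan) {
  out <- net
  out$K <- net$K + plan$delta_K
  out$K[out$K < 0 & out$K > -1e-12] <- 0  # numerical dust from exact removal
  if (any(out$K < 0))
    stop("internal error: plan drove indegrees negative")
  out
}

# LA/HA outcome of the flow from the inactive state at a given kappa
.outcome_at_kappa <- function(net, scaling, kappa, ha_threshold = 100,
                              s_max = 100, h = 0.01) {
  sc <- scaling
  sc$kappa <- kappa
  tr <- integrate_flow(apply_drive_scaling(net, sc), s_max = s_max, h = h)
  if (mean(tr$nu[nrow(tr$nu), ]) < ha_threshold) "LA" else "HA"
}

# Localize an unstable fixed point for the stabilization loop. The flow
# from the inactive state crosses over at a saddle-node fold in monotone
# (purely excitatory) networks, where the LA and unstable points merge and
# the linearization degenerates; probing initial conditions on the segment
# between the LA and HA states instead yields a kappa bracket at which the
# trajectories pass a well-separated unstable fixed point.
.locate_for_stabilize <- function(net, scaling, kappa_target, localize_tol,
                                  s_max, h) {
  fp_la <- find_stable_fixed_point(net, s_max = s_max, h = h)
  sc_hi <- scaling
  sc_hi$kappa <- kappa_target
  net_hi <- apply_drive_scaling(net, sc_hi)
  nu_high <- rep(0.8 * 1000 / max(net$par$tau_r), net$N)
  fp_ha <- find_stable_fixed_point(net_hi, nu0 = nu_high, s_max = s_max,
                                   h = h)
  if (fp_ha$stability != "stable" || fp_la$stability != "stable")
    stop("stabilize: could not resolve the LA and HA reference states")
  sc_lo <- scaling
  sc_lo$kappa <- 1
  last_err <- NULL
  for (c_probe in c(0.5, 0.25, 0.1, 0.05, 0.02, 0.01)) {
    nu0 <- pmax(fp_la$nu_star + c_probe * (fp_ha$nu_star - fp_la$nu_star), 0)
    ufp <- tryCatch(
      locate_unstable_fixed_point(net, sc_lo, sc_hi, nu0 = nu0,
                                  bisect_tol = localize_tol,
                                  s_max = s_max, h = h),
      error = function(e) e)
    if (inherits(ufp, "fixed_point") && ufp$stability == "unstable")
      return(ufp)
    last_err <- ufp
  }
  stop("stabilize: failed to localize an unstable fixed point (last error: ",
       if (inherits(last_err, "condition")) conditionMessage(last_err)
       else "refined point not unstable", ")")
}

# bisect the critical kappa in (lo, hi); requires LA at lo. Returns the
# bracket, or hi if LA everywhere.
.critical_kappa <- function(net, scaling, lo, hi, tol, ...) {
  if (.outcome_at_kappa(net, scaling, lo, ...) != "LA")
    stop("stabilize: low-activity state lost at kappa = ", lo,
         "; the last modification destabilized the network")
  if (.outcome_at_kappa(net, scaling, hi, ...) == "LA")
    return(list(lo = hi, hi = NA_real_, stable_at_target = TRUE))
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (.outcome_at_kappa(net, scaling, mid, ...) == "LA") lo <- mid
    else hi <- mid
  }
  list(lo = lo, hi = hi, stable_at_target = FALSE)
}

#' Iterative eigenmode stabilization of the low-activity state
#'
#' Raises the external drive to the target level `kappa_target` while
#' preserving the basin of attraction of the low-activity state. Each
#' iteration: (1) bisects the current critical drive level (the largest
#' kappa for which the flow from the inactive state still reaches the LA
#' attractor); (2) localizes the unstable fixed point at that bracket; (3)
#' builds the linear response there, predicts the shift induced by raising
#' the drive to the target, and selects the critical (unstable) eigenmode;
#' (4) realizes the compensation as an indegree change restricted to that
#' single mode, applies the connectivity constraints, and updates the
#' network. The loop stops when the critical kappa reaches the target,
#' and aborts with diagnostics if it fails to increase across two
#' consecutive iterations or the iteration cap is hit.
#'
#' @param network a [network_model()]
#' @param kappa_target drive level to be reached with an intact LA basin
#' @param scaling a [drive_scaling()] template naming the driven
#'   populations (its `kappa` field is ignored)
#' @param constraints a [constraint_set()]; defaults to non-negativity
#'   only
#' @param max_iter iteration cap
#' @param bisect_tol bracket width for the per-iteration critical kappa
#' @param localize_tol bracket width for the unstable-point localization
#' @param kappa_step optional maximal kappa increment compensated per
#'   iteration (default: the full remaining gap)
#' @param ha_threshold mean rate separating LA from HA outcomes (spikes/s)
#' @param s_max,h flow-integration controls
#' @return list with the modified `network`, the per-iteration `report`
#'   (critical kappa, unstable-point rates, selected mode, change
#'   summaries), and `converged`
#' @export
stabilize <- function(network, kappa_target, scaling = drive_scaling(),
                      constraints = constraint_set(), max_iter = 10L,
                      bisect_tol = 1e-7, localize_tol = 1e-9,
                      kappa_step = NULL, ha_threshold = 100,
                      s_max = 100, h = 0.01) {
  net <- .check_network(network)
  if (kappa_target <= 1) stop("stabilize: kappa_target must exceed 1")
  if (.outcome_at_kappa(net, scaling, 1, ha_threshold, s_max, h) != "LA")
    stop("stabilize: the unscaled network does not reach a low-activity ",
         "state from the inactive initial condition")
  report <- list()
  prev_crit <- 0
  for (iter in seq_len(max_iter)) {
    cr <- .critical_kappa(net, scaling, lo = 1, hi = kappa_target,
                          tol = bisect_tol, ha_threshold = ha_threshold,
                          s_max = s_max, h = h)
    if (cr$stable_at_target) {
      return(list(network = net, report = report, converged = TRUE,
                  iterations = length(report)))
    }
    if (iter > 2 && cr$lo <= prev_crit + bisect_tol)
      stop("stabilize: no progress (critical kappa stuck near ",
           signif(cr$lo, 8), ") after iteration ", iter - 1,
           "; see the report for the iterations so far")
    prev_crit <- cr$lo
    ufp <- .locate_for_stabilize(net, scaling, kappa_target, localize_tol,
                                 s_max, h)
    sc_c <- scaling
    sc_c$kappa <- ufp$provenance$kappa_lo
    net_c <- apply_drive_scaling(net, sc_c)
    lr <- effective_connectivity(net_c, ufp, residual_tol = 1e-4)
    # perturbation: raising the drive from the critical level to the goal
    goal <- if (is.null(kappa_step)) kappa_target
            else min(kappa_target, cr$lo + kappa_step)
    sc_goal <- scaling
    sc_goal$kappa <- goal
    d_Kext <- apply_drive_scaling(net, sc_goal)$K_ext -
              net_c$K_ext
    a_spec <- param_spec("K_ext", delta = d_Kext)
    sh <- predict_shift(lr, delta_bar(net_c, ufp, a_spec), d_Kext)
    mode <- select_critical_mode(lr, sh)
    plan <- indegree_mode_solution(net_c, ufp, lr, a_spec, modes = mode)
    plan <- apply_constraints(plan, net_c, constraints, lr = lr)
    net <- .apply_plan(net, plan)
    report[[iter]] <- list(iteration = iter, critical_kappa = cr$lo,
                           unstable_nu = ufp$nu_star,
                           s_c = ufp$provenance$s_c,
                           selected_mode = mode,
                           lambda = lr$lambdas[mode],
                           eta = sh$eta,
                           delta_K_norm = sqrt(sum(plan$delta_K^2)),
                           summaries = plan$summaries,
                           removed = sum(plan$removed))
  }
  cr <- .critical_kappa(net, scaling, lo = 1, hi = kappa_target,
                        tol = bisect_tol, ha_threshold = ha_threshold,
                        s_max = s_max, h = h)
  list(network = net, report = report,
       converged = cr$stable_at_target, iterations = length(report))
}
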