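---
title: "Mean-field analysis and targeted stabilization of LIF network models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mean-field analysis and targeted stabilization of LIF network models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`mfstab` works at the level of neuronal populations. A network of `N`
populations of leaky integrate-and-fire (LIF) neurons with exponentially
decaying postsynaptic currents is summarized by an indegree matrix `K`
(row `i`, column `j`: the number of synapses a neuron in target population
`i` receives from population `j`), a synaptic weight matrix `J` (pA), one
set of neuron parameters per population, and an external Poisson drive
(`K_ext` sources per neuron at rate `nu_ext` with weight `J_ext`).

Under the diffusion approximation the recurrent and external input to
population `i` is summarized by its mean and variance,

$$\mu_i = \tau_m \Big[\sum_j K_{ij} w_{ij} \nu_j + K_{\mathrm{ext},i}\, w_\mathrm{ext}\, \nu_\mathrm{ext}\Big],
\qquad
\sigma_i^2 = \tau_m \Big[\sum_j K_{ij} w_{ij}^2 \nu_j + K_{\mathrm{ext},i}\, w_\mathrm{ext}^2\, \nu_\mathrm{ext}\Big],$$

with effective weights $w = J\,\tau_s/C_m$ (mV; the membrane resistance is
absorbed into the current, the standard exponential-current convention:
87.8 pA corresponds to 0.1756 mV with the default parameters). The
stationary rate of each population is the first-passage-time (Siegert)
gain

$$\frac{1}{\Phi_i} = \tau_r + \tau_m \sqrt{\pi}
\int_{\frac{V_r-\mu_i}{\sigma_i}+\gamma\sqrt{\tau_s/\tau_m}}^{\frac{\theta-\mu_i}{\sigma_i}+\gamma\sqrt{\tau_s/\tau_m}}
e^{x^2}\,(1+\mathrm{erf}\,x)\,dx,$$

where the boundary shift with $\gamma = |\zeta(1/2)|/2$ is the
linear-order correction for synaptic filtering ($\tau_s \ll \tau_m$).
$\gamma$ is evaluated from the Riemann zeta function at first use, not
hard-coded. Stationary network states are the equilibria of the
pseudo-time flow

$$\frac{d\nu}{ds} = \Phi(\nu) - \nu,$$

which is a root-finding device, not a model of the real-time dynamics:
its attractors are the stable self-consistent rate vectors, and its
velocity field is what the unstable-point localization exploits.

Assumptions inherited from the diffusion approximation: high indegrees,
weak individual synapses, and Poissonian spiking. They degrade gracefully
— in the saturated high-activity (HA) regime the gain approaches the
deterministic limit, which the implementation switches to exactly at
`sigma = 0`.

## Numerical evaluation of the gain

The integrand $e^{x^2}(1+\mathrm{erf}\,x) = \mathrm{erfcx}(-x)$ overflows
catastrophically if evaluated literally. The compiled kernel splits the
domain at 0: on the negative side it integrates the scaled complementary
error function (with an asymptotic-series branch beyond $x = 25$ and a
logarithmic substitution for the far tail beyond $-20$, which flattens
the $1/|x|$ decay), and on the positive side it uses
$\int 2e^{x^2} = \sqrt{\pi}\,\mathrm{erfi}$ analytically minus a bounded
remainder. Each bounded piece is handled by a fixed 48-node
Gauss–Legendre rule, which resolves these analytic integrands to machine
precision; the test suite checks the result against an independent
adaptive-quadrature oracle at relative tolerance $10^{-8}$ over a 20-point
$(\mu, \sigma)$ grid. When the threshold bound exceeds the overflow limit
($\approx 26.5$) the rate underflows to exactly zero, the correct
deep-subthreshold limit. The sensitivities $S_i = \partial\Phi_i/\partial\mu_i$
and $T_i = (\partial\Phi_i/\partial\sigma_i)/(2\sigma_i)$ are evaluated
analytically from the boundary terms of the integral in log-magnitude
arithmetic, and `gain_derivatives()` refuses `sigma = 0`, where `T` is
undefined.

## Fixed points

`integrate_flow()` is classical RK4 with step `h = 0.01` in pseudo-time;
rates are clipped at zero after each step (inhibition can transiently
undershoot from the inactive state) and clipping is recorded.
Convergence is declared when the flow speed stays below `1e-10` for 10
consecutive steps (`s_max = 100` by default); a point is labeled *stable*
only if the flow converged **and** all eigenvalues of the effective
connectivity there have real part below 1. For one and two populations,
`enumerate_fixed_points()` brackets every root on a dense grid (with a
doubled-resolution consistency check) or polishes a grid of damped-Newton
starts, so the LA/separatrix/HA structure can be verified exhaustively.

`locate_unstable_fixed_point()` implements the drive-bisection procedure:
with a fixed initial condition, the scaling factor $\kappa$ of the
external drive is bisected (default bracket width $10^{-9}$) between an
outcome that relaxes to the low-activity (LA) attractor and one that
escapes to the HA attractor. Near the critical $\kappa$ the trajectory
lingers near an unstable fixed point on the separatrix; the critical
pseudo-time $s_c$ is the last strict local minimum of the speed before
the two bracketing trajectories diverge (population-mean distance above 1
spike/s), with the first sample counting as a boundary minimum when the
probe starts next to the fixed point. The state at $s_c$ is refined by a
damped Newton iteration on $\Phi(\nu)-\nu$ (with a retry from the
HA-side trajectory, and a warned fall-back to the unrefined state if the
iteration escapes to a stable attractor). LA/HA outcomes are classified
by the population-mean rate against a 100 spikes/s threshold rather than
by distance to reference states: the HA state itself moves with
$\kappa$, and a distance rule can mistake that drift for bistability.

One structural point deserves emphasis. In a *monotone* (purely
excitatory) network, flow from the inactive state $\nu(0)=0$ converges to
the lowest equilibrium, so the from-rest transition to the HA state
happens exactly at the saddle-node fold where the LA and unstable points
merge — there the linearization is parabolic and no eigenvalue exceeds 1.
A genuine separatrix crossing is recovered by probing initial
conditions on the segment between the LA and HA states: the stabilization
loop does this automatically (fractions 0.5, 0.25, … of the LA→HA
segment) and keeps the first probe whose refined point is genuinely
unstable. The from-rest criterion is still what defines the basin and
the critical drive; only the localization probe differs.

## Linear response and eigenmode decomposition

At a fixed point the effective connectivity is
$M = \tau_m (S W + T W_2)$ with $W = K \circ w$ and
$W_2 = K \circ w \circ w$ (Hadamard products); `effective_connectivity()`
verifies it against a finite-difference Jacobian of the gain map in the
tests. Left eigenvectors are taken from the inverse of the
right-eigenvector matrix, which enforces bi-orthogonality
($v_l^T u_n = \delta_{ln}$) and completeness by construction; a condition
number above $10^{10}$ raises an error naming the clustered eigenvalues
instead of returning a meaningless basis. Eigenpairs are sorted by
descending real part, then imaginary part, so mode indices are
reproducible across runs.

The first-order shift of a fixed point under a parameter perturbation
$\delta a$ is $\delta\nu^* = (1-M)^{-1}\bar\Delta_a\,\delta a$ with
$\bar\Delta_a = S\,\partial\mu/\partial a + T\,\partial\sigma^2/\partial a$.
Matrix parameters are vectorized row-major, making the indegree
sensitivity block-sparse over target rows (checked exhaustively at
`N = 3`). Per-mode contributions are defined by expanding the realized
shift itself,
$\tilde\eta_l = \frac{\hat a_l}{1-\lambda_l}\,
\frac{\delta\nu^{*T}u_l}{\delta\nu^{*T}\delta\nu^*}$ with
$\hat a_l = v_l^T \bar\Delta_a \delta a$, and combining conjugate pairs
$\eta_l = \tilde\eta_l + \tilde\eta_l^*$; their sum is 1 identically,
which the suite asserts to $10^{-8}$. A sign convention lurks here: in
the compensation setting the mode coefficients point *against* the
perturbation, $\epsilon_l = -\hat a_l/\hat\nu_l$. We keep the minus sign
there, and only there, so that the contributions $\eta_l$ decompose the
realized shift and $\sum_l \eta_l = 1$ holds independently of any
convention.

## Compensation and stabilization

The separatrix-preservation condition is
$\bar\Delta_a \delta a = -\bar\Delta_b \delta b$: the feedback factor
$(1-M)^{-1}$ multiplies both sides of the shift and drops out.
`compensate_scalar()` solves it exactly when square, in the least-norm
sense (SVD pseudoinverse) when underdetermined, and refuses inconsistent
overdetermined systems, reporting the residual. For the one-population
network with $a = \nu_\mathrm{ext}$, $b = K$ everything cancels down to
$\delta K = -K_\mathrm{ext}\,\delta\nu_\mathrm{ext}/\nu^*$, which the
tests reproduce from the general machinery to $10^{-8}$. Note that with
*uniform* weights the compensation is exact (both input moments are
restored identically), so the quadratic-residual study in the tests uses
a heterogeneous-weight two-population fixture where the compensation is
genuinely first-order; there the residual shift falls by a factor ≈4 per
halving of $\delta a$.

The indegree realization restricted to eigenmodes uses
$\delta K_{ij} = \sum_l \epsilon_l\,(u_l v_l^T)_{ij}\,/\,
[\tau_m(S_i w_{ij} + T_i w_{ij}^2)]$. The placement of $\tau_m$ and the
row factor is fixed by requiring that substituting this ansatz back into
the direct sensitivity reproduces $\sum_l \epsilon_l u_l (v_l^T\nu)$
exactly — the suite verifies this identity to $10^{-8}$ (in practice it
holds to machine precision) for random mode subsets. A selected complex
mode is combined with its conjugate partner (added with a warning if
missing) so the realized change is real; structurally absent connections
($J_{ij}=0$) cannot carry indegree changes and are reported rather than
silently invented.

`stabilize()` iterates: bisect the critical drive level from rest; stop
once it reaches the target; otherwise localize the unstable fixed point
(probe scheme above), build the linear response there, compensate the
remaining drive increase along the single critical eigenmode (the unique
mode with $\mathrm{Re}\,\lambda > 1$; with several, the largest-$\eta$
one is taken with a warning), apply the constraint set, and update `K`.
Constraints are enforced by projection — forbidden entries zeroed first,
then negative indegrees clipped to exact removal — and the shift achieved
after projection is re-estimated and reported next to the unconstrained
target rather than silently re-fit. The loop aborts with diagnostics if
the critical drive fails to increase across two iterations; each
iteration may optionally compensate only a bounded $\kappa$ step
(`kappa_step`) instead of the full remaining gap.

## The synthetic fixtures

No external dataset is used; the generators define the study conditions:

* `build_single_pop()` — one excitatory population with `K_ext = K` and
  a single weight, the minimal bistable architecture. The recurrent
  indegree of this illustration is not fixed by published values, so it
  is a parameter; the default `K = 140`, `nu_ext = 30` spikes/s was
  chosen once (by a one-dimensional root scan over the drive) so that the
  drive sweep traverses the full saddle-node structure: one LA root below
  ≈15 spikes/s external rate, three roots (LA/separatrix/HA) in a window
  around the default, and a lone HA root above ≈50. With Table-level
  weights (87.8 pA) the LA state of this architecture is essentially
  silent; its rates rise toward the fold, as in the bifurcation diagram
  the sweep reproduces.
* `build_two_pop()` — the same network split into two equal,
  mutually coupled subpopulations (`K/2` each), giving an
  exchange-symmetric two-dimensional phase space whose root set matches
  the one-dimensional one on the diagonal.
* `build_ei_pair()` — a classical inhibition-dominated two-population
  network, monostable, used to exercise the no-bistability error paths.
* `build_random_multipop(N, seed)` — jittered networks around an
  excitatory backbone whose **net** recurrent mean input reproduces the
  bistable single-population reference: with a fraction `p_inh` of
  inhibitory populations (weight `g J`, indegree 1/8 of the backbone),
  the excitatory total is raised to `base_K + |g| base_K/8` so the
  planted LA/HA bistability survives the inhibition. All draws are under
  an explicit seed and leave the caller's RNG untouched.
* `build_layered_toy()` — a small area-by-layer grid with population
  sizes, for the area-level summaries (FLN/SLN) and the anatomical
  constraint rules (no cross-area connections from inhibitory or layer-4
  sources).

What the fixtures deliberately do **not** emulate: the connectome-derived
heterogeneity of a real multi-area model (hundreds of populations,
broad indegree distributions, laminar projection patterns), conduction
delays, and non-Poissonian input statistics. Passing tests therefore
demonstrate the correctness of the machinery — gain evaluation, fixed
points, eigenmode algebra, compensation — under controlled conditions,
not the biological conclusions drawn from any specific dataset, whose
reproduction would require the original connectivity data and is outside
this package's scope.

## Problem sizes and tolerances

The suite runs networks of 1–10 populations; the drive bisections in the
tests use bracket widths of $10^{-5}$–$10^{-6}$ in $\kappa$ (the default
is $10^{-9}$, the granularity at which the two bracketing trajectories
are indistinguishable until the separatrix), and the stabilization
examples target drive increases of 60–80% — far larger than the
percent-level increments the linear theory is designed around, which is
why a single iteration with a large compensation can land the LA state
close to the preserved separatrix. Step-halving of the RK4 integrator
changes terminal states by less than $10^{-8}$ spikes/s on the fixtures.

## Known limitations

* The gain is the stationary, linear-order-in-$\sqrt{\tau_s/\tau_m}$
  expression; no colored-noise corrections beyond the boundary shift, no
  conductance-based synapses, no frequency-dependent response.
* Fixed points only: no continuation of branches, no computation of the
  full separatrix manifold, and no spiking-level validation.
* The enumeration of *all* unstable fixed points in high dimensions is
  heuristic (one per stabilization iteration, at the current critical
  drive); distinctness across iterations is by pairwise distance, and
  reports flag this provenance.
* Weight-based ($\delta J$) stabilization is an extension point: the
  sensitivity `delta_bar(..., param_spec("J"))` exists, but the loop
  modifies indegrees only.
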