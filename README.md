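# mfstab

Mean-field stability analysis and targeted stabilization of spiking
network models.

## The problem

Population-level models of cortex — an indegree matrix `K`, synaptic
weights `J`, and an external Poisson drive onto networks of leaky
integrate-and-fire (LIF) neurons — are chronically underconstrained by
anatomy: raising the excitatory drive enough to give deep-layer
populations realistic firing rates shrinks the basin of attraction of the
physiological low-activity (LA) state until the network falls into a
pathological high-activity (HA) attractor. `mfstab` implements the
mean-field machinery that makes this trade-off explicit and invertible:
it computes stationary rates from connectivity, finds the stable and
unstable fixed points of the self-consistent rate equations, and derives
*minimal, anatomically constrained* indegree modifications that preserve
the LA basin while the drive is increased. It is aimed at modelers who
build data-driven multi-population spiking models and need to know which
connections control global stability.

## The method in brief

Stationary rates solve \(\nu = \Phi(\nu)\), where \(\Phi\) is the Siegert
first-passage gain of the LIF neuron under the diffusion approximation
(with the \(\gamma\sqrt{\tau_s/\tau_m}\,\sigma\), \(\gamma=|\zeta(1/2)|/2\)
boundary shift for filtered synapses); input moments follow
\(\mu_i=\tau_m[\sum_j K_{ij}w_{ij}\nu_j + K_{\mathrm{ext},i} w_\mathrm{ext}\nu_\mathrm{ext}]\)
and its squared-weight analogue. Fixed points are found by RK4
pseudo-time integration of \(\dot\nu = \Phi(\nu)-\nu\); unstable fixed
points on the separatrix are localized by bisecting the external-drive
factor \(\kappa\) and taking the last local minimum of the flow speed
before the bracketing trajectories diverge. Around a fixed point, the
linear response is governed by the effective connectivity
\(M=\tau_m(SW+TW_2)\); a parameter change \(\delta a\) shifts the fixed
point by \(\delta\nu^*=(1-M)^{-1}\bar\Delta_a\delta a\). Because the
feedback factor drops out of the compensation condition
\(\bar\Delta_a\delta a = -\bar\Delta_b\delta b\), preserving the unstable
fixed point — and with it, approximately, the separatrix — reduces to a
linear solve. Restricting \(\delta K\) to the critical eigenmode of `M`
(the one with \(\mathrm{Re}\,\lambda>1\)) yields the most effective
minimal modification; `stabilize()` iterates localization, mode
selection, compensation, and constraint projection until a target drive
level is reached. See the vignette
(`vignettes/mean-field-stabilization.Rmd`) for the full derivations,
conventions, and numerical choices.

## Worked example

The bundled single-population fixture (recurrent and external indegree
140, weight 87.8 pA, external rate 30 spikes/s) is bistable:

```r
library(mfstab)
net <- build_single_pop()
fps <- enumerate_fixed_points(net)
for (fp in fps) print(fp)
#> fixed point [stable, LA]: residual 1.34e-18
#>   rates (spikes/s): 0
#> fixed point [unstable, separatrix]: residual 2.13e-14
#>   rates (spikes/s): 34.5134
#> fixed point [stable, HA]: residual 0
#>   rates (spikes/s): 188.662
```

The LA state is silent, the HA state fires near 189 spikes/s, and the
unstable point between them (34.5 spikes/s) marks the basin boundary. Its
instability shows in the effective connectivity, and the compensation for
a 1 spike/s drive increase follows from the general machinery:

```r
u  <- fps[[2]]
lr <- effective_connectivity(net, u)
Re(lr$lambdas)
#> [1] 2.025314          # > 1: one repelling direction

compensate_scalar(net, u, param_spec("nu_ext", delta = 1), param_spec("K"))
#> [1] -4.056396
```

Raising the external rate by 1 spike/s while *removing* ≈4.06 recurrent
synapses per neuron leaves the unstable point — hence the basin boundary
— where it was; the number equals the closed form
\(-K_\mathrm{ext}\,\delta\nu_\mathrm{ext}/\nu^* = -140/34.5134\). The
same workflow scales to multi-population networks through
`locate_unstable_fixed_point()` and `stabilize()`; a command-line wrapper
with `analyze`, `stabilize`, and `scan` subcommands is installed under
`inst/cli/mfstab`.

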