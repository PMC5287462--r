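# Synthetic network fixtures: the illustrative one- and two-population
# architectures and seeded random multi-population networks.

# evaluate expr under a fixed seed without disturbing the caller's RNG state
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Single self-coupled excitatory population
#'
#' One excitatory population coupled to itself with indegree `K` and driven
#' by `K_ext` external Poisson sources of rate `nu_ext`; all synapses share
#' the weight `J`. With the default parameters the self-consistent rate
#' equation is bistable: a low-activity (LA) and a high-activity (HA)
#' stable fixed point coexist with an unstable fixed point between them,
#' and sweeping `nu_ext` from low to high traverses the
#' one/three/one fixed-point structure of the saddle-node scenario.
#'
#' @param K recurrent indegree
#' @param nu_ext external Poisson rate (spikes/s)
#' @param K_ext external indegree (defaults to `K`, the illustrative
#'   architecture)
#' @param J synaptic weight (pA)
#' @param params a [neuron_params()]
#' @param layer layer label given to the population (used by drive-scaling
#'   selectors)
#' @return a [network_model()]
#' @export
build_single_pop <- function(K = 140, nu_ext = 30, K_ext = K, J = 87.8,
                             params = neuron_params(), layer = "5E") {
  network_model(K = matrix(K, 1, 1), J = matrix(J, 1, 1), params = params,
                K_ext = K_ext, J_ext = J, nu_ext = nu_ext,
                labels = data.frame(pop = "E", area = "A1", layer = layer,
                                    ei = "E"))
}

#' Two mutually coupled excitatory subpopulations
#'
#' Splits the single self-coupled population of [build_single_pop()] into
#' two subpopulations of equal size: each receives `K/2` connections from
#' itself and `K/2` from the other, so the total recurrent input at
#' symmetric rates equals that of the single-population network. The phase
#' space is symmetric under population exchange.
#'
#' @inheritParams build_single_pop
#' @return a [network_model()] with two populations
#' @export
build_two_pop <- function(K = 140, nu_ext = 30, K_ext = K, J = 87.8,
                          params = neuron_params(), layer = "5E") {
  network_model(K = matrix(K / 2, 2, 2), J = matrix(J, 2, 2),
                params = params, K_ext = K_ext, J_ext = J, nu_ext = nu_ext,
                labels = data.frame(pop = c("E1", "E2"), area = "A1",
                                    layer = layer, ei = "E"))
}

#' Excitatory-inhibitory population pair
#'
#' A classical two-population network with one excitatory and one
#' inhibitory population. With the default inhibition-dominated weights the
#' self-consistency map has a single fixed point (monostable), which makes
#' this fixture useful for exercising the no-bistability error paths.
#'
#' @param K_e indegree from the excitatory population (both targets)
#' @param K_i indegree from the inhibitory population (both targets)
#' @param g relative inhibitory synaptic strength (negative)
#' @inheritParams build_single_pop
#' @return a [network_model()] with populations E and I
#' @export
build_ei_pair <- function(K_e = 140, K_i = 35, g = -4, nu_ext = 30,
                          K_ext = K_e, J = 87.8, params = neuron_params()) {
  K <- cbind(c(K_e, K_e), c(K_i, K_i))
  Jm <- cbind(c(J, J), c(g * J, g * J))
  network_model(K = K, J = Jm, params = params, K_ext = K_ext, J_ext = J,
                nu_ext = nu_ext,
                labels = data.frame(pop = c("E", "I"), area = "A1",
                                    layer = c("5E", "5I"), ei = c("E", "I")))
}

#' Seeded random multi-population network with planted bistability
#'
#' Generates an `N`-population network around an excitatory backbone that
#' reproduces, population-averaged, the bistable single-population fixture:
#' the total excitatory recurrent indegree of every target is `base_K` up
#' to multiplicative jitter, distributed uniformly over the excitatory
#' sources. A fraction `p_inh` of populations is inhibitory with weight
#' `g * J` and a comparatively small indegree, perturbing but not
#' destroying the planted LA/HA bistability. All draws use the supplied
#' seed; the caller's RNG state is left untouched, so repeated calls with
#' the same arguments are bit-identical.
#'
#' @param N number of populations
#' @param seed integer seed for all random draws
#' @param p_inh fraction of inhibitory populations
#' @param base_K total excitatory recurrent indegree per target
#' @param jitter relative amplitude of the uniform multiplicative jitter
#' @param g relative inhibitory synaptic strength
#' @inheritParams build_single_pop
#' @return a [network_model()]
#' @export
build_random_multipop <- function(N = 10, seed = 1, p_inh = 0.2,
                                  base_K = 140, jitter = 0.2, nu_ext = 30,
                                  g = -4, J = 87.8,
                                  params = neuron_params()) {
  if (N < 1) stop("build_random_multipop: N must be >= 1")
  .with_seed(seed, {
    n_inh <- floor(p_inh * N)
    n_exc <- N - n_inh
    if (n_exc < 1) stop("build_random_multipop: need at least one excitatory population")
    exc <- seq_len(n_exc)
    jit <- function(n) 1 + jitter * stats::runif(n, -1, 1)
    K <- matrix(0, N, N)
    Jm <- matrix(0, N, N)
    # inhibitory indegree is 1/8 of the excitatory backbone per target; the
    # excitatory total is raised so the NET recurrent mean input matches
    # the bistable single-population reference (K_exc - |g| K_inh = base_K)
    k_inh_tot <- if (n_inh > 0) base_K / 8 else 0
    k_exc_tot <- base_K + abs(g) * k_inh_tot
    K[, exc] <- (k_exc_tot / n_exc) * jit(N * n_exc)
    Jm[, exc] <- J
    if (n_inh > 0) {
      inh <- (n_exc + 1):N
      K[, inh] <- (k_inh_tot / n_inh) * jit(N * n_inh)
      Jm[, inh] <- g * J
    }
    K_ext <- base_K * jit(N)
    ei <- rep(c("E", "I"), c(n_exc, n_inh))
    labels <- data.frame(pop = paste0(ei, c(seq_len(n_exc),
                                            seq_len(max(n_inh, 0)))[seq_len(N)]),
                         area = "A1",
                         layer = paste0("5", ei), ei = ei)
    network_model(K = K, J = Jm, params = params, K_ext = K_ext, J_ext = J,
                  nu_ext = nu_ext, labels = labels)
  })
}

#' Layered multi-area toy network
#'
#' Small area-by-layer grid used to exercise the area-level summaries
#' (FLN/SLN) and label-based connectivity constraints. Intra-area
#' connectivity is dense; cross-area connections originate in excitatory
#' layers only, with seeded jitter on all indegrees. Population sizes are
#' drawn so size-weighted summaries are non-trivial.
#'
#' @param areas character vector of area names
#' @param layers character vector of layer names; a trailing `"I"` marks a
#'   population as inhibitory, anything else as excitatory
#' @param seed integer seed
#' @inheritParams build_single_pop
#' @return a [network_model()] with labels, `pop_sizes`, and an
#'   `area_partition` attached as attribute `"partition"`
#' @export
build_layered_toy <- function(areas = c("X", "Y"),
                              layers = c("23E", "4E", "5E", "6E", "23I"),
                              seed = 1, nu_ext = 30, J = 87.8,
                              params = neuron_params()) {
  .with_seed(seed, {
    grid <- expand.grid(layer = layers, area = areas,
                        stringsAsFactors = FALSE)[, c(2, 1)]
    N <- nrow(grid)
    ei <- ifelse(grepl("I$", grid$layer), "I", "E")
    K <- matrix(0, N, N)
    Jm <- matrix(0, N, N)
    for (i in seq_len(N)) {
      for (j in seq_len(N)) {
        same_area <- grid$area[i] == grid$area[j]
        if (same_area) {
          K[i, j] <- 50 * (1 + 0.3 * stats::runif(1, -1, 1))
        } else if (ei[j] == "E") {
          K[i, j] <- 15 * (1 + 0.3 * stats::runif(1, -1, 1))
        }
        Jm[i, j] <- if (ei[j] == "E") J else -4 * J
      }
    }
    labels <- data.frame(pop = paste(grid$area, grid$layer, sep = "."),
                         area = grid$area, layer = grid$layer, ei = ei)
    net <- network_model(K = K, J = Jm, params = params, K_ext = 100,
                         J_ext = J, nu_ext = nu_ext, labels = labels,
                         pop_sizes = round(stats::runif(N, 500, 1500)))
    attr(net, "partition") <- area_partition(grid$area,
                                             supragranular = grid$layer == "23E")
    net
  })
}
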