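# Area partitions and the relative cross-area indegree summaries FLN/SLN.

#' Partition populations into named areas
#'
#' @param areas character vector (length N) assigning each population to an
#'   area
#' @param supragranular optional logical vector (length N) marking the
#'   supragranular excitatory source populations (layer 2/3E), used by
#'   [sln()]
#' @return object of class `area_partition`
#' @export
area_partition <- function(areas, supragranular = NULL) {
  areas <- as.character(areas)
  if (anyNA(areas)) stop("area_partition: every population needs an area")
  if (!is.null(supragranular)) {
    supragranular <- as.logical(rep_len(supragranular, length(areas)))
  }
  structure(list(areas = areas, supragranular = supragranular),
            class = "area_partition")
}

.check_partition <- function(partition, net) {
  if (!inherits(partition, "area_partition"))
    stop("expected an area_partition object")
  if (length(partition$areas) != net$N)
    stop("area_partition does not match the number of populations")
  partition
}

# total cross-area synapses per target-area neuron: with pop_sizes,
# sum_{i in A, j in B} K_ij n_i / sum_{i in A} n_i; otherwise the unweighted
# indegree sum (reported via attribute).
.area_indegree <- function(net, partition) {
  areas <- unique(partition$areas)
  nA <- length(areas)
  KA <- matrix(0, nA, nA, dimnames = list(areas, areas))
  weighted <- !is.null(net$pop_sizes)
  n <- if (weighted) net$pop_sizes else rep(1, net$N)
  for (A in areas) {
    ia <- which(partition$areas == A)
    wA <- n[ia] / sum(n[ia])
    for (B in areas) {
      jb <- which(partition$areas == B)
      KA[A, B] <- sum(net$K[ia, jb, drop = FALSE] * wA)
    }
  }
  attr(KA, "size_weighted") <- weighted
  KA
}

#' Fraction of labeled neurons (relative cross-area indegree)
#'
#' For each target area `A`, the share of its total cross-area indegree
#' contributed by each external source area `B`:
#' `FLN_AB = K_AB / sum_{B' != A} K_AB'`, where `K_AB` is the total number
#' of synapses from `B` per neuron in `A` (population-size weighted when
#' `pop_sizes` are available, unweighted otherwise — the result records
#' which via the `"size_weighted"` attribute). Rows of isolated areas (no
#' cross-area input) are `NA` and listed in the `"undefined_rows"`
#' attribute rather than propagating NaN silently.
#'
#' @param network a [network_model()]
#' @param partition an [area_partition()]
#' @return area x area matrix with `NA` diagonal; defined rows sum to 1
#' @export
fln <- function(network, partition) {
  net <- .check_network(network)
  partition <- .check_partition(partition, net)
  KA <- .area_indegree(net, partition)
  out <- KA
  diag(out) <- NA_real_
  undef <- character(0)
  for (A in rownames(out)) {
    tot <- sum(out[A, ], na.rm = TRUE)
    if (tot > 0) {
      out[A, ] <- out[A, ] / tot
    } else {
      out[A, ] <- NA_real_
      undef <- c(undef, A)
    }
  }
  attr(out, "size_weighted") <- attr(KA, "size_weighted")
  attr(out, "undefined_rows") <- undef
  out
}

#' Fraction of supragranular labeled neurons
#'
#' Share of each cross-area projection that originates in the designated
#' supragranular excitatory populations (layer 2/3E):
#' `SLN_AB = sum_i K^{i,2/3E}_{AB} n^i_A / sum_{i, j in exc} K^{ij}_{AB} n^i_A`.
#' Requires `pop_sizes` on the network and a `supragranular` designation on
#' the partition; excitatory source populations are those with label
#' `ei == "E"` (all populations if no `ei` labels exist).
#'
#' @inheritParams fln
#' @return area x area matrix with entries in `[0, 1]` (`NA` where the
#'   excitatory projection is empty, and on the diagonal)
#' @export
sln <- function(network, partition) {
  net <- .check_network(network)
  partition <- .check_partition(partition, net)
  if (is.null(net$pop_sizes))
    stop("sln: network has no pop_sizes; synapse counts are undefined")
  if (is.null(partition$supragranular))
    stop("sln: partition has no supragranular designation")
  exc <- if (is.null(net$labels$ei)) rep(TRUE, net$N) else net$labels$ei == "E"
  areas <- unique(partition$areas)
  out <- matrix(NA_real_, length(areas), length(areas),
                dimnames = list(areas, areas))
  n <- net$pop_sizes
  for (A in areas) {
    ia <- which(partition$areas == A)
    for (B in setdiff(areas, A)) {
      jb_exc <- which(partition$areas == B & exc)
      jb_sg <- which(partition$areas == B & partition$supragranular)
      tot <- sum(net$K[ia, jb_exc, drop = FALSE] * n[ia])
      if (tot > 0)
        out[A, B] <- sum(net$K[ia, jb_sg, drop = FALSE] * n[ia]) / tot
    }
  }
  out
}
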