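# Parametrized scaling of the external drive (kappa).

#' External-drive scaling rule
#'
#' Describes a multiplicative enhancement of the external indegree of
#' selected populations: the primary targets' `K_ext` is multiplied by
#' `kappa`, and an optional secondary selector follows an affine rule in
#' `kappa`. The default secondary rule is the unique affine map through
#' (1, 1) and (1.15, 1.5), i.e. `K_sec,ext / K_ext = 1 + (kappa - 1) * (0.5 / 0.15)`,
#' so a 15% enhancement of the primary targets comes with a 50% enhancement
#' of the secondary ones.
#'
#' Selectors are either a character value matched against the `layer`
#' column of the network labels, or a predicate `function(labels)`
#' returning a logical vector over populations.
#'
#' @param kappa dimensionless drive multiplier, `>= 0`; `kappa = 1` leaves
#'   the network unchanged
#' @param target selector for the primary populations (default layer
#'   `"5E"`)
#' @param secondary selector for the secondary populations (default layer
#'   `"6E"`), or `NULL` for none
#' @param secondary_slope slope of the affine secondary rule (ratio gained
#'   per unit of `kappa - 1`)
#' @return an object of class `drive_scaling`
#' @export
drive_scaling <- function(kappa = 1, target = "5E", secondary = "6E",
                          secondary_slope = 0.5 / 0.15) {
  if (!is.numeric(kappa) || length(kappa) != 1L || !is.finite(kappa) || kappa < 0)
    stop("drive_scaling: 'kappa' must be a single number >= 0")
  structure(list(kappa = kappa, target = target, secondary = secondary,
                 secondary_slope = secondary_slope),
            class = "drive_scaling")
}

#' @export
print.drive_scaling <- function(x, ...) {
  cat(sprintf("drive scaling: kappa = %g\n", x$kappa))
  invisible(x)
}

.resolve_selector <- function(selector, labels) {
  if (is.null(selector)) return(rep(FALSE, nrow(labels)))
  if (is.function(selector)) {
    sel <- selector(labels)
  } else if (is.character(selector)) {
    sel <- if (is.null(labels$layer)) rep(FALSE, nrow(labels))
           else labels$layer %in% selector
  } else if (is.logical(selector)) {
    sel <- rep_len(selector, nrow(labels))
  } else stop("unsupported selector type")
  as.logical(sel)
}

#' Apply a drive scaling to a network
#'
#' Multiplies the external indegree of the primary target populations by
#' `kappa` and sets the secondary populations' external indegree according
#' to the affine secondary rule. `kappa = 1` returns the network exactly
#' unchanged. An empty primary selector triggers a warning and the network
#' is returned as is.
#'
#' @param network a [network_model()]
#' @param scaling a [drive_scaling()]
#' @return the scaled `network_model`
#' @export
apply_drive_scaling <- function(network, scaling) {
  net <- .check_network(network)
  if (!inherits(scaling, "drive_scaling"))
    stop("apply_drive_scaling: 'scaling' must be a drive_scaling object")
  if (scaling$kappa == 1) return(net)
  primary <- .resolve_selector(scaling$target, net$labels)
  if (!any(primary)) {
    warning("apply_drive_scaling: selector matches no population; ",
            "returning network unchanged")
    return(net)
  }
  secondary <- .resolve_selector(scaling$secondary, net$labels)
  out <- net
  out$K_ext[primary] <- net$K_ext[primary] * scaling$kappa
  if (any(secondary)) {
    ratio <- 1 + (scaling$kappa - 1) * scaling$secondary_slope
    out$K_ext[secondary] <- net$K_ext[secondary] * ratio
  }
  out
}
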