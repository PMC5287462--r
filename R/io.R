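# Serialization: network configs (YAML + labeled delimited matrices),
# trajectories, fixed-point and eigenspectrum reports, modification plans.

.fmt15 <- function(x) formatC(x, digits = 17, format = "g")

.write_matrix <- function(M, file) {
  ch <- matrix(.fmt15(M), nrow(M), ncol(M), dimnames = dimnames(M))
  utils::write.table(ch, file, sep = "\t", quote = FALSE,
                     col.names = NA, row.names = TRUE)
}

.read_matrix <- function(file) {
  df <- utils::read.table(file, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE, colClasses = "character")
  M <- apply(as.matrix(df), c(1, 2), as.numeric)
  M
}

#' Write a network model to files
#'
#' Serializes a network as one YAML config plus two delimited-text
#' matrices. `stem` is extended to `<stem>_config.yaml`, `<stem>_K.tsv` and
#' `<stem>_J.tsv`. Matrices carry population labels as header row and
#' column; rows are targets, columns sources. The round trip through
#' [read_network()] is lossless to at least 15 significant digits.
#'
#' @param network a [network_model()]
#' @param stem path prefix for the three files
#' @return the three file paths, invisibly
#' @export
write_network <- function(network, stem) {
  net <- .check_network(network)
  paths <- paste0(stem, c("_config.yaml", "_K.tsv", "_J.tsv"))
  cfg <- list(
    convention = "rows are targets: K[i, j] is the indegree of population i from population j",
    weight_unit = net$weight_unit,
    nu_ext = net$nu_ext,
    J_ext = net$J_ext,
    K_ext = as.numeric(net$K_ext),
    ext_multiplier = net$ext_multiplier,
    populations = lapply(seq_len(net$N), function(i) {
      lab <- as.list(net$labels[i, , drop = FALSE])
      lab <- lapply(lab, as.vector)
      if (!is.null(net$pop_sizes)) lab$size <- net$pop_sizes[i]
      p <- net$params[[i]]
      lab$neuron <- p[names(p)]
      lab
    }))
  yaml::write_yaml(cfg, paths[1], precision = 15)
  .write_matrix(net$K, paths[2])
  .write_matrix(net$J, paths[3])
  invisible(paths)
}

#' Read a network model written by [write_network()]
#'
#' @param stem the path prefix used when writing
#' @return a [network_model()]
#' @export
read_network <- function(stem) {
  cfg <- yaml::read_yaml(paste0(stem, "_config.yaml"))
  K <- .read_matrix(paste0(stem, "_K.tsv"))
  J <- .read_matrix(paste0(stem, "_J.tsv"))
  pops <- cfg$populations
  lab_fields <- setdiff(names(pops[[1]]), c("neuron", "size"))
  labels <- do.call(rbind, lapply(pops, function(p)
    as.data.frame(p[lab_fields], stringsAsFactors = FALSE)))
  params <- lapply(pops, function(p) do.call(neuron_params, p$neuron))
  sizes <- if (!is.null(pops[[1]]$size))
    vapply(pops, `[[`, numeric(1), "size") else NULL
  network_model(K = K, J = J, params = params, K_ext = cfg$K_ext,
                J_ext = cfg$J_ext, nu_ext = cfg$nu_ext, labels = labels,
                pop_sizes = sizes, ext_multiplier = cfg$ext_multiplier,
                weight_unit = cfg$weight_unit)
}

#' Export a trajectory as delimited text
#'
#' Columns: pseudo-time `s`, one rate column per population, and the flow
#' speed.
#'
#' @param trajectory an [integrate_flow()] result
#' @param file output path
#' @param header optional named list written as `# key: value` comment
#'   lines
#' @export
write_trajectory <- function(trajectory, file, header = NULL) {
  if (!inherits(trajectory, "trajectory")) stop("expected a trajectory")
  con <- file(file, "w")
  on.exit(close(con))
  for (nm in names(header))
    writeLines(sprintf("# %s: %s", nm, header[[nm]]), con)
  df <- data.frame(s = trajectory$s, trajectory$nu,
                   speed = trajectory$speed)
  names(df) <- c("s", paste0("nu", seq_len(ncol(trajectory$nu))), "speed")
  utils::write.table(format(df, digits = 15), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Eigenspectrum report
#'
#' Writes a delimited table of the eigenmodes at a fixed point: mode
#' index, real and imaginary part of the eigenvalue, the real shift
#' contribution `eta` (when a [predict_shift()] is supplied), and the
#' populations with the largest right-eigenvector magnitudes.
#'
#' @param lr a [effective_connectivity()] result
#' @param file output path
#' @param shift optional [predict_shift()] providing `eta`
#' @param top number of top populations listed per mode
#' @export
write_spectrum_report <- function(lr, file, shift = NULL, top = 3L) {
  if (!inherits(lr, "linear_response")) stop("expected a linear_response")
  N <- length(lr$lambdas)
  labs <- lr$network$labels$pop
  topstr <- vapply(seq_len(N), function(l) {
    mag <- abs(lr$U[, l])
    paste(labs[order(-mag)][seq_len(min(top, N))], collapse = ",")
  }, character(1))
  df <- data.frame(mode = seq_len(N),
                   re_lambda = Re(lr$lambdas),
                   im_lambda = Im(lr$lambdas),
                   eta = if (!is.null(shift)) shift$eta else NA_real_,
                   top_populations = topstr)
  utils::write.table(format(df, digits = 10), file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Fixed-point report
#'
#' Structured-text (YAML) report of one or more fixed points including
#' their provenance.
#'
#' @param fps a `fixed_point` or list of them
#' @param file output path
#' @param header optional named list prepended to the report
#' @export
write_fixed_point_report <- function(fps, file, header = NULL) {
  if (inherits(fps, "fixed_point")) fps <- list(fps)
  entries <- lapply(fps, function(fp)
    list(rates = as.numeric(fp$nu_star),
         residual = fp$residual,
         stability = fp$stability,
         label = fp$label,
         provenance = fp$provenance))
  yaml::write_yaml(c(header, list(fixed_points = entries)), file,
                   precision = 15)
  invisible(file)
}

#' Modification-plan report
#'
#' Writes the indegree change matrix and a per-target summary table.
#' `stem` is extended to `<stem>_deltaK.tsv` and `<stem>_summary.tsv`.
#'
#' @param plan a [indegree_mode_solution()] result
#' @param network the network the plan applies to
#' @param stem path prefix
#' @export
write_plan <- function(plan, network, stem) {
  net <- .check_network(network)
  if (!inherits(plan, "modification_plan")) stop("expected a modification_plan")
  dk <- plan$delta_K
  dimnames(dk) <- dimnames(net$K)
  .write_matrix(dk, paste0(stem, "_deltaK.tsv"))
  df <- data.frame(pop = net$labels$pop,
                   total_K = rowSums(net$K),
                   total_delta_K = rowSums(plan$delta_K),
                   per_target_rel = plan$summaries$per_target_rel)
  utils::write.table(format(df, digits = 10), paste0(stem, "_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(stem)
}
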