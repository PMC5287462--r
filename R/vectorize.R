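# Row-major vectorization convention for matrix-valued parameters.

#' Vectorize a matrix by concatenating its rows
#'
#' Row-major flattening: entry `(i, j)` of an `N x N` matrix maps to
#' position `(i - 1) * N + j` of the vector. This is the convention used
#' for matrix-valued parameters throughout the linear-response machinery,
#' so that the sensitivity of population `i` to its own row of indegrees
#' occupies one contiguous block.
#'
#' @param M a matrix
#' @return numeric vector of length `nrow(M) * ncol(M)`
#' @seealso [devectorize()]
#' @export
vectorize <- function(M) {
  M <- as.matrix(M)
  as.vector(t(M))
}

#' Inverse of [vectorize()]
#'
#' @param v numeric vector whose length is a perfect square (or supply
#'   `nrow`/`ncol` for non-square shapes)
#' @param nrow,ncol optional target shape
#' @return a matrix with `v` laid out row-major
#' @export
devectorize <- function(v, nrow = NULL, ncol = NULL) {
  if (is.null(nrow) && is.null(ncol)) {
    n <- sqrt(length(v))
    if (n != round(n))
      stop("devectorize: length is not a perfect square; supply nrow/ncol")
    nrow <- ncol <- as.integer(n)
  } else if (is.null(ncol)) {
    ncol <- length(v) / nrow
  } else if (is.null(nrow)) {
    nrow <- length(v) / ncol
  }
  if (nrow * ncol != length(v))
    stop("devectorize: shape does not match length")
  matrix(v, nrow = nrow, ncol = ncol, byrow = TRUE)
}
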