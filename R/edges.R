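#' Edge vectorization of symmetric connectivity matrices
#'
#' Connectivity matrices are stored edge-wise as the strict upper triangle in
#' row-major order: (1,2), (1,3), ..., (1,p), (2,3), ..., (p-1,p). A 90-ROI
#' network yields 4005 edges, the 14-ROI motor subnetwork 91.
#'
#' @param m Symmetric matrix with zero diagonal.
#' @param tol Symmetry tolerance (default 1e-10).
#' @return Numeric vector of length p*(p-1)/2.
#' @seealso [devectorize_edges()], [edge_index_map()]
#' @export
vectorize_edges <- function(m, tol = 1e-10) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (max(abs(m - t(m))) > tol) {
    stop("matrix is not symmetric within tolerance ", tol)
  }
  # row-major upper triangle == column-major traversal of the transpose's
  # lower triangle
  tm <- t(m)
  tm[lower.tri(tm)]
}

#' Rebuild a symmetric zero-diagonal matrix from an edge vector
#'
#' Inverse of [vectorize_edges()].
#'
#' @param v Edge vector of length p*(p-1)/2.
#' @param p Number of ROIs; inferred from `length(v)` when omitted.
#' @return p x p symmetric matrix with zero diagonal.
#' @export
devectorize_edges <- function(v, p = NULL) {
  if (is.null(p)) {
    p <- (1 + sqrt(1 + 8 * length(v))) / 2
    if (abs(p - round(p)) > 1e-9) stop("length(v) is not p*(p-1)/2 for integer p")
    p <- as.integer(round(p))
  }
  stopifnot(length(v) == p * (p - 1) / 2)
  m <- matrix(0, p, p)
  tm <- t(m)
  tm[lower.tri(tm)] <- v
  m <- t(tm)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

#' Map edge positions to ROI index pairs
#'
#' @param p Number of ROIs.
#' @return Two-column integer matrix (`i`, `j`), row k giving the ROI pair of
#'   edge k in the row-major upper-triangle ordering, i < j.
#' @export
edge_index_map <- function(p) {
  i <- rep.int(seq_len(p - 1L), times = (p - 1L):1L)
  j <- sequence((p - 1L):1L) + i
  cbind(i = i, j = j)
}

#' Edge position of an ROI pair
#'
#' @param i,j ROI indices (order-free; must differ).
#' @param p Number of ROIs.
#' @return Integer position within the row-major upper-triangle edge vector.
#' @export
edge_index <- function(i, j, p) {
  lo <- pmin(i, j); hi <- pmax(i, j)
  if (any(lo == hi)) stop("diagonal entries have no edge index")
  if (any(hi > p) || any(lo < 1)) stop("ROI index out of range")
  as.integer((lo - 1) * (2 * p - lo) / 2 + (hi - lo))
}

# validate FC matrix invariants: symmetric, zero diagonal, entries in [0,1]
validate_fc <- function(m, what = "FC matrix", tol = 1e-10) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop(what, ": not square")
  if (max(abs(m - t(m))) > tol) stop(what, ": not symmetric")
  if (max(abs(diag(m))) > tol) stop(what, ": nonzero diagonal")
  bad <- which(m < -tol | m > 1 + tol)
  if (length(bad)) {
    stop(what, ": entries outside [0,1] at positions ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  invisible(TRUE)
}
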