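#' Strong-connection relation of an affinity graph
#'
#' Node i strongly depends on node j when `A_ij >= theta * sum_{k != i} A_ik`,
#' i.e. strength is measured relative to the off-diagonal row sum of the
#' coupling matrix. The relation is directional (row sums differ between the
#' endpoints even though `A` is symmetric); the C/F splitting symmetrizes it.
#' A node with zero off-diagonal row sum has no strong connections.
#'
#' @param graph A `swa_level`.
#' @param theta Strength threshold in `[0, 1]`. With `theta = 0` every
#'   nonzero edge is strong.
#' @return A sparse logical (pattern) matrix `S` with `S[i, j]` true when i
#'   strongly depends on j.
#' @export
strong_connections <- function(graph, theta) {
  stopifnot(theta >= 0, theta <= 1)
  A <- graph$A
  n <- nrow(A)
  Aoff <- A
  Matrix::diag(Aoff) <- 0
  Aoff <- Matrix::drop0(Aoff)
  rs <- Matrix::rowSums(Aoff)
  tr <- methods::as(methods::as(Aoff, "generalMatrix"), "TsparseMatrix")
  i <- tr@i + 1L
  j <- tr@j + 1L
  keep <- tr@x > 0 & tr@x >= theta * rs[i]
  Matrix::sparseMatrix(
    i = i[keep], j = j[keep], x = TRUE, dims = c(n, n)
  )
}

#' First pass of Ruge-Stuben C/F splitting
#'
#' Partitions the nodes of a level into C-points (seeds of coarse-level
#' blocks) and F-points using the first pass of the classical algebraic
#' multigrid coarsening algorithm on the symmetrized (union of both
#' directions) strong-connection graph. Each unassigned node is weighted by
#' the number of nodes strongly depending on it; the maximum-weight node
#' (lowest index on ties) becomes a C-point, its strong neighbours become
#' F-points, and the weights of those F-points' other strong neighbours are
#' incremented. Nodes listed in `forced_c` (salient blocks) are seeded as
#' C-points before the loop; nodes without strong connections become
#' C-points so isolated blocks survive coarsening.
#'
#' @param graph A `swa_level`.
#' @param theta Strength threshold passed to [strong_connections()].
#' @param forced_c Integer vector of node indices pre-designated as C-points
#'   (defaults to the level's salient nodes).
#' @return An object of class `swa_cf_split`: list with `c_points`,
#'   `f_points` (increasing integer indices) and `forced`.
#' @export
first_pass_cf <- function(graph, theta, forced_c = which(graph$salient)) {
  n <- n_nodes(graph)
  forced_c <- sort(unique(as.integer(forced_c)))
  if (length(forced_c) && (min(forced_c) < 1L || max(forced_c) > n)) {
    stop("forced_c out of range", call. = FALSE)
  }
  S <- strong_connections(graph, theta)
  Ssym <- methods::as(S | Matrix::t(S), "CsparseMatrix")
  state <- rs_first_pass_cpp(Ssym@p, Ssym@i, n, forced_c - 1L)
  structure(
    list(
      c_points = which(state == 1L),
      f_points = which(state == 2L),
      forced = forced_c
    ),
    class = "swa_cf_split"
  )
}

#' @export
print.swa_cf_split <- function(x, ...) {
  cat(sprintf(
    "<swa_cf_split> %d C-points (%d forced), %d F-points\n",
    length(x$c_points), length(x$forced), length(x$f_points)
  ))
  invisible(x)
}
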