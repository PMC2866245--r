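## Diagonals used by the saliency measures:
##   L_ii = off-diagonal row sum of A (similarity-weighted boundary length)
##   W_ii = A_ii                     (twice the similarity-weighted area)
##   G_ii, V_ii: unweighted counterparts from the Boolean matrices.
saliency_diagonals <- function(graph) {
  A <- graph$A
  dA <- unname(Matrix::diag(A))
  list(
    L = unname(Matrix::rowSums(A)) - dA,
    W = dA,
    G = unname(Matrix::diag(graph$G)),
    V = unname(Matrix::diag(graph$V))
  )
}

#' Normalized-cut energy of a block indicator
#'
#' For a Boolean indicator u of a block on level r, returns
#' `(u' L u) / ((1/2) u' W u)` with `L` the weighted graph Laplacian of the
#' level's affinity matrix and `W = A`: the similarity-weighted boundary of
#' the block divided by its similarity-weighted area. Low energy means the
#' block is weakly coupled to its surroundings relative to its internal
#' cohesion.
#'
#' @param graph A `swa_level`.
#' @param indicator Logical or 0/1 numeric vector over the level's nodes.
#' @return Nonnegative scalar.
#' @export
energy_functional <- function(graph, indicator) {
  u <- as.numeric(indicator)
  stopifnot(length(u) == n_nodes(graph), all(u %in% c(0, 1)))
  if (!any(u == 1)) {
    stop("indicator must select at least one node", call. = FALSE)
  }
  A <- graph$A
  dA <- Matrix::diag(A)
  Au <- as.numeric(A %*% u)
  denom <- 0.5 * sum(u * Au)
  if (denom <= 0) {
    stop("undefined saliency: block has zero weighted area", call. = FALSE)
  }
  # u' L u with L = diag(offdiag row sums) - offdiag(A)
  off_rs <- Matrix::rowSums(A) - dA
  num <- sum(u * (off_rs * u - (Au - dA * u)))
  num / denom
}

#' Original (scale-dependent) saliency of a node
#'
#' `Gamma_i = L_ii / ((1/2) W_ii)`: the energy of the single-node indicator.
#' Because boundary length grows linearly and area quadratically with block
#' size, this measure shrinks on coarser levels; it favours large segments.
#' Undefined on the finest level where `W_ii = 0`.
#'
#' @param graph A `swa_level` at level >= 2.
#' @param node Node index.
#' @return Nonnegative scalar.
#' @export
saliency_original <- function(graph, node) {
  d <- saliency_diagonals(graph)
  if (d$W[node] <= 0) {
    stop("undefined saliency: W_ii = 0 (finest level or decoupled node)",
         call. = FALSE)
  }
  d$L[node] / (0.5 * d$W[node])
}

#' Scale-invariant saliency of a node
#'
#' `Gamma_i = (L_ii / G_ii) / (W_ii / V_ii)`: the average similarity along
#' the block boundary divided by the average similarity in the block
#' interior. Normalizing the weighted boundary length and area by their
#' unweighted (Boolean) counterparts removes the size and shape dependence of
#' the original measure, so one saliency threshold works on all levels.
#'
#' @param graph A `swa_level` at level >= 2.
#' @param node Node index.
#' @return Nonnegative scalar.
#' @export
saliency_scale_invariant <- function(graph, node) {
  d <- saliency_diagonals(graph)
  if (d$G[node] <= 0 || d$V[node] <= 0 || d$W[node] <= 0) {
    stop("undefined saliency: zero boundary length, area, or weighted area",
         call. = FALSE)
  }
  (d$L[node] / d$G[node]) / (d$W[node] / d$V[node])
}

#' Detect salient blocks on a level
#'
#' Evaluates the chosen saliency measure for every non-salient node
#' (simultaneously, from the level's current operators) and flags those with
#' `Gamma_i < gamma`. To avoid spurious small segments no detection happens
#' on levels up to `sigma`. Flagged nodes are decoupled: their off-diagonal
#' affinities are zeroed (symmetrically) so no later rescaling or
#' interpolation can re-attach them, and they are forced C-points on all
#' coarser levels. A fully decoupled node (zero weighted boundary) has
#' saliency 0 and is flagged.
#'
#' @param graph A `swa_level`.
#' @param gamma Positive saliency threshold (strict inequality, so
#'   `gamma = 0` never flags).
#' @param sigma Detection threshold level: detection only when
#'   `graph$level > sigma`.
#' @param measure `"scale_invariant"` (default) or `"original"`.
#' @return List of class `swa_saliency_report`: the updated `graph`, the
#'   per-node saliency `values` (NA where undefined and not decoupled),
#'   `newly_salient` indices, and `measure`.
#' @export
detect_salient <- function(graph, gamma, sigma,
                           measure = c("scale_invariant", "original")) {
  stopifnot(gamma >= 0, sigma >= 0)
  measure <- match.arg(measure)
  n <- n_nodes(graph)
  values <- rep(NA_real_, n)
  newly <- integer(0)
  if (graph$level > sigma) {
    d <- saliency_diagonals(graph)
    values <- if (measure == "scale_invariant") {
      ifelse(d$L == 0, 0,
             (d$L / d$G) / (d$W / d$V))
    } else {
      ifelse(d$L == 0, 0, d$L / (0.5 * d$W))
    }
    newly <- which(!graph$salient & !is.na(values) & values < gamma)
    if (length(newly)) {
      graph$salient[newly] <- TRUE
      A <- graph$A
      keep_diag <- Matrix::diag(A)[newly]
      A[newly, ] <- 0
      A[, newly] <- 0
      A[cbind(newly, newly)] <- keep_diag
      graph$A <- Matrix::drop0(A)
    }
  }
  structure(
    list(graph = graph, values = values, newly_salient = newly,
         measure = measure),
    class = "swa_saliency_report"
  )
}

#' @export
print.swa_saliency_report <- function(x, ...) {
  cat(sprintf(
    "<swa_saliency_report> level %d, measure %s: %d newly salient (%d total)\n",
    x$graph$level, x$measure, length(x$newly_salient), sum(x$graph$salient)
  ))
  invisible(x)
}
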