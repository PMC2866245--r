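#' Interpolation (prolongation) operator from a C/F splitting
#'
#' Column j of the operator represents the coarse node seeded at C-point
#' `c_points[j]`. A C-point row carries a single 1 in its own column; an
#' F-point row distributes the node over the C-points it couples to,
#' proportionally to the affinities: `P_ij = A_{i,C_j} / sum_{k in C} A_ik`.
#' Every row sums to one, so a coarse node is an overlapping, fractional
#' block of fine nodes.
#'
#' @param graph A `swa_level`.
#' @param split A `swa_cf_split` for that level.
#' @return Sparse `n_fine x n_coarse` matrix with unit row sums.
#' @export
build_interpolation <- function(graph, split) {
  n <- n_nodes(graph)
  cpts <- split$c_points
  fpts <- split$f_points
  nc <- length(cpts)
  if (length(cpts) + length(fpts) != n ||
      length(intersect(cpts, fpts)) > 0L) {
    stop("split does not partition the nodes of this level", call. = FALSE)
  }
  A <- graph$A
  # F-point rows: affinities to C-points, row-normalized over C columns only
  AFC <- A[fpts, cpts, drop = FALSE]
  rs <- Matrix::rowSums(AFC)
  if (any(rs <= 0)) {
    stop(
      "internal consistency error: F-point with zero coupling to all C-points",
      call. = FALSE
    )
  }
  AFC <- Matrix::Diagonal(length(fpts), 1 / rs) %*% AFC
  tr <- methods::as(methods::as(AFC, "generalMatrix"), "TsparseMatrix")
  P <- Matrix::sparseMatrix(
    i = c(cpts, fpts[tr@i + 1L]),
    j = c(seq_len(nc), tr@j + 1L),
    x = c(rep(1, nc), tr@x),
    dims = c(n, nc)
  )
  P
}

#' Galerkin triple product
#'
#' Coarsens a symmetric operator `M` to the next level as `t(P) %*% M %*% P`.
#' Applied identically to the affinity matrix `A`, the boundary-length matrix
#' `G`, and the area matrix `V`.
#'
#' @param matrix_fine Symmetric sparse (or dense) matrix on the fine level.
#' @param P Interpolation operator from [build_interpolation()].
#' @return Symmetric coarse-level matrix `t(P) M P`.
#' @export
galerkin <- function(matrix_fine, P) {
  M <- Matrix::crossprod(P, matrix_fine %*% P)
  # symmetrize away rounding drift
  methods::as((M + Matrix::t(M)) / 2, "CsparseMatrix")
}

## Column masses of P (sizes of the fractional blocks).
column_mass <- function(P) {
  m <- Matrix::colSums(P)
  if (any(m <= 0)) {
    stop("internal consistency error: empty interpolation column",
         call. = FALSE)
  }
  m
}

#' Mean intensity of coarse blocks
#'
#' The mean intensity of a coarse node is the column-normalized weighted mean
#' of the fine-node intensities it aggregates:
#' `I_j = sum_i P_ij I_i / sum_i P_ij`. A constant image therefore stays
#' constant on every level.
#'
#' @param P Interpolation operator.
#' @param intensity_fine Per-node intensities on the fine level.
#' @return Numeric vector of coarse-node mean intensities.
#' @export
coarse_intensity <- function(P, intensity_fine) {
  stopifnot(nrow(P) == length(intensity_fine))
  as.numeric(Matrix::crossprod(P, intensity_fine)) / column_mass(P)
}

#' Multilevel variance features of coarse blocks
#'
#' Appends one new texture component per coarsening step. For coarse node j
#' with column-normalized membership weights w, the new (last) component is
#' the variance of the fine-node mean intensities within its block,
#' `E(I^2) - E(I)^2` under w (clamped at 0 against rounding). The components
#' inherited from finer levels are the same weighted average applied to the
#' fine nodes' existing feature components (recursive averaging), so a node
#' on level r+1 carries an r-component feature vector.
#'
#' @param P Interpolation operator.
#' @param intensity_fine Fine-level per-node mean intensities.
#' @param features_fine Fine-level feature matrix (`n_fine x (r-1)` columns).
#' @return Coarse feature matrix with one more column than `features_fine`.
#' @export
coarse_features <- function(P, intensity_fine, features_fine) {
  stopifnot(nrow(P) == length(intensity_fine),
            nrow(P) == nrow(features_fine))
  m <- column_mass(P)
  Pn <- P %*% Matrix::Diagonal(ncol(P), 1 / m)  # columns sum to 1
  e1 <- as.numeric(Matrix::crossprod(Pn, intensity_fine))
  e2 <- as.numeric(Matrix::crossprod(Pn, intensity_fine^2))
  newvar <- pmax(e2 - e1^2, 0)
  prefix <- as.matrix(Matrix::crossprod(Pn, features_fine))
  cbind(prefix, newvar, deparse.level = 0)
}

## Multiply the entries of symmetric sparse A by exp(-scale * dist(i, j))
## where dist is evaluated per stored entry; diagonal entries always get
## factor 1 because dist(i, i) = 0.
rescale_entries <- function(A, dist_fun, scale) {
  if (scale == 0) return(A)
  tr <- methods::as(methods::as(A, "generalMatrix"), "TsparseMatrix")
  i <- tr@i + 1L
  j <- tr@j + 1L
  x <- tr@x * exp(-scale * dist_fun(i, j))
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = dim(A))
}

#' Rescale coarse affinities by block mean-intensity similarity
#'
#' After the Galerkin product, couplings between coarse blocks are multiplied
#' by `exp(-alpha_tilde * |I_i - I_j|)` so that blocks of similar average
#' intensity stay strongly coupled. The diagonal is unchanged (`|dI| = 0`).
#'
#' @param A_coarse Symmetric coarse affinity matrix.
#' @param I_coarse Coarse-node mean intensities.
#' @param alpha_tilde Nonnegative rescaling factor; 0 is a no-op.
#' @return Rescaled affinity matrix (entries only shrink or stay equal).
#' @export
rescale_by_intensity <- function(A_coarse, I_coarse, alpha_tilde) {
  stopifnot(alpha_tilde >= 0, nrow(A_coarse) == length(I_coarse))
  rescale_entries(A_coarse, function(i, j) abs(I_coarse[i] - I_coarse[j]),
                  alpha_tilde)
}

#' Rescale coarse affinities by texture (variance-feature) similarity
#'
#' Couplings are multiplied by `exp(-beta * d(f_i, f_j))` where d is the L1
#' (default) or L2 distance between the nodes' multilevel variance feature
#' vectors. Variance of small blocks is uninformative, so the rescaling is a
#' no-op on levels up to `rho`.
#'
#' @param A_coarse Symmetric coarse affinity matrix.
#' @param features Coarse feature matrix (`n x (level-1)`).
#' @param beta Nonnegative rescaling factor.
#' @param level Level the matrix lives on.
#' @param rho Variance-rescaling threshold level: applied only when
#'   `level > rho`.
#' @param metric `"l1"` (default) or `"l2"` feature distance.
#' @return Rescaled affinity matrix.
#' @export
rescale_by_variance <- function(A_coarse, features, beta, level, rho,
                                metric = c("l1", "l2")) {
  stopifnot(beta >= 0, nrow(A_coarse) == nrow(features))
  metric <- match.arg(metric)
  if (level <= rho || ncol(features) == 0L) {
    return(A_coarse)
  }
  dist_fun <- switch(metric,
    l1 = function(i, j) {
      d <- abs(features[i, , drop = FALSE] - features[j, , drop = FALSE])
      rowSums(d)
    },
    l2 = function(i, j) {
      d <- features[i, , drop = FALSE] - features[j, , drop = FALSE]
      sqrt(rowSums(d * d))
    }
  )
  rescale_entries(A_coarse, dist_fun, beta)
}
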