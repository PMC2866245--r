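#' Normalize an intensity array so its maximum equals one
#'
#' Input images (any bit depth) are rescaled by their maximum so that the
#' brightest pixel has intensity 1; all graph-weight parameters are then
#' interpreted on this common dimensionless scale.
#'
#' @param raw Numeric array (2D matrix or 3D array) of raw intensities.
#' @return Numeric array of the same shape with `max(.) == 1` and all values
#'   in `[0, 1]` when the input is nonnegative.
#' @examples
#' normalize_image(matrix(c(0, 7, 14, 7), 2, 2))
#' @export
normalize_image <- function(raw) {
  if (length(raw) == 0L) {
    stop("image is empty", call. = FALSE)
  }
  if (!is.numeric(raw) || !all(is.finite(raw))) {
    stop("image must be finite and numeric", call. = FALSE)
  }
  mx <- max(raw)
  if (mx <= 0) {
    stop("image maximum must be positive (all-zero input?)", call. = FALSE)
  }
  raw / mx
}

#' Construct one level of the multigrid hierarchy
#'
#' Internal constructor for the per-level bundle of operators: the affinity
#' matrix `A`, the Boolean-derived boundary-length matrix `G` and area matrix
#' `V`, per-node mean intensities, the multilevel variance feature matrix
#' (`n x (level-1)` columns), and the salient flags.
#'
#' @keywords internal
new_level_graph <- function(level, A, G, V, intensity, features, salient,
                            dims = NULL, detection = NULL) {
  stopifnot(nrow(A) == length(intensity))
  if (is.null(features)) {
    features <- matrix(0, nrow(A), 0L)
  }
  structure(
    list(
      level = as.integer(level),
      A = A, G = G, V = V,
      intensity = as.numeric(intensity),
      features = features,
      salient = as.logical(salient),
      dims = dims,
      detection = if (is.null(detection)) integer(nrow(A)) else detection
    ),
    class = "swa_level"
  )
}

#' @export
print.swa_level <- function(x, ...) {
  cat(sprintf(
    "<swa_level> level %d: %d nodes, %d salient, %d feature component(s)\n",
    x$level, nrow(x$A), sum(x$salient), ncol(x$features)
  ))
  invisible(x)
}

n_nodes <- function(graph) nrow(graph$A)

## Index pairs of axis-aligned neighbours of an ny x nx (x nt) array, using
## R's column-major linear indices as node ids. Border nodes simply have
## fewer neighbours; there are no diagonal edges.
axis_neighbor_pairs <- function(dims) {
  ny <- dims[1L]
  nx <- dims[2L]
  nt <- if (length(dims) >= 3L) dims[3L] else 1L
  npix <- ny * nx * nt
  idx <- seq_len(npix)
  coord <- arrayInd(idx, c(ny, nx, nt))
  from <- integer(0)
  to <- integer(0)
  kind <- integer(0)  # 1 spatial, 2 temporal
  # vertical (y + 1)
  sel <- coord[, 1L] < ny
  from <- c(from, idx[sel]); to <- c(to, idx[sel] + 1L)
  kind <- c(kind, rep(1L, sum(sel)))
  # horizontal (x + 1)
  sel <- coord[, 2L] < nx
  from <- c(from, idx[sel]); to <- c(to, idx[sel] + ny)
  kind <- c(kind, rep(1L, sum(sel)))
  # temporal (t + 1)
  if (nt > 1L) {
    sel <- coord[, 3L] < nt
    from <- c(from, idx[sel]); to <- c(to, idx[sel] + ny * nx)
    kind <- c(kind, rep(2L, sum(sel)))
  }
  list(from = from, to = to, kind = kind, n = npix)
}

#' Build the finest-level affinity graph of an image or image stack
#'
#' Nodes are pixels (2D) or voxels (3D space-time stack); edges connect
#' axis-aligned neighbours only (4-connectivity in 2D, 6-connectivity in 3D).
#' The edge weight between neighbouring nodes i and j is
#' `exp(-alpha * |I_i - I_j|)`, so equal intensities give weight 1 and the
#' weight decays with intensity contrast. Alongside the weighted affinity
#' matrix the Boolean adjacency (`V`, the "area matrix") and its unweighted
#' graph Laplacian (`G`, the "boundary length matrix") are built; these are
#' later Galerkin-coarsened, never rescaled, and feed the scale-invariant
#' saliency measure.
#'
#' @param img Normalized intensity array (see [normalize_image()]).
#' @param alpha Nonnegative intensity scaling factor for spatial edges.
#' @param alpha_temporal Scaling factor for temporal edges of a 3D stack;
#'   defaults to `alpha` (frames are treated exactly like the spatial
#'   dimensions).
#' @return A `swa_level` object at level 1. The affinity matrix has a zero
#'   diagonal and all off-diagonal weights in `[0, 1]`.
#' @examples
#' g <- build_fine_graph(normalize_image(matrix(runif(12), 3, 4)), alpha = 10)
#' @export
build_fine_graph <- function(img, alpha, alpha_temporal = alpha) {
  stopifnot(is.numeric(alpha), alpha >= 0, alpha_temporal >= 0)
  dims <- dim(img)
  if (is.null(dims) || !(length(dims) %in% c(2L, 3L))) {
    stop("img must be a 2D matrix or 3D array", call. = FALSE)
  }
  if (max(img) > 1 + 1e-12 || min(img) < 0) {
    stop("img must be normalized to [0, 1] with max 1", call. = FALSE)
  }
  pr <- axis_neighbor_pairs(dims)
  ivec <- as.numeric(img)
  a <- ifelse(pr$kind == 2L, alpha_temporal, alpha)
  w <- exp(-a * abs(ivec[pr$from] - ivec[pr$to]))
  A <- Matrix::sparseMatrix(
    i = c(pr$from, pr$to), j = c(pr$to, pr$from), x = c(w, w),
    dims = c(pr$n, pr$n)
  )
  V <- Matrix::sparseMatrix(
    i = c(pr$from, pr$to), j = c(pr$to, pr$from), x = 1,
    dims = c(pr$n, pr$n)
  )
  deg <- Matrix::rowSums(V)
  G <- Matrix::Diagonal(pr$n, deg) - V
  new_level_graph(
    level = 1L, A = A, G = G, V = V,
    intensity = ivec, features = NULL,
    salient = logical(pr$n), dims = dims
  )
}
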