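## Shared builders and brute-force oracles for the test suite.

## Random symmetric affinity graph (zero diagonal) as a finest-level
## swa_level; G and V derive from the sparsity pattern.
random_affinity_graph <- function(n, p = 0.3, seed = 1) {
  set.seed(seed)
  A <- matrix(0, n, n)
  upper <- which(upper.tri(A))
  on <- upper[stats::runif(length(upper)) < p]
  A[on] <- stats::runif(length(on), 0.05, 1)
  A <- A + t(A)
  V <- (A > 0) * 1
  G <- diag(rowSums(V)) - V
  swaseg:::new_level_graph(
    level = 1L,
    A = methods::as(A, "CsparseMatrix"),
    G = methods::as(G, "CsparseMatrix"),
    V = methods::as(V, "CsparseMatrix"),
    intensity = stats::runif(n),
    features = NULL,
    salient = logical(n)
  )
}

## Level-2 graph from exact non-overlapping aggregation of a centered k x k
## block against its background, with e^{-alpha} the block/background
## contrast weight. Column 1 is the block.
block_level2_graph <- function(k, alpha = log(2), pad = 3) {
  n <- k + 2 * pad
  fx <- make_uniform_square(n, k)
  g <- build_fine_graph(fx$image, alpha = alpha)
  u <- as.numeric(fx$mask == 2L)
  P <- methods::as(cbind(u, 1 - u), "CsparseMatrix")
  swaseg:::new_level_graph(
    level = 2L,
    A = galerkin(g$A, P),
    G = galerkin(g$G, P),
    V = galerkin(g$V, P),
    intensity = coarse_intensity(P, g$intensity),
    features = coarse_features(P, g$intensity, g$features),
    salient = c(FALSE, FALSE)
  )
}

## A generic level-2 graph (nonzero diagonals) by aggregating a random image
## over a coarse pixel grid with Boolean blocks.
random_level2_graph <- function(ny = 8, nx = 8, block = 2, alpha = 5,
                                seed = 1) {
  set.seed(seed)
  img <- normalize_image(matrix(stats::runif(ny * nx, 0.2, 1), ny, nx))
  g <- build_fine_graph(img, alpha = alpha)
  by <- ceiling(row(img) / block)
  bx <- ceiling(col(img) / block)
  grp <- as.integer(factor(paste(by, bx)))
  P <- Matrix::sparseMatrix(i = seq_along(grp), j = grp, x = 1)
  swaseg:::new_level_graph(
    level = 2L,
    A = galerkin(g$A, P),
    G = galerkin(g$G, P),
    V = galerkin(g$V, P),
    intensity = coarse_intensity(P, g$intensity),
    features = coarse_features(P, g$intensity, g$features),
    salient = logical(max(grp))
  )
}

## Dense brute-force triple product oracle.
dense_galerkin <- function(M, P) {
  t(as.matrix(P)) %*% as.matrix(M) %*% as.matrix(P)
}

## Brute-force strong-connection relation straight from the definition.
brute_strong <- function(A, theta) {
  A <- as.matrix(A)
  diag(A) <- 0
  n <- nrow(A)
  S <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    rs <- sum(A[i, ])
    for (j in seq_len(n)) {
      if (j != i && A[i, j] > 0 && A[i, j] >= theta * rs) S[i, j] <- TRUE
    }
  }
  S
}
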