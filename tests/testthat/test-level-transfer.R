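make_split <- function(c_points, f_points, forced = integer(0)) {
  structure(list(c_points = c_points, f_points = f_points, forced = forced),
            class = "swa_cf_split")
}

test_that("interpolation rows follow the C/F rules", {
  # node 1 is F with weights 0.6, 0.2 to C-points 2, 3 and 0.2 to F node 4:
  # F neighbour excluded from the denominator -> row (0.75, 0.25)
  A <- matrix(0, 4, 4)
  A[1, 2] <- 0.6; A[1, 3] <- 0.2; A[1, 4] <- 0.2; A[4, 2] <- 0.5
  A <- pmax(A, t(A))
  g <- swaseg:::new_level_graph(1L, methods::as(A, "CsparseMatrix"),
                                Matrix::Diagonal(4), Matrix::Diagonal(4),
                                rep(0.5, 4), NULL, logical(4))
  P <- build_interpolation(g, make_split(c(2L, 3L), c(1L, 4L)))
  expect_equal(as.numeric(P[1, ]), c(0.75, 0.25))
  # C-point rows carry a single 1 in their own column
  expect_equal(as.numeric(P[2, ]), c(1, 0))
  expect_equal(as.numeric(P[3, ]), c(0, 1))
  # F node 4 couples only to C-point 2
  expect_equal(as.numeric(P[4, ]), c(1, 0))
})

test_that("interpolation rows always sum to one", {
  for (seed in 1:5) {
    g <- random_affinity_graph(40, 0.25, seed = seed)
    split <- first_pass_cf(g, 0.15)
    P <- build_interpolation(g, split)
    expect_equal(Matrix::rowSums(P), rep(1, 40), tolerance = 1e-12)
    expect_true(all(P@x >= 0))
  }
})

test_that("an F-point without C couplings raises an internal error", {
  A <- matrix(0, 3, 3)
  A[1, 2] <- A[2, 1] <- 0.5
  g <- swaseg:::new_level_graph(1L, methods::as(A, "CsparseMatrix"),
                                Matrix::Diagonal(3), Matrix::Diagonal(3),
                                rep(0.5, 3), NULL, logical(3))
  expect_error(build_interpolation(g, make_split(2L, c(1L, 3L))),
               "internal consistency")
})

test_that("Galerkin product matches the dense triple product", {
  expect_equal(as.matrix(galerkin(Matrix::Diagonal(4, 1:4),
                                  Matrix::Diagonal(4))),
               diag(as.numeric(1:4)))
  for (seed in 1:4) {
    n <- 25 * seed  # up to 100 nodes
    g <- random_affinity_graph(n, 0.2, seed = seed)
    split <- first_pass_cf(g, 0.2)
    P <- build_interpolation(g, split)
    for (M in list(g$A, g$G, g$V)) {
      expect_equal(as.matrix(galerkin(M, P)), unname(dense_galerkin(M, P)),
                   tolerance = 1e-12)
    }
  }
})

test_that("worked 3x3 block stencil gives boundary 12 and area 24", {
  fx <- make_uniform_square(9, 3)
  g <- build_fine_graph(fx$image, alpha = log(2))
  u <- as.numeric(fx$mask == 2L)
  P <- methods::as(cbind(u, 1 - u), "CsparseMatrix")
  expect_equal(galerkin(g$G, P)[1, 1], 12)
  expect_equal(galerkin(g$V, P)[1, 1], 24)
})

test_that("Boolean partitions turn G and V diagonals into boundary lengths and edge counts", {
  set.seed(11)
  img <- normalize_image(matrix(stats::runif(96, 0.3, 1), 8, 12))
  g <- build_fine_graph(img, alpha = 2)
  # random rectangular blocks: 2x3 tiling
  grp <- as.integer(factor(paste(ceiling(row(img) / 4), ceiling(col(img) / 4))))
  P <- Matrix::sparseMatrix(i = seq_along(grp), j = grp, x = 1)
  Gd <- Matrix::diag(galerkin(g$G, P))
  Vd <- Matrix::diag(galerkin(g$V, P))
  # direct edge counting from the Boolean adjacency
  Vm <- as.matrix(g$V)
  for (b in seq_len(max(grp))) {
    inb <- grp == b
    boundary <- sum(Vm[inb, !inb])
    internal <- sum(Vm[inb, inb]) / 2
    expect_equal(Gd[b], boundary)
    expect_equal(Vd[b], 2 * internal)
  }
})

test_that("coarse intensities are column-normalized weighted means", {
  P <- methods::as(cbind(c(0.5, 0.5), c(0.5, 0.5)), "CsparseMatrix")
  expect_equal(coarse_intensity(P, c(0.2, 0.4)), c(0.3, 0.3))
  # a constant image stays constant through arbitrary transfer chains
  g <- random_affinity_graph(30, 0.3, seed = 9)
  g$intensity <- rep(0.7, 30)
  split <- first_pass_cf(g, 0.2)
  P <- build_interpolation(g, split)
  expect_equal(coarse_intensity(P, g$intensity),
               rep(0.7, length(split$c_points)))
})

test_that("coarse features append the within-block intensity variance", {
  P <- methods::as(cbind(c(0.5, 0.5)), "CsparseMatrix")
  f <- coarse_features(P, c(0.2, 0.4), matrix(0, 2, 0))
  expect_equal(dim(f), c(1L, 1L))
  expect_equal(f[1, 1], 0.01)  # E(I^2) - E(I)^2 = 0.1 - 0.09
  # constant block -> zero variance; zero prefixes stay zero
  P2 <- methods::as(cbind(c(1, 1, 0), c(0, 0, 1)) * 1.0, "CsparseMatrix")
  f2 <- coarse_features(P2, c(0.5, 0.5, 0.8), matrix(0, 3, 2))
  expect_equal(f2, cbind(matrix(0, 2, 2), c(0, 0)))
  expect_equal(ncol(f2), 3L)  # grows by exactly one component
})

test_that("variance components are clamped nonnegative", {
  P <- methods::as(cbind(c(1e-9, 1 - 1e-9)), "CsparseMatrix")
  f <- coarse_features(P, c(0.3, 0.3), matrix(0, 2, 0))
  expect_gte(f[1, 1], 0)
})

test_that("intensity rescaling multiplies couplings by exp(-at |dI|)", {
  A <- methods::as(matrix(c(0, 0.5, 0.5, 0), 2, 2), "CsparseMatrix")
  expect_equal(rescale_by_intensity(A, c(0.3, 0.8), 0), A)
  R <- rescale_by_intensity(A, c(0.3, 0.8), 2)
  expect_equal(R[1, 2], 0.5 * exp(-1))
  expect_equal(rescale_by_intensity(A, c(0.6, 0.6), 2)[1, 2], 0.5)
})

test_that("variance rescaling respects the rho level threshold", {
  A <- methods::as(matrix(c(0, 0.4, 0.4, 0), 2, 2), "CsparseMatrix")
  f <- matrix(c(0, 0.05), 2, 1)
  expect_equal(rescale_by_variance(A, f, 100, level = 2, rho = 2), A)
  R <- rescale_by_variance(A, f, 100, level = 3, rho = 2)
  expect_equal(R[1, 2], 0.4 * exp(-5))
  # identical feature vectors leave A unchanged
  expect_equal(as.matrix(rescale_by_variance(A, matrix(0.3, 2, 1), 50, 3, 1)),
               as.matrix(A))
})

test_that("rescalings only shrink couplings and preserve symmetry", {
  g <- random_level2_graph(8, 8, 2, alpha = 5, seed = 2)
  R1 <- rescale_by_intensity(g$A, g$intensity, 30)
  R2 <- rescale_by_variance(R1, g$features, 50, level = 2, rho = 1)
  expect_true(all(R2@x <= g$A@x + 1e-14))
  expect_equal(R2, Matrix::t(R2))
  # diagonal untouched
  expect_equal(Matrix::diag(R2), Matrix::diag(g$A))
})
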