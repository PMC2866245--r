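test_that("strong connections follow the row-sum criterion", {
  # star row with off-diagonal weights 0.5, 0.3, 0.2 and theta = 0.25:
  # row sum 1.0, so 0.5 and 0.3 are strong, 0.2 is not
  A <- matrix(0, 4, 4)
  A[1, 2:4] <- c(0.5, 0.3, 0.2)
  A <- A + t(A)
  g <- swaseg:::new_level_graph(1L, methods::as(A, "CsparseMatrix"),
                                Matrix::Diagonal(4), Matrix::Diagonal(4),
                                rep(0.5, 4), NULL, logical(4))
  S <- strong_connections(g, 0.25)
  expect_true(S[1, 2] && S[1, 3])
  expect_false(S[1, 4])
  # leaves depend on the hub: each leaf's whole row sum sits on edge to 1
  expect_true(all(S[2:4, 1]))
})

test_that("theta limit cases: 0 keeps every edge, 1 needs the whole row", {
  g <- random_affinity_graph(12, 0.4, seed = 3)
  S0 <- strong_connections(g, 0)
  expect_equal(as.matrix(S0) > 0, as.matrix(g$A) > 0)
  # theta = 1: strong only when one neighbour carries the entire row sum
  A <- matrix(0, 3, 3)
  A[1, 2] <- 1; A[2, 3] <- 0.5; A[2, 1] <- 1
  A <- pmax(A, t(A))
  g1 <- swaseg:::new_level_graph(1L, methods::as(A, "CsparseMatrix"),
                                 Matrix::Diagonal(3), Matrix::Diagonal(3),
                                 rep(0.1, 3), NULL, logical(3))
  S1 <- strong_connections(g1, 1)
  expect_true(S1[1, 2])    # node 1's only neighbour
  expect_false(S1[2, 1])   # node 2 splits its row sum
  expect_true(S1[3, 2])
})

test_that("strong connections match the brute-force definition", {
  for (seed in 1:4) {
    g <- random_affinity_graph(20, 0.3, seed = seed)
    for (theta in c(0.05, 0.25, 0.6)) {
      expect_equal(unname(as.matrix(strong_connections(g, theta)) > 0),
                   brute_strong(g$A, theta))
    }
  }
})

test_that("an isolated node yields no strong connections and becomes C", {
  A <- matrix(0, 3, 3)
  A[1, 2] <- A[2, 1] <- 0.8
  g <- swaseg:::new_level_graph(1L, methods::as(A, "CsparseMatrix"),
                                Matrix::Diagonal(3), Matrix::Diagonal(3),
                                rep(0.5, 3), NULL, logical(3))
  expect_silent(S <- strong_connections(g, 0.5))
  expect_equal(sum(S[3, ]), 0)
  split <- first_pass_cf(g, 0.5)
  expect_true(3 %in% split$c_points)
})

test_that("a single-node graph coarsens to a single C-point", {
  g <- swaseg:::new_level_graph(
    1L, Matrix::Matrix(0, 1, 1, sparse = TRUE),
    Matrix::Matrix(0, 1, 1, sparse = TRUE),
    Matrix::Matrix(0, 1, 1, sparse = TRUE),
    0.5, NULL, FALSE
  )
  split <- first_pass_cf(g, 0.1)
  expect_identical(split$c_points, 1L)
  expect_length(split$f_points, 0)
})

test_that("uniform path of five nodes splits into the expected C/F pattern", {
  # hand-executed first pass: degrees (1,2,2,2,1); node 2 wins the tie,
  # nodes 1 and 3 become F, node 4's measure grows to 3 and becomes C,
  # node 5 becomes F -> C = {2, 4}
  A <- matrix(0, 5, 5)
  for (i in 1:4) A[i, i + 1] <- A[i + 1, i] <- 1
  g <- swaseg:::new_level_graph(1L, methods::as(A, "CsparseMatrix"),
                                Matrix::Diagonal(5), Matrix::Diagonal(5),
                                rep(0.5, 5), NULL, logical(5))
  split <- first_pass_cf(g, 0.1)
  expect_identical(split$c_points, c(2L, 4L))
  expect_identical(split$f_points, c(1L, 3L, 5L))
})

test_that("forcing every node gives a coarse level identical to the fine one", {
  g <- random_affinity_graph(10, 0.5, seed = 5)
  split <- first_pass_cf(g, 0.2, forced_c = 1:10)
  expect_identical(split$c_points, 1:10)
})

test_that("first pass is deterministic and strictly coarsens", {
  for (seed in 1:5) {
    g <- random_affinity_graph(30, 0.25, seed = seed)
    s1 <- first_pass_cf(g, 0.2)
    s2 <- first_pass_cf(g, 0.2)
    expect_identical(s1$c_points, s2$c_points)
    has_strong <- Matrix::nnzero(strong_connections(g, 0.2)) > 0
    if (has_strong) {
      expect_lt(length(s1$c_points), 30)
    }
  }
})

test_that("C-points form a maximal independent set of the strong graph", {
  for (seed in 1:6) {
    n <- 5 + 5 * seed
    g <- random_affinity_graph(n, 0.3, seed = seed + 10)
    theta <- c(0.1, 0.3)[seed %% 2 + 1]
    split <- first_pass_cf(g, theta)
    S <- strong_connections(g, theta)
    Ssym <- as.matrix(S | Matrix::t(S))
    cp <- split$c_points
    # independence (brute force over all C pairs)
    for (a in cp) for (b in cp) {
      if (a < b) expect_false(Ssym[a, b])
    }
    # maximality: every F-point has a strong connection to some C-point
    for (f in split$f_points) {
      expect_true(any(Ssym[f, cp]))
    }
  }
})

test_that("forced C-points survive even inside strongly connected cliques", {
  A <- matrix(0.9, 4, 4); diag(A) <- 0
  g <- swaseg:::new_level_graph(1L, methods::as(A, "CsparseMatrix"),
                                Matrix::Diagonal(4), Matrix::Diagonal(4),
                                rep(0.5, 4), NULL, logical(4))
  split <- first_pass_cf(g, 0.2, forced_c = c(1L, 2L))
  expect_true(all(c(1L, 2L) %in% split$c_points))
  expect_true(all(c(1L, 2L) %in% split$forced))
})
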