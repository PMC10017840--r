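test_that("KNN hyperedges contain the centroid and its k nearest features", {
  # three features at mutual distances d(a,b)=1, d(a,c)=2, d(b,c)=1.5
  X <- cbind(a = c(0, 0), b = c(1, 0), c = c(1.375, sqrt(4 - 1.375^2)))
  he <- knn_hyperedges(X, k = 1)
  expect_equal(unname(he$H[, "a"]), c(1, 1, 0))   # {a, b}
  expect_equal(unname(he$H[, "b"]), c(1, 1, 0))   # {a, b}
  expect_equal(unname(he$H[, "c"]), c(0, 1, 1))   # {b, c}
  expect_equal(he$w, rep(1, 3))
})

test_that("every hyperedge has degree k + 1 and k = N - 1 gives the complete incidence", {
  set.seed(4)
  X <- matrix(rnorm(50), 10, 5)
  he <- knn_hyperedges(X, k = 2)
  expect_equal(unname(colSums(he$H)), rep(3, 5))
  expect_true(all(diag(he$H) == 1))               # centroid always included
  full <- knn_hyperedges(X, k = 4)
  expect_equal(unname(full$H), matrix(1, 5, 5))
  expect_error(knn_hyperedges(X, k = 5), "\\[1, 4\\]")
  expect_error(knn_hyperedges(X, k = 0), "\\[1, 4\\]")
})

test_that("single-hyperedge Laplacian matches the analytic closed form", {
  H <- matrix(c(1, 1), 2, 1)
  lap <- hypergraph_laplacian(H, 1)
  expect_equal(lap$d_v, c(1, 1))
  expect_equal(lap$d_e, 2)
  expect_equal(unname(lap$S), matrix(0.5, 2, 2))
  expect_equal(unname(lap$L), matrix(c(0.5, -0.5, -0.5, 0.5), 2, 2))
})

test_that("complete-hyperedge Laplacian matches its closed form", {
  set.seed(8)
  N <- 6
  X <- matrix(rnorm(8 * N), 8, N)
  hg <- feature_hypergraph(X, k = N - 1)
  # every hyperedge is the full vertex set: S_ij = sum_e 1/N = 1
  expect_equal(unname(hg$S), matrix(1, N, N))
  expect_equal(unname(hg$L), diag(N, N) - matrix(1, N, N))
})

test_that("degrees, similarity and Laplacian follow their definitions on a weighted example", {
  H <- matrix(c(1, 1, 1, 0,
                0, 0, 1, 1), 4, 2)
  w <- c(1, 2)
  lap <- hypergraph_laplacian(H, w)
  expect_equal(lap$d_v, as.vector(H %*% w))
  expect_equal(lap$d_e, c(3, 2))
  # element-wise brute force of S = H W De^-1 H^T
  S_expect <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) for (e in 1:2)
    S_expect[i, j] <- S_expect[i, j] + w[e] * H[i, e] * H[j, e] / sum(H[, e])
  expect_equal(unname(lap$S), S_expect)
  expect_equal(unname(lap$L), diag(lap$d_v) - S_expect)
})

test_that("every constructed hypergraph satisfies the type invariants", {
  for (s in 1:25) {
    set.seed(s)
    N <- sample(4:12, 1)
    X <- matrix(rnorm(15 * N), 15, N)
    hg <- feature_hypergraph(X, k = sample(seq_len(N - 1), 1))
    expect_true(all(hg$H %in% c(0, 1)))
    expect_true(all(colSums(hg$H) >= 2))
    expect_true(all(rowSums(hg$H) >= 1))
    expect_equal(hg$d_v, as.vector(hg$H %*% hg$w))
    expect_equal(hg$d_e, colSums(hg$H))
    expect_equal(hg$S, t(hg$S))
    # L annihilates constants and is PSD
    expect_lt(max(abs(hg$L %*% rep(1, N))), 1e-10)
    expect_gt(min(eigen(hg$L, symmetric = TRUE, only.values = TRUE)$values),
              -1e-10)
  }
})

test_that("degenerate hypergraph inputs are rejected", {
  H <- matrix(c(1, 1, 0, 0), 2, 2)
  expect_error(hypergraph_laplacian(H, c(1, 1)), "empty hyperedge")
  expect_error(hypergraph_laplacian(matrix(c(1, 2), 2, 1), 1), "binary")
  expect_error(hypergraph_laplacian(matrix(c(1, 1), 2, 1), -1), "positive")
})
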