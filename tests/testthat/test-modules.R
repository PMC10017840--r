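test_that("z-scores follow the population-sd formula and flag constant columns", {
  G <- cbind(a = c(3, 1, 1, 1), b = c(2, 2, 2, 2))
  zs <- zscore_membership(G)
  # column a: mean 1.5, population sd sqrt(0.75); z(3) = 1.5/0.866 > 1
  expect_equal(as.numeric(zs$z[1, "a"]), (3 - 1.5) / sqrt(0.75))
  expect_equal(unname(zs$membership[, "a"]), c(TRUE, FALSE, FALSE, FALSE))
  # constant column: degenerate, no members
  expect_true(zs$degenerate["b"])
  expect_false(any(zs$membership[, "b"]))
  expect_equal(unname(zs$z[, "b"]), rep(0, 4))
})

test_that("z-score columns are standardized and membership is scale-free", {
  set.seed(5)
  G <- matrix(runif(60), 20, 3)
  zs <- zscore_membership(G)
  expect_equal(unname(colMeans(zs$z)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(sqrt(colMeans(zs$z^2))), rep(1, 3), tolerance = 1e-12)
  # positive rescaling of a column leaves membership unchanged
  G2 <- G; G2[, 2] <- G2[, 2] * 37
  expect_identical(zscore_membership(G2)$membership, zs$membership)
})

test_that("raising the threshold never adds members", {
  set.seed(7)
  G <- matrix(runif(100), 25, 4)
  m1 <- zscore_membership(G, threshold = 0.5)$membership
  m2 <- zscore_membership(G, threshold = 1)$membership
  m3 <- zscore_membership(G, threshold = 1.5)$membership
  expect_true(all(m2 <= m1))
  expect_true(all(m3 <= m2))
})

test_that("modules below the minimum size on either side are dropped", {
  mk <- function(counts, n) {
    M <- matrix(FALSE, n, length(counts))
    for (j in seq_along(counts)) M[seq_len(counts[j]), j] <- TRUE
    M
  }
  roi <- mk(c(10, 5, 4, 0), 12)
  gene <- mk(c(4, 5, 10, 0), 12)
  expect_equal(filter_modules(roi, gene), c(FALSE, TRUE, FALSE, FALSE))
  # lowering min_size never removes a retained module
  expect_true(all(filter_modules(roi, gene) <= filter_modules(roi, gene, 4)))
  expect_error(filter_modules(roi, gene[, 1:2]), "same number")
})

test_that("module restricted to all features reproduces the global error", {
  nets <- make_random_nets(6, 8, seed = 121)
  model <- hg_init_factors(6, 8, 2, seed = 3)
  err <- module_relative_error(nets, model, rep(TRUE, 6), rep(TRUE, 8))
  expect_equal(unname(err["total"]), relative_error(model, nets))
  expect_error(module_relative_error(nets, model, logical(6), rep(TRUE, 8)),
               "empty")
})

test_that("exactly factorized networks give zero error for every module", {
  gt <- make_exact_nets(8, 10, 2, seed = 131)
  model <- list(G1 = gt$G1, G2 = gt$G2, S11 = gt$S11, S22 = gt$S22)
  err <- module_relative_error(nets = gt$nets, model = model,
                               roi_members = 1:4, gene_members = 3:7)
  expect_equal(unname(err), rep(0, 4))
})

test_that("the stronger of two planted blocks has the smaller module error", {
  # two block modules with signal strengths 10 and 1; the same additive
  # noise is relatively much larger for the weak block, so the strong
  # module's restricted reconstruction error is smaller
  set.seed(9)
  p <- 16; q <- 20
  G1 <- matrix(0, p, 2); G2 <- matrix(0, q, 2)
  G1[1:8, 1] <- 10; G1[9:16, 2] <- 1
  G2[1:10, 1] <- 10; G2[11:20, 2] <- 1
  noise <- function(n, m) matrix(runif(n * m, 0, 0.5), n, m)
  R11 <- tcrossprod(G1) + noise(p, p); R11 <- (R11 + t(R11)) / 2; diag(R11) <- diag(tcrossprod(G1))
  R22 <- tcrossprod(G2) + noise(q, q); R22 <- (R22 + t(R22)) / 2; diag(R22) <- diag(tcrossprod(G2))
  R12 <- tcrossprod(G1, G2) + noise(p, q)
  nets <- as_association_networks(R11, R22, R12)
  model <- list(G1 = G1, G2 = G2, S11 = diag(2), S22 = diag(2))
  err_strong <- module_relative_error(nets, model, 1:8, 1:10)
  err_weak <- module_relative_error(nets, model, 9:16, 11:20)
  expect_lt(err_strong["total"], err_weak["total"])
  expect_lt(err_strong["roi"], err_weak["roi"])
  expect_lt(err_strong["gene"], err_weak["gene"])
})

test_that("extracted module members are exactly the above-threshold labels", {
  sim <- simulate_paired_data(40, 12, 15, seed = 10)
  nets <- association_networks(sim$X, sim$Y)
  fit <- hgnetnmf(nets, rank = 3, seed = 2, max_iter = 100)
  mods <- extract_modules(fit, nets, threshold = 1, min_size = 2)
  for (j in 1:3) {
    expect_identical(mods$roi_members[[j]],
                     rownames(fit$G1)[mods$z_roi[, j] > 1])
    expect_identical(mods$gene_members[[j]],
                     rownames(fit$G2)[mods$z_gene[, j] > 1])
  }
})
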