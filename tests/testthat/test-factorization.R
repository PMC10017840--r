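test_that("objective matches an element-wise brute-force evaluation", {
  nets <- make_random_nets(5, 6, seed = 11)
  model <- hg_init_factors(5, 6, 2, seed = 3)
  model$lambda1 <- 0.01; model$lambda2 <- 0.01
  sim <- simulate_paired_data(20, 5, 6, seed = 2)
  hg1 <- feature_hypergraph(sim$X, 2)
  hg2 <- feature_hypergraph(sim$Y, 2)

  # independent double-loop sums
  frob2 <- function(M) { s <- 0; for (i in seq_len(nrow(M))) for (j in seq_len(ncol(M))) s <- s + M[i, j]^2; s }
  tr_pen <- function(G, L) { s <- 0; for (a in seq_len(ncol(G))) s <- s + sum(G[, a] * (L %*% G[, a])); s }
  expected <- frob2(nets$R11 - model$G1 %*% model$S11 %*% t(model$G1)) +
    frob2(nets$R12 - model$G1 %*% t(model$G2)) +
    frob2(nets$R22 - model$G2 %*% model$S22 %*% t(model$G2)) +
    0.01 * tr_pen(model$G1, hg1$L) + 0.01 * tr_pen(model$G2, hg2$L)
  expect_equal(hg_objective(nets, model, hg1, hg2), expected)

  # zero factors leave the whole data norm as residual
  zero <- list(G1 = matrix(0, 5, 2), G2 = matrix(0, 6, 2),
               S11 = matrix(0, 2, 2), S22 = matrix(0, 2, 2))
  expect_equal(hg_objective(nets, zero),
               sum(nets$R11^2) + sum(nets$R12^2) + sum(nets$R22^2))
})

test_that("objective is zero and updates are a fixed point at an exact factorization", {
  gt <- make_exact_nets(6, 8, 2, seed = 21)
  model <- list(G1 = gt$G1, G2 = gt$G2, S11 = gt$S11, S22 = gt$S22,
                lambda1 = 0, lambda2 = 0)
  expect_equal(hg_objective(gt$nets, model), 0)
  stepped <- hg_update_step(gt$nets, model, eps = 0)
  expect_equal(unname(stepped$G1), model$G1, tolerance = 1e-12)
  expect_equal(unname(stepped$G2), model$G2, tolerance = 1e-12)
  expect_equal(unname(stepped$S11), model$S11, tolerance = 1e-12)
  expect_equal(unname(stepped$S22), model$S22, tolerance = 1e-12)
})

test_that("one scalar update pass matches hand-evaluated ratios", {
  nets <- as_association_networks(matrix(1), matrix(1), matrix(1))
  model <- list(G1 = matrix(0.5), G2 = matrix(0.5),
                S11 = matrix(0.5), S22 = matrix(0.5),
                lambda1 = 0, lambda2 = 0)
  out <- hg_update_step(nets, model, eps = 0)
  # independent scalar evaluation of the four ratios, in update order
  g <- 0.5
  s11_new <- 0.5 * (g * 1 * g) / (g^2 * 0.5 * g^2)
  s22_new <- 0.5 * (g * 1 * g) / (g^2 * 0.5 * g^2)
  g1_new <- g * (2 * 1 * g * s11_new + 1 * g) /
    (2 * g * s11_new * g^2 * s11_new + g * g^2)
  g2_new <- g * (1 * g1_new + 2 * 1 * g * s22_new) /
    (g * g1_new^2 + 2 * g * s22_new * g^2 * s22_new)
  expect_equal(as.numeric(out$S11), s11_new)
  expect_equal(as.numeric(out$S22), s22_new)
  expect_equal(as.numeric(out$G1), g1_new)
  expect_equal(as.numeric(out$G2), g2_new)
})

test_that("fitting is deterministic given a seed", {
  nets <- make_random_nets(8, 10, seed = 31)
  f1 <- hgnetnmf(nets, rank = 3, seed = 5, max_iter = 50)
  f2 <- hgnetnmf(nets, rank = 3, seed = 5, max_iter = 50)
  expect_identical(f1$G1, f2$G1)
  expect_identical(f1$G2, f2$G2)
  expect_identical(f1$objective_trace, f2$objective_trace)
  f3 <- hgnetnmf(nets, rank = 3, seed = 6, max_iter = 50)
  expect_false(identical(f1$G1, f3$G1))
})

test_that("unregularized fits agree per-iteration with an independent plain implementation", {
  nets <- make_random_nets(7, 9, seed = 41)
  k <- 3
  init <- hg_init_factors(7, 9, k, seed = 13)
  G1 <- init$G1; G2 <- init$G2; S11 <- init$S11; S22 <- init$S22
  model <- c(init, list(lambda1 = 0, lambda2 = 0))
  eps <- 1e-10
  for (it in 1:10) {
    # reference: the plain tri-factorization rules written out directly
    S11 <- S11 * (t(G1) %*% nets$R11 %*% G1) /
      (t(G1) %*% G1 %*% S11 %*% t(G1) %*% G1 + eps)
    S22 <- S22 * (t(G2) %*% nets$R22 %*% G2) /
      (t(G2) %*% G2 %*% S22 %*% t(G2) %*% G2 + eps)
    G1 <- G1 * (2 * nets$R11 %*% G1 %*% S11 + nets$R12 %*% G2) /
      (2 * G1 %*% S11 %*% t(G1) %*% G1 %*% S11 + G1 %*% t(G2) %*% G2 + eps)
    G2 <- G2 * (2 * nets$R22 %*% G2 %*% S22 + t(nets$R12) %*% G1) /
      (2 * G2 %*% S22 %*% t(G2) %*% G2 %*% S22 + G2 %*% t(G1) %*% G1 + eps)
    model <- hg_update_step(nets, model, eps = eps)
    expect_equal(model$S11, S11, tolerance = 1e-12)
    expect_equal(model$G1, G1, tolerance = 1e-12)
    expect_equal(model$G2, G2, tolerance = 1e-12)
  }
})

test_that("objective descends and factors stay non-negative on random problems", {
  for (s in 1:20) {
    nets <- make_random_nets(8, 10, seed = 100 + s)
    sim <- simulate_paired_data(20, 8, 10, seed = s)
    hg1 <- feature_hypergraph(sim$X, 3); hg2 <- feature_hypergraph(sim$Y, 3)
    lam <- c(0, 0.0001, 0.01, 0.1)[(s %% 4) + 1]
    fit <- hgnetnmf(nets, rank = 2, lambda1 = lam, lambda2 = lam,
                    hg1 = hg1, hg2 = hg2, seed = s, max_iter = 60)
    tr <- fit$objective_trace
    expect_true(all(diff(tr) <= 1e-8 * pmax(tr[-length(tr)], 1e-10)))
    expect_true(all(fit$G1 >= 0) && all(fit$G2 >= 0) &&
                  all(fit$S11 >= 0) && all(fit$S22 >= 0))
  }
})

test_that("noise-free networks at the true rank are recovered almost exactly", {
  gt <- make_exact_nets(12, 15, 2, seed = 51)
  fit <- hgnetnmf(gt$nets, rank = 2, seed = 4, max_iter = 8000, tol = 0)
  expect_lt(relative_error(fit, gt$nets), 1e-3)
})

test_that("invalid fit arguments are rejected", {
  nets <- make_random_nets(6, 8, seed = 61)
  expect_error(hgnetnmf(nets, rank = 0), "rank")
  expect_error(hgnetnmf(nets, rank = 7), "rank")
  expect_error(hgnetnmf(nets, rank = 2, lambda1 = 0.1), "hg1")
  expect_error(hgnetnmf(nets, rank = 2, lambda1 = -1), "non-negative")
})
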