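# Independent oracles and fixture builders used across the suite.

# Pearson correlation by the textbook formula (no stats::cor).
oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Association triple constructed exactly from known non-negative factors,
# so the factorization residual can reach zero at the true rank.
make_exact_nets <- function(p, q, k, seed = 1) {
  set.seed(seed)
  G1 <- matrix(runif(p * k), p, k)
  G2 <- matrix(runif(q * k), q, k)
  A <- matrix(runif(k * k), k, k); S11 <- (A + t(A)) / 2
  B <- matrix(runif(k * k), k, k); S22 <- (B + t(B)) / 2
  list(nets = as_association_networks(tcrossprod(G1 %*% S11, G1),
                                      tcrossprod(G2 %*% S22, G2),
                                      tcrossprod(G1, G2)),
       G1 = G1, G2 = G2, S11 = S11, S22 = S22)
}

# Small random association triple (symmetric, non-negative, unit diagonal).
make_random_nets <- function(p, q, seed = 1) {
  set.seed(seed)
  sym <- function(n) {
    M <- matrix(runif(n * n), n, n); M <- (M + t(M)) / 2; diag(M) <- 1; M
  }
  as_association_networks(sym(p), sym(q), matrix(runif(p * q), p, q))
}

# Brute-force maximal clique centrality on an adjacency matrix (n <= 12):
# enumerate every vertex subset, keep cliques of size >= 2 with no
# extending vertex, and sum (|C|-1)! over the maximal cliques at each node.
oracle_mcc <- function(adj) {
  n <- nrow(adj)
  scores <- numeric(n)
  for (mask in seq_len(2^n - 1)) {
    members <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    m <- length(members)
    if (m < 2) next
    sub <- adj[members, members, drop = FALSE]
    if (any(sub[upper.tri(sub)] == 0)) next           # not a clique
    outside <- setdiff(seq_len(n), members)
    extendable <- any(vapply(outside, function(v) all(adj[v, members] == 1),
                             logical(1)))
    if (extendable) next                               # not maximal
    scores[members] <- scores[members] + factorial(m - 1)
  }
  scores
}

# Random undirected graph as a 0/1 adjacency matrix.
random_adjacency <- function(n, p_edge, seed) {
  set.seed(seed)
  adj <- matrix(0L, n, n)
  adj[upper.tri(adj)] <- as.integer(runif(n * (n - 1) / 2) < p_edge)
  adj + t(adj)
}
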