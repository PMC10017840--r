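#' K-nearest-neighbour hyperedges over feature profiles
#'
#' Builds one hyperedge per feature (vertex): the feature itself (the
#' centroid) plus its `k` nearest neighbour features by Euclidean distance
#' between feature columns, i.e. profiles across samples. Every hyperedge
#' therefore has degree `k + 1` and all hyperedge weights are 1.
#'
#' Ties at the k-th neighbour are broken toward the lowest feature index so
#' the construction is deterministic across platforms.
#'
#' @param X Sample-by-feature numeric matrix; the hypergraph vertices are the
#'   `N = ncol(X)` features.
#' @param k Neighbour count, between 1 and `N - 1`.
#' @param standardize If `TRUE`, z-score each feature column before computing
#'   distances. Default `FALSE` (raw Euclidean distance).
#' @return List with `H` (N x N binary incidence matrix, one column per
#'   hyperedge) and `w` (unit hyperedge weights).
#' @seealso [hypergraph_laplacian()], [feature_hypergraph()]
#' @export
knn_hyperedges <- function(X, k, standardize = FALSE) {
  X <- as.matrix(X)
  N <- ncol(X)
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k > N - 1)
    stop(sprintf("'k' must lie in [1, %d]", N - 1))
  k <- as.integer(k)
  if (standardize) X <- scale(X)

  D <- as.matrix(dist(t(X)))
  H <- matrix(0, N, N)
  for (j in seq_len(N)) {
    d <- D[, j]
    d[j] <- Inf                       # centroid added explicitly
    nb <- order(d)[seq_len(k)]        # order() breaks ties by lowest index
    H[c(j, nb), j] <- 1
  }
  labels <- colnames(X)
  if (!is.null(labels)) dimnames(H) <- list(labels, labels)
  list(H = H, w = rep(1, N))
}

#' Hypergraph degree matrices, similarity matrix, and Laplacian
#'
#' From a binary incidence matrix `H` (vertices x hyperedges) and positive
#' hyperedge weights `w`, computes the vertex degrees
#' \eqn{d(v_i) = \sum_j w_j H_{ij}}, hyperedge degrees
#' \eqn{\delta(e_j) = \sum_i H_{ij}}, the similarity matrix
#' \eqn{S = H W D_e^{-1} H^T} and the hypergraph Laplacian
#' \eqn{L = D_v - S}. `S` and `L` are symmetric positive semidefinite, and
#' the rows of `S` sum to the vertex degrees, so `L` annihilates the
#' constant vector.
#'
#' @param H Binary incidence matrix, vertices in rows, hyperedges in columns.
#'   Every hyperedge must contain at least one vertex.
#' @param w Strictly positive hyperedge weights, one per column of `H`.
#' @return List with vertex degrees `d_v`, hyperedge degrees `d_e`,
#'   similarity `S` and Laplacian `L`.
#' @export
hypergraph_laplacian <- function(H, w = rep(1, ncol(H))) {
  H <- as.matrix(H)
  if (any(H != 0 & H != 1)) stop("'H' must be binary")
  if (length(w) != ncol(H)) stop("'w' must have one weight per hyperedge")
  if (any(w <= 0)) stop("hyperedge weights must be strictly positive")

  d_e <- colSums(H)
  if (any(d_e == 0)) stop("empty hyperedge: degree zero makes De^-1 undefined")
  d_v <- as.vector(H %*% w)

  S <- H %*% (w / d_e * t(H))         # H W De^-1 H^T without forming diagonals
  L <- -S
  diag(L) <- diag(L) + d_v
  dimnames(S) <- dimnames(L) <- list(rownames(H), rownames(H))
  list(d_v = d_v, d_e = d_e, S = S, L = L)
}

#' Build the full feature hypergraph for one modality
#'
#' Convenience wrapper: KNN hyperedges ([knn_hyperedges()]) followed by the
#' degree/similarity/Laplacian computation ([hypergraph_laplacian()]).
#'
#' @inheritParams knn_hyperedges
#' @return An object of class `"hypergraph"` with elements `H`, `w`, `d_v`,
#'   `d_e`, `S`, `L`, and `k`.
#' @examples
#' sim <- simulate_paired_data(40, 10, 12, seed = 2)
#' hg <- feature_hypergraph(sim$X, k = 3)
#' colSums(hg$H)      # every hyperedge has k + 1 members
#' max(abs(hg$L %*% rep(1, 10)))   # Laplacian annihilates constants
#' @export
feature_hypergraph <- function(X, k, standardize = FALSE) {
  he <- knn_hyperedges(X, k, standardize = standardize)
  lap <- hypergraph_laplacian(he$H, he$w)
  structure(c(he, lap, list(k = as.integer(k))), class = "hypergraph")
}

#' @export
print.hypergraph <- function(x, ...) {
  cat(sprintf("Feature hypergraph: %d vertices, %d hyperedges (KNN, k = %d)\n",
              nrow(x$H), ncol(x$H), x$k))
  invisible(x)
}
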