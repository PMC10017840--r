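#' Noise-robustness simulation study
#'
#' Reproduces the simulation protocol used to compare the hypergraph-
#' regularized factorization against the unregularized netNMF baseline:
#' for each noise level, paired matrices are generated with a shared latent
#' factor ([simulate_paired_data()]), absolute-Pearson association networks
#' are built, and both algorithms are fitted from matched seeds; the joint
#' relative reconstruction error is recorded per replicate.
#'
#' The regularization weight is selected per noise level by relative error
#' on a diagonal grid (`lambda1 = lambda2`, evaluated on the first
#' replicate's networks) and then held fixed across replicates; the two
#' modalities are exchangeable in this design, so the diagonal grid loses
#' nothing while keeping the study affordable.
#'
#' @param n Sample count per replicate (300 in the small-sample design,
#'   1000 in the large-sample one).
#' @param p,q Feature counts for the two modalities.
#' @param noise_levels Noise standard deviations to sweep.
#' @param seeds Integer vector of replicate seeds (one generated dataset and
#'   matched factor initialization per seed).
#' @param rank Factorization rank; defaults to the [suggest_rank()]
#'   heuristic.
#' @param knn_k Neighbour size for the feature hypergraphs.
#' @param lambda_grid Candidate regularization weights for the per-level
#'   selection.
#' @param lambda Optional fixed weight (skips selection).
#' @param max_iter,tol Convergence settings passed to [hgnetnmf()].
#' @return Data frame with one row per (noise level, seed, algorithm):
#'   columns `noise`, `seed`, `algorithm` (`"hgnetnmf"` or `"netnmf"`),
#'   `lambda`, `relative_error`, `n_iter`.
#' @examples
#' \donttest{
#' res <- simulation_study(n = 100, p = 40, q = 60, noise_levels = c(1, 5),
#'                         seeds = 1, knn_k = 5)
#' aggregate(relative_error ~ noise + algorithm, res, mean)
#' }
#' @export
simulation_study <- function(n = 300, p = 200, q = 2000,
                             noise_levels = 1:5, seeds = 1:5,
                             rank = suggest_rank(n, p, q), knn_k = 10,
                             lambda_grid = c(0.0001, 0.001, 0.01, 0.1),
                             lambda = NULL, max_iter = 500, tol = 1e-6) {
  rows <- list()
  for (noise in noise_levels) {
    lam <- lambda
    for (si in seq_along(seeds)) {
      seed <- seeds[si]
      sim <- simulate_paired_data(n, p, q, sigma_noise = noise, seed = seed)
      nets <- association_networks(sim$X, sim$Y)
      hg1 <- feature_hypergraph(sim$X, knn_k)
      hg2 <- feature_hypergraph(sim$Y, knn_k)

      if (is.null(lam)) {   # select on the first replicate of this level
        scores <- vapply(lambda_grid, function(l) {
          f <- hgnetnmf(nets, rank = rank, lambda1 = l, lambda2 = l,
                        hg1 = hg1, hg2 = hg2, seed = seed,
                        max_iter = max_iter, tol = tol)
          relative_error(f, nets)
        }, numeric(1))
        lam <- lambda_grid[which.min(scores)]
      }

      fit_hg <- hgnetnmf(nets, rank = rank, lambda1 = lam, lambda2 = lam,
                         hg1 = hg1, hg2 = hg2, seed = seed,
                         max_iter = max_iter, tol = tol)
      fit_net <- hgnetnmf(nets, rank = rank, lambda1 = 0, lambda2 = 0,
                          seed = seed, max_iter = max_iter, tol = tol)
      rows[[length(rows) + 1L]] <- data.frame(
        noise = noise, seed = seed,
        algorithm = c("hgnetnmf", "netnmf"),
        lambda = c(lam, 0),
        relative_error = c(relative_error(fit_hg, nets),
                           relative_error(fit_net, nets)),
        n_iter = c(fit_hg$n_iter, fit_net$n_iter))
    }
  }
  do.call(rbind, rows)
}
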