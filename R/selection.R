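#' Heuristic rank (module count) suggestion
#'
#' The customary rule for the number of paired modules: at most one tenth of
#' the smallest of the sample count and the two feature counts, floored at 2.
#'
#' @param n_samples,p,q Positive dimensions of the data.
#' @return Integer rank suggestion.
#' @examples
#' suggest_rank(306, 140, 510)   # 14
#' suggest_rank(300, 20, 50)     # 2
#' @export
suggest_rank <- function(n_samples, p, q) {
  if (n_samples < 1 || p < 1 || q < 1) stop("dimensions must be positive")
  max(2L, as.integer(floor(min(n_samples, p, q) / 10)))
}

#' Select KNN neighbour sizes by fitted relative error
#'
#' Exhaustively fits the model for every pair of neighbour sizes
#' `(k1, k2)` — `k1` for the modality-1 feature hypergraph, `k2` for
#' modality 2 — and returns the pair minimizing the relative reconstruction
#' error. Association networks are built once from the raw matrices; only
#' the hypergraphs change across the grid.
#'
#' Ties in the argmin are broken toward smaller `(k1, k2)` (lexicographic)
#' for parsimony.
#'
#' @param X1,X2 Sample-by-feature matrices for the two modalities.
#' @param k1_grid,k2_grid Integer vectors of candidate neighbour sizes,
#'   each within `[1, N - 1]` for its modality.
#' @param rank Factorization rank (default from [suggest_rank()]).
#' @param lambda1,lambda2 Regularization weights held fixed during the
#'   neighbour search.
#' @param seed Seed passed to every fit.
#' @param ... Further arguments to [hgnetnmf()] (e.g. `max_iter`, `tol`).
#' @return An object of class `"hg_selection"`: list with `grid` (data frame
#'   of evaluated tuples and scores) and `best` (row of `grid`).
#' @export
select_knn_sizes <- function(X1, X2, k1_grid, k2_grid,
                             rank = suggest_rank(nrow(X1), ncol(X1), ncol(X2)),
                             lambda1 = 0.001, lambda2 = 0.001,
                             seed = 1L, ...) {
  k1_grid <- sort(unique(as.integer(k1_grid)))
  k2_grid <- sort(unique(as.integer(k2_grid)))
  if (any(k1_grid < 1) || any(k1_grid > ncol(X1) - 1))
    stop("'k1_grid' must lie within [1, ncol(X1) - 1]")
  if (any(k2_grid < 1) || any(k2_grid > ncol(X2) - 1))
    stop("'k2_grid' must lie within [1, ncol(X2) - 1]")

  nets <- association_networks(X1, X2)
  hg1s <- lapply(k1_grid, function(k) feature_hypergraph(X1, k))
  hg2s <- lapply(k2_grid, function(k) feature_hypergraph(X2, k))

  grid <- expand.grid(k2 = k2_grid, k1 = k1_grid)[, c("k1", "k2")]
  grid$score <- NA_real_
  for (i in seq_len(nrow(grid))) {
    i1 <- match(grid$k1[i], k1_grid); i2 <- match(grid$k2[i], k2_grid)
    fit <- tryCatch(
      hgnetnmf(nets, rank = rank, lambda1 = lambda1, lambda2 = lambda2,
               hg1 = hg1s[[i1]], hg2 = hg2s[[i2]], seed = seed, ...),
      error = function(e) stop(sprintf("fit failed at (k1 = %d, k2 = %d): %s",
                                       grid$k1[i], grid$k2[i],
                                       conditionMessage(e)), call. = FALSE))
    grid$score[i] <- relative_error(fit, nets)
  }
  # lexicographic order of the grid plus which.min gives the smaller-k tie-break
  grid <- grid[order(grid$k1, grid$k2), ]
  rownames(grid) <- NULL
  structure(list(grid = grid, best = grid[which.min(grid$score), ]),
            class = "hg_selection")
}

#' Select regularization weights by fitted relative error
#'
#' Exhaustive evaluation of every `(lambda1, lambda2)` pair on a grid,
#' scored by relative reconstruction error; the argmin pair is returned,
#' ties broken toward smaller values.
#'
#' @param nets An `"assoc_networks"` object.
#' @param hg1,hg2 Feature hypergraphs for the two modalities.
#' @param lambda_grid Non-negative candidate weights; the default is the
#'   usual four-decade grid.
#' @param rank Factorization rank.
#' @param seed Seed passed to every fit.
#' @param ... Further arguments to [hgnetnmf()].
#' @return An object of class `"hg_selection"` (see [select_knn_sizes()]).
#' @export
select_lambdas <- function(nets, hg1, hg2,
                           lambda_grid = c(0.0001, 0.001, 0.01, 0.1),
                           rank, seed = 1L, ...) {
  if (!length(lambda_grid) || any(lambda_grid < 0))
    stop("'lambda_grid' must be a non-empty vector of non-negative values")
  lambda_grid <- sort(unique(lambda_grid))
  grid <- expand.grid(lambda2 = lambda_grid, lambda1 = lambda_grid)[, c("lambda1", "lambda2")]
  grid$score <- NA_real_
  for (i in seq_len(nrow(grid))) {
    fit <- tryCatch(
      hgnetnmf(nets, rank = rank,
               lambda1 = grid$lambda1[i], lambda2 = grid$lambda2[i],
               hg1 = if (grid$lambda1[i] > 0) hg1 else NULL,
               hg2 = if (grid$lambda2[i] > 0) hg2 else NULL,
               seed = seed, ...),
      error = function(e) stop(sprintf(
        "fit failed at (lambda1 = %g, lambda2 = %g): %s",
        grid$lambda1[i], grid$lambda2[i], conditionMessage(e)), call. = FALSE))
    grid$score[i] <- relative_error(fit, nets)
  }
  grid <- grid[order(grid$lambda1, grid$lambda2), ]
  rownames(grid) <- NULL
  structure(list(grid = grid, best = grid[which.min(grid$score), ]),
            class = "hg_selection")
}

#' @export
print.hg_selection <- function(x, ...) {
  cat(sprintf("Parameter selection over %d grid points\n", nrow(x$grid)))
  cat("best:\n")
  print(x$best, row.names = FALSE)
  invisible(x)
}
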