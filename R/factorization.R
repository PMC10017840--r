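#' Fit a hypergraph-regularized network tri-factorization (HG-netNMF)
#'
#' Jointly factorizes the association triple \eqn{(R_{11}, R_{22}, R_{12})}
#' into non-negative factors \eqn{G_1, G_2, S_{11}, S_{22}} by minimizing
#' \deqn{\|R_{11}-G_1S_{11}G_1^T\|_F^2 + \|R_{12}-G_1G_2^T\|_F^2 +
#'       \|R_{22}-G_2S_{22}G_2^T\|_F^2 +
#'       \lambda_1\,\mathrm{tr}(G_1^TL_1G_1) +
#'       \lambda_2\,\mathrm{tr}(G_2^TL_2G_2)}
#' subject to all factors being non-negative, where \eqn{L_1, L_2} are
#' hypergraph Laplacians over the two modalities' features. With
#' \eqn{\lambda_1 = \lambda_2 = 0} this is the unregularized netNMF joint
#' tri-factorization. Columns of \eqn{G_1} and \eqn{G_2} are paired modules:
#' the cross term \eqn{\|R_{12}-G_1G_2^T\|} couples column \eqn{j} of
#' \eqn{G_1} to column \eqn{j} of \eqn{G_2}.
#'
#' Optimization uses element-wise multiplicative updates derived from the
#' KKT conditions. The Laplacian enters through its split
#' \eqn{L = D_v - S}: the similarity part \eqn{S G} is added to the update
#' numerator and the degree part \eqn{D_v G} to the denominator, which keeps
#' every factor entry non-negative at every iteration (the standard device
#' in graph-regularized NMF). `S11`/`S22` are initialized symmetric and the
#' updates preserve that symmetry.
#'
#' @param nets An `"assoc_networks"` object (see [association_networks()] or
#'   [as_association_networks()]).
#' @param rank Number of paired modules `k`, between 1 and `min(p, q)`. See
#'   [suggest_rank()] for the usual heuristic.
#' @param lambda1,lambda2 Non-negative hypergraph regularization weights for
#'   the ROI-side and gene-side factors.
#' @param hg1,hg2 `"hypergraph"` objects (from [feature_hypergraph()]) for
#'   the two modalities. Required when the corresponding lambda is positive;
#'   ignored (may be `NULL`) when it is zero.
#' @param seed Integer seed for the uniform(0, 1) factor initialization.
#' @param max_iter Maximum number of update sweeps.
#' @param tol Convergence tolerance on the relative objective change.
#' @param eps Small positive guard added to update denominators.
#'
#' @return An object of class `"hgnetnmf"`: list with factor matrices `G1`
#'   (p x k), `G2` (q x k), `S11`, `S22` (k x k), the hyperparameters,
#'   `objective_trace` (initial objective followed by one value per
#'   iteration), `converged`, `n_iter`, and `seed`.
#'
#' @examples
#' sim <- simulate_paired_data(60, 12, 15, seed = 3)
#' nets <- association_networks(sim$X, sim$Y)
#' hg1 <- feature_hypergraph(sim$X, k = 3)
#' hg2 <- feature_hypergraph(sim$Y, k = 3)
#' fit <- hgnetnmf(nets, rank = 3, lambda1 = 0.01, lambda2 = 0.01,
#'                 hg1 = hg1, hg2 = hg2, seed = 1)
#' fit
#' relative_error(fit, nets)
#' @export
hgnetnmf <- function(nets, rank, lambda1 = 0, lambda2 = 0,
                     hg1 = NULL, hg2 = NULL, seed = 1L,
                     max_iter = 500L, tol = 1e-6, eps = .EPS_GUARD) {
  stopifnot(inherits(nets, "assoc_networks"))
  p <- nrow(nets$R11); q <- nrow(nets$R22)
  if (!is.numeric(rank) || rank < 1 || rank > min(p, q))
    stop(sprintf("'rank' must lie in [1, %d]", min(p, q)))
  if (lambda1 < 0 || lambda2 < 0) stop("lambdas must be non-negative")
  if (lambda1 > 0 && is.null(hg1)) stop("'hg1' is required when lambda1 > 0")
  if (lambda2 > 0 && is.null(hg2)) stop("'hg2' is required when lambda2 > 0")
  .check_hg <- function(hg, n, arg) {
    if (is.null(hg)) return(NULL)
    if (!is.list(hg) || is.null(hg$S) || is.null(hg$d_v))
      stop(sprintf("'%s' must be a hypergraph object with S and d_v", arg))
    if (nrow(hg$S) != n)
      stop(sprintf("'%s' has %d vertices but the network has %d features",
                   arg, nrow(hg$S), n))
    hg
  }
  hg1 <- .check_hg(hg1, p, "hg1"); hg2 <- .check_hg(hg2, q, "hg2")
  rank <- as.integer(rank)

  model <- hg_init_factors(p, q, rank, seed = seed)
  model$lambda1 <- lambda1; model$lambda2 <- lambda2
  model$seed <- as.integer(seed)

  obj <- hg_objective(nets, model, hg1, hg2)
  trace <- numeric(max_iter + 1L)
  trace[1L] <- obj
  converged <- FALSE
  n_iter <- 0L
  for (it in seq_len(max_iter)) {
    model <- hg_update_step(nets, model, hg1, hg2, eps = eps)
    obj_new <- hg_objective(nets, model, hg1, hg2)
    if (!is.finite(obj_new))
      stop(sprintf("non-finite objective at iteration %d", it))
    trace[it + 1L] <- obj_new
    n_iter <- it
    if (abs(obj - obj_new) <= tol * max(obj, eps)) {
      converged <- TRUE
      break
    }
    obj <- obj_new
  }

  model$objective_trace <- trace[seq_len(n_iter + 1L)]
  model$converged <- converged
  model$n_iter <- n_iter
  model$roi_ids <- nets$roi_ids
  model$gene_ids <- nets$gene_ids
  rownames(model$G1) <- nets$roi_ids
  rownames(model$G2) <- nets$gene_ids
  class(model) <- "hgnetnmf"
  model
}

#' Seeded uniform initialization of the four factor matrices
#'
#' Draws `G1`, `G2` i.i.d. uniform(0, 1) and `S11`, `S22` as symmetrized
#' uniform draws. Factors are never initialized at zero, since zero is an
#' absorbing state of multiplicative updates.
#'
#' @param p,q,rank Dimensions of the factorization.
#' @param seed Integer seed.
#' @return List with `G1`, `G2`, `S11`, `S22`, and `k`.
#' @export
hg_init_factors <- function(p, q, rank, seed = 1L) {
  set.seed(as.integer(seed))
  G1 <- matrix(runif(p * rank), p, rank)
  G2 <- matrix(runif(q * rank), q, rank)
  A <- matrix(runif(rank * rank), rank, rank)
  S11 <- (A + t(A)) / 2
  B <- matrix(runif(rank * rank), rank, rank)
  S22 <- (B + t(B)) / 2
  list(G1 = G1, G2 = G2, S11 = S11, S22 = S22, k = as.integer(rank))
}

#' Regularized tri-factorization objective value
#'
#' Sum of the three squared Frobenius residuals plus the two hypergraph
#' trace penalties. With `lambda1 = lambda2 = 0` this is exactly the netNMF
#' objective.
#'
#' @param nets An `"assoc_networks"` object.
#' @param model List (or `"hgnetnmf"` object) with `G1`, `G2`, `S11`, `S22`
#'   and, for the penalty, `lambda1`/`lambda2` (default 0 if absent).
#' @param hg1,hg2 Hypergraph objects supplying the Laplacians; `NULL` means
#'   no penalty on that side.
#' @return Non-negative scalar.
#' @export
hg_objective <- function(nets, model, hg1 = NULL, hg2 = NULL) {
  G1 <- model$G1; G2 <- model$G2
  .check_shapes(nets, model)
  l1 <- if (is.null(model$lambda1)) 0 else model$lambda1
  l2 <- if (is.null(model$lambda2)) 0 else model$lambda2
  obj <- sum((nets$R11 - tcrossprod(G1 %*% model$S11, G1))^2) +
         sum((nets$R12 - tcrossprod(G1, G2))^2) +
         sum((nets$R22 - tcrossprod(G2 %*% model$S22, G2))^2)
  if (l1 > 0 && !is.null(hg1)) {
    L1 <- if (!is.null(hg1$L)) hg1$L else diag(hg1$d_v) - hg1$S
    obj <- obj + l1 * sum(G1 * (L1 %*% G1))
  }
  if (l2 > 0 && !is.null(hg2)) {
    L2 <- if (!is.null(hg2$L)) hg2$L else diag(hg2$d_v) - hg2$S
    obj <- obj + l2 * sum(G2 * (L2 %*% G2))
  }
  obj
}

.check_shapes <- function(nets, model) {
  p <- nrow(nets$R11); q <- nrow(nets$R22); k <- ncol(model$G1)
  if (nrow(model$G1) != p || nrow(model$G2) != q ||
      ncol(model$G2) != k ||
      !all(dim(model$S11) == k) || !all(dim(model$S22) == k))
    stop("factor dimensions do not match the association networks")
  invisible(TRUE)
}

#' One multiplicative KKT update sweep
#'
#' Applies, in order, the `S11`, `S22`, `G1` and `G2` element-wise
#' multiplicative updates. The hypergraph Laplacian \eqn{L = D_v - S} is
#' split so the similarity part contributes to the numerator and the degree
#' part to the denominator, preserving non-negativity:
#' \deqn{S_{11} \leftarrow S_{11} \odot \frac{G_1^TR_{11}G_1}
#'       {G_1^TG_1S_{11}G_1^TG_1 + \epsilon}}
#' \deqn{G_1 \leftarrow G_1 \odot \frac{2R_{11}G_1S_{11} + R_{12}G_2 +
#'       \lambda_1 S^{(1)}G_1}{2G_1S_{11}G_1^TG_1S_{11} + G_1G_2^TG_2 +
#'       \lambda_1 D_v^{(1)}G_1 + \epsilon}}
#' and symmetrically for `S22` and `G2`. The `G1` update uses the freshly
#' updated `S11` (and likewise for `G2`).
#'
#' @inheritParams hg_objective
#' @param eps Positive guard added to every denominator.
#' @return The model list with updated factors.
#' @export
hg_update_step <- function(nets, model, hg1 = NULL, hg2 = NULL,
                           eps = .EPS_GUARD) {
  G1 <- model$G1; G2 <- model$G2; S11 <- model$S11; S22 <- model$S22
  l1 <- if (is.null(model$lambda1)) 0 else model$lambda1
  l2 <- if (is.null(model$lambda2)) 0 else model$lambda2
  R11 <- nets$R11; R22 <- nets$R22; R12 <- nets$R12

  GtG1 <- crossprod(G1)
  S11 <- S11 * crossprod(G1, R11 %*% G1) / (GtG1 %*% S11 %*% GtG1 + eps)

  GtG2 <- crossprod(G2)
  S22 <- S22 * crossprod(G2, R22 %*% G2) / (GtG2 %*% S22 %*% GtG2 + eps)

  A1 <- G1 %*% S11
  num1 <- 2 * (R11 %*% A1) + R12 %*% G2
  den1 <- 2 * (A1 %*% (GtG1 %*% S11)) + G1 %*% GtG2
  if (l1 > 0) {
    num1 <- num1 + l1 * (hg1$S %*% G1)
    den1 <- den1 + l1 * (hg1$d_v * G1)
  }
  G1 <- G1 * num1 / (den1 + eps)

  GtG1 <- crossprod(G1)
  A2 <- G2 %*% S22
  num2 <- 2 * (R22 %*% A2) + crossprod(R12, G1)
  den2 <- 2 * (A2 %*% (crossprod(G2) %*% S22)) + G2 %*% GtG1
  if (l2 > 0) {
    num2 <- num2 + l2 * (hg2$S %*% G2)
    den2 <- den2 + l2 * (hg2$d_v * G2)
  }
  G2 <- G2 * num2 / (den2 + eps)

  if (any(!is.finite(G1)) || any(!is.finite(G2)) ||
      any(!is.finite(S11)) || any(!is.finite(S22)))
    stop("non-finite factor entries after multiplicative update")

  model$G1 <- G1; model$G2 <- G2; model$S11 <- S11; model$S22 <- S22
  model
}
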