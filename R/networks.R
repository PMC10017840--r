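#' Absolute Pearson association networks from paired feature matrices
#'
#' Computes the three non-negative association matrices the tri-factorization
#' consumes: `R11 = |cor(X)|` among the first modality's features,
#' `R22 = |cor(Y)|` among the second modality's features, and the
#' cross-modality network `R12 = |cor(X, Y)|`. Absolute values make every
#' entry non-negative; `R11` and `R22` are symmetric with unit diagonal.
#'
#' @param X Sample-by-feature numeric matrix for modality 1 (e.g., ROI
#'   gray-matter volumes).
#' @param Y Sample-by-feature numeric matrix for modality 2 (e.g., gene
#'   expression), same samples in the same order as `X`.
#' @param method How negative correlations are made non-negative:
#'   `"absolute"` (the default) takes `|r|`, treating strong negative
#'   association as association; `"truncate"` sets negative correlations to
#'   zero, treating them as absent. The choice changes the spectrum of the
#'   resulting networks and hence the reconstruction error scale; see the
#'   methods vignette.
#'
#' @return An object of class `"assoc_networks"`: list with `R11` (p x p),
#'   `R22` (q x q), `R12` (p x q), `roi_ids`, `gene_ids`.
#'
#' @details A feature column with zero variance has no defined correlation;
#'   such columns raise an error naming the offending column rather than
#'   being dropped silently, so feature indices stay exact.
#'
#' @examples
#' sim <- simulate_paired_data(50, 6, 8, seed = 1)
#' nets <- association_networks(sim$X, sim$Y)
#' range(nets$R12)
#' @export
association_networks <- function(X, Y, method = c("absolute", "truncate")) {
  method <- match.arg(method)
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y))
    stop("'X' and 'Y' must have the same number of samples (rows)")
  if (!is.null(rownames(X)) && !is.null(rownames(Y)) &&
      !identical(rownames(X), rownames(Y)))
    stop("'X' and 'Y' have mismatched sample labels")
  .check_variance(X, "X")
  .check_variance(Y, "Y")

  nonneg <- if (method == "absolute") abs else function(r) pmax(r, 0)
  R11 <- nonneg(cor(X)); diag(R11) <- 1
  R22 <- nonneg(cor(Y)); diag(R22) <- 1
  R12 <- nonneg(cor(X, Y))

  as_association_networks(R11, R22, R12,
                          roi_ids = colnames(X), gene_ids = colnames(Y))
}

.check_variance <- function(M, name) {
  v <- apply(M, 2, function(col) max(col) - min(col))
  bad <- which(v == 0)
  if (length(bad)) {
    lab <- if (!is.null(colnames(M))) colnames(M)[bad[1]] else bad[1]
    stop(sprintf("zero-variance column in '%s': %s", name, lab))
  }
}

#' Assemble precomputed association matrices into a network triple
#'
#' Validates and packages three non-negative association matrices (for use
#' when networks were computed elsewhere, rather than from raw data via
#' [association_networks()]).
#'
#' @param R11 p x p non-negative symmetric matrix.
#' @param R22 q x q non-negative symmetric matrix.
#' @param R12 p x q non-negative matrix.
#' @param roi_ids,gene_ids Optional feature labels; defaults taken from
#'   dimnames or generated.
#' @return An object of class `"assoc_networks"`.
#' @export
as_association_networks <- function(R11, R22, R12, roi_ids = NULL, gene_ids = NULL) {
  R11 <- as.matrix(R11); R22 <- as.matrix(R22); R12 <- as.matrix(R12)
  p <- nrow(R11); q <- nrow(R22)
  if (ncol(R11) != p || ncol(R22) != q)
    stop("'R11' and 'R22' must be square")
  if (nrow(R12) != p || ncol(R12) != q)
    stop(sprintf("'R12' must be %d x %d to match R11 and R22", p, q))
  if (min(R11) < 0 || min(R22) < 0 || min(R12) < 0)
    stop("association matrices must be non-negative")
  if (max(abs(R11 - t(R11))) > 1e-12) stop("'R11' must be symmetric")
  if (max(abs(R22 - t(R22))) > 1e-12) stop("'R22' must be symmetric")

  if (is.null(roi_ids)) roi_ids <- rownames(R11)
  if (is.null(roi_ids)) roi_ids <- paste0("ROI_", seq_len(p))
  if (is.null(gene_ids)) gene_ids <- rownames(R22)
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(q))
  dimnames(R11) <- list(roi_ids, roi_ids)
  dimnames(R22) <- list(gene_ids, gene_ids)
  dimnames(R12) <- list(roi_ids, gene_ids)

  structure(list(R11 = R11, R22 = R22, R12 = R12,
                 roi_ids = roi_ids, gene_ids = gene_ids),
            class = "assoc_networks")
}

#' @export
print.assoc_networks <- function(x, ...) {
  cat(sprintf("Association networks: R11 %d x %d, R22 %d x %d, R12 %d x %d\n",
              nrow(x$R11), ncol(x$R11), nrow(x$R22), ncol(x$R22),
              nrow(x$R12), ncol(x$R12)))
  invisible(x)
}
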