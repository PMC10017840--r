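#' Joint relative reconstruction error
#'
#' The scalar used for hyperparameter selection and the simulation studies:
#' \deqn{\sqrt{\|R_{11}-R_{11}'\|_F^2 + \|R_{12}-R_{12}'\|_F^2 +
#'             \|R_{22}-R_{22}'\|_F^2} \;/\;
#'       \sqrt{\|R_{11}\|_F^2 + \|R_{12}\|_F^2 + \|R_{22}\|_F^2}}
#' with reconstructions \eqn{R_{11}' = G_1S_{11}G_1^T},
#' \eqn{R_{12}' = G_1G_2^T}, \eqn{R_{22}' = G_2S_{22}G_2^T}. Zero for an
#' exact factorization; 1 when all factors are zero.
#'
#' @param model A fitted `"hgnetnmf"` object (or any list with the four
#'   factor matrices).
#' @param nets The `"assoc_networks"` object the model was fitted to.
#' @param per_matrix If `TRUE`, return the mean of the three per-matrix
#'   relative errors instead of the joint Frobenius normalization.
#' @return A scalar in approximately `[0, 1]`.
#' @export
relative_error <- function(model, nets, per_matrix = FALSE) {
  .check_shapes(nets, model)
  rec <- hg_reconstruct(model)
  res <- c(sum((nets$R11 - rec$R11)^2),
           sum((nets$R12 - rec$R12)^2),
           sum((nets$R22 - rec$R22)^2))
  dat <- c(sum(nets$R11^2), sum(nets$R12^2), sum(nets$R22^2))
  if (per_matrix) mean(sqrt(res / dat)) else sqrt(sum(res) / sum(dat))
}

#' Reconstructed association matrices from fitted factors
#'
#' @param model A fitted `"hgnetnmf"` object.
#' @return List with `R11`, `R12`, `R22` reconstructions.
#' @export
hg_reconstruct <- function(model) {
  list(R11 = tcrossprod(model$G1 %*% model$S11, model$G1),
       R12 = tcrossprod(model$G1, model$G2),
       R22 = tcrossprod(model$G2 %*% model$S22, model$G2))
}

#' Pearson correlations between data and reconstructed networks
#'
#' Correlates the strict upper triangles of `R11` with its reconstruction
#' and of `R22` with its reconstruction (the diagonal and lower triangle are
#' redundant for symmetric matrices), and the full flattened `R12` with its
#' reconstruction.
#'
#' @inheritParams relative_error
#' @return Named numeric vector `c(r11, r22, r12)`.
#' @export
reconstruction_correlations <- function(model, nets) {
  .check_shapes(nets, model)
  rec <- hg_reconstruct(model)
  up <- function(M) M[upper.tri(M)]
  safe_cor <- function(a, b) {
    if (sd(a) == 0 || sd(b) == 0)
      stop("correlation undefined: constant matrix entries")
    cor(a, b)
  }
  c(r11 = safe_cor(up(nets$R11), up(rec$R11)),
    r22 = safe_cor(up(nets$R22), up(rec$R22)),
    r12 = safe_cor(as.vector(nets$R12), as.vector(rec$R12)))
}
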