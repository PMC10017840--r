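#' @export
print.hgnetnmf <- function(x, ...) {
  cat(sprintf("HG-netNMF fit: rank %d, lambda1 = %g, lambda2 = %g\n",
              x$k, x$lambda1, x$lambda2))
  cat(sprintf("  %d x %d ROI factor, %d x %d gene factor\n",
              nrow(x$G1), x$k, nrow(x$G2), x$k))
  cat(sprintf("  %d iterations, %s (final objective %.6g)\n",
              x$n_iter,
              if (x$converged) "converged" else "max_iter reached",
              x$objective_trace[length(x$objective_trace)]))
  invisible(x)
}

#' Summarize a fitted HG-netNMF model
#'
#' @param object A fitted `"hgnetnmf"` object.
#' @param nets Optional `"assoc_networks"` object; when supplied the summary
#'   includes the relative reconstruction error and the data-reconstruction
#'   correlations.
#' @param ... Unused.
#' @return An object of class `"summary.hgnetnmf"`.
#' @export
summary.hgnetnmf <- function(object, nets = NULL, ...) {
  out <- list(k = object$k, lambda1 = object$lambda1, lambda2 = object$lambda2,
              n_iter = object$n_iter, converged = object$converged,
              objective = object$objective_trace[length(object$objective_trace)],
              seed = object$seed)
  if (!is.null(nets)) {
    out$relative_error <- relative_error(object, nets)
    out$reconstruction_correlations <- reconstruction_correlations(object, nets)
  }
  class(out) <- "summary.hgnetnmf"
  out
}

#' @export
print.summary.hgnetnmf <- function(x, ...) {
  cat(sprintf("HG-netNMF: rank %d, lambda = (%g, %g), seed %d\n",
              x$k, x$lambda1, x$lambda2, x$seed))
  cat(sprintf("  %d iterations (%s), objective %.6g\n", x$n_iter,
              if (x$converged) "converged" else "not converged", x$objective))
  if (!is.null(x$relative_error)) {
    cat(sprintf("  relative reconstruction error: %.4f\n", x$relative_error))
    rc <- x$reconstruction_correlations
    cat(sprintf("  reconstruction correlations: r11 %.4f, r22 %.4f, r12 %.4f\n",
                rc["r11"], rc["r22"], rc["r12"]))
  }
  invisible(x)
}

#' Extract factor matrices from a fitted model
#'
#' @param object A fitted `"hgnetnmf"` object.
#' @param ... Unused.
#' @return List with `G1`, `G2`, `S11`, `S22`.
#' @export
coef.hgnetnmf <- function(object, ...) {
  object[c("G1", "G2", "S11", "S22")]
}

#' Reconstructed networks from a fitted model
#'
#' @inheritParams coef.hgnetnmf
#' @return List of reconstructions `R11`, `R12`, `R22` (see
#'   [hg_reconstruct()]).
#' @export
fitted.hgnetnmf <- function(object, ...) {
  hg_reconstruct(object)
}

#' Residual matrices of a fitted model
#'
#' @inheritParams coef.hgnetnmf
#' @param nets The `"assoc_networks"` object the model was fitted to.
#' @return List of residual matrices `R11`, `R12`, `R22` (data minus
#'   reconstruction).
#' @export
residuals.hgnetnmf <- function(object, nets, ...) {
  rec <- hg_reconstruct(object)
  list(R11 = nets$R11 - rec$R11,
       R12 = nets$R12 - rec$R12,
       R22 = nets$R22 - rec$R22)
}

#' Plot the objective trace of a fitted model
#'
#' @param x A fitted `"hgnetnmf"` object.
#' @param log Axis specification passed to [graphics::plot()]; the default
#'   log-scales the objective axis.
#' @param ... Further graphical parameters.
#' @return `x`, invisibly.
#' @importFrom graphics plot
#' @export
plot.hgnetnmf <- function(x, log = "y", ...) {
  tr <- x$objective_trace
  graphics::plot(seq_along(tr) - 1L, tr, type = "l", log = log,
                 xlab = "iteration", ylab = "objective", ...)
  invisible(x)
}
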