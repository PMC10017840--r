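#' Simulate paired imaging/gene matrices with a shared latent factor
#'
#' Generates a sample-by-ROI matrix `X` and a sample-by-gene matrix `Y` in
#' which a subset of columns carries a common latent factor. A latent factor
#' \eqn{\epsilon} of length `n` is drawn from the standard normal, together
#' with an ROI weight vector \eqn{u} (length `p`) and a gene weight vector
#' \eqn{v} (length `q`). Signal-bearing ("correlated") columns are built as
#' \eqn{X_{\cdot j} = u_j \epsilon + e} with additive Gaussian noise
#' \eqn{e \sim N(0, \sigma^2)}; the remaining columns are pure noise
#' \eqn{X_{\cdot j} = e}. The gene matrix uses the same construction with
#' \eqn{v}. The noise standard deviation `sigma_noise` is the "noise level".
#'
#' The first `round(frac_correlated * p)` ROI columns (and analogously for
#' genes) are the signal-bearing ones; their indices are recorded in the
#' returned truth object, so no bookkeeping is lost by the block layout.
#'
#' @param n Number of samples (rows). Must be at least 3.
#' @param p Number of ROI features (columns of `X`).
#' @param q Number of gene features (columns of `Y`).
#' @param sigma_noise Positive noise standard deviation (the noise level).
#' @param frac_correlated Fraction of columns, in `(0, 1]`, that carry the
#'   latent factor; applied independently to ROIs and genes.
#' @param seed Integer seed; identical arguments and seed reproduce the
#'   matrices bit-for-bit.
#'
#' @return An object of class `"hg_sim"`: a list with elements
#'   \item{X}{`n x p` numeric matrix with sample and ROI labels.}
#'   \item{Y}{`n x q` numeric matrix with sample and gene labels.}
#'   \item{truth}{list recording `u`, `v`, `eps`, `corr_rois`, `corr_genes`,
#'     `sigma_noise` and `seed`.}
#'
#' @examples
#' sim <- simulate_paired_data(n = 50, p = 6, q = 8, sigma_noise = 1, seed = 7)
#' dim(sim$X)
#' sim$truth$corr_rois
#' @export
simulate_paired_data <- function(n, p, q, sigma_noise = 1, frac_correlated = 0.5,
                                 seed = 1L) {
  if (!is.numeric(n) || n < 3) stop("'n' must be at least 3")
  if (!is.numeric(p) || p < 2 || !is.numeric(q) || q < 2)
    stop("'p' and 'q' must be at least 2")
  if (!is.numeric(sigma_noise) || length(sigma_noise) != 1 || sigma_noise <= 0)
    stop("'sigma_noise' must be a positive number")
  if (!is.numeric(frac_correlated) || frac_correlated <= 0 || frac_correlated > 1)
    stop("'frac_correlated' must lie in (0, 1]")
  n <- as.integer(n); p <- as.integer(p); q <- as.integer(q)

  set.seed(as.integer(seed))
  eps <- rnorm(n)
  u <- rnorm(p)
  v <- rnorm(q)
  corr_rois <- seq_len(max(1L, as.integer(round(frac_correlated * p))))
  corr_genes <- seq_len(max(1L, as.integer(round(frac_correlated * q))))

  X <- matrix(rnorm(n * p, sd = sigma_noise), n, p)
  X[, corr_rois] <- X[, corr_rois] + outer(eps, u[corr_rois])
  Y <- matrix(rnorm(n * q, sd = sigma_noise), n, q)
  Y[, corr_genes] <- Y[, corr_genes] + outer(eps, v[corr_genes])

  dimnames(X) <- list(paste0("S", seq_len(n)), paste0("ROI_", seq_len(p)))
  dimnames(Y) <- list(paste0("S", seq_len(n)), paste0("gene_", seq_len(q)))

  structure(list(
    X = X, Y = Y,
    truth = list(u = u, v = v, eps = eps,
                 corr_rois = corr_rois, corr_genes = corr_genes,
                 sigma_noise = sigma_noise, seed = as.integer(seed))
  ), class = "hg_sim")
}

#' @export
print.hg_sim <- function(x, ...) {
  cat(sprintf(
    "Simulated paired data: %d samples, %d ROIs (%d signal), %d genes (%d signal), noise sd %.3g, seed %d\n",
    nrow(x$X), ncol(x$X), length(x$truth$corr_rois),
    ncol(x$Y), length(x$truth$corr_genes), x$truth$sigma_noise, x$truth$seed))
  invisible(x)
}
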