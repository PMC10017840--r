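#' Column-wise z-score module membership
#'
#' For each factor column \eqn{j}, standardizes the loadings with the
#' population standard deviation,
#' \eqn{z_{ij} = (G_{ij} - \mu_{\cdot j}) / \sigma_{\cdot j}} with
#' \eqn{\sigma_{\cdot j} = \sqrt{\frac{1}{N}\sum_i (G_{ij}-\mu_{\cdot j})^2}},
#' and declares feature \eqn{i} a member of module \eqn{j} when
#' \eqn{z_{ij}} strictly exceeds the threshold.
#'
#' A constant column has no defined z-score; it is flagged as degenerate,
#' its z-scores are set to 0 and it yields no members.
#'
#' @param G Non-negative factor matrix with at least 2 rows (features in
#'   rows, modules in columns).
#' @param threshold Membership threshold on the z-score (default 1; strict
#'   inequality).
#' @return List with `z` (z-score matrix), `membership` (logical matrix) and
#'   `degenerate` (logical per column).
#' @export
zscore_membership <- function(G, threshold = 1) {
  G <- as.matrix(G)
  if (nrow(G) < 2) stop("'G' must have at least 2 rows")
  N <- nrow(G)
  mu <- colMeans(G)
  sigma <- sqrt(colMeans(sweep(G, 2, mu)^2))   # population sd (divide by N)
  degenerate <- sigma == 0
  z <- sweep(G, 2, mu)
  z <- sweep(z, 2, ifelse(degenerate, 1, sigma), "/")
  z[, degenerate] <- 0
  membership <- z > threshold
  membership[, degenerate] <- FALSE
  dimnames(z) <- dimnames(membership) <- dimnames(G)
  list(z = z, membership = membership, degenerate = degenerate)
}

#' Drop modules with too few members on either side
#'
#' A paired module is retained only when it has at least `min_size` members
#' on the ROI side and at least `min_size` members on the gene side
#' ("fewer than five" is dropped at the default).
#'
#' @param membership_roi,membership_gene Logical membership matrices with
#'   equal column counts (features x modules).
#' @param min_size Minimum member count per side (default 5).
#' @return Logical vector of retained flags, one per module.
#' @export
filter_modules <- function(membership_roi, membership_gene, min_size = 5) {
  if (ncol(membership_roi) != ncol(membership_gene))
    stop("membership matrices must have the same number of modules")
  colSums(membership_roi) >= min_size & colSums(membership_gene) >= min_size
}

#' Per-module relative reconstruction error
#'
#' Restricts the reconstructions to one module's member rows and columns and
#' computes relative Frobenius errors on the restricted submatrices: the ROI
#' submatrix of `R11`, the gene submatrix of `R22`, the cross submatrix of
#' `R12`, and a combined total over all three. The module with the smallest
#' total error is the "significant module" singled out for network analysis.
#'
#' @param nets An `"assoc_networks"` object.
#' @param model The fitted `"hgnetnmf"` model.
#' @param roi_members,gene_members Integer or logical indices of the
#'   module's members on each side; both must be non-empty.
#' @return Named numeric vector `c(roi, gene, cross, total)`.
#' @export
module_relative_error <- function(nets, model, roi_members, gene_members) {
  if (is.logical(roi_members)) roi_members <- which(roi_members)
  if (is.logical(gene_members)) gene_members <- which(gene_members)
  if (!length(roi_members) || !length(gene_members))
    stop("module has an empty member set")
  rec <- hg_reconstruct(model)
  r11 <- nets$R11[roi_members, roi_members, drop = FALSE]
  r22 <- nets$R22[gene_members, gene_members, drop = FALSE]
  r12 <- nets$R12[roi_members, gene_members, drop = FALSE]
  e11 <- sum((r11 - rec$R11[roi_members, roi_members])^2)
  e22 <- sum((r22 - rec$R22[gene_members, gene_members])^2)
  e12 <- sum((r12 - rec$R12[roi_members, gene_members])^2)
  c(roi = sqrt(e11 / sum(r11^2)),
    gene = sqrt(e22 / sum(r22^2)),
    cross = sqrt(e12 / sum(r12^2)),
    total = sqrt((e11 + e22 + e12) / (sum(r11^2) + sum(r22^2) + sum(r12^2))))
}

#' Extract paired ROI/gene modules from a fitted model
#'
#' Applies [zscore_membership()] to both factor matrices, drops modules with
#' fewer than `min_size` members on either side ([filter_modules()]), and —
#' when `nets` is supplied — scores every retained module by its restricted
#' reconstruction error ([module_relative_error()]). Module indices are the
#' 1-based column indices of `G1`/`G2`.
#'
#' @param model A fitted `"hgnetnmf"` object.
#' @param nets Optional `"assoc_networks"` object for per-module errors.
#' @param threshold z-score membership threshold (default 1).
#' @param min_size Minimum members per side for retention (default 5).
#' @return An object of class `"module_set"`: list with `k`, `roi_members`
#'   and `gene_members` (lists of label vectors), `z_roi`, `z_gene`,
#'   `retained`, `module_errors` (matrix, rows = modules, or `NULL`), and
#'   `significant` (index of the retained module with smallest total error,
#'   or `NA`).
#' @export
extract_modules <- function(model, nets = NULL, threshold = 1, min_size = 5) {
  zs1 <- zscore_membership(model$G1, threshold)
  zs2 <- zscore_membership(model$G2, threshold)
  k <- ncol(model$G1)
  roi_lab <- if (!is.null(rownames(model$G1))) rownames(model$G1)
             else paste0("ROI_", seq_len(nrow(model$G1)))
  gene_lab <- if (!is.null(rownames(model$G2))) rownames(model$G2)
              else paste0("gene_", seq_len(nrow(model$G2)))
  roi_members <- lapply(seq_len(k), function(j) roi_lab[zs1$membership[, j]])
  gene_members <- lapply(seq_len(k), function(j) gene_lab[zs2$membership[, j]])
  retained <- filter_modules(zs1$membership, zs2$membership, min_size)

  module_errors <- NULL
  significant <- NA_integer_
  if (!is.null(nets) && any(retained)) {
    module_errors <- matrix(NA_real_, k, 4,
                            dimnames = list(NULL, c("roi", "gene", "cross", "total")))
    for (j in which(retained)) {
      module_errors[j, ] <- module_relative_error(
        nets, model, zs1$membership[, j], zs2$membership[, j])
    }
    significant <- which(retained)[which.min(module_errors[retained, "total"])]
  }

  structure(list(k = k, roi_members = roi_members, gene_members = gene_members,
                 z_roi = zs1$z, z_gene = zs2$z,
                 retained = retained, module_errors = module_errors,
                 significant = significant,
                 threshold = threshold, min_size = min_size),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  cat(sprintf("Module set: %d modules, %d retained (>= %d members per side, z > %g)\n",
              x$k, sum(x$retained), x$min_size, x$threshold))
  for (j in seq_len(x$k)) {
    cat(sprintf("  module %d: %d ROIs, %d genes%s%s\n", j,
                length(x$roi_members[[j]]), length(x$gene_members[[j]]),
                if (x$retained[j]) "" else " [dropped]",
                if (!is.na(x$significant) && x$significant == j) " [significant]" else ""))
  }
  invisible(x)
}
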