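#' Thresholded correlation interaction network
#'
#' Builds an undirected simple graph over the rows/columns of a symmetric
#' association (sub)matrix, with an edge wherever the off-diagonal entry
#' strictly exceeds the threshold. Self-loops are never created and each
#' undirected pair appears once.
#'
#' @param R Symmetric non-negative association matrix with labels (e.g. the
#'   `R11` or `R22` submatrix of a significant module).
#' @param threshold Edge inclusion threshold (strict `>`). A threshold at or
#'   above the maximum off-diagonal value yields an edgeless graph with a
#'   warning.
#' @return An object of class `"ranked_network"`: list with `nodes`, `edges`
#'   (data frame `from`, `to`, `weight`), `threshold` and the `igraph`
#'   object `graph`.
#' @export
threshold_network <- function(R, threshold) {
  R <- as.matrix(R)
  if (nrow(R) != ncol(R)) stop("'R' must be square")
  if (max(abs(R - t(R))) > 1e-8) stop("'R' must be symmetric")
  labels <- rownames(R)
  if (is.null(labels)) labels <- paste0("V", seq_len(nrow(R)))

  idx <- which(upper.tri(R) & R > threshold, arr.ind = TRUE)
  edges <- data.frame(from = labels[idx[, 1]], to = labels[idx[, 2]],
                      weight = R[idx], stringsAsFactors = FALSE)
  if (nrow(edges) == 0 && threshold >= 1)
    warning("threshold >= 1 on a correlation matrix yields an empty graph")

  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = labels))
  structure(list(nodes = labels, edges = edges, threshold = threshold,
                 graph = g),
            class = "ranked_network")
}

#' Maximal clique centrality (MCC) hub scores
#'
#' Scores every node by \eqn{\mathrm{MCC}(v) = \sum_{C \in M(v)} (|C|-1)!}
#' where \eqn{M(v)} is the set of maximal cliques containing \eqn{v}. A node
#' whose maximal cliques are all single edges scores its degree (each edge
#' contributes \eqn{(2-1)! = 1}); an isolated node scores 0. Nodes are
#' ranked by score descending, ties broken lexicographically by label.
#'
#' Maximal cliques are enumerated with the pivoting Bron–Kerbosch algorithm
#' (via \pkg{igraph}), practical for module-sized graphs.
#'
#' @param network A `"ranked_network"` object (from [threshold_network()])
#'   or an `igraph` graph.
#' @param top Number of top-ranked nodes to report (default 10).
#' @return List with `scores` (named numeric vector in input node order),
#'   `ranking` (data frame `node`, `score` sorted by the ranking rule) and
#'   `top` (character vector of the `top` highest-ranked labels).
#' @examples
#' R <- matrix(c(1, .95, .91, .95, 1, .85, .91, .85, 1), 3, 3,
#'             dimnames = list(letters[1:3], letters[1:3]))
#' net <- threshold_network(R, 0.9)
#' mcc_hub_scores(net)$scores
#' @export
mcc_hub_scores <- function(network, top = 10) {
  g <- if (inherits(network, "ranked_network")) network$graph
       else if (igraph::is_igraph(network)) network
       else stop("'network' must be a ranked_network or igraph object")
  labels <- igraph::V(g)$name
  if (is.null(labels)) labels <- as.character(seq_len(igraph::vcount(g)))
  scores <- stats::setNames(numeric(length(labels)), labels)
  cliques <- igraph::max_cliques(g, min = 2)
  for (cl in cliques) {
    members <- labels[as.integer(cl)]
    scores[members] <- scores[members] + factorial(length(cl) - 1L)
  }
  ranking <- data.frame(node = labels, score = unname(scores),
                        stringsAsFactors = FALSE)
  ranking <- ranking[order(-ranking$score, ranking$node), ]
  rownames(ranking) <- NULL
  list(scores = scores, ranking = ranking,
       top = head(ranking$node, top))
}

#' @export
print.ranked_network <- function(x, ...) {
  cat(sprintf("Thresholded network (> %g): %d nodes, %d edges\n",
              x$threshold, length(x$nodes), nrow(x$edges)))
  invisible(x)
}
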