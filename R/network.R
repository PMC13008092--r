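#' Weighted psychometric network
#'
#' The estimated partial-association network: a symmetric signed p x p
#' edge-weight matrix with zero diagonal, plus per-node construct/measure
#' metadata. Forbidden (skip-logic) pairs always carry weight exactly 0.
#'
#' @param weights Symmetric numeric matrix, zero diagonal.
#' @param node_metadata Data.frame with `label`, `construct`, `measure`.
#' @return An object of class `weighted_network`.
#' @export
weighted_network <- function(weights, node_metadata) {
  weights <- as.matrix(weights)
  p <- nrow(weights)
  stopifnot(ncol(weights) == p, is.data.frame(node_metadata),
            nrow(node_metadata) == p)
  if (any(!is.finite(weights)))
    stop("weighted_network: non-finite weights", call. = FALSE)
  if (max(abs(weights - t(weights))) > 1e-10)
    stop("weighted_network: weights must be symmetric", call. = FALSE)
  if (any(diag(weights) != 0))
    stop("weighted_network: diagonal must be zero", call. = FALSE)
  dimnames(weights) <- list(node_metadata$label, node_metadata$label)
  structure(list(weights = weights, node_metadata = node_metadata),
            class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  p <- nrow(x$weights)
  ut <- x$weights[upper.tri(x$weights)]
  cat("Weighted network: ", p, " nodes, ", sum(ut != 0), " edges (",
      sum(ut > 0), " positive, ", sum(ut < 0), " negative)\n", sep = "")
  invisible(x)
}

#' Edge list of a weighted network
#'
#' @param network A [weighted_network()].
#' @return Data.frame `node_a`, `node_b`, `weight` (nonzero edges,
#'   `node_a` before `node_b` in node order).
#' @export
network_edges <- function(network) {
  stopifnot(inherits(network, "weighted_network"))
  w <- network$weights
  idx <- which(upper.tri(w) & w != 0, arr.ind = TRUE)
  data.frame(node_a = rownames(w)[idx[, 1]],
             node_b = colnames(w)[idx[, 2]],
             weight = w[idx],
             stringsAsFactors = FALSE)
}

#' Convert a weighted network to an igraph graph
#'
#' Edges carry the signed `weight` attribute and its absolute value
#' `abs_weight`; vertices carry `construct` and `measure`.
#'
#' @param network A [weighted_network()].
#' @return An `igraph` graph.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "weighted_network"))
  # isolated vertices are kept: the adjacency matrix fixes the vertex set
  g <- igraph::graph_from_adjacency_matrix(network$weights,
                                           mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::V(g)$construct <- network$node_metadata$construct
  igraph::V(g)$measure <- network$node_metadata$measure
  if (igraph::ecount(g) > 0)
    igraph::E(g)$abs_weight <- abs(igraph::E(g)$weight)
  g
}

#' Write a network as CSV edge list and GraphML
#'
#' @param network A [weighted_network()].
#' @param csv_path,graphml_path Output paths (`NULL` to skip either).
#' @param community Optional [spinglass_partition()] result; community ids
#'   are added as a GraphML vertex attribute.
#' @return Invisibly, the paths written.
#' @export
write_network <- function(network, csv_path = NULL, graphml_path = NULL,
                          community = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(network_edges(network), csv_path, row.names = FALSE)
  if (!is.null(graphml_path)) {
    g <- as_igraph(network)
    if (!is.null(community))
      igraph::V(g)$community <- unname(
        community$assignment[igraph::V(g)$name])
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(c(csv_path, graphml_path))
}
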