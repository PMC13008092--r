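#' Node strength
#'
#' Strength of node i is the sum of the weights of its incident edges,
#' \eqn{s_i = \sum_j |w_{ij}|} under the default absolute-value convention
#' (signed networks; set `signed = TRUE` to sum raw signed weights).
#'
#' @param network A [weighted_network()].
#' @param signed Sum signed weights instead of absolute values.
#' @return Named numeric vector.
#' @export
node_strength <- function(network, signed = FALSE) {
  stopifnot(inherits(network, "weighted_network"))
  w <- if (signed) network$weights else abs(network$weights)
  rowSums(w)
}

#' Betweenness centrality
#'
#' Fraction of all-pairs shortest paths passing through each node, with
#' edge lengths 1/|w| (strong associations are short), computed by
#' Brandes' algorithm with fractional credit for tied shortest paths, and
#' normalized by (p-1)(p-2)/2 so values lie in \[0, 1\]. Disconnected
#' pairs contribute nothing; isolated nodes score 0.
#'
#' @param network A [weighted_network()].
#' @return Named numeric vector in \[0, 1\].
#' @export
node_betweenness <- function(network) {
  stopifnot(inherits(network, "weighted_network"))
  p <- nrow(network$weights)
  g <- as_igraph(network)
  if (igraph::ecount(g) == 0 || p < 3)
    return(stats::setNames(rep(0, p), network$node_metadata$label))
  b <- igraph::betweenness(g, weights = 1 / igraph::E(g)$abs_weight,
                           directed = FALSE, normalized = TRUE)
  stats::setNames(as.numeric(b), igraph::V(g)$name)
}

#' Categorical assortativity by a node attribute
#'
#' Newman's attribute assortativity computed on absolute edge-weight mass:
#' with mixing matrix e (fraction of total |w| mass connecting each pair of
#' categories) and marginals \eqn{a_g = \sum_h e_{gh}},
#' \deqn{r = \frac{\sum_g e_{gg} - \sum_g a_g^2}{1 - \sum_g a_g^2}.}
#' r = 1 when all edge mass stays within categories; negative values
#' indicate disassortative mixing. Invariant to global rescaling of the
#' weights.
#'
#' @param network A [weighted_network()].
#' @param attribute Either the name of a node-metadata column
#'   (`"construct"` or `"measure"`) or a vector of per-node labels.
#' @return List of class `assortativity_result`: `attribute`, `r`,
#'   `mixing` (category x category matrix summing to 1).
#' @export
assortativity_categorical <- function(network, attribute = "construct") {
  stopifnot(inherits(network, "weighted_network"))
  labels <- if (length(attribute) == 1 &&
                attribute %in% names(network$node_metadata)) {
    att_name <- attribute
    network$node_metadata[[attribute]]
  } else {
    att_name <- "custom"
    stopifnot(length(attribute) == nrow(network$weights))
    attribute
  }
  if (anyNA(labels)) stop("assortativity: unlabeled node", call. = FALSE)
  w <- abs(network$weights)
  total <- sum(w)
  if (total == 0)
    stop("assortativity undefined: network has no edges", call. = FALSE)
  cats <- sort(unique(labels))
  f <- factor(labels, levels = cats)
  # aggregate |w| mass over ordered category pairs; each undirected edge
  # contributes half its mass in each direction, making e symmetric
  m <- rowsum(w, f)
  e <- t(rowsum(t(m), f)) / total
  a <- rowSums(e)
  saa <- sum(a * a)
  r <- if (abs(1 - saa) < 1e-15) 1 else (sum(diag(e)) - saa) / (1 - saa)
  structure(list(attribute = att_name, r = as.numeric(r), mixing = e),
            class = "assortativity_result")
}

#' @export
print.assortativity_result <- function(x, ...) {
  cat("Assortativity by ", x$attribute, ": r = ", round(x$r, 4), "\n",
      sep = "")
  invisible(x)
}

#' Centrality table
#'
#' @param network A [weighted_network()].
#' @return Data.frame: `node`, `construct`, `measure`, `strength`,
#'   `betweenness`.
#' @export
centrality_table <- function(network) {
  stopifnot(inherits(network, "weighted_network"))
  data.frame(node = network$node_metadata$label,
             construct = network$node_metadata$construct,
             measure = network$node_metadata$measure,
             strength = as.numeric(node_strength(network)),
             betweenness = as.numeric(node_betweenness(network)),
             stringsAsFactors = FALSE)
}
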