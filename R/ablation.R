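#' Node-ablation test
#'
#' Quantifies a node's bridging role: the node's column is removed from the
#' data (not merely from the graph), the network is re-estimated, and the
#' construct (or other attribute) assortativity of the ablated network is
#' compared to the original's. Ablating a true bridge decouples the two
#' constructs and so increases assortativity.
#'
#' @param dataset A [binary_indicator_dataset()] with at least 4 nodes.
#' @param node Label of the node to ablate.
#' @param config An [estimation_config()].
#' @param attribute Node-metadata column for assortativity (default
#'   `"construct"`).
#' @param original_network Optional pre-estimated network for `dataset`
#'   (avoids refitting in batch runs); must come from the same config.
#' @return List of class `ablation_result`: `node`, `original` and
#'   `ablated` assortativity, `difference` (ablated - original), and both
#'   networks.
#' @export
ablate_and_compare <- function(dataset, node, config = estimation_config(),
                               attribute = "construct",
                               original_network = NULL) {
  if (is.null(original_network))
    original_network <- estimate_network(dataset, config)
  r0 <- assortativity_categorical(original_network, attribute)$r
  reduced <- drop_node(dataset, node)
  ablated_network <- estimate_network(reduced, config)
  r1 <- tryCatch(assortativity_categorical(ablated_network, attribute)$r,
                 error = function(e)
                   stop("ablate_and_compare: assortativity undefined after ",
                        "removing '", node, "': ", conditionMessage(e),
                        call. = FALSE))
  structure(list(node = node, original = r0, ablated = r1,
                 difference = r1 - r0,
                 original_network = original_network,
                 ablated_network = ablated_network),
            class = "ablation_result")
}

#' @export
print.ablation_result <- function(x, ...) {
  cat("Ablation of '", x$node, "': assortativity ",
      round(x$original, 4), " -> ", round(x$ablated, 4),
      " (difference ", round(x$difference, 4), ")\n", sep = "")
  invisible(x)
}

#' Ablate the top-k betweenness nodes in turn
#'
#' @param dataset A [binary_indicator_dataset()].
#' @param k Number of highest-betweenness nodes to ablate (each separately).
#' @param config An [estimation_config()].
#' @param attribute Assortativity attribute.
#' @return Data.frame: `node`, `betweenness`, `original`, `ablated`,
#'   `difference`; the shared original network as attribute `"network"`.
#' @export
ablate_top_betweenness <- function(dataset, k = 3,
                                   config = estimation_config(),
                                   attribute = "construct") {
  net <- estimate_network(dataset, config)
  btw <- node_betweenness(net)
  targets <- names(sort(btw, decreasing = TRUE))[seq_len(min(k, length(btw)))]
  rows <- lapply(targets, function(nd) {
    res <- ablate_and_compare(dataset, nd, config, attribute,
                              original_network = net)
    data.frame(node = nd, betweenness = unname(btw[nd]),
               original = res$original, ablated = res$ablated,
               difference = res$difference, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "network") <- net
  out
}
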