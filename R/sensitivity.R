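#' Stability of the network across the EBIC penalty grid
#'
#' Re-estimates the network at each gamma in the grid (default 0 to 1 in
#' steps of 0.05, the base gamma added if absent) and reports, relative to
#' the base-gamma network: the assortativity difference, the fraction of
#' nodes remaining in the same community (after optimal label matching by
#' maximum-weight bipartite matching on the partition confusion matrix),
#' and the Spearman correlations of strength and of betweenness (all nodes,
#' average-rank ties). A network with no edges at large gamma is flagged
#' degenerate and its comparison metrics reported as `NA`.
#'
#' @param dataset A [binary_indicator_dataset()].
#' @param base_config An [estimation_config()]; its `gamma` is the base.
#' @param gammas Numeric grid in \[0, 1\].
#' @param attribute Assortativity attribute (default `"construct"`).
#' @param community_args Extra arguments passed to
#'   [spinglass_partition()] (the same seed is used at every gamma).
#' @return Data.frame, one row per gamma: `gamma`, `n_edges`,
#'   `assortativity`, `assortativity_diff`, `community_overlap`,
#'   `spearman_strength`, `spearman_betweenness`, `degenerate`, `is_base`.
#' @export
gamma_sweep <- function(dataset, base_config = estimation_config(),
                        gammas = seq(0, 1, by = 0.05),
                        attribute = "construct",
                        community_args = list()) {
  stopifnot(all(gammas >= 0 & gammas <= 1))
  gammas <- sort(unique(c(gammas, base_config$gamma)))
  fit_at <- function(g) {
    cfg <- base_config
    cfg$gamma <- g
    estimate_network(dataset, cfg)
  }
  base_net <- fit_at(base_config$gamma)
  base_assort <- assortativity_categorical(base_net, attribute)$r
  base_strength <- node_strength(base_net)
  base_btw <- node_betweenness(base_net)
  base_part <- do.call(spinglass_partition,
                       c(list(base_net, seed = base_config$seed),
                         community_args))
  rows <- lapply(gammas, function(g) {
    net <- if (g == base_config$gamma) base_net else fit_at(g)
    n_edges <- sum(net$weights[upper.tri(net$weights)] != 0)
    degenerate <- n_edges == 0
    if (degenerate)
      return(data.frame(gamma = g, n_edges = 0, assortativity = NA_real_,
                        assortativity_diff = NA_real_,
                        community_overlap = NA_real_,
                        spearman_strength = NA_real_,
                        spearman_betweenness = NA_real_,
                        degenerate = TRUE,
                        is_base = g == base_config$gamma))
    r <- assortativity_categorical(net, attribute)$r
    part <- do.call(spinglass_partition,
                    c(list(net, seed = base_config$seed), community_args))
    data.frame(
      gamma = g, n_edges = n_edges, assortativity = r,
      assortativity_diff = r - base_assort,
      community_overlap = community_overlap(base_part$assignment,
                                            part$assignment),
      spearman_strength = spearman_safe(base_strength, node_strength(net)),
      spearman_betweenness = spearman_safe(base_btw, node_betweenness(net)),
      degenerate = FALSE, is_base = g == base_config$gamma)
  })
  do.call(rbind, rows)
}

# Spearman correlation with average-rank ties; identical vectors (including
# constant ones, where cor is undefined) count as perfect agreement
spearman_safe <- function(a, b) {
  if (isTRUE(all.equal(as.numeric(a), as.numeric(b)))) return(1)
  suppressWarnings(stats::cor(a, b, method = "spearman"))
}

#' Fraction of nodes remaining in the same community
#'
#' Matches the communities of two partitions by maximum-weight bipartite
#' matching on their confusion matrix, then returns the fraction of nodes
#' whose community maps to its matched counterpart.
#'
#' @param a,b Integer community assignments over the same nodes.
#' @return Fraction in \[0, 1\].
#' @export
community_overlap <- function(a, b) {
  stopifnot(length(a) == length(b))
  conf <- table(a, b)
  na <- nrow(conf)
  nb <- ncol(conf)
  # bipartite graph: rows of conf on one side, columns on the other
  el <- which(conf > 0, arr.ind = TRUE)
  g <- igraph::make_empty_graph(na + nb, directed = FALSE)
  igraph::V(g)$type <- c(rep(FALSE, na), rep(TRUE, nb))
  g <- igraph::add_edges(g, rbind(el[, 1], na + el[, 2]))
  igraph::E(g)$weight <- conf[el]
  mt <- igraph::max_bipartite_match(g, weights = igraph::E(g)$weight)
  matched <- mt$matching[seq_len(na)]
  agree <- 0
  for (i in seq_len(na)) {
    if (!is.na(matched[i]))
      agree <- agree + conf[i, matched[i] - na]
  }
  as.numeric(agree / length(a))
}
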