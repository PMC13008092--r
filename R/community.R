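#' Spin-glass community detection on a signed weighted network
#'
#' Minimizes the signed spin-glass Hamiltonian
#' \deqn{H = -\sum_{i<j}\left[w^+_{ij} - \gamma^+ p^+_{ij}\right]
#'   \delta(c_i, c_j) + \sum_{i<j}\left[w^-_{ij} - \gamma^-
#'   p^-_{ij}\right]\delta(c_i, c_j)}
#' where \eqn{w^\pm} are the positive/negative parts of the weight matrix
#' and \eqn{p^\pm_{ij} = s^\pm_i s^\pm_j / (2 m^\pm)} are configuration-model
#' expectations computed per sign layer, via simulated annealing (Metropolis
#' single-node moves, geometric cooling, multiple restarts keeping the best
#' partition, final greedy descent). Communities therefore hold more
#' positive weight — and less negative weight — internally than expected at
#' random. Disconnected components are partitioned separately (each
#' isolated node forms its own community) and community ids are relabeled
#' canonically by smallest member index. Reproducible under a fixed seed.
#'
#' @param network A [weighted_network()] with at least one edge.
#' @param max_communities Maximum number of communities (spin states) per
#'   connected component.
#' @param gamma_plus,gamma_minus Resolution parameters for the positive and
#'   negative layers.
#' @param seed Integer seed.
#' @param schedule List: `t_start`, `t_stop`, `cool`, `sweeps` (node moves
#'   per temperature = `sweeps * p`), `restarts`.
#' @return An object of class `community_partition`: `assignment` (named
#'   integer vector, ids contiguous from 1), `n_communities`,
#'   `hamiltonian`, and `config` (echo of the tuning used).
#' @export
spinglass_partition <- function(network, max_communities = 10,
                                gamma_plus = 1, gamma_minus = 1, seed = 1,
                                schedule = list(t_start = 1, t_stop = 0.01,
                                                cool = 0.99, sweeps = 50,
                                                restarts = 10)) {
  stopifnot(inherits(network, "weighted_network"), max_communities >= 2)
  w <- network$weights
  p <- nrow(w)
  if (all(w == 0))
    stop("spinglass_partition: network has no edges", call. = FALSE)
  set.seed(seed)
  adj <- w != 0
  comp <- connected_components(adj)
  assignment <- integer(p)
  total_h <- 0
  next_id <- 1L
  for (nodes in comp) {
    if (length(nodes) == 1) {
      assignment[nodes] <- next_id
      next_id <- next_id + 1L
      next
    }
    sub <- w[nodes, nodes, drop = FALSE]
    cost <- spinglass_pair_costs(sub, gamma_plus, gamma_minus)
    q <- min(max_communities, length(nodes))
    res <- .spinglass_anneal(cost, as.integer(q), schedule$t_start,
                             schedule$t_stop, schedule$cool,
                             as.integer(schedule$sweeps * length(nodes)),
                             as.integer(schedule$restarts))
    ids <- match(res$assignment, unique(res$assignment))
    assignment[nodes] <- next_id - 1L + ids
    next_id <- next_id + max(ids)
    total_h <- total_h + res$hamiltonian
  }
  assignment <- canonical_labels(assignment)
  names(assignment) <- network$node_metadata$label
  structure(list(assignment = assignment,
                 n_communities = max(assignment),
                 hamiltonian = total_h,
                 config = list(max_communities = max_communities,
                               gamma_plus = gamma_plus,
                               gamma_minus = gamma_minus, seed = seed,
                               schedule = schedule)),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat("Community partition: ", x$n_communities, " communities, H = ",
      round(x$hamiltonian, 4), "\n", sep = "")
  print(table(community = x$assignment))
  invisible(x)
}

# pair costs such that H(partition) = sum over same-community pairs i<j
spinglass_pair_costs <- function(w, gamma_plus, gamma_minus) {
  wp <- pmax(w, 0)
  wm <- pmax(-w, 0)
  sp <- rowSums(wp)
  sm <- rowSums(wm)
  mp <- sum(sp) / 2
  mm <- sum(sm) / 2
  pp <- if (mp > 0) outer(sp, sp) / (2 * mp) else matrix(0, nrow(w), nrow(w))
  pm <- if (mm > 0) outer(sm, sm) / (2 * mm) else matrix(0, nrow(w), nrow(w))
  cost <- -(wp - gamma_plus * pp) + (wm - gamma_minus * pm)
  diag(cost) <- 0
  cost
}

#' Hamiltonian of an arbitrary partition
#'
#' Evaluates the signed spin-glass objective for a given assignment;
#' useful for comparing partitions.
#'
#' @param network A [weighted_network()].
#' @param assignment Integer vector of community ids (full network order).
#' @param gamma_plus,gamma_minus Resolution parameters.
#' @return The Hamiltonian (sum over connected components, each with its
#'   own configuration-model expectation).
#' @export
partition_hamiltonian <- function(network, assignment, gamma_plus = 1,
                                  gamma_minus = 1) {
  stopifnot(inherits(network, "weighted_network"),
            length(assignment) == nrow(network$weights))
  w <- network$weights
  comp <- connected_components(w != 0)
  total <- 0
  for (nodes in comp) {
    if (length(nodes) < 2) next
    cost <- spinglass_pair_costs(w[nodes, nodes, drop = FALSE],
                                 gamma_plus, gamma_minus)
    a <- assignment[nodes]
    same <- outer(a, a, "==")
    total <- total + sum(cost[upper.tri(cost) & same])
  }
  total
}

# connected components of a logical adjacency matrix; returns list of
# integer index vectors
connected_components <- function(adj) {
  p <- nrow(adj)
  seen <- rep(FALSE, p)
  out <- list()
  for (s in seq_len(p)) {
    if (seen[s]) next
    queue <- s
    seen[s] <- TRUE
    members <- integer(0)
    while (length(queue) > 0) {
      v <- queue[[1]]
      queue <- queue[-1]
      members <- c(members, v)
      nb <- which(adj[v, ] & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    out[[length(out) + 1]] <- sort(members)
  }
  out
}

# relabel community ids contiguously in order of each community's smallest
# member index
canonical_labels <- function(assignment) {
  first <- tapply(seq_along(assignment), assignment, min)
  ord <- rank(first)
  as.integer(ord[as.character(assignment)])
}
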