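# Independent brute-force oracles used to validate the package's graph
# algorithms at small sizes. These are written from the definitions and do
# not call the implementation under test.

# exact Ising state probabilities by direct summation over all 2^p states
oracle_state_probs <- function(tau, omega) {
  p <- length(tau)
  states <- as.matrix(expand.grid(rep(list(0:1), p)))
  e <- apply(states, 1, function(x)
    sum(tau * x) + sum(omega[upper.tri(omega)] *
                         (outer(x, x)[upper.tri(omega)])))
  w <- exp(e - max(e))
  w / sum(w)
}

# all simple paths between s and t (vectors of vertex sequences)
all_simple_paths_st <- function(adj, s, t) {
  p <- nrow(adj)
  paths <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == t) {
      paths[[length(paths) + 1]] <<- path
      return(invisible())
    }
    for (u in which(adj[v, ])) {
      if (!u %in% path) walk(c(path, u))
    }
  }
  walk(s)
  paths
}

# normalized weighted betweenness by exhaustive shortest-path enumeration;
# edge length 1/|w|, fractional credit for ties, divisor (p-1)(p-2)/2
oracle_betweenness <- function(w) {
  p <- nrow(w)
  adj <- abs(w) > 0
  len <- ifelse(adj, 1 / abs(w), Inf)
  bet <- numeric(p)
  for (s in seq_len(p - 1)) {
    for (t in seq(s + 1, p)) {
      paths <- all_simple_paths_st(adj, s, t)
      if (length(paths) == 0) next
      d <- vapply(paths, function(pp)
        sum(len[cbind(pp[-length(pp)], pp[-1])]), numeric(1))
      dmin <- min(d)
      short <- paths[d <= dmin + 1e-9]
      for (pp in short) {
        inner <- pp[-c(1, length(pp))]
        bet[inner] <- bet[inner] + 1 / length(short)
      }
    }
  }
  bet / ((p - 1) * (p - 2) / 2)
}

# signed spin-glass Hamiltonian written directly from the definition
oracle_hamiltonian <- function(w, assignment, gamma_plus = 1,
                               gamma_minus = 1) {
  p <- nrow(w)
  wp <- pmax(w, 0); wm <- pmax(-w, 0)
  sp <- rowSums(wp); sm <- rowSums(wm)
  mp <- sum(sp) / 2; mm <- sum(sm) / 2
  h <- 0
  for (i in seq_len(p - 1)) {
    for (j in seq(i + 1, p)) {
      if (assignment[i] != assignment[j]) next
      ppij <- if (mp > 0) sp[i] * sp[j] / (2 * mp) else 0
      pmij <- if (mm > 0) sm[i] * sm[j] / (2 * mm) else 0
      h <- h - (wp[i, j] - gamma_plus * ppij) +
        (wm[i, j] - gamma_minus * pmij)
    }
  }
  h
}

# all set partitions of n items as restricted growth strings
all_partitions <- function(n) {
  out <- list()
  grow <- function(prefix, mx) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (v in seq_len(mx + 1)) grow(c(prefix, v), max(mx, v))
  }
  grow(1L, 1L)
  out
}

# minimum Hamiltonian over every partition (exhaustive). The per-pair
# term is assembled once from the definition; each partition then
# contributes the sum over its same-community pairs.
oracle_min_hamiltonian <- function(w, gamma_plus = 1, gamma_minus = 1) {
  p <- nrow(w)
  wp <- pmax(w, 0); wm <- pmax(-w, 0)
  sp <- rowSums(wp); sm <- rowSums(wm)
  mp <- sum(sp) / 2; mm <- sum(sm) / 2
  pp <- if (mp > 0) outer(sp, sp) / (2 * mp) else matrix(0, p, p)
  pm <- if (mm > 0) outer(sm, sm) / (2 * mm) else matrix(0, p, p)
  pair <- -(wp - gamma_plus * pp) + (wm - gamma_minus * pm)
  ut <- upper.tri(pair)
  parts <- all_partitions(p)
  min(vapply(parts, function(a)
    sum(pair[ut & outer(a, a, "==")]), numeric(1)))
}

# exhaustive all-subsets min-EBIC support for one nodewise logistic
# regression (unpenalized refits)
oracle_best_subset <- function(y, x, gamma) {
  pc <- ncol(x)
  n <- length(y)
  best <- NULL
  best_crit <- Inf
  for (mask in 0:(2^pc - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(pc) - 1)) > 0)
    fit <- if (length(sel) == 0) glm(y ~ 1, family = binomial())
    else glm(y ~ x[, sel, drop = FALSE], family = binomial())
    ll <- as.numeric(logLik(fit))
    crit <- -2 * ll + length(sel) * log(n) +
      2 * gamma * length(sel) * log(pc)
    if (crit < best_crit - 1e-9) {
      best_crit <- crit
      best <- sel
    }
  }
  sort(best)
}
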