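#' Ising model parameters
#'
#' Container for the parameters of a pairwise binary Markov random field
#' (Ising model in 0/1 coding): per-node thresholds \eqn{\tau_i} and a
#' symmetric coupling matrix \eqn{\Omega} with zero diagonal, both on the
#' log-odds scale. The joint distribution is
#' \deqn{P(x) \propto \exp\left(\sum_i \tau_i x_i +
#'   \sum_{i<j} \Omega_{ij} x_i x_j\right).}
#' The same object serves as the simulator's ground truth and as the
#' estimand of the network-estimation routines.
#'
#' @param thresholds Numeric vector of node intercepts (log-odds scale).
#' @param couplings Symmetric numeric matrix with zero diagonal; entry
#'   `[i, j]` is the pairwise interaction weight between nodes i and j.
#' @param labels Optional character vector of node labels; defaults to the
#'   names of `thresholds`, the dimnames of `couplings`, or `V1..Vp`.
#' @return An object of class `ising_parameters`.
#' @export
ising_parameters <- function(thresholds, couplings, labels = NULL) {
  thresholds <- as.numeric(thresholds)
  couplings <- as.matrix(couplings)
  p <- length(thresholds)
  if (p < 2) stop("ising_parameters: need at least 2 nodes", call. = FALSE)
  if (!all(dim(couplings) == c(p, p)))
    stop("ising_parameters: couplings must be ", p, "x", p, call. = FALSE)
  if (any(!is.finite(thresholds)) || any(!is.finite(couplings)))
    stop("ising_parameters: non-finite parameter values", call. = FALSE)
  if (max(abs(couplings - t(couplings))) > 1e-12)
    stop("ising_parameters: couplings must be symmetric", call. = FALSE)
  if (any(diag(couplings) != 0))
    stop("ising_parameters: couplings must have zero diagonal", call. = FALSE)
  if (is.null(labels)) {
    labels <- if (!is.null(rownames(couplings))) rownames(couplings)
    else paste0("V", seq_len(p))
  }
  dimnames(couplings) <- list(labels, labels)
  names(thresholds) <- labels
  structure(list(thresholds = thresholds, couplings = couplings),
            class = "ising_parameters")
}

#' @export
print.ising_parameters <- function(x, ...) {
  p <- length(x$thresholds)
  nz <- sum(x$couplings[upper.tri(x$couplings)] != 0)
  cat("Ising parameters: ", p, " nodes, ", nz, " nonzero couplings\n",
      sep = "")
  cat("  thresholds in [", round(min(x$thresholds), 3), ", ",
      round(max(x$thresholds), 3), "]\n", sep = "")
  invisible(x)
}

n_nodes <- function(params) length(params$thresholds)
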