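#' Sample binary data from an Ising model
#'
#' Draws n rows from \eqn{P(x) \propto \exp(\sum_i \tau_i x_i + \sum_{i<j}
#' \Omega_{ij} x_i x_j)} by single-chain Gibbs sampling: `burn_in` full
#' sweeps are discarded, then each recorded row is separated from the
#' previous one by `thinning` sweeps. When covariate effects are supplied,
#' each respondent's draw is taken under their own covariate-shifted
#' threshold vector. After sampling, skip-logic is enforced
#' deterministically (parent = 1 forces child = 0) and survey weights are
#' drawn lognormal, normalized to mean 1.
#'
#' @param params An [ising_parameters()] object.
#' @param n Number of respondents.
#' @param covariate_effects Optional list with elements `covariates` (an
#'   n-row data.frame of factors) and `shifts` (a named list, one p x
#'   n_levels matrix per covariate, added to the thresholds of respondents
#'   at each level).
#' @param seed Integer seed.
#' @param burn_in Discarded initial sweeps (default 1000).
#' @param thinning Sweeps between recorded rows (default 10).
#' @param node_metadata Optional node metadata; defaults to generic labels
#'   with a single construct.
#' @param skip_pairs List of `(parent, child)` label pairs to enforce; each
#'   becomes a forbidden pair of the returned dataset.
#' @param weight_spec `list(meanlog =, sdlog =)` for lognormal survey
#'   weights; `NULL` gives uniform weights.
#' @return A [binary_indicator_dataset()].
#' @export
sample_ising <- function(params, n, covariate_effects = NULL, seed = 1,
                         burn_in = 1000, thinning = 10,
                         node_metadata = NULL, skip_pairs = list(),
                         weight_spec = NULL) {
  stopifnot(inherits(params, "ising_parameters"), n >= 1, burn_in >= 0,
            thinning >= 1)
  p <- n_nodes(params)
  labels <- names(params$thresholds)
  if (is.null(node_metadata))
    node_metadata <- data.frame(label = labels, construct = "A",
                                measure = "subjective",
                                stringsAsFactors = FALSE)
  set.seed(seed)
  tau <- matrix(rep(params$thresholds, each = n), nrow = n)
  covs <- NULL
  if (!is.null(covariate_effects)) {
    covs <- as.data.frame(covariate_effects$covariates)
    stopifnot(nrow(covs) == n)
    for (nm in names(covariate_effects$shifts)) {
      sh <- covariate_effects$shifts[[nm]]  # p x n_levels
      lev <- as.integer(factor(covs[[nm]]))
      tau <- tau + t(sh[, lev, drop = FALSE])
    }
  }
  x <- .gibbs_sample(tau, params$couplings, as.integer(burn_in),
                     as.integer(thinning))
  colnames(x) <- labels
  for (sp in skip_pairs) {
    parent <- sp[1]; child <- sp[2]
    x[x[, parent] == 1L, child] <- 0L
  }
  weights <- if (is.null(weight_spec)) rep(1, n) else {
    w <- stats::rlnorm(n, weight_spec$meanlog, weight_spec$sdlog)
    w / mean(w)
  }
  binary_indicator_dataset(x, node_metadata, covariates = covs,
                           survey_weights = weights,
                           forbidden_pairs = skip_pairs)
}

#' Simulate a complete planted-structure dataset
#'
#' Convenience wrapper: draws ground-truth parameters from the design,
#' draws respondent covariates, Gibbs-samples the indicator matrix under
#' covariate-shifted thresholds, enforces skip logic, and attaches survey
#' weights. The ground truth is attached as attribute `"ground_truth"`.
#'
#' @param design A [planted_design()].
#' @param n Number of respondents.
#' @param seed Integer seed controlling parameters, covariates, sampling
#'   and weights.
#' @param burn_in,thinning Gibbs controls, see [sample_ising()].
#' @return A [binary_indicator_dataset()] with attribute `"ground_truth"`.
#' @export
simulate_dataset <- function(design, n, seed = 1, burn_in = 1000,
                             thinning = 10) {
  stopifnot(inherits(design, "planted_design"))
  params <- build_planted_parameters(design, seed = seed)
  covariate_effects <- NULL
  if (length(design$covariate_spec) > 0) {
    set.seed(seed + 1L)
    p <- nrow(design$node_metadata)
    covs <- list()
    shifts <- list()
    for (nm in names(design$covariate_spec)) {
      cs <- design$covariate_spec[[nm]]
      probs <- if (is.null(cs$probs)) rep(1 / cs$n_levels, cs$n_levels)
      else cs$probs
      covs[[nm]] <- factor(sample.int(cs$n_levels, n, replace = TRUE,
                                      prob = probs))
      sh <- cs$shifts
      if (is.null(sh)) sh <- matrix(0, p, cs$n_levels)
      if (is.null(dim(sh)))  # vector: same shift for all non-reference levels
        sh <- cbind(0, matrix(rep(sh, cs$n_levels - 1), nrow = p))
      stopifnot(nrow(sh) == p, ncol(sh) == cs$n_levels)
      shifts[[nm]] <- sh
    }
    covariate_effects <- list(covariates = as.data.frame(covs),
                              shifts = shifts)
  }
  ds <- sample_ising(params, n, covariate_effects = covariate_effects,
                     seed = seed + 2L, burn_in = burn_in,
                     thinning = thinning,
                     node_metadata = design$node_metadata,
                     skip_pairs = design$skip_pairs,
                     weight_spec = design$weight_spec)
  attr(ds, "ground_truth") <- params
  ds
}

#' Exact Ising state probabilities by enumeration
#'
#' Brute-force partition-function evaluation over all 2^p states; intended
#' for validating the Gibbs sampler at small p.
#'
#' @param params An [ising_parameters()] with p <= 20.
#' @return A data.frame with one row per state: the p indicator columns and
#'   `prob`.
#' @export
ising_state_probabilities <- function(params) {
  stopifnot(inherits(params, "ising_parameters"))
  p <- n_nodes(params)
  if (p > 20) stop("enumeration limited to p <= 20", call. = FALSE)
  states <- as.matrix(expand.grid(rep(list(0:1), p)))
  colnames(states) <- names(params$thresholds)
  loge <- states %*% params$thresholds +
    rowSums((states %*% params$couplings) * states) / 2
  pr <- exp(loge - max(loge))
  out <- as.data.frame(states)
  out$prob <- as.numeric(pr / sum(pr))
  out
}
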