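#' Bonferroni adjustment
#'
#' @param p_values Numeric vector of raw p-values in \[0, 1\].
#' @param m Family size (>= number of p-values; default that number).
#' @return Adjusted p-values `pmin(1, m * p)`.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("bonferroni: p-values must lie in [0, 1]", call. = FALSE)
  if (m < length(p_values))
    stop("bonferroni: m must be at least the number of p-values",
         call. = FALSE)
  pmin(1, m * p_values)
}

# add-one one-tailed p-value: share of replicates contradicting the
# alternative; never 0, minimum 1/(B+1)
add_one_p <- function(n_contradicting, B) (1 + n_contradicting) / (B + 1)

#' Survey-weighted bootstrap inference for network statistics
#'
#' Each replicate resamples n respondents with replacement with selection
#' probability proportional to survey weight (with uniform weights this is
#' the ordinary bootstrap), re-estimates the network, and recomputes the
#' requested statistics — assortativity by each requested attribute,
#' strength and betweenness per node — along with, optionally, the paired
#' comparisons: a configuration-model reference network (is observed
#' centrality higher than the null's?) and ablated networks for given
#' nodes (is original assortativity lower than the ablated one's?).
#' Because the resampling weights already carry the survey design, the
#' within-replicate estimation is unweighted. Percentile confidence
#' intervals are formed at the Bonferroni-adjusted level
#' `1 - 0.05 / m`, and one-tailed p-values use the add-one estimator
#' `(1 + #contradicting replicates) / (B + 1)`, then Bonferroni adjustment
#' with family size `m`.
#'
#' @param dataset A [binary_indicator_dataset()].
#' @param config An [estimation_config()]; within replicates
#'   `use_survey_weights` is turned off (the resampling performs the
#'   weighting).
#' @param metric_spec List: `assortativity` (character vector of
#'   attributes, default construct + measure), `strength`, `betweenness`
#'   (logical).
#' @param B Number of bootstrap replicates (default 10000; scale down for
#'   exploratory runs).
#' @param seed Integer seed.
#' @param compare Character subset of `c("null", "ablate")`.
#' @param ablate_nodes Node labels to ablate per replicate (required when
#'   `"ablate"` requested).
#' @param m Bonferroni family size; default = number of tested
#'   comparisons.
#' @param max_failure_rate Abort if more than this fraction of replicates
#'   fails (default 0.05); failed replicates are dropped and counted.
#' @return An object of class `inference_report`: `estimates` (per-metric
#'   observed value, bootstrap mean, percentile CI), `tests` (per
#'   comparison: observed difference, raw and adjusted one-tailed p),
#'   `replicates` (matrix of per-replicate metric values), `B_effective`,
#'   `n_failed`, `m`, `seed`.
#' @export
bootstrap_pipeline <- function(dataset, config = estimation_config(),
                               metric_spec = list(
                                 assortativity = c("construct", "measure"),
                                 strength = TRUE, betweenness = TRUE),
                               B = 10000, seed = 1,
                               compare = character(0),
                               ablate_nodes = character(0),
                               m = NULL, max_failure_rate = 0.05) {
  stopifnot(inherits(dataset, "binary_indicator_dataset"), B >= 1)
  if (length(compare) > 0)
    compare <- match.arg(compare, c("null", "ablate"), several.ok = TRUE)
  if ("ablate" %in% compare && length(ablate_nodes) == 0)
    stop("bootstrap_pipeline: 'ablate' comparison needs ablate_nodes",
         call. = FALSE)
  labels <- dataset$node_metadata$label
  n <- nrow(dataset$values)

  observed_net <- estimate_network(dataset, config)
  replicate_config <- config
  replicate_config$use_survey_weights <- FALSE

  eval_metrics <- function(net, nulls_seed = NULL, ds = NULL,
                           cfg = replicate_config) {
    out <- c()
    for (att in metric_spec$assortativity) {
      r <- tryCatch(assortativity_categorical(net, att)$r,
                    error = function(e) NA_real_)
      out <- c(out, stats::setNames(r, paste0("assortativity_", att)))
    }
    if (isTRUE(metric_spec$strength))
      out <- c(out, stats::setNames(node_strength(net),
                                    paste0("strength_", labels)))
    if (isTRUE(metric_spec$betweenness))
      out <- c(out, stats::setNames(node_betweenness(net),
                                    paste0("betweenness_", labels)))
    if ("null" %in% compare) {
      nb <- configuration_null(net, seed = nulls_seed)
      if (isTRUE(metric_spec$strength))
        out <- c(out, stats::setNames(
          node_strength(net) - node_strength(nb),
          paste0("strength_vs_null_", labels)))
      if (isTRUE(metric_spec$betweenness))
        out <- c(out, stats::setNames(
          node_betweenness(net) - node_betweenness(nb),
          paste0("betweenness_vs_null_", labels)))
    }
    if ("ablate" %in% compare) {
      for (nd in ablate_nodes) {
        for (att in metric_spec$assortativity) {
          d <- tryCatch({
            res <- ablate_and_compare(ds, nd, cfg, att,
                                      original_network = net)
            res$difference
          }, error = function(e) NA_real_)
          out <- c(out, stats::setNames(
            d, paste0("ablation_", att, "_", nd)))
        }
      }
    }
    out
  }

  set.seed(seed)
  prob <- dataset$survey_weights / sum(dataset$survey_weights)
  obs <- eval_metrics(observed_net, nulls_seed = seed, ds = dataset,
                      cfg = config)
  reps <- matrix(NA_real_, B, length(obs),
                 dimnames = list(NULL, names(obs)))
  n_failed <- 0
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE, prob = prob)
    val <- tryCatch({
      ds_b <- resample_dataset(dataset, idx)
      net_b <- estimate_network(ds_b, replicate_config)
      eval_metrics(net_b, nulls_seed = seed + b, ds = ds_b)
    }, error = function(e) NULL)
    if (is.null(val)) n_failed <- n_failed + 1 else reps[b, ] <- val
  }
  if (n_failed > max_failure_rate * B)
    stop("bootstrap_pipeline: ", n_failed, " of ", B,
         " replicates failed (limit ", max_failure_rate * 100, "%)",
         call. = FALSE)
  reps <- reps[!apply(is.na(reps), 1, all), , drop = FALSE]
  B_eff <- nrow(reps)

  is_test <- grepl("_vs_null_|^ablation_", names(obs))
  if (is.null(m)) m <- max(1L, sum(is_test))
  level <- 1 - 0.05 / m
  lo <- (1 - level) / 2
  hi <- 1 - lo

  est <- data.frame(
    metric = names(obs),
    observed = as.numeric(obs),
    boot_mean = colMeans(reps, na.rm = TRUE),
    ci_lower = apply(reps, 2, stats::quantile, probs = lo, na.rm = TRUE,
                     names = FALSE),
    ci_upper = apply(reps, 2, stats::quantile, probs = hi, na.rm = TRUE,
                     names = FALSE),
    stringsAsFactors = FALSE, row.names = NULL)

  tests <- NULL
  if (any(is_test)) {
    tnames <- names(obs)[is_test]
    p_raw <- vapply(tnames, function(nm) {
      v <- reps[, nm]
      v <- v[!is.na(v)]
      # alternative: difference > 0 (centrality above null / assortativity
      # rises under ablation); contradictions are replicates with diff <= 0
      add_one_p(sum(v <= 0), length(v))
    }, numeric(1))
    tests <- data.frame(metric = tnames,
                        observed = as.numeric(obs[is_test]),
                        p_raw = as.numeric(p_raw),
                        p_adjusted = bonferroni(as.numeric(p_raw), m = m),
                        direction = "greater",
                        stringsAsFactors = FALSE, row.names = NULL)
  }

  structure(list(estimates = est, tests = tests, replicates = reps,
                 B = B, B_effective = B_eff, n_failed = n_failed,
                 m = m, level = level, seed = seed,
                 observed_network = observed_net),
            class = "inference_report")
}

#' @export
print.inference_report <- function(x, ...) {
  cat("Bootstrap inference: B =", x$B_effective, "effective replicates",
      if (x$n_failed > 0) paste0("(", x$n_failed, " failed)"), "\n")
  cat("Percentile CIs at level", round(x$level, 5),
      "(Bonferroni m =", x$m, ")\n")
  print(utils::head(x$estimates, 8), row.names = FALSE)
  if (!is.null(x$tests)) {
    cat("One-tailed tests (alternative: difference > 0):\n")
    print(utils::head(x$tests[order(x$tests$p_adjusted), ], 8),
          row.names = FALSE)
  }
  invisible(x)
}
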