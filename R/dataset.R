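#' Respondent-by-indicator binary dataset
#'
#' The analysis-ready container: a complete-case n x p matrix of 0/1
#' indicators, per-node metadata (construct and measure labels), an optional
#' categorical covariate table, strictly positive survey weights, and a set
#' of forbidden (skip-logic) node pairs that estimation must never connect.
#'
#' @param values n x p matrix (or data.frame) with entries in {0, 1}; no
#'   missing values (the analysis is complete-case).
#' @param node_metadata Data.frame with columns `label`, `construct`,
#'   `measure`, one row per column of `values`.
#' @param covariates Optional n-row data.frame of categorical covariates.
#' @param survey_weights Optional numeric vector of positive weights
#'   (default: uniform).
#' @param forbidden_pairs List of length-2 character vectors of node labels
#'   (unordered pairs).
#' @return An object of class `binary_indicator_dataset`.
#' @export
binary_indicator_dataset <- function(values, node_metadata,
                                     covariates = NULL,
                                     survey_weights = NULL,
                                     forbidden_pairs = list()) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  if (anyNA(values))
    stop("binary_indicator_dataset: missing values not allowed ",
         "(complete-case analysis)", call. = FALSE)
  if (!all(values %in% c(0L, 1L)))
    stop("binary_indicator_dataset: values must be 0/1", call. = FALSE)
  stopifnot(is.data.frame(node_metadata),
            all(c("label", "construct", "measure") %in% names(node_metadata)))
  p <- ncol(values)
  n <- nrow(values)
  if (nrow(node_metadata) != p)
    stop("binary_indicator_dataset: node_metadata rows must match columns",
         call. = FALSE)
  colnames(values) <- node_metadata$label
  if (is.null(survey_weights)) survey_weights <- rep(1, n)
  if (length(survey_weights) != n || any(survey_weights <= 0) ||
      anyNA(survey_weights))
    stop("binary_indicator_dataset: weights must be n strictly positive",
         call. = FALSE)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n)
      stop("binary_indicator_dataset: covariates must have n rows",
           call. = FALSE)
    if (anyNA(covariates))
      stop("binary_indicator_dataset: covariates must be complete",
           call. = FALSE)
    covariates[] <- lapply(covariates, function(x) factor(x))
  }
  forbidden_pairs <- lapply(forbidden_pairs, function(fp) {
    fp <- as.character(fp)
    if (length(fp) != 2 || !all(fp %in% node_metadata$label) ||
        fp[1] == fp[2])
      stop("binary_indicator_dataset: forbidden pair must name two ",
           "distinct known nodes", call. = FALSE)
    sort(fp)
  })
  forbidden_pairs <- unique(forbidden_pairs)
  structure(list(values = values, node_metadata = node_metadata,
                 covariates = covariates, survey_weights = survey_weights,
                 forbidden_pairs = forbidden_pairs),
            class = "binary_indicator_dataset")
}

#' @export
print.binary_indicator_dataset <- function(x, ...) {
  cat("Binary indicator dataset: ", nrow(x$values), " respondents x ",
      ncol(x$values), " nodes\n", sep = "")
  tab <- table(x$node_metadata$construct, x$node_metadata$measure)
  print(tab)
  if (!is.null(x$covariates))
    cat("Covariates:", paste(names(x$covariates), collapse = ", "), "\n")
  cat(length(x$forbidden_pairs), "forbidden (skip-logic) pair(s)\n")
  invisible(x)
}

#' Drop one node from a dataset
#'
#' Removes the indicator column, its metadata row, and any forbidden pair
#' referencing it. Used by the ablation test, which removes the node from
#' the data (not merely from the estimated graph) before re-estimation.
#'
#' @param dataset A [binary_indicator_dataset()].
#' @param node Node label.
#' @return The reduced dataset.
#' @export
drop_node <- function(dataset, node) {
  stopifnot(inherits(dataset, "binary_indicator_dataset"))
  labels <- dataset$node_metadata$label
  if (!node %in% labels)
    stop("drop_node: unknown node '", node, "'", call. = FALSE)
  if (ncol(dataset$values) <= 3)
    stop("drop_node: need at least 3 nodes after removal", call. = FALSE)
  keep <- labels != node
  fp <- Filter(function(x) !node %in% x, dataset$forbidden_pairs)
  binary_indicator_dataset(dataset$values[, keep, drop = FALSE],
                           dataset$node_metadata[keep, , drop = FALSE],
                           covariates = dataset$covariates,
                           survey_weights = dataset$survey_weights,
                           forbidden_pairs = fp)
}

#' Resample respondents (used by the weighted bootstrap)
#' @noRd
resample_dataset <- function(dataset, idx) {
  binary_indicator_dataset(
    dataset$values[idx, , drop = FALSE],
    dataset$node_metadata,
    covariates = if (is.null(dataset$covariates)) NULL
    else dataset$covariates[idx, , drop = FALSE],
    survey_weights = dataset$survey_weights[idx],
    forbidden_pairs = dataset$forbidden_pairs)
}

#' Write a dataset bundle to disk
#'
#' Writes `values.csv`, `covariates.csv` (if present), `weights.csv` and
#' `metadata.json` (node metadata, forbidden pairs, and optionally the
#' ground-truth parameters that generated the data) into a directory.
#'
#' @param dataset A [binary_indicator_dataset()].
#' @param dir Output directory (created if needed).
#' @param ground_truth Optional [ising_parameters()] to record.
#' @return `dir`, invisibly.
#' @export
write_dataset_bundle <- function(dataset, dir, ground_truth = NULL) {
  stopifnot(inherits(dataset, "binary_indicator_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(dataset$values),
                   file.path(dir, "values.csv"), row.names = FALSE)
  if (!is.null(dataset$covariates))
    utils::write.csv(dataset$covariates, file.path(dir, "covariates.csv"),
                     row.names = FALSE)
  utils::write.csv(data.frame(weight = dataset$survey_weights),
                   file.path(dir, "weights.csv"), row.names = FALSE)
  meta <- list(node_metadata = dataset$node_metadata,
               forbidden_pairs = dataset$forbidden_pairs)
  if (!is.null(ground_truth))
    meta$ground_truth <- list(thresholds = unname(ground_truth$thresholds),
                              couplings = unname(ground_truth$couplings))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a dataset bundle written by [write_dataset_bundle()]
#'
#' @param dir Directory containing `values.csv`, `weights.csv`,
#'   `metadata.json` and optionally `covariates.csv`.
#' @return A [binary_indicator_dataset()]; if the bundle records ground
#'   truth it is attached as attribute `"ground_truth"`.
#' @export
read_dataset_bundle <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  values <- utils::read.csv(file.path(dir, "values.csv"),
                            check.names = FALSE)
  wfile <- file.path(dir, "weights.csv")
  weights <- if (file.exists(wfile)) utils::read.csv(wfile)$weight else NULL
  cfile <- file.path(dir, "covariates.csv")
  covs <- if (file.exists(cfile)) utils::read.csv(cfile) else NULL
  fp <- meta$forbidden_pairs
  if (is.matrix(fp)) fp <- split(fp, seq_len(nrow(fp)))
  ds <- binary_indicator_dataset(values, as.data.frame(meta$node_metadata),
                                 covariates = covs, survey_weights = weights,
                                 forbidden_pairs = fp)
  if (!is.null(meta$ground_truth)) {
    gt <- ising_parameters(meta$ground_truth$thresholds,
                           meta$ground_truth$couplings,
                           labels = ds$node_metadata$label)
    attr(ds, "ground_truth") <- gt
  }
  ds
}
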