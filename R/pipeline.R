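#' Run the full network analysis from a config file
#'
#' One-command orchestration of the whole pipeline on either a synthetic
#' planted-structure dataset or user-supplied CSV files: network estimation
#' (eLasso), assortativity and centralities, spin-glass communities,
#' configuration-model null comparison, ablation of the top-k betweenness
#' nodes, survey-weighted bootstrap inference, and the gamma sensitivity
#' sweep. Writes a report directory with a JSON summary, CSV tables, a
#' GraphML export, and a log of all effective settings and seeds. Reruns
#' with the same config produce identical output.
#'
#' The config (JSON or YAML, or an equivalent R list) has blocks:
#' \describe{
#'   \item{data}{either `synthetic: {n, seed, design: {...planted_design
#'     arguments...}}` or `files: {dir}` pointing at a
#'     [write_dataset_bundle()] directory.}
#'   \item{estimation}{[estimation_config()] arguments (gamma, rule, ...).}
#'   \item{community}{`max_communities`, `gamma_plus`, `gamma_minus`,
#'     `seed`.}
#'   \item{nulls}{`n_null`, `seed`.}
#'   \item{ablation}{`top_k`, `attribute`.}
#'   \item{inference}{`B`, `seed`, `m` (Bonferroni family size, optional),
#'     `enabled`.}
#'   \item{sweep}{`gammas` or `step`, `enabled`.}
#' }
#'
#' @param config Path to a JSON/YAML config file, or a list.
#' @param out_dir Report directory (created; contents overwritten).
#' @return Invisibly, a list with every computed object plus the summary.
#' @export
run_full_analysis <- function(config, out_dir) {
  cfg <- load_config(config)
  validate_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "log.txt")
  log_lines <- character(0)
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  # --- data ---------------------------------------------------------------
  if (!is.null(cfg$data$synthetic)) {
    syn <- cfg$data$synthetic
    design <- if (is.null(syn$design) || identical(syn$design, "demo"))
      demo_design()
    else do.call(planted_design, resolve_design_args(syn$design))
    say("simulating dataset: n = ", syn$n, ", seed = ", syn$seed)
    dataset <- simulate_dataset(design, n = syn$n, seed = syn$seed)
  } else {
    say("reading dataset bundle from ", cfg$data$files$dir)
    dataset <- tryCatch(read_dataset_bundle(cfg$data$files$dir),
                        error = function(e)
                          stop(psychonet_error("data", conditionMessage(e))))
  }

  # --- estimation ---------------------------------------------------------
  est_args <- cfg$estimation
  if (is.null(est_args)) est_args <- list()
  config_est <- do.call(estimation_config, est_args)
  say("estimating network (gamma = ", config_est$gamma, ", rule = ",
      config_est$rule, ")")
  network <- estimate_network(dataset, config_est)
  say("network: ", nrow(network_edges(network)), " edges over ",
      nrow(network$weights), " nodes")

  # --- metrics ------------------------------------------------------------
  centr <- centrality_table(network)
  assort <- lapply(c("construct", "measure"), function(att)
    assortativity_categorical(network, att))
  names(assort) <- c("construct", "measure")
  say("assortativity: construct = ", round(assort$construct$r, 4),
      ", measure = ", round(assort$measure$r, 4))

  # --- communities --------------------------------------------------------
  comm_args <- cfg$community
  if (is.null(comm_args)) comm_args <- list()
  comm_seed <- comm_args$seed %||% 1L
  part <- spinglass_partition(
    network, max_communities = comm_args$max_communities %||% 10,
    gamma_plus = comm_args$gamma_plus %||% 1,
    gamma_minus = comm_args$gamma_minus %||% 1, seed = comm_seed)
  say("communities: ", part$n_communities, " (H = ",
      round(part$hamiltonian, 4), ")")

  # --- null models --------------------------------------------------------
  n_null <- cfg$nulls$n_null %||% 100
  null_seed <- cfg$nulls$seed %||% 1L
  say("null-model comparison: ", n_null, " configuration networks")
  nulls <- null_centrality_comparison(network, n_null = n_null,
                                      seed = null_seed)

  # --- ablation -----------------------------------------------------------
  top_k <- cfg$ablation$top_k %||% 3
  abl_att <- cfg$ablation$attribute %||% "construct"
  say("ablating top-", top_k, " betweenness nodes")
  ablation <- ablate_top_betweenness(dataset, k = top_k,
                                     config = config_est,
                                     attribute = abl_att)

  # --- bootstrap inference ------------------------------------------------
  inference <- NULL
  if (isTRUE(cfg$inference$enabled %||% TRUE)) {
    B <- cfg$inference$B %||% 10000
    say("bootstrap inference: B = ", B)
    inference <- bootstrap_pipeline(
      dataset, config_est, B = B, seed = cfg$inference$seed %||% 1L,
      compare = c("null", "ablate"),
      ablate_nodes = ablation$node[1],
      m = cfg$inference$m)
  }

  # --- gamma sweep --------------------------------------------------------
  sweep <- NULL
  if (isTRUE(cfg$sweep$enabled %||% TRUE)) {
    gammas <- cfg$sweep$gammas %||%
      seq(0, 1, by = cfg$sweep$step %||% 0.05)
    say("gamma sweep over ", length(gammas), " values")
    sweep <- gamma_sweep(dataset, config_est, gammas = gammas,
                         attribute = abl_att)
  }

  # --- report -------------------------------------------------------------
  write_network(network, csv_path = file.path(out_dir, "network_edges.csv"),
                graphml_path = file.path(out_dir, "network.graphml"),
                community = part)
  utils::write.csv(centr, file.path(out_dir, "centrality.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(node = names(part$assignment),
                              community = as.integer(part$assignment)),
                   file.path(out_dir, "communities.csv"), row.names = FALSE)
  utils::write.csv(nulls$table, file.path(out_dir, "null_comparison.csv"),
                   row.names = FALSE)
  utils::write.csv(ablation, file.path(out_dir, "ablation.csv"),
                   row.names = FALSE)
  if (!is.null(inference)) {
    utils::write.csv(inference$estimates,
                     file.path(out_dir, "inference_estimates.csv"),
                     row.names = FALSE)
    if (!is.null(inference$tests))
      utils::write.csv(inference$tests,
                       file.path(out_dir, "inference_tests.csv"),
                       row.names = FALSE)
  }
  if (!is.null(sweep))
    utils::write.csv(sweep, file.path(out_dir, "gamma_sweep.csv"),
                     row.names = FALSE)

  summary <- list(
    nodes = nrow(network$weights),
    edges = nrow(network_edges(network)),
    node_counts = as.list(table(paste(dataset$node_metadata$construct,
                                      dataset$node_metadata$measure))),
    assortativity = list(construct = assort$construct$r,
                         measure = assort$measure$r),
    n_communities = part$n_communities,
    hamiltonian = part$hamiltonian,
    top_betweenness = centr$node[order(-centr$betweenness)][1:3],
    top_strength = centr$node[order(-centr$strength)][1:3],
    ablation = lapply(seq_len(nrow(ablation)), function(i)
      list(node = ablation$node[i], difference = ablation$difference[i])),
    settings = list(estimation = unclass(config_est),
                    community = part$config, n_null = n_null,
                    null_seed = null_seed,
                    inference = if (!is.null(inference))
                      list(B = inference$B, m = inference$m,
                           seed = inference$seed)))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("report written to ", out_dir)
  writeLines(log_lines, log_path)

  invisible(list(dataset = dataset, network = network, centrality = centr,
                 assortativity = assort, communities = part, nulls = nulls,
                 ablation = ablation, inference = inference, sweep = sweep,
                 summary = summary))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

load_config <- function(config) {
  if (is.list(config)) return(config)
  if (!file.exists(config))
    stop(psychonet_error("config", paste0("config file not found: ",
                                          config)))
  if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
  else jsonlite::read_json(config, simplifyVector = TRUE)
}

psychonet_error <- function(kind, messages) {
  structure(class = c(paste0("psychonet_", kind, "_error"), "error",
                      "condition"),
            list(message = paste(messages, collapse = "\n"), call = NULL))
}

# field-by-field schema check; collects all problems before failing
validate_config <- function(cfg) {
  problems <- character(0)
  need <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  need(is.list(cfg), "config must be a list / JSON object")
  if (!is.list(cfg)) stop(psychonet_error("config", problems))
  need(!is.null(cfg$data), "data: block required")
  if (!is.null(cfg$data)) {
    has_syn <- !is.null(cfg$data$synthetic)
    has_files <- !is.null(cfg$data$files)
    need(has_syn || has_files,
         "data: either 'synthetic' or 'files' required")
    if (has_syn) {
      need(!is.null(cfg$data$synthetic$n) && cfg$data$synthetic$n >= 10,
           "data.synthetic.n: integer >= 10 required")
      need(!is.null(cfg$data$synthetic$seed),
           "data.synthetic.seed: required")
    }
    if (has_files)
      need(!is.null(cfg$data$files$dir),
           "data.files.dir: path required")
  }
  g <- cfg$estimation$gamma
  if (!is.null(g)) need(g >= 0 && g <= 1,
                        "estimation.gamma: must lie in [0, 1]")
  r <- cfg$estimation$rule
  if (!is.null(r)) need(r %in% c("and", "or"),
                        "estimation.rule: 'and' or 'or'")
  B <- cfg$inference$B
  if (!is.null(B)) need(B >= 1, "inference.B: must be >= 1")
  nn <- cfg$nulls$n_null
  if (!is.null(nn)) need(nn >= 1, "nulls.n_null: must be >= 1")
  if (length(problems) > 0) stop(psychonet_error("config", problems))
  invisible(TRUE)
}

# JSON-parsed design blocks arrive with lists where planted_design expects
# vectors/data.frames; coerce the common cases
resolve_design_args <- function(design) {
  if (is.null(design)) return(list())
  if (!is.null(design$node_metadata))
    design$node_metadata <- as.data.frame(design$node_metadata)
  for (fld in c("bridge_pairs", "skip_pairs"))
    if (!is.null(design[[fld]]) && !is.list(design[[fld]]))
      design[[fld]] <- apply(design[[fld]], 1, c, simplify = FALSE)
  if (!is.null(design$weight_spec))
    design$weight_spec <- as.list(design$weight_spec)
  design
}
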