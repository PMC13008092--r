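#' Node layout of the two-construct survey instrument
#'
#' Node metadata emulating a 34-indicator instrument measuring two constructs
#' with a mix of objective and subjective items: 14 physical-functioning
#' nodes (2 objective performance tests, 12 subjective difficulty items) and
#' 20 social-connection nodes (9 objective, 11 subjective).
#'
#' @return A data.frame with columns `label`, `construct`
#'   (`physical_functioning` / `social_connection`) and `measure`
#'   (`objective` / `subjective`).
#' @export
survey_layout <- function() {
  pf_obj <- c("low_grip_strength", "incomplete_balance_tests")
  pf_sub <- c("diff_bathing", "diff_dressing", "diff_walking", "diff_bed",
              "diff_toilet", "diff_eating", "diff_map", "diff_phone",
              "diff_money", "diff_shopping", "diff_medication", "diff_meals")
  sc_obj <- c("no_spouse", "no_children", "no_family", "no_friends",
              "low_contact_spouse", "low_contact_children",
              "low_contact_family", "low_contact_friends",
              "infreq_participation")
  sc_sub <- c("lack_companionship", "feel_left_out", "feel_isolated",
              "feel_alone", "not_in_tune", "no_one_to_turn_to",
              "not_understood", "not_close_to_anyone", "not_part_of_group",
              "no_common_interests", "not_close_spouse")
  data.frame(
    label = c(pf_obj, pf_sub, sc_obj, sc_sub),
    construct = rep(c("physical_functioning", "social_connection"),
                    c(length(pf_obj) + length(pf_sub),
                      length(sc_obj) + length(sc_sub))),
    measure = c(rep("objective", length(pf_obj)),
                rep("subjective", length(pf_sub)),
                rep("objective", length(sc_obj)),
                rep("subjective", length(sc_sub))),
    stringsAsFactors = FALSE
  )
}

#' Planted-structure design for the Ising simulator
#'
#' Describes the ground-truth structure a synthetic dataset should carry:
#' two construct blocks that are densely coupled within and sparsely coupled
#' between, designated bridge pairs crossing the constructs, categorical
#' covariates that shift node thresholds, deterministic skip-logic pairs,
#' and non-uniform survey weights.
#'
#' @param node_metadata Data.frame with columns `label`, `construct`,
#'   `measure`; defaults to [survey_layout()].
#' @param within_coupling Magnitude (> 0) of within-construct couplings.
#' @param between_coupling Magnitude (>= 0) of non-bridge cross-construct
#'   couplings.
#' @param bridge_coupling Magnitude of bridge couplings; must be at least
#'   `within_coupling`.
#' @param within_density,between_density Probability in \[0, 1\] that a
#'   within-construct (resp. non-bridge cross-construct) pair receives a
#'   coupling.
#' @param bridge_pairs List of length-2 character vectors (node labels) that
#'   must cross constructs; these pairs always receive `bridge_coupling`.
#' @param negative_fraction Probability that a drawn non-bridge coupling is
#'   negative (bridges are always positive).
#' @param threshold_mean,threshold_sd Normal distribution of base node
#'   thresholds (log-odds); the negative default makes endorsement the
#'   rarer state, as for difficulty/loneliness indicators.
#' @param covariate_spec Named list; each element describes one categorical
#'   covariate as a list with `n_levels` (integer >= 2), optional `probs`
#'   (level probabilities), and `shifts`, a p x n_levels matrix (or a vector
#'   recycled over levels 2..L with zeros for the reference level) of
#'   threshold shifts added to each node when a respondent has that level.
#' @param skip_pairs List of length-2 character vectors `(parent, child)`;
#'   when the parent indicator is 1 the child is deterministically set to 0
#'   (the survey never asks the child question), and the pair is recorded as
#'   forbidden for estimation.
#' @param weight_spec List with `meanlog` and `sdlog`: survey weights are
#'   drawn lognormal and normalized to mean 1.
#' @return An object of class `planted_design`.
#' @export
planted_design <- function(node_metadata = survey_layout(),
                           within_coupling = 0.5,
                           between_coupling = 0.15,
                           bridge_coupling = 1,
                           within_density = 0.3,
                           between_density = 0.05,
                           bridge_pairs = list(),
                           negative_fraction = 0.1,
                           threshold_mean = -1,
                           threshold_sd = 0.25,
                           covariate_spec = list(),
                           skip_pairs = list(),
                           weight_spec = list(meanlog = 0, sdlog = 0.5)) {
  stopifnot(is.data.frame(node_metadata),
            all(c("label", "construct", "measure") %in% names(node_metadata)))
  p <- nrow(node_metadata)
  if (p < 2) stop("planted_design: need at least 2 nodes", call. = FALSE)
  if (anyDuplicated(node_metadata$label))
    stop("planted_design: duplicate node labels", call. = FALSE)
  if (within_coupling <= 0)
    stop("planted_design: within_coupling must be > 0", call. = FALSE)
  if (between_coupling < 0)
    stop("planted_design: between_coupling must be >= 0", call. = FALSE)
  if (bridge_coupling < within_coupling)
    stop("planted_design: bridge_coupling must be >= within_coupling",
         call. = FALSE)
  for (d in c(within_density, between_density))
    if (d < 0 || d > 1)
      stop("planted_design: densities must lie in [0, 1]", call. = FALSE)
  cons <- stats::setNames(node_metadata$construct, node_metadata$label)
  for (bp in bridge_pairs) {
    if (length(bp) != 2 || !all(bp %in% node_metadata$label))
      stop("planted_design: bridge pair must name two known nodes",
           call. = FALSE)
    if (cons[[bp[1]]] == cons[[bp[2]]])
      stop("planted_design: bridge pair must cross constructs: ",
           paste(bp, collapse = " - "), call. = FALSE)
  }
  for (sp in skip_pairs) {
    if (length(sp) != 2 || !all(sp %in% node_metadata$label) ||
        sp[1] == sp[2])
      stop("planted_design: skip pair must name two distinct known nodes",
           call. = FALSE)
  }
  for (nm in names(covariate_spec)) {
    cs <- covariate_spec[[nm]]
    if (is.null(cs$n_levels) || cs$n_levels < 2)
      stop("planted_design: covariate '", nm, "' needs n_levels >= 2",
           call. = FALSE)
  }
  structure(list(node_metadata = node_metadata,
                 within_coupling = within_coupling,
                 between_coupling = between_coupling,
                 bridge_coupling = bridge_coupling,
                 within_density = within_density,
                 between_density = between_density,
                 bridge_pairs = bridge_pairs,
                 negative_fraction = negative_fraction,
                 threshold_mean = threshold_mean,
                 threshold_sd = threshold_sd,
                 covariate_spec = covariate_spec,
                 skip_pairs = skip_pairs,
                 weight_spec = weight_spec),
            class = "planted_design")
}

#' Demonstration design mirroring the two-construct survey instrument
#'
#' A ready-made [planted_design()] over the 34-node [survey_layout()]:
#' dense within-construct coupling, sparse cross-construct coupling, two
#' bridge pairs linking the performance/participation side of each
#' construct, an age-group covariate that raises the thresholds of the
#' difficulty items, the three skip-logic pairs implied by the
#' no-spouse/no-children routing, and lognormal survey weights.
#'
#' @return A [planted_design()].
#' @export
demo_design <- function() {
  meta <- survey_layout()
  p <- nrow(meta)
  shifts <- matrix(0, p, 3)
  diff_nodes <- grepl("^diff_", meta$label)
  shifts[diff_nodes, 2] <- 0.4
  shifts[diff_nodes, 3] <- 0.8
  planted_design(
    node_metadata = meta,
    bridge_pairs = list(
      c("incomplete_balance_tests", "feel_isolated"),
      c("diff_walking", "infreq_participation")),
    covariate_spec = list(
      age_group = list(n_levels = 3, shifts = shifts)),
    skip_pairs = list(
      c("no_children", "low_contact_children"),
      c("no_spouse", "low_contact_spouse"),
      c("no_spouse", "not_close_spouse")))
}

#' Draw ground-truth Ising parameters from a planted design
#'
#' Couplings are drawn independently pair by pair: a within-construct pair
#' receives magnitude `within_coupling` with probability `within_density`, a
#' cross-construct pair magnitude `between_coupling` with probability
#' `between_density`, and every designated bridge pair always receives
#' `bridge_coupling` (positive). Drawn non-bridge couplings are negated with
#' probability `negative_fraction`. Thresholds are Normal(`threshold_mean`,
#' `threshold_sd`). Deterministic under a fixed seed.
#'
#' @param design A [planted_design()].
#' @param seed Integer seed.
#' @return An [ising_parameters()] object; the design is attached as
#'   attribute `"design"`.
#' @export
build_planted_parameters <- function(design, seed = 1) {
  stopifnot(inherits(design, "planted_design"))
  set.seed(seed)
  meta <- design$node_metadata
  p <- nrow(meta)
  labels <- meta$label
  omega <- matrix(0, p, p, dimnames = list(labels, labels))
  bridge_idx <- vapply(design$bridge_pairs, function(bp)
    paste(sort(match(bp, labels)), collapse = "-"), character(1))
  for (i in seq_len(p - 1)) {
    for (j in seq((i + 1), p)) {
      key <- paste(i, j, sep = "-")
      if (key %in% bridge_idx) {
        omega[i, j] <- design$bridge_coupling
      } else if (meta$construct[i] == meta$construct[j]) {
        if (stats::runif(1) < design$within_density) {
          s <- if (stats::runif(1) < design$negative_fraction) -1 else 1
          omega[i, j] <- s * design$within_coupling
        }
      } else if (design$between_density > 0 &&
                 stats::runif(1) < design$between_density) {
        s <- if (stats::runif(1) < design$negative_fraction) -1 else 1
        omega[i, j] <- s * design$between_coupling
      }
    }
  }
  omega <- omega + t(omega)
  tau <- stats::rnorm(p, design$threshold_mean, design$threshold_sd)
  out <- ising_parameters(tau, omega, labels = labels)
  attr(out, "design") <- design
  out
}
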