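make_chain_dataset <- function(n, seed, coupling = 1) {
  # 4-node chain: 1-2, 2-3, 3-4
  omega <- matrix(0, 4, 4)
  omega[cbind(1:3, 2:4)] <- coupling
  omega <- omega + t(omega)
  par <- ising_parameters(rep(0, 4), omega)
  sample_ising(par, n, seed = seed, burn_in = 300, thinning = 3)
}

test_that("ebic evaluates the penalized likelihood criterion", {
  # k = 0 kills both penalty terms
  expect_equal(ebic(-100, 0, n = 500, p_candidates = 7, gamma = 0.9), 200)
  # hand evaluation with ln(e) = 1: 200 + 2*ln(e) + 2*0.25*2*ln(e) = 203
  expect_equal(ebic(-100, 2, n = exp(1), p_candidates = exp(1),
                    gamma = 0.25), 203)
  # gamma = 0 reduces to the classical BIC
  expect_equal(ebic(-50, 3, n = 100, p_candidates = 12, gamma = 0),
               -2 * (-50) + 3 * log(100))
  expect_error(ebic(NaN, 1, 10, 3, 0.25), "non-finite")
})

test_that("the nodewise path starts empty and selection is gamma-monotone", {
  ds <- make_chain_dataset(800, seed = 21)
  cfg <- estimation_config(gamma = 0.25)
  path <- fit_nodewise_path("V2", ds, cfg)

  # at lambda_max every node coefficient is exactly zero
  expect_true(all(path$node_coefficients[1, ] == 0))
  expect_identical(path$k[1], 0)
  # lambdas strictly decreasing
  expect_true(all(diff(path$lambdas) < 0))

  # selected support size never increases in gamma on a fixed path
  sizes <- vapply(seq(0, 1, by = 0.1), function(g) {
    cfg_g <- estimation_config(gamma = g)
    select_by_ebic(path, cfg_g)$k
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))

  # single-lambda path degenerates to that model
  short <- path
  keep <- 5L
  short$lambdas <- path$lambdas[keep]
  short$node_coefficients <- path$node_coefficients[keep, , drop = FALSE]
  short$loglik <- path$loglik[keep]
  short$k <- path$k[keep]
  sel <- select_by_ebic(short, cfg)
  expect_equal(unname(sel$node_coefficients),
               unname(path$node_coefficients[keep, ]))
})

test_that("unpenalized covariate coefficients match a plain logistic fit", {
  meta <- two_block_meta(6)
  sh <- matrix(0, 6, 2); sh[, 2] <- 0.8
  des <- planted_design(meta, within_density = 0, within_coupling = 0.5,
                        covariate_spec = list(
                          grp = list(n_levels = 2, shifts = sh)))
  ds <- simulate_dataset(des, 2000, seed = 31, burn_in = 200, thinning = 2)
  cfg <- estimation_config(use_survey_weights = FALSE)
  path <- fit_nodewise_path("n1", ds, cfg)
  # at lambda_max (no node predictors) the covariate coefficient equals
  # the unpenalized covariates-only logistic regression
  ref <- glm(ds$values[, "n1"] ~ ds$covariates$grp, family = binomial())
  expect_equal(unname(path$covariate_coefficients[1, 1]),
               unname(coef(ref)[2]), tolerance = 1e-3)
})

test_that("strong couplings are recovered with the right sign", {
  omega <- matrix(0, 3, 3)
  omega[1, 2] <- omega[2, 1] <- 1.5
  par <- ising_parameters(c(0, 0, 0), omega)
  ds <- sample_ising(par, 5000, seed = 41, burn_in = 300, thinning = 3)
  cfg <- estimation_config(gamma = 0.25)
  sel <- select_by_ebic(fit_nodewise_path("V1", ds, cfg), cfg)
  expect_gt(sel$node_coefficients[["V2"]], 0)

  # a node with an all-zero coupling row is usually left unconnected
  empty <- 0
  for (s in 1:10) {
    dsz <- sample_ising(par, 2000, seed = 100 + s, burn_in = 300,
                        thinning = 3)
    selz <- select_by_ebic(fit_nodewise_path("V3", dsz, cfg), cfg)
    if (all(selz$node_coefficients == 0)) empty <- empty + 1
  }
  expect_gte(empty, 8)
})

test_that("estimate_network is symmetric, respects forbidden pairs and AND<=OR", {
  des <- two_block_design(10)
  ds <- simulate_dataset(des, 1500, seed = 51, burn_in = 300, thinning = 3)
  cfg_and <- estimation_config(rule = "and")
  cfg_or <- estimation_config(rule = "or")
  net_and <- estimate_network(ds, cfg_and)
  net_or <- estimate_network(ds, cfg_or)

  expect_identical(net_and$weights, t(net_and$weights))
  expect_true(all(diag(net_and$weights) == 0))
  # AND support is contained in OR support
  expect_true(all(net_or$weights[net_and$weights != 0] != 0))

  # a strongly coupled forbidden pair still gets weight exactly 0
  gt <- attr(ds, "ground_truth")
  within_pairs <- which(gt$couplings != 0 & upper.tri(gt$couplings),
                        arr.ind = TRUE)
  strong <- within_pairs[which.max(abs(gt$couplings[within_pairs])), ]
  lab <- rownames(gt$couplings)[strong]
  ds_fb <- binary_indicator_dataset(ds$values, ds$node_metadata,
                                    covariates = ds$covariates,
                                    survey_weights = ds$survey_weights,
                                    forbidden_pairs = list(lab))
  net_fb <- estimate_network(ds_fb, cfg_and)
  expect_identical(net_fb$weights[lab[1], lab[2]], 0)

  # constant node fails with the node named
  vals <- ds$values
  vals[, "n4"] <- 0L
  ds_const <- binary_indicator_dataset(vals, ds$node_metadata)
  expect_error(estimate_network(ds_const, cfg_and), "n4")
})

test_that("all-zero couplings give an empty network at gamma 0.25", {
  par <- ising_parameters(rep(-0.5, 10), matrix(0, 10, 10))
  edge_counts <- vapply(1:5, function(s) {
    ds <- sample_ising(par, 5000, seed = 200 + s, burn_in = 300,
                       thinning = 3)
    net <- estimate_network(ds, estimation_config(gamma = 0.25))
    sum(net$weights[upper.tri(net$weights)] != 0)
  }, numeric(1))
  expect_identical(median(edge_counts), 0)
})

test_that("covariate adjustment removes confounded edges", {
  # one binary covariate shifts nodes n1 and n2 jointly; no direct coupling
  meta <- two_block_meta(4)
  sh <- matrix(0, 4, 2)
  sh[1:2, 2] <- 2
  des <- planted_design(meta, within_density = 0, within_coupling = 0.5,
                        covariate_spec = list(
                          grp = list(n_levels = 2, shifts = sh)))
  spurious_without <- 0
  absent_with <- 0
  reps <- 50
  for (s in seq_len(reps)) {
    ds <- simulate_dataset(des, 1500, seed = 300 + s, burn_in = 200,
                           thinning = 2)
    cfg <- estimation_config(gamma = 0.25, use_survey_weights = FALSE)
    net_adj <- estimate_network(ds, cfg)
    ds_nocov <- binary_indicator_dataset(ds$values, ds$node_metadata,
                                         survey_weights = ds$survey_weights)
    net_raw <- estimate_network(ds_nocov, cfg)
    if (net_raw$weights["n1", "n2"] != 0) spurious_without <-
        spurious_without + 1
    if (net_adj$weights["n1", "n2"] == 0) absent_with <- absent_with + 1
  }
  expect_gte(spurious_without, 0.75 * reps)
  expect_gte(absent_with, 0.75 * reps)
})

test_that("survey weights tilt the fit toward heavy respondents", {
  # two subpopulations with opposite couplings; upweighting one flips the
  # estimated sign of the pooled edge
  omega_pos <- matrix(c(0, 1.2, 1.2, 0), 2, 2)
  omega_neg <- -omega_pos
  pos <- sample_ising(ising_parameters(c(0, 0), omega_pos), 1500,
                      seed = 61, burn_in = 300, thinning = 3)
  neg <- sample_ising(ising_parameters(c(0, 0), omega_neg), 1500,
                      seed = 62, burn_in = 300, thinning = 3)
  meta <- data.frame(label = c("V1", "V2"), construct = "A",
                     measure = "subjective", stringsAsFactors = FALSE)
  vals <- rbind(pos$values, neg$values)
  w <- c(rep(5, 1500), rep(0.1, 1500))
  ds <- binary_indicator_dataset(vals, meta, survey_weights = w)
  cfg_w <- estimation_config(rule = "or", use_survey_weights = TRUE)
  cfg_u <- estimation_config(rule = "or", use_survey_weights = FALSE)
  path_w <- fit_nodewise_path("V1", ds, cfg_w)
  sel_w <- select_by_ebic(path_w, cfg_w)
  expect_gt(sel_w$node_coefficients[["V2"]], 0)
  # sanity: unweighted pooled fit cannot be strongly positive
  sel_u <- select_by_ebic(fit_nodewise_path("V1", ds, cfg_u), cfg_u)
  expect_lt(sel_u$node_coefficients[["V2"]],
            sel_w$node_coefficients[["V2"]])
})
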