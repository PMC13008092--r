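hub_design <- function() {
  # 6-node hub: node n1 coupled to every other node
  meta <- data.frame(label = paste0("n", 1:6), construct = "A",
                     measure = "subjective", stringsAsFactors = FALSE)
  omega <- matrix(0, 6, 6)
  omega[1, 2:6] <- omega[2:6, 1] <- 1
  ising_parameters(rep(-0.5, 6), omega, labels = meta$label)
}

test_that("bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroni(0.001, m = 34), 0.034)
  expect_equal(bonferroni(0.5, m = 34), 1)
  expect_equal(bonferroni(c(0.2, 0.04), m = 2), c(0.4, 0.08))
  expect_equal(bonferroni(0.07), 0.07)  # m = 1 identity
  expect_error(bonferroni(c(0.1, 0.2), m = 1), "at least")
  expect_error(bonferroni(1.2), "\\[0, 1\\]")
})

test_that("add-one p-values never reach zero", {
  expect_equal(psychonet:::add_one_p(0, 199), 1 / 200)
  expect_equal(psychonet:::add_one_p(199, 199), 1)
  expect_gte(psychonet:::add_one_p(0, 10000), 1 / 10001)
})

test_that("bootstrap reports are seed-deterministic", {
  par <- hub_design()
  ds <- sample_ising(par, 300, seed = 61, burn_in = 200, thinning = 2,
                     weight_spec = list(meanlog = 0, sdlog = 0.4))
  cfg <- estimation_config()
  r1 <- bootstrap_pipeline(ds, cfg, B = 15, seed = 5,
                           metric_spec = list(assortativity = character(0),
                                              strength = TRUE,
                                              betweenness = FALSE))
  r2 <- bootstrap_pipeline(ds, cfg, B = 15, seed = 5,
                           metric_spec = list(assortativity = character(0),
                                              strength = TRUE,
                                              betweenness = FALSE))
  expect_identical(r1$replicates, r2$replicates)
  expect_identical(r1$estimates, r2$estimates)
  expect_identical(r1$B_effective, 15L)
})

test_that("uniform weights reduce to the ordinary bootstrap", {
  # with equal weights the selection probabilities are uniform: the index
  # frequencies over many replicates pass a goodness-of-fit test
  n <- 40
  prob <- rep(1, n) / n
  set.seed(9)
  counts <- tabulate(
    unlist(lapply(1:500, function(b) sample.int(n, n, TRUE, prob = prob))),
    nbins = n)
  expect_gt(stats::chisq.test(counts)$p.value, 0.001)
})

test_that("CI level tracks the Bonferroni family size", {
  par <- hub_design()
  ds <- sample_ising(par, 300, seed = 63, burn_in = 200, thinning = 2)
  cfg <- estimation_config(use_survey_weights = FALSE)
  spec <- list(assortativity = character(0), strength = TRUE,
               betweenness = FALSE)
  r1 <- bootstrap_pipeline(ds, cfg, B = 40, seed = 3, metric_spec = spec,
                           m = 1)
  r5 <- bootstrap_pipeline(ds, cfg, B = 40, seed = 3, metric_spec = spec,
                           m = 5)
  expect_equal(r1$level, 0.95)
  expect_equal(r5$level, 1 - 0.05 / 5)
  # wider family -> wider (or equal) intervals, lower <= upper always
  expect_true(all(r1$estimates$ci_lower <= r1$estimates$ci_upper))
  expect_true(all(r5$estimates$ci_lower <= r1$estimates$ci_lower + 1e-12))
  expect_true(all(r5$estimates$ci_upper >= r1$estimates$ci_upper - 1e-12))
})

test_that("comparison tests carry one-tailed add-one p-values", {
  des <- two_block_design(10, bridge = list(c("n2", "n8")))
  ds <- simulate_dataset(des, 800, seed = 65, burn_in = 200, thinning = 2)
  cfg <- estimation_config()
  rep <- bootstrap_pipeline(
    ds, cfg, B = 12, seed = 4,
    metric_spec = list(assortativity = "construct", strength = FALSE,
                       betweenness = TRUE),
    compare = c("null", "ablate"), ablate_nodes = "n2")
  expect_false(is.null(rep$tests))
  expect_true(all(rep$tests$p_raw >= 1 / (rep$B_effective + 1)))
  expect_true(all(rep$tests$p_adjusted >= rep$tests$p_raw - 1e-12))
  expect_true(all(rep$tests$p_adjusted <= 1))
  expect_true(any(grepl("^ablation_construct_n2$", rep$tests$metric)))
  expect_true(any(grepl("^betweenness_vs_null_", rep$tests$metric)))
})
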