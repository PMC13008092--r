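test_that("planted parameters honor the design structure", {
  meta <- two_block_meta(10)
  # no cross-construct mass when between_density = 0 and no bridges
  des0 <- planted_design(meta, within_coupling = 0.5, between_density = 0,
                         within_density = 0.5)
  par0 <- build_planted_parameters(des0, seed = 3)
  cross <- outer(meta$construct, meta$construct, "!=")
  expect_true(all(par0$couplings[cross] == 0))

  # full within density puts |coupling| = within_coupling on every
  # within-construct pair
  des1 <- planted_design(meta, within_coupling = 0.5, within_density = 1,
                         between_density = 0)
  par1 <- build_planted_parameters(des1, seed = 3)
  within <- outer(meta$construct, meta$construct, "==")
  diag(within) <- FALSE
  expect_true(all(abs(par1$couplings[within]) == 0.5))

  # bridge pairs always get the elevated coupling
  des2 <- planted_design(meta, within_coupling = 0.5, bridge_coupling = 1.2,
                         bridge_pairs = list(c("n2", "n7")))
  par2 <- build_planted_parameters(des2, seed = 3)
  expect_identical(par2$couplings["n2", "n7"], 1.2)

  # determinism
  expect_identical(build_planted_parameters(des2, seed = 9),
                   build_planted_parameters(des2, seed = 9))

  # configuration errors
  expect_error(planted_design(meta, within_coupling = 0),
               "within_coupling")
  expect_error(planted_design(meta, within_density = 1.5), "densities")
  expect_error(planted_design(meta, bridge_pairs = list(c("n1", "n2"))),
               "cross constructs")
  expect_error(planted_design(meta, skip_pairs = list(c("n1", "n1"))),
               "distinct")
})

test_that("Gibbs draws match exact enumeration at small p", {
  # p = 2, independent symmetric nodes: marginal 1/2 within 3 MC SEs
  par2 <- ising_parameters(c(0, 0), matrix(0, 2, 2))
  ds2 <- sample_ising(par2, 10000, seed = 11, burn_in = 200, thinning = 5)
  se <- sqrt(0.25 / 10000)
  expect_lt(abs(mean(ds2$values[, 1]) - 0.5), 3 * se)

  # p = 4: KL divergence between sampled and exact state frequencies small
  omega <- matrix(0, 4, 4)
  omega[1, 2] <- omega[2, 1] <- 0.8
  omega[2, 3] <- omega[3, 2] <- -0.6
  omega[3, 4] <- omega[4, 3] <- 0.4
  tau <- c(0.2, -0.3, 0.1, 0)
  par4 <- ising_parameters(tau, omega)
  ds4 <- sample_ising(par4, 30000, seed = 12, burn_in = 500, thinning = 5)
  exact <- oracle_state_probs(tau, omega)
  key <- apply(ds4$values, 1, function(x) sum(x * 2^(seq_along(x) - 1)))
  states <- as.matrix(expand.grid(rep(list(0:1), 4)))
  lev <- states %*% 2^(0:3)
  emp <- as.numeric(table(factor(key, levels = lev))) / 30000
  kl <- sum(ifelse(exact > 0, exact * log(exact / pmax(emp, 1e-12)), 0))
  expect_lt(kl, 0.005)

  # positive coupling shows as a positive empirical log odds-ratio
  parc <- ising_parameters(c(0, 0), matrix(c(0, 1, 1, 0), 2, 2))
  dsc <- sample_ising(parc, 10000, seed = 13, burn_in = 200, thinning = 5)
  tab <- table(dsc$values[, 1], dsc$values[, 2]) + 0.5
  expect_gt(log(tab[1, 1] * tab[2, 2] / (tab[1, 2] * tab[2, 1])), 0)
})

test_that("skip logic, weights, and determinism hold in simulated data", {
  des <- two_block_design(10)
  des$skip_pairs <- list(c("n1", "n2"))
  des$weight_spec <- list(meanlog = 0, sdlog = 0.5)
  ds <- simulate_dataset(des, 500, seed = 4, burn_in = 200, thinning = 3)

  # skip rule: parent = 1 forces child = 0 in every row
  expect_true(all(ds$values[ds$values[, "n1"] == 1, "n2"] == 0))
  # and the pair is recorded as forbidden
  expect_true(list(c("n1", "n2")) %in% ds$forbidden_pairs ||
                any(vapply(ds$forbidden_pairs, identical, logical(1),
                           c("n1", "n2"))))

  # weights strictly positive, mean-normalized, non-uniform
  expect_true(all(ds$survey_weights > 0))
  expect_equal(mean(ds$survey_weights), 1, tolerance = 1e-12)
  expect_gt(stats::sd(ds$survey_weights), 0)

  # identical (design, seed) gives identical datasets
  ds2 <- simulate_dataset(des, 500, seed = 4, burn_in = 200, thinning = 3)
  expect_identical(ds$values, ds2$values)
  expect_identical(ds$survey_weights, ds2$survey_weights)

  # no missing entries and 0/1 coding (complete-case contract)
  expect_false(anyNA(ds$values))
  expect_true(all(ds$values %in% c(0L, 1L)))
})

test_that("covariate shifts move node prevalences", {
  meta <- two_block_meta(6)
  sh <- matrix(0, 6, 2)
  sh[1, 2] <- 2  # level 2 raises node n1's threshold strongly
  des <- planted_design(meta, within_density = 0, within_coupling = 0.5,
                        covariate_spec = list(
                          grp = list(n_levels = 2, shifts = sh)))
  ds <- simulate_dataset(des, 4000, seed = 8, burn_in = 200, thinning = 2)
  g <- ds$covariates$grp
  p1 <- mean(ds$values[g == 1, "n1"])
  p2 <- mean(ds$values[g == 2, "n1"])
  expect_gt(p2, p1 + 0.2)
})

test_that("dataset bundles round-trip through CSV/JSON", {
  des <- two_block_design(8)
  des$skip_pairs <- list(c("n1", "n2"))
  ds <- simulate_dataset(des, 120, seed = 6, burn_in = 100, thinning = 2)
  dir <- withr::local_tempdir()
  write_dataset_bundle(ds, dir, ground_truth = attr(ds, "ground_truth"))
  back <- read_dataset_bundle(dir)
  expect_identical(unname(back$values), unname(ds$values))
  expect_equal(back$survey_weights, ds$survey_weights, tolerance = 1e-12)
  expect_identical(back$forbidden_pairs, ds$forbidden_pairs)
  gt <- attr(back, "ground_truth")
  expect_equal(gt$couplings, attr(ds, "ground_truth")$couplings,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("dichotomize applies median-split, recode and cutpoint rules", {
  # grip-strength style median split: below the median codes low = 1,
  # ties at the median fall in the non-event class
  expect_identical(dichotomize(c(20, 29, 35, 40), "median_split"),
                   c(1L, 0L, 0L, 0L))
  # Likert loneliness recoding: "often"/"some of the time" = high
  map <- c("often" = 1, "some of the time" = 1, "hardly ever" = 0)
  expect_identical(
    dichotomize(c("often", "some of the time", "hardly ever"),
                "recode_map", map = map),
    c(1L, 1L, 0L))
  # identity recode of an already-binary column
  expect_identical(dichotomize(c(0, 1, 1, 0), "recode_map",
                               map = c("0" = 0, "1" = 1)),
                   c(0L, 1L, 1L, 0L))
  # cutpoint rule, both sides
  expect_identical(dichotomize(c(1, 5, 9), "cutpoint", cut = 5),
                   c(1L, 0L, 0L))
  expect_identical(dichotomize(c(1, 5, 9), "cutpoint", cut = 5,
                               event_side = "above"),
                   c(0L, 1L, 1L))
  # degenerate/invalid input
  expect_error(dichotomize(rep(3, 5), "median_split"), "distinct")
  expect_error(dichotomize(c("a", "b"), "recode_map", map = c(a = 1)),
               "unmapped")
})
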