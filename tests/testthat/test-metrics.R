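test_that("strength sums absolute incident weights", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.5
  w[1, 3] <- w[3, 1] <- -0.3
  net <- net_from_matrix(w)
  expect_equal(unname(node_strength(net)), c(0.8, 0.5, 0.3))
  # signed variant keeps signs
  expect_equal(unname(node_strength(net, signed = TRUE)), c(0.2, 0.5, -0.3))

  # isolated node scores zero, and strength equals the absolute column sums
  w4 <- matrix(0, 4, 4)
  w4[1, 2] <- w4[2, 1] <- 1.1
  net4 <- net_from_matrix(w4)
  expect_equal(unname(node_strength(net4)), colSums(abs(w4)))
  expect_equal(unname(node_strength(net4))[3:4], c(0, 0))
})

test_that("betweenness matches closed forms on stars and paths", {
  # 5-node star: center carries every leaf pair, leaves none
  w <- matrix(0, 5, 5)
  w[1, 2:5] <- w[2:5, 1] <- 0.7
  b <- node_betweenness(net_from_matrix(w))
  expect_equal(unname(b), c(1, 0, 0, 0, 0))

  # 3-node path: middle node carries its single non-adjacent pair
  w3 <- matrix(0, 3, 3)
  w3[1, 2] <- w3[2, 1] <- 0.5
  w3[2, 3] <- w3[3, 2] <- 0.9
  expect_equal(unname(node_betweenness(net_from_matrix(w3))), c(0, 1, 0))
})

test_that("betweenness equals exhaustive path enumeration on random graphs", {
  set.seed(77)
  for (rep in 1:20) {
    p <- sample(5:8, 1)
    w <- random_weight_matrix(p, density = 0.5, neg = 0.2)
    if (all(w == 0)) next
    got <- unname(node_betweenness(net_from_matrix(w)))
    expect_equal(got, oracle_betweenness(w), tolerance = 1e-10)
  }
})

test_that("assortativity reproduces closed forms and is scale invariant", {
  # all edge mass within groups: r = 1
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 0.5
  w[3, 4] <- w[4, 3] <- 0.8
  grp <- c("A", "A", "B", "B")
  net <- net_from_matrix(w, construct = grp)
  expect_equal(assortativity_categorical(net, "construct")$r, 1)

  # two equal groups, only between-group mass: r = -1
  wb <- matrix(0, 4, 4)
  wb[1, 3] <- wb[3, 1] <- 0.5
  wb[2, 4] <- wb[4, 2] <- 0.5
  netb <- net_from_matrix(wb, construct = grp)
  expect_equal(assortativity_categorical(netb, "construct")$r, -1)

  # invariance to global rescaling; mixing matrix sums to 1
  set.seed(5)
  wr <- random_weight_matrix(8, density = 0.5, neg = 0.3)
  grp8 <- rep(c("A", "B"), each = 4)
  r1 <- assortativity_categorical(net_from_matrix(wr, grp8), "construct")
  r2 <- assortativity_categorical(net_from_matrix(wr * 7.3, grp8),
                                  "construct")
  expect_equal(r1$r, r2$r, tolerance = 1e-12)
  expect_equal(sum(r1$mixing), 1, tolerance = 1e-12)

  # with equal |w| everywhere it agrees with the unweighted formula
  # (independent implementation in igraph)
  set.seed(6)
  wu <- random_weight_matrix(10, density = 0.4, neg = 0)
  wu[wu != 0] <- 0.6
  grp10 <- rep(c("A", "B"), 5)
  net10 <- net_from_matrix(wu, grp10)
  ours <- assortativity_categorical(net10, "construct")$r
  g <- as_igraph(net10)
  ref <- igraph::assortativity_nominal(g, factor(grp10))
  expect_equal(ours, ref, tolerance = 1e-10)

  # all-zero network is an error
  expect_error(assortativity_categorical(net_from_matrix(matrix(0, 3, 3))),
               "undefined")
})

test_that("centrality table lines up nodes with both measures", {
  des <- two_block_design(8)
  ds <- simulate_dataset(des, 800, seed = 71, burn_in = 200, thinning = 2)
  net <- estimate_network(ds, estimation_config())
  tab <- centrality_table(net)
  expect_identical(tab$node, net$node_metadata$label)
  expect_equal(tab$strength, unname(node_strength(net)))
  expect_equal(tab$betweenness, unname(node_betweenness(net)))
  expect_true(all(tab$strength >= 0))
  expect_true(all(tab$betweenness >= 0 & tab$betweenness <= 1))
})
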