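test_that("link distances match examples and the breadth-first oracle", {
  g <- default_reduced_graph()
  d <- link_distance_matrix(g)
  ## connected pairs named in the design are at distance 1
  expect_equal(d["1", "2"], 1)
  expect_equal(d["6", "4"], 1)
  expect_equal(d["5", "7"], 1)
  expect_equal(unname(diag(d)), rep(0, 7))
  expect_equal(unclass(d), bfs_distances_oracle(adjacency_matrix(g)),
               ignore_attr = TRUE)
  ## triangle inequality
  n <- nrow(d)
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    expect_lte(d[i, j], d[i, k] + d[k, j])
  }
})

test_that("link distances agree with the oracle on sampled null-ensemble members", {
  ens <- full_ensemble()
  set.seed(7)
  for (idx in sample(nrow(ens$members), 100)) {
    edges <- ens$edge_index[ens$members[idx, ], , drop = FALSE]
    adj <- matrix(0, 7, 7)
    adj[edges] <- 1
    adj <- adj + t(adj)
    expect_equal(ens$link_distances[idx, ],
                 t(bfs_distances_oracle(adj))[lower.tri(adj)])
    g <- relational_graph(1:7, edges)
    expect_equal(unclass(link_distance_matrix(g)),
                 bfs_distances_oracle(adj), ignore_attr = TRUE)
  }
})

test_that("Euclidean distances come from the layout and require one", {
  g <- two_node_graph()
  d <- euclidean_distance_matrix(g)
  expect_equal(d["a", "b"], 1)
  expect_equal(d["a", "a"], 0)
  rg <- default_reduced_graph()
  de <- euclidean_distance_matrix(rg)
  expect_equal(unname(de[rg$edges]), rep(1, 7), tolerance = 1e-9)
  expect_identical(de, t(de))
  no_layout <- relational_graph(1:3, rbind(c(1, 2), c(2, 3)))
  expect_error(euclidean_distance_matrix(no_layout), "layout")
})

test_that("communicability equals the negative matrix exponential", {
  ## 2-node closed form: exp([[0,1],[1,0]]) = [[cosh 1, sinh 1], ...]
  g2 <- two_node_graph()
  c2 <- communicability_matrix(g2)
  expect_equal(c2["a", "b"], -sinh(1), tolerance = 1e-10)
  expect_equal(c2["a", "a"], -cosh(1), tolerance = 1e-10)
  ## truncated-series oracle on the reduced and training graphs
  for (g in list(default_reduced_graph(), default_training_graph())) {
    a <- adjacency_matrix(g)
    expect_equal(unclass(communicability_matrix(g)),
                 -truncated_expm_oracle(a, 60), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
  expect_identical(unclass(c2), t(unclass(c2)))
})

test_that("successor representation equals the resolvent and its series", {
  g2 <- two_node_graph()
  ## gamma_fraction 0 -> identity
  expect_equal(unclass(successor_representation_matrix(g2, 0)),
               diag(2), ignore_attr = TRUE)
  ## lambda_max = 1 for a single edge, so gamma_fraction 0.5 -> gamma 0.5;
  ## closed form (I - A/2)^-1 = [[4/3, 2/3], [2/3, 4/3]]
  s <- successor_representation_matrix(g2, 0.5)
  expect_equal(unclass(s), matrix(c(4, 2, 2, 4) / 3, 2,
                                  dimnames = list(c("a", "b"), c("a", "b"))),
               tolerance = 1e-10, ignore_attr = TRUE)
  ## series oracle at the conventional discount on the reduced graph
  g <- default_reduced_graph()
  a <- adjacency_matrix(g)
  sr <- successor_representation_matrix(g, 0.85)
  gamma <- attr(sr, "params")$gamma
  expect_equal(unclass(sr), truncated_sr_oracle(a, gamma, 200),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(successor_representation_matrix(g, 1), "diverges")
  expect_error(successor_representation_matrix(g, 1.2), "diverges")
  ## the analysis regressor is the negative of the resolvent
  expect_equal(unclass(proximity_regressor(g, "successor", 0.85)),
               -unclass(sr), ignore_attr = TRUE)
})

test_that("asymmetry index follows its closed form and is direction-invariant", {
  cnt <- matrix(0, 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  cnt["x", "y"] <- 5; cnt["y", "x"] <- 5
  expect_equal(asymmetry_index(cnt, "x", "y"), 0)
  cnt["x", "y"] <- 7; cnt["y", "x"] <- 0
  expect_equal(asymmetry_index(cnt, "x", "y"), 1)
  cnt["x", "y"] <- 3; cnt["y", "x"] <- 1
  expect_equal(asymmetry_index(cnt, "x", "y"), 0.5)
  expect_equal(asymmetry_index(cnt, "y", "x"),
               asymmetry_index(cnt, "x", "y"))
  cnt["x", "y"] <- 0; cnt["y", "x"] <- 0
  expect_error(asymmetry_index(cnt, "x", "y"), "never experienced")
  ## random counts stay in [0, 1] and are swap-invariant
  set.seed(31)
  for (r in 1:50) {
    cnt[1, 2] <- rpois(1, 4); cnt[2, 1] <- rpois(1, 4)
    if (cnt[1, 2] + cnt[2, 1] == 0) next
    a <- asymmetry_index(cnt, 1, 2)
    expect_gte(a, 0); expect_lte(a, 1)
    expect_equal(a, asymmetry_index(cnt, 2, 1))
  }
})

test_that("experience-weighted edge lengths follow d = 1 - c / (1 + cmax)", {
  g <- two_node_graph()
  cnt <- matrix(c(0, 9, 0, 0), 2, byrow = TRUE,
                dimnames = list(c("a", "b"), c("a", "b")))
  ew <- empirical_edge_lengths(cnt, g)
  expect_equal(ew$length[ew$from == "a"], 1 - 9 / 10)  # c = cmax = 9
  expect_equal(ew$length[ew$from == "b"], 1)           # never experienced
  ## strictly decreasing in c for fixed cmax
  lens <- 1 - (0:9) / (1 + 9)
  expect_true(all(diff(lens) < 0))
  expect_true(all(ew$length > 0 & ew$length <= 1))
  expect_error(empirical_edge_lengths(cnt * 0, g), "cmax")
})

test_that("directed shortest paths add link lengths and match brute force", {
  ## 3-node path with weights 0.2 and 0.3 -> end-to-end 0.5
  g3 <- path3_graph()
  ew <- data.frame(from = c("1", "2", "2", "3"), to = c("2", "1", "3", "2"),
                   length = c(0.2, 0.2, 0.3, 0.3))
  d <- directed_shortest_paths(ew, g3)
  expect_equal(d["1", "3"], 0.5)
  ## uniform counts reproduce link distance up to a positive scalar
  g <- default_reduced_graph()
  cnt <- adjacency_matrix(g) * 4
  ewu <- empirical_edge_lengths(cnt, g)
  du <- directed_shortest_paths(ewu, g)
  link <- link_distance_matrix(g)
  off <- upper_pairs(unclass(du)) / upper_pairs(unclass(link))
  expect_equal(off, rep(off[1], length(off)), tolerance = 1e-12)
  expect_gt(off[1], 0)
  ## random seeded counts vs exhaustive simple-path enumeration
  set.seed(99)
  cnt <- adjacency_matrix(g) * matrix(rpois(49, 6), 7)
  ew <- empirical_edge_lengths(cnt, g)
  dsp <- directed_shortest_paths(ew, g)
  wmat <- matrix(Inf, 7, 7)
  wmat[cbind(match(ew$from, g$nodes), match(ew$to, g$nodes))] <- ew$length
  for (i in 1:7) for (j in 1:7) {
    if (i == j) next
    expect_equal(dsp[i, j], shortest_path_oracle(wmat, i, j),
                 tolerance = 1e-12)
  }
  ## symmetrised variant averages the two directions
  dsym <- directed_shortest_paths(ew, g, symmetrise = TRUE)
  expect_equal(unclass(dsym), (unclass(dsp) + t(unclass(dsp))) / 2,
               ignore_attr = TRUE)
})
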