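rt_fixture <- function(n_subjects = 3, beta = 0.1, noise = 0.05,
                       obj_sd = 0.1, blocks = 4, seed = 61,
                       metric = "communicability") {
  cfg <- cohort_config(n_subjects = n_subjects, generative_metric = metric,
                       beta_metric = beta, object_effect_sd = obj_sd,
                       noise_sd = noise, seed = seed)
  simulate_rt_cohort(cfg, default_reduced_graph(), blocks = blocks, reps = 3)
}

test_that("rt preprocessing demeans objects and averages transitions per block", {
  trials <- rt_fixture()
  resp <- preprocess_rt(trials)
  expect_equal(nrow(resp), 3 * 42)
  ## per-object means of the demeaned values vanish by construction
  tr <- trials
  tr$logdem <- log(tr$rt_ms) -
    ave(log(tr$rt_ms), interaction(tr$subject, tr$object))
  mns <- tapply(tr$logdem, interaction(tr$subject, tr$object), mean)
  expect_true(all(abs(mns) < 1e-12))
  ## brute-force recomputation oracle for a handful of cells
  set.seed(1)
  for (k in sample(nrow(resp), 12)) {
    s <- resp$subject[k]; i <- resp$predecessor[k]; j <- resp$object[k]
    sub <- tr[tr$subject == s, ]
    per_block <- vapply(sort(unique(sub$block)), function(b) {
      rows <- sub$block == b & !is.na(sub$predecessor) &
        sub$predecessor == i & sub$object == j
      mean(sub$logdem[rows])
    }, 0)
    expect_equal(resp$response[k], mean(per_block), tolerance = 1e-12)
  }
})

test_that("constant response times preprocess to zero", {
  trials <- rt_fixture(beta = 0, noise = 0, obj_sd = 0)
  resp <- preprocess_rt(trials)
  expect_true(all(abs(resp$response) < 1e-12))
})

test_that("noiseless RTs preprocess to the metric plus per-object offsets", {
  ## log turns the generative model additive; demeaning then leaves
  ## beta * metric shifted by an object-specific constant, exactly
  g <- default_reduced_graph()
  beta <- 0.2
  trials <- rt_fixture(beta = beta, noise = 0, obj_sd = 0.2)
  resp <- preprocess_rt(trials)
  comm <- communicability_matrix(g)
  dev <- resp$response - beta * comm[cbind(resp$predecessor, resp$object)]
  spread_within_object <- tapply(dev, paste(resp$subject, resp$object), sd)
  expect_true(all(spread_within_object < 1e-12))
})

test_that("rescaling a subject's RTs does not change the demeaned measures", {
  trials <- rt_fixture()
  scaled <- trials
  rows <- scaled$subject == 2
  scaled$rt_ms[rows] <- scaled$rt_ms[rows] * 3.7
  expect_equal(preprocess_rt(scaled)$response,
               preprocess_rt(trials)$response, tolerance = 1e-10)
})

test_that("a missing transition in a block is reported with pair and block", {
  trials <- rt_fixture(n_subjects = 2, blocks = 2)
  drop <- trials$subject == 1 & trials$block == 2 &
    !is.na(trials$predecessor) & trials$predecessor == "3" &
    trials$object == "5"
  expect_error(preprocess_rt(trials[!drop, ]), "block 2.*3->5")
})

test_that("rt regression agrees with the closed-form OLS oracle", {
  g <- default_reduced_graph()
  trials <- rt_fixture(beta = 0.1, noise = 0.1, seed = 42)
  resp <- preprocess_rt(trials)
  fit <- rt_regression(resp, graph = g, center = FALSE)
  regs <- list(communicability = communicability_matrix(g),
               link = link_distance_matrix(g),
               euclidean = euclidean_distance_matrix(g))
  for (s in unique(resp$subject)) {
    rows <- resp$subject == s
    x <- cbind(1, vapply(regs, function(m) {
      m[cbind(resp$predecessor[rows], resp$object[rows])]
    }, numeric(sum(rows))))
    expect_equal(unname(fit$coefficients[s, ]),
                 ols_oracle(x, resp$response[rows])[-1], tolerance = 1e-10)
  }
})

test_that("the behavioural pipeline recovers the generative structure at full scale", {
  g <- default_reduced_graph()
  cfg <- cohort_config(n_subjects = 26, generative_metric = "communicability",
                       beta_metric = 0.02, object_effect_sd = 0.05,
                       noise_sd = 0.2, seed = 512)
  trials <- simulate_rt_cohort(cfg, g, blocks = 10, reps = 3)
  fit <- rt_regression(preprocess_rt(trials), graph = g)
  p <- setNames(fit$group$p, fit$group$regressor)
  est <- setNames(fit$group$estimate, fit$group$regressor)
  expect_lt(p["communicability"], 0.05)
  expect_gt(est["communicability"], 0)
  expect_gt(p["link"], 0.05)
  expect_gt(p["euclidean"], 0.05)
})

test_that("permuted responses give near-null group statistics", {
  g <- default_reduced_graph()
  trials <- rt_fixture(n_subjects = 6, beta = 0.1, noise = 0.1, seed = 900)
  resp <- preprocess_rt(trials)
  set.seed(77)
  ts <- vapply(1:10, function(r) {
    perm <- resp
    for (s in unique(perm$subject)) {
      rows <- which(perm$subject == s)
      perm$response[rows] <- perm$response[sample(rows)]
    }
    fit <- rt_regression(perm, graph = g)
    fit$group$t[fit$group$regressor == "communicability"]
  }, 0)
  expect_lt(abs(mean(ts)), 1)
})

test_that("identical subjects are flagged, not crashed", {
  g <- default_reduced_graph()
  one <- preprocess_rt(rt_fixture(n_subjects = 2, seed = 5))
  clone <- one[one$subject == 1, ]
  clone2 <- clone
  clone2$subject <- 2
  twins <- rbind(clone, clone2)
  attr(twins, "nodes") <- g$nodes
  expect_warning(fit <- rt_regression(twins, graph = g),
                 "zero across-subject variance")
  expect_true(any(is.na(fit$group$t)) || all(fit$group$t == 0))
})

test_that("communicability bins are equal-count, ordered and oracle-exact", {
  g <- default_reduced_graph()
  comm <- communicability_matrix(g)
  ## a cohort exactly affine in communicability has monotone bin means
  pairs <- expand.grid(pred = g$nodes, obj = g$nodes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$pred != pairs$obj, ]
  affine <- data.frame(subject = 1, predecessor = pairs$pred,
                       object = pairs$obj,
                       response = 0.3 * comm[cbind(pairs$pred, pairs$obj)])
  attr(affine, "nodes") <- g$nodes
  bins <- communicability_bins(affine, comm, n_bins = 6)
  expect_equal(bins$n_pairs, rep(7L, 6))           # 42 / 6
  expect_true(all(diff(bins$mean_communicability) > 0))
  expect_true(all(diff(bins$mean_response) > 0))
  expect_error(communicability_bins(affine, comm, n_bins = 43),
               "cannot form")
  ## bin means match a brute-force group-by on a noisy preprocessed cohort
  noisy <- preprocess_rt(rt_fixture(beta = 0.1, noise = 0.2, seed = 87))
  b2 <- communicability_bins(noisy, comm, n_bins = 6)
  ## communicability is symmetric, so every value is tied across the two
  ## orientations of a pair; the tie-break is the stable enumeration order
  ## of ordered pairs, which the oracle must share to agree exactly
  op <- relmap:::ordered_pairs(g$nodes)
  pv <- comm[cbind(op$pred, op$obj)]
  ord <- order(pv)
  oracle_means <- vapply(split(ord, rep(1:6, each = 7)), function(ix) {
    sel <- paste(op$pred[ix], op$obj[ix])
    keys <- paste(noisy$predecessor, noisy$object)
    mean(vapply(split(noisy$response[keys %in% sel],
                      noisy$subject[keys %in% sel]), mean, 0))
  }, 0)
  expect_equal(b2$mean_response, unname(oracle_means), tolerance = 1e-12)
})
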