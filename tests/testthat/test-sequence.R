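nodes7 <- as.character(1:7)

test_that("scanner runs realise the balanced day-2 design exactly", {
  sq <- generate_scanner_run(nodes7, reps_per_transition = 10, seed = 1)
  expect_length(sq, 421L)
  cnt <- transition_counts(sq)
  off <- cnt[row(cnt) != col(cnt)]
  expect_true(all(off == 10L))
  expect_true(all(diag(cnt) == 0L))
  ## no immediate repeats
  expect_false(any(sq$items[-1] == sq$items[-421]))
  ## in-degree equals out-degree inside the circuit
  expect_equal(rowSums(cnt), colSums(cnt))
})

test_that("small balanced sequences satisfy exact counts", {
  sq3 <- generate_scanner_run(as.character(1:3), 1, seed = 4)
  expect_length(sq3, 7L)
  cnt <- transition_counts(sq3)
  expect_true(all(cnt[row(cnt) != col(cnt)] == 1L))
  sq2 <- generate_behaviour_block(as.character(1:2), 2, seed = 4)
  expect_equal(sq2$items, rep(sq2$items[1:2], length.out = 5))
  expect_error(generate_scanner_run(nodes7, 0, seed = 1), "positive")
  expect_error(generate_scanner_run("1", 1, seed = 1), "two objects")
})

test_that("behaviour blocks accumulate to the published totals", {
  blocks <- lapply(1:10, function(b) {
    generate_behaviour_block(nodes7, reps_per_transition = 3, seed = b)
  })
  expect_true(all(vapply(blocks, length, 0L) == 127L))
  total <- Reduce(`+`, lapply(blocks, transition_counts))
  expect_true(all(total[row(total) != col(total)] == 30L))
})

test_that("training walks traverse only links and respect the window", {
  g <- default_training_graph()
  edge_key <- paste(g$edges[, 1], g$edges[, 2])
  for (seed in 1:25) {
    sq <- generate_training_walk(g, n_items = 133, exclusion_window = 3,
                                 seed = seed)
    expect_length(sq, 133L)
    it <- sq$items
    ia <- match(it[-133], g$nodes)
    ib <- match(it[-1], g$nodes)
    step <- paste(ifelse(ia < ib, it[-133], it[-1]),
                  ifelse(ia < ib, it[-1], it[-133]))
    expect_true(all(step %in% edge_key))
    for (w in 1:3) {
      expect_false(any(it[seq_len(133 - w)] == it[seq_len(133 - w) + w]))
    }
  }
  ## window 0 on a single edge alternates
  g2 <- two_node_graph()
  sq2 <- generate_training_walk(g2, 10, exclusion_window = 0, seed = 1)
  expect_equal(sq2$items, rep(sq2$items[1:2], 5))
})

test_that("sequences are deterministic given the seed and vary across seeds", {
  a <- generate_scanner_run(nodes7, 10, seed = 123)
  b <- generate_scanner_run(nodes7, 10, seed = 123)
  c <- generate_scanner_run(nodes7, 10, seed = 124)
  expect_identical(a, b)
  expect_false(identical(a$items, c$items))
  w1 <- generate_training_walk(default_training_graph(), 50, 3, seed = 9)
  w2 <- generate_training_walk(default_training_graph(), 50, 3, seed = 9)
  expect_identical(w1, w2)
})

test_that("the cover task places one probe per transition and builds the exclusion mask", {
  sq <- generate_scanner_run(nodes7, 10, seed = 2)
  cv <- annotate_cover_task(sq, patch_prob = 0.5, probes_per_transition = 1,
                            seed = 3)
  expect_equal(sum(cv$probe), 42L)            # 10% of the 420 transitions
  probe_pairs <- paste(cv$items[which(cv$probe) - 1L],
                       cv$items[which(cv$probe)])
  expect_equal(sort(unique(probe_pairs)), sort(probe_pairs))
  ## exclusion covers each probe and the two following trials
  pos <- which(cv$probe)
  expect_true(all(cv$excluded[pos]))
  expect_true(all(cv$excluded[pmin(pos + 1L, 421L)]))
  expect_true(all(cv$excluded[pmin(pos + 2L, 421L)]))
  expected_mask <- unique(as.vector(outer(pos, 0:2, `+`)))
  expect_equal(sum(cv$excluded), sum(expected_mask <= 421L))
  ## no patches when the probability is zero
  cv0 <- annotate_cover_task(sq, patch_prob = 0, seed = 3)
  expect_false(any(cv0$patch))
  expect_error(annotate_cover_task(sq, probes_per_transition = 11, seed = 1),
               "not enough occurrences")
})

test_that("transition counts and presentation counts conserve totals", {
  sq <- stimulus_sequence(c("1", "2", "1"), nodes = c("1", "2"))
  cnt <- transition_counts(sq)
  expect_equal(cnt["1", "2"], 1L)
  expect_equal(cnt["2", "1"], 1L)
  expect_equal(presentation_counts(sq), c("1" = 2L, "2" = 1L))
  big <- generate_scanner_run(nodes7, 10, seed = 6)
  expect_equal(sum(transition_counts(big)), length(big) - 1L)
  expect_equal(sum(presentation_counts(big)), length(big))
  expect_error(stimulus_sequence(c("1", "1", "2")), "never repeat")
})

test_that("mean gaps match their examples and the quadratic-scan oracle", {
  s1 <- stimulus_sequence(c("1", "2", "3", "1"), nodes = as.character(1:3))
  g1 <- mean_gap_matrix(s1, symmetrise = FALSE)
  expect_equal(g1["1", "3"], 1)   # one item between 1 and 3
  s2 <- stimulus_sequence(c("1", "2", "1"), nodes = c("1", "2"))
  g2 <- mean_gap_matrix(s2, symmetrise = FALSE)
  expect_equal(g2["1", "2"], 0)
  ## long seeded walk vs oracle, directed and symmetrised
  walk <- generate_training_walk(default_training_graph(), 200, 3, seed = 5)
  gd <- mean_gap_matrix(walk, symmetrise = FALSE)
  gs <- mean_gap_matrix(walk, symmetrise = TRUE)
  for (i in walk$nodes) for (j in walk$nodes) {
    if (i == j) next
    expect_equal(gd[i, j], gap_scan_oracle(walk$items, i, j))
  }
  ij <- c("1", "9")
  both <- c(gd[ij[1], ij[2]], gd[ij[2], ij[1]])
  expect_equal(gs[ij[1], ij[2]], mean(both))
  expect_identical(gs, t(gs))
})

test_that("events tables carry onsets, flags and predecessors", {
  sq <- annotate_cover_task(generate_scanner_run(nodes7, 10, seed = 2),
                            seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  ev <- write_events_tsv(sq, path, stim_duration = 1, seed = 4)
  expect_equal(nrow(ev), 421L)
  expect_true(all(diff(ev$onset) >= 1 + 1))   # duration + minimum ITI
  expect_true(all(diff(ev$onset) <= 1 + 5))
  expect_identical(ev$predecessor[-1], ev$object[-421])
  back <- read.delim(path, na.strings = "n/a",
                     colClasses = c(object = "character"))
  expect_equal(nrow(back), 421L)
  expect_equal(back$object, ev$object)
})
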