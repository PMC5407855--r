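#' Stimulus sequences
#'
#' A stimulus sequence is an ordered presentation of objects (graph nodes)
#' plus per-trial flags: the mirrored/normal orientation of the object, the
#' presence of the cover-task grey patch, whether the trial is a probe
#' (report trial), and whether the trial is excluded from analysis (probe
#' trials and the two following trials, to avoid button-press artefacts).
#'
#' @param items character vector of presented node labels; no two
#'   consecutive items may be identical.
#' @param nodes the node universe (default: unique items, in order of first
#'   appearance).
#' @param orientation,patch,probe,excluded per-trial flag vectors; defaults
#'   are neutral.
#' @param design free-form descriptor of the generating design.
#' @param seed seed the sequence was generated under, if any.
#' @return An object of class `stimulus_sequence`.
#' @export
stimulus_sequence <- function(items, nodes = unique(items),
                              orientation = rep("normal", length(items)),
                              patch = rep(FALSE, length(items)),
                              probe = rep(FALSE, length(items)),
                              excluded = rep(FALSE, length(items)),
                              design = "manual", seed = NA_integer_) {
  items <- as.character(items)
  nodes <- as.character(nodes)
  if (!all(items %in% nodes)) stop("items outside the node universe")
  n <- length(items)
  if (n >= 2L && any(items[-1L] == items[-n])) {
    stop("objects must never repeat on consecutive trials")
  }
  stopifnot(length(orientation) == n, length(patch) == n,
            length(probe) == n, length(excluded) == n)
  structure(list(items = items, nodes = nodes,
                 orientation = as.character(orientation),
                 patch = as.logical(patch), probe = as.logical(probe),
                 excluded = as.logical(excluded),
                 design = design, seed = seed),
            class = "stimulus_sequence")
}

#' @export
print.stimulus_sequence <- function(x, ...) {
  cat("Stimulus sequence (", x$design, "): ", length(x$items), " items over ",
      length(x$nodes), " objects\n", sep = "")
  cat("  head:", paste(utils::head(x$items, 12L), collapse = " "),
      if (length(x$items) > 12L) "...", "\n")
  if (any(x$probe)) {
    cat("  probes:", sum(x$probe), " excluded trials:", sum(x$excluded), "\n")
  }
  invisible(x)
}

#' @export
length.stimulus_sequence <- function(x) length(x$items)

#' Day-1 training walk on the full graph
#'
#' Generates a training sequence as a random walk on the graph: every
#' consecutive pair of items is a link, and an item may not reappear until
#' at least `exclusion_window` other items have intervened (the published
#' design used a window of 3).  Dead ends under the window constraint are
#' resolved by bounded backtracking; if that fails the walk restarts from a
#' seed offset, so the result is still deterministic given `seed`.
#' Orientations are randomised uniformly per trial.
#'
#' @param graph a [relational_graph()].
#' @param n_items sequence length (133 per training block in the published
#'   design).
#' @param exclusion_window minimum number of other items between two
#'   presentations of the same item.
#' @param seed integer seed.
#' @param max_backtrack total backtracking budget before restarting.
#' @return A [stimulus_sequence()].
#' @export
generate_training_walk <- function(graph, n_items = 133L,
                                   exclusion_window = 3L, seed,
                                   max_backtrack = 50L) {
  stopifnot(inherits(graph, "relational_graph"), n_items >= 1L,
            exclusion_window >= 0L)
  nbrs <- split(c(graph$edges[, 2L], graph$edges[, 1L]),
                c(graph$edges[, 1L], graph$edges[, 2L]))
  for (attempt in 0:20) {
    items <- with_seed(derive_seed(seed, paste0("training_walk", attempt)),
                       walk_attempt(graph$nodes, nbrs, n_items,
                                    exclusion_window, max_backtrack))
    if (!is.null(items)) {
      ori <- with_seed(derive_seed(seed, "training_orientation"),
                       sample(c("normal", "mirrored"), n_items,
                              replace = TRUE))
      return(stimulus_sequence(items, nodes = graph$nodes,
                               orientation = ori,
                               design = "training_walk", seed = seed))
    }
  }
  stop("could not generate a training walk satisfying the exclusion window ",
       "after bounded backtracking and restarts")
}

## One backtracking attempt; returns NULL on failure.
walk_attempt <- function(nodes, nbrs, n_items, window, max_backtrack) {
  items <- character(n_items)
  tried <- vector("list", n_items)   # candidates already rejected per slot
  items[1L] <- sample(nodes, 1L)
  t <- 2L
  backtracks <- 0L
  while (t <= n_items) {
    recent <- items[max(1L, t - window):(t - 1L)]
    cand <- setdiff(nbrs[[items[t - 1L]]], c(recent, tried[[t]]))
    if (length(cand)) {
      items[t] <- if (length(cand) == 1L) cand else sample(cand, 1L)
      t <- t + 1L
      ## fresh subtree: forget rejections recorded for the next slot
      if (t <= n_items) tried[t] <- list(NULL)
    } else {
      ## dead end at slot t: blame the choice made at t - 1 and retry it
      backtracks <- backtracks + 1L
      if (backtracks > max_backtrack || t <= 2L) return(NULL)
      tried[[t - 1L]] <- c(tried[[t - 1L]], items[t - 1L])
      items[t - 1L] <- ""
      t <- t - 1L
    }
  }
  items
}

## Randomised Eulerian circuit (Hierholzer) on the complete directed
## multigraph over `nodes` with every arc repeated `reps` times.  Guarantees
## every ordered pair of distinct nodes occurs exactly `reps` times as a
## consecutive pair, with no immediate repeats, by construction.
eulerian_balanced_sequence <- function(nodes, reps) {
  n <- length(nodes)
  remaining <- matrix(reps, n, n)
  diag(remaining) <- 0L
  stack <- integer(n * (n - 1L) * reps + 1L)
  stack[1L] <- sample.int(n, 1L)
  top <- 1L
  circuit <- integer(length(stack))
  filled <- 0L
  while (top > 0L) {
    v <- stack[top]
    out <- remaining[v, ]
    total <- sum(out)
    if (total > 0L) {
      w <- sample.int(n, 1L, prob = out)
      remaining[v, w] <- remaining[v, w] - 1L
      top <- top + 1L
      stack[top] <- w
    } else {
      filled <- filled + 1L
      circuit[filled] <- v
      top <- top - 1L
    }
  }
  nodes[rev(circuit[seq_len(filled)])]
}

#' Day-2 scanner run with balanced transitions
#'
#' Generates one fMRI run: transitions are randomised under the constraint
#' that each ordered pair of distinct objects occurs exactly
#' `reps_per_transition` times and objects never repeat.  Implemented as a
#' randomised Eulerian circuit on the complete directed multigraph, which
#' guarantees the counts exactly; for 7 objects and 10 repetitions the run
#' has 42 x 10 + 1 = 421 items.
#'
#' @param nodes node labels presented in the run (the reduced-graph objects).
#' @param reps_per_transition occurrences of every ordered transition.
#' @param seed integer seed.
#' @return A [stimulus_sequence()] of length
#'   `length(nodes) * (length(nodes) - 1) * reps_per_transition + 1`.
#' @export
generate_scanner_run <- function(nodes, reps_per_transition = 10L, seed) {
  balanced_sequence(nodes, reps_per_transition, seed, "scanner_run")
}

#' Day-2 behavioural test block with balanced transitions
#'
#' Same balanced-transition construction as [generate_scanner_run()], at the
#' behavioural design size: 7 objects and 3 repetitions per ordered
#' transition give 42 x 3 + 1 = 127 items per block, hence 30 occurrences of
#' every transition over 10 blocks.
#'
#' @inheritParams generate_scanner_run
#' @return A [stimulus_sequence()].
#' @export
generate_behaviour_block <- function(nodes, reps_per_transition = 3L, seed) {
  balanced_sequence(nodes, reps_per_transition, seed, "behaviour_block")
}

balanced_sequence <- function(nodes, reps, seed, design) {
  nodes <- as.character(nodes)
  if (length(nodes) < 2L) stop("need at least two objects")
  if (anyDuplicated(nodes)) stop("node labels must be unique")
  if (!is.numeric(reps) || length(reps) != 1L || reps < 1L) {
    stop("'reps_per_transition' must be a positive integer")
  }
  items <- with_seed(derive_seed(seed, paste0(design, "_circuit")),
                     eulerian_balanced_sequence(nodes, as.integer(reps)))
  ori <- with_seed(derive_seed(seed, paste0(design, "_orientation")),
                   sample(c("normal", "mirrored"), length(items),
                          replace = TRUE))
  stimulus_sequence(items, nodes = nodes, orientation = ori,
                    design = design, seed = seed)
}

#' Annotate a balanced run with the cover task
#'
#' Adds the attention cover task to a scanner run: a grey patch on a random
#' fraction of objects, and probe (report) trials placed so that each ordered
#' transition is probed exactly `probes_per_transition` times — for one probe
#' per transition, 42 probes in a 421-item run, i.e. 10% of the 420
#' transition trials.  Probe trials and the two following trials are marked
#' excluded, mirroring the button-press exclusion rule.
#'
#' @param seq a [stimulus_sequence()] from [generate_scanner_run()].
#' @param patch_prob probability an object carries the patch.
#' @param probes_per_transition probes per ordered transition type.
#' @param seed integer seed.
#' @return The sequence with `patch`, `probe` and `excluded` flags set.
#' @export
annotate_cover_task <- function(seq, patch_prob = 0.5,
                                probes_per_transition = 1L, seed) {
  stopifnot(inherits(seq, "stimulus_sequence"),
            patch_prob >= 0, patch_prob <= 1)
  n <- length(seq$items)
  key <- paste(seq$items[-n], seq$items[-1L], sep = "\r")
  occ <- split(seq_len(n - 1L) + 1L, key)   # trial index completing each pair
  short <- vapply(occ, length, 0L) < probes_per_transition
  if (any(short)) {
    stop("not enough occurrences to place ", probes_per_transition,
         " probe(s) for transition(s): ",
         paste(gsub("\r", "->", names(occ)[short]), collapse = ", "))
  }
  probe_pos <- with_seed(derive_seed(seed, "cover_probes"), {
    unlist(lapply(occ, function(p) {
      if (length(p) == 1L) p else sample(p, probes_per_transition)
    }), use.names = FALSE)
  })
  probe <- logical(n)
  probe[probe_pos] <- TRUE
  patch <- with_seed(derive_seed(seed, "cover_patch"),
                     stats::runif(n) < patch_prob)
  excluded <- logical(n)
  for (off in 0:2) {
    idx <- probe_pos + off
    excluded[idx[idx <= n]] <- TRUE
  }
  seq$patch <- patch
  seq$probe <- probe
  seq$excluded <- excluded
  seq
}

#' Directed transition counts of a sequence
#'
#' @param seq a [stimulus_sequence()].
#' @return Integer matrix over the node universe; entry (i, j) counts trials
#'   on which j was preceded by i.  The diagonal is zero since objects never
#'   repeat.
#' @export
transition_counts <- function(seq) {
  stopifnot(inherits(seq, "stimulus_sequence"))
  nodes <- seq$nodes
  m <- matrix(0L, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  n <- length(seq$items)
  if (n >= 2L) {
    idx <- cbind(match(seq$items[-n], nodes), match(seq$items[-1L], nodes))
    for (r in seq_len(nrow(idx))) {
      m[idx[r, 1L], idx[r, 2L]] <- m[idx[r, 1L], idx[r, 2L]] + 1L
    }
  }
  m
}

#' Mean temporal gap between object pairs
#'
#' For each ordered pair (i, j), the mean number of items that occurred
#' between an occurrence of j and the most recent prior occurrence of i
#' (0 when i immediately precedes j).  Since presentation and inter-trial
#' timing were constant during training, this is proportional to the average
#' time elapsed between the two objects, the temporal-proximity regressor
#' that competes with link distance.
#'
#' @param seq a [stimulus_sequence()].
#' @param symmetrise average the (i, j) and (j, i) entries (the form used as
#'   a regressor); set `FALSE` for raw directed gaps.
#' @return Numeric matrix over the node universe; `NA` for pairs that never
#'   co-occurred (and on the diagonal).
#' @export
mean_gap_matrix <- function(seq, symmetrise = TRUE) {
  stopifnot(inherits(seq, "stimulus_sequence"))
  nodes <- seq$nodes
  n <- length(nodes)
  pos <- split(seq_along(seq$items), factor(seq$items, levels = nodes))
  g <- matrix(NA_real_, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(n)) {
    pi <- pos[[i]]
    if (!length(pi)) next
    for (j in seq_len(n)) {
      if (i == j) next
      pj <- pos[[j]]
      if (!length(pj)) next
      ## for each occurrence of j, nearest prior occurrence of i
      prev_idx <- findInterval(pj - 1L, pi)
      keep <- prev_idx >= 1L
      if (!any(keep)) next
      gaps <- pj[keep] - pi[prev_idx[keep]] - 1L
      g[i, j] <- mean(gaps)
    }
  }
  if (symmetrise) {
    both <- !is.na(g) & !is.na(t(g))
    one <- is.na(g) & !is.na(t(g))
    sym <- g
    sym[both] <- ((g + t(g)) / 2)[both]
    sym[one] <- t(g)[one]
    g <- sym
  }
  g
}

#' Per-object presentation counts
#'
#' @param seq a [stimulus_sequence()].
#' @return Named integer vector over the node universe, summing to the
#'   sequence length.
#' @export
presentation_counts <- function(seq) {
  stopifnot(inherits(seq, "stimulus_sequence"))
  tab <- table(factor(seq$items, levels = seq$nodes))
  stats::setNames(as.integer(tab), seq$nodes)
}

#' Write a sequence as a BIDS-style events table
#'
#' Synthesises onsets from a constant stimulus duration plus jittered
#' inter-trial intervals drawn from a truncated Poisson distribution (mean
#' 2 s in the published design), and writes one row per trial with columns
#' `onset`, `duration`, `object`, `predecessor`, `orientation`, `patch`,
#' `probe`, `excluded`.
#'
#' @param seq a [stimulus_sequence()].
#' @param path output TSV path.
#' @param stim_duration stimulus duration in seconds (1 s scanner, 2 s
#'   training).
#' @param iti_mean,iti_min,iti_max truncated-Poisson inter-trial interval
#'   parameters in seconds.
#' @param seed integer seed for the jitter.
#' @return The events data frame, invisibly.
#' @export
write_events_tsv <- function(seq, path, stim_duration = 1,
                             iti_mean = 2, iti_min = 1, iti_max = 5,
                             seed = 1L) {
  stopifnot(inherits(seq, "stimulus_sequence"), iti_min <= iti_max)
  n <- length(seq$items)
  iti <- with_seed(derive_seed(seed, "events_iti"), {
    draw <- stats::rpois(n, iti_mean)
    while (any(bad <- draw < iti_min | draw > iti_max)) {
      draw[bad] <- stats::rpois(sum(bad), iti_mean)
    }
    draw
  })
  onset <- cumsum(c(0, rep(stim_duration, n - 1L) + iti[-n]))
  ev <- data.frame(onset = onset, duration = stim_duration,
                   object = seq$items,
                   predecessor = c(NA, seq$items[-n]),
                   orientation = seq$orientation, patch = seq$patch,
                   probe = seq$probe, excluded = seq$excluded,
                   stringsAsFactors = FALSE)
  utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "n/a")
  invisible(ev)
}
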