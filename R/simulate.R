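#' Cohort configuration for synthetic subjects
#'
#' Bundles the generative parameters shared by the adaptation and
#' response-time simulators.  The generative model is the minimal structure
#' the downstream analyses presuppose: a per-subject response to the ordered
#' transition i -> j equal to
#' `beta_metric * m(i, j) + object_effect(j) + noise`, with a proximity
#' metric m, Gaussian per-object offsets (the object main effects that the
#' demeaning controls remove) and Gaussian trial noise.
#'
#' @param n_subjects number of subjects (23 in the scanned cohort, 26 in the
#'   behavioural cohort).
#' @param generative_metric metric generating the distance signal: one of
#'   `"link"`, `"euclidean"`, `"communicability"`, `"successor"`.
#' @param beta_metric generative slope on the metric.
#' @param object_effect_sd standard deviation of per-subject, per-object
#'   offsets.
#' @param noise_sd standard deviation of trial noise.
#' @param rt_baseline baseline log response time (log-milliseconds) for the
#'   response-time simulator.
#' @param gamma_fraction successor-representation discount fraction.
#' @param seed integer seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 23L, generative_metric = "communicability",
                          beta_metric = 1, object_effect_sd = 0.5,
                          noise_sd = 1, rt_baseline = log(700),
                          gamma_fraction = 0.85, seed = 1L) {
  generative_metric <- match.arg(generative_metric,
                                 c("link", "euclidean", "communicability",
                                   "successor"))
  stopifnot(n_subjects >= 2L, object_effect_sd >= 0, noise_sd >= 0,
            gamma_fraction >= 0, gamma_fraction < 1)
  structure(list(n_subjects = as.integer(n_subjects),
                 generative_metric = generative_metric,
                 beta_metric = beta_metric,
                 object_effect_sd = object_effect_sd,
                 noise_sd = noise_sd, rt_baseline = rt_baseline,
                 gamma_fraction = gamma_fraction,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Simulate a cohort of per-transition adaptation estimates
#'
#' For every subject and every ordered pair of distinct objects, draws one
#' scalar adaptation parameter estimate under the configured generative
#' model.  The sign convention matches repetition suppression: responses
#' *increase* with distance-like regressors (suppression for close pairs),
#' so the communicability and successor metrics enter through their negated
#' (regressor) forms.
#'
#' @param config a [cohort_config()].
#' @param graph a [relational_graph()].
#' @return A data frame of class `transition_cohort` with columns `subject`,
#'   `predecessor`, `object`, `response` (n_subjects x n(n-1) rows), and
#'   attributes `nodes` and `config`.
#' @export
simulate_adaptation_cohort <- function(config, graph) {
  stopifnot(inherits(config, "cohort_config"),
            inherits(graph, "relational_graph"))
  m <- proximity_regressor(graph, config$generative_metric,
                           config$gamma_fraction)
  pairs <- ordered_pairs(graph$nodes)
  mvals <- unclass(m)[cbind(pairs$pred, pairs$obj)]
  out <- with_seed(derive_seed(config$seed, "adaptation_cohort"), {
    do.call(rbind, lapply(seq_len(config$n_subjects), function(s) {
      u <- stats::setNames(stats::rnorm(length(graph$nodes), 0,
                                        config$object_effect_sd),
                           graph$nodes)
      data.frame(subject = s, predecessor = pairs$pred, obj = pairs$obj,
                 response = config$beta_metric * mvals + u[pairs$obj] +
                   stats::rnorm(nrow(pairs), 0, config$noise_sd),
                 stringsAsFactors = FALSE)
    }))
  })
  names(out)[names(out) == "obj"] <- "object"
  transition_cohort(out, graph$nodes, config)
}

transition_cohort <- function(df, nodes, config = NULL) {
  rownames(df) <- NULL
  structure(df, nodes = nodes, config = config,
            class = c("transition_cohort", "data.frame"))
}

#' Simulate a behavioural response-time cohort
#'
#' Generates, per subject, `blocks` balanced test blocks (via
#' [generate_behaviour_block()]) and per-trial response times under the
#' generative model: log RT = `rt_baseline` + object effect + `beta_metric`
#' x metric(predecessor, object) + Gaussian noise.  Response times are
#' returned in milliseconds.  The first trial of each block has no
#' predecessor and receives no metric contribution.
#'
#' @param config a [cohort_config()].
#' @param graph a [relational_graph()] (the metric is computed on it; its
#'   nodes are the presented objects).
#' @param blocks test blocks per subject (10 in the published design).
#' @param reps repetitions of each ordered transition per block (3 in the
#'   published design).
#' @param error_rate probability a trial is flagged incorrect.
#' @return A data frame of class `rt_trials` with columns `subject`,
#'   `block`, `trial`, `predecessor`, `object`, `rt_ms`, `correct`.
#' @export
simulate_rt_cohort <- function(config, graph, blocks = 10L, reps = 3L,
                               error_rate = 0) {
  stopifnot(inherits(config, "cohort_config"),
            inherits(graph, "relational_graph"),
            error_rate >= 0, error_rate < 1)
  m <- proximity_regressor(graph, config$generative_metric,
                           config$gamma_fraction)
  nodes <- graph$nodes
  rows <- vector("list", config$n_subjects * blocks)
  k <- 0L
  for (s in seq_len(config$n_subjects)) {
    u <- with_seed(derive_seed(config$seed, paste0("rt_object_effects_", s)),
                   stats::setNames(stats::rnorm(length(nodes), 0,
                                                config$object_effect_sd),
                                   nodes))
    for (b in seq_len(blocks)) {
      sq <- generate_behaviour_block(
        nodes, reps,
        seed = derive_seed(config$seed, paste0("rt_seq_", s, "_", b)))
      n <- length(sq$items)
      pred <- c(NA, sq$items[-n])
      metric_term <- c(0, unclass(m)[cbind(pred[-1L], sq$items[-1L])])
      noise <- with_seed(derive_seed(config$seed,
                                     paste0("rt_noise_", s, "_", b)),
                         stats::rnorm(n, 0, config$noise_sd))
      correct <- with_seed(derive_seed(config$seed,
                                       paste0("rt_correct_", s, "_", b)),
                           stats::runif(n) >= error_rate)
      k <- k + 1L
      rows[[k]] <- data.frame(
        subject = s, block = b, trial = seq_len(n), predecessor = pred,
        object = sq$items,
        rt_ms = exp(config$rt_baseline + u[sq$items] +
                      config$beta_metric * metric_term + noise),
        correct = correct, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, nodes = nodes, config = config,
            class = c("rt_trials", "data.frame"))
}

#' Simulate training histories (transition-count matrices)
#'
#' Per subject, generates the day-1 training blocks as constrained random
#' walks on the training graph and aggregates directed transition counts
#' over all blocks.  Finite random walks naturally experience the two
#' directions of a link unequally often, which is what the asymmetry-index
#' and experience-weighted shortest-path analyses exploit.
#'
#' @param graph the training [relational_graph()].
#' @param n_subjects number of subjects.
#' @param blocks training blocks per subject (12 in the published design).
#' @param items_per_block items per block (133 in the published design).
#' @param exclusion_window repeat-exclusion window for the walk.
#' @param seed integer seed.
#' @return A list of directed count matrices, one per subject.
#' @export
simulate_training_histories <- function(graph, n_subjects = 23L,
                                        blocks = 12L, items_per_block = 133L,
                                        exclusion_window = 3L, seed = 1L) {
  stopifnot(inherits(graph, "relational_graph"))
  lapply(seq_len(n_subjects), function(s) {
    total <- NULL
    for (b in seq_len(blocks)) {
      sq <- generate_training_walk(
        graph, n_items = items_per_block,
        exclusion_window = exclusion_window,
        seed = derive_seed(seed, paste0("training_", s, "_", b)))
      cnt <- transition_counts(sq)
      total <- if (is.null(total)) cnt else total + cnt
    }
    total
  })
}

#' Write / read a transition cohort as CSV
#'
#' Plain-text interchange format: columns `subject`, `predecessor`,
#' `object`, `response`.
#'
#' @param cohort a `transition_cohort` data frame.
#' @param path CSV path.
#' @return `write_cohort_csv`: `path` invisibly; `read_cohort_csv`: a
#'   `transition_cohort`.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort)[, c("subject", "predecessor",
                                             "object", "response")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @param nodes node universe; defaults to the labels present.
#' @export
read_cohort_csv <- function(path, nodes = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(predecessor = "character",
                                       object = "character"))
  need <- c("subject", "predecessor", "object", "response")
  if (!all(need %in% names(df))) {
    stop("cohort CSV must have columns: ", paste(need, collapse = ", "))
  }
  if (is.null(nodes)) nodes <- sort(unique(c(df$predecessor, df$object)))
  transition_cohort(df[, need], nodes)
}
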