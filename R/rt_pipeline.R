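#' Preprocess response-time trials into per-transition measures
#'
#' The behavioural analysis chain: response times are log-transformed;
#' each subject's mean log RT for each *object* is subtracted (removing
#' object main effects such as recognisability); demeaned values are
#' averaged per ordered transition within each block; and block means are
#' averaged across blocks, yielding one value per ordered pair per subject.
#' The first trial of each block (no predecessor) never enters.
#'
#' @param trials an `rt_trials` data frame (columns `subject`, `block`,
#'   `trial`, `predecessor`, `object`, `rt_ms`, `correct`), e.g. from
#'   [simulate_rt_cohort()].
#' @param exclude_incorrect drop trials flagged incorrect before any
#'   averaging (default).
#' @return A `transition_cohort` data frame of demeaned log RTs (columns
#'   `subject`, `predecessor`, `object`, `response`).
#' @export
preprocess_rt <- function(trials, exclude_incorrect = TRUE) {
  stopifnot(is.data.frame(trials),
            all(c("subject", "block", "predecessor", "object", "rt_ms") %in%
                  names(trials)))
  if (any(trials$rt_ms <= 0)) stop("response times must be positive")
  keep <- rep(TRUE, nrow(trials))
  if (exclude_incorrect && "correct" %in% names(trials)) {
    keep <- keep & trials$correct
  }
  tr <- trials[keep, , drop = FALSE]
  tr$logrt <- log(tr$rt_ms)
  ## per-subject object demeaning, across all blocks
  obj_key <- interaction(tr$subject, tr$object, drop = TRUE)
  tr$dem <- tr$logrt - stats::ave(tr$logrt, obj_key)
  tr <- tr[!is.na(tr$predecessor), , drop = FALSE]

  nodes <- attr(trials, "nodes")
  if (is.null(nodes)) nodes <- sort(unique(as.character(trials$object)))
  subjects <- unique(tr$subject)
  blocks <- sort(unique(tr$block))
  pairs <- ordered_pairs(nodes)
  pair_key <- paste(pairs$pred, pairs$obj, sep = "\r")

  out <- vector("list", length(subjects))
  for (si in seq_along(subjects)) {
    s <- subjects[si]
    rows <- tr[tr$subject == s, , drop = FALSE]
    block_means <- matrix(NA_real_, length(pair_key), length(blocks),
                          dimnames = list(pair_key, blocks))
    for (bi in seq_along(blocks)) {
      b <- rows[rows$block == blocks[bi], , drop = FALSE]
      key <- paste(b$predecessor, b$object, sep = "\r")
      mns <- tapply(b$dem, key, mean)
      missing <- setdiff(pair_key, names(mns))
      if (length(missing)) {
        stop("subject ", s, ", block ", blocks[bi],
             ": no trials for transition(s) ",
             paste(gsub("\r", "->", missing), collapse = ", "))
      }
      block_means[, bi] <- mns[pair_key]
    }
    out[[si]] <- data.frame(subject = s, predecessor = pairs$pred,
                            object = pairs$obj,
                            response = rowMeans(block_means),
                            stringsAsFactors = FALSE)
  }
  transition_cohort(do.call(rbind, out), nodes, attr(trials, "config"))
}

#' Regression of proximity metrics on response times
#'
#' The behavioural counterpart of the neural competitive regression: the
#' standard model regresses communicability, link distance and Euclidean
#' distance jointly onto each subject's per-transition demeaned log RTs,
#' with group-level two-tailed t-tests on the coefficients.  Shares its
#' implementation with [transition_regression()].
#'
#' @param responses a `transition_cohort` from [preprocess_rt()].
#' @param regressors named list of proximity matrices; the default for a
#'   supplied `graph` is `list(communicability, link, euclidean)`.
#' @param graph optional [relational_graph()] used to build the default
#'   regressor set.
#' @param ... passed to [transition_regression()].
#' @return A `transition_regression` object.
#' @export
rt_regression <- function(responses, regressors = NULL, graph = NULL, ...) {
  if (is.null(regressors)) {
    if (is.null(graph)) {
      stop("supply either 'regressors' or a 'graph' for the default set")
    }
    regressors <- list(
      communicability = communicability_matrix(graph),
      link = link_distance_matrix(graph),
      euclidean = euclidean_distance_matrix(graph))
  }
  transition_regression(responses, regressors, ...)
}

#' Bin transitions by communicability
#'
#' Visualisation summary of the communicability effect: ordered transitions
#' are sorted by their communicability value and split into `n_bins` bins
#' with an equal number of transitions per bin (ties broken by stable pair
#' order; when the pair count is not divisible, the leading bins take the
#' remainder).  Reports the across-subject mean response per bin.
#'
#' @param responses a `transition_cohort` (e.g. demeaned log RTs).
#' @param comm communicability proximity matrix.
#' @param n_bins number of bins (6 in the published figure).
#' @return Data frame with one row per bin: `bin`, `n_pairs`,
#'   `mean_communicability`, `mean_response`, `sem_response`.
#' @export
communicability_bins <- function(responses, comm, n_bins = 6L) {
  stopifnot(is.data.frame(responses))
  comm <- as.matrix(comm)
  nodes <- attr(responses, "nodes")
  if (is.null(nodes)) {
    nodes <- sort(unique(c(as.character(responses$predecessor),
                           as.character(responses$object))))
  }
  pairs <- ordered_pairs(nodes)
  n_pairs <- nrow(pairs)
  if (n_bins > n_pairs) {
    stop("cannot form ", n_bins, " bins from ", n_pairs, " transitions")
  }
  cvals <- comm[cbind(pairs$pred, pairs$obj)]
  ord <- order(cvals)            # stable: ties keep pair order
  sizes <- rep(n_pairs %/% n_bins, n_bins)
  extra <- n_pairs %% n_bins
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  bin_of_sorted <- rep(seq_len(n_bins), times = sizes)
  bin <- integer(n_pairs)
  bin[ord] <- bin_of_sorted
  pair_bin <- stats::setNames(bin, paste(pairs$pred, pairs$obj, sep = "\r"))

  ## per-subject bin means first, then across-subject mean and SEM
  key <- paste(responses$predecessor, responses$object, sep = "\r")
  b <- pair_bin[key]
  subjects <- unique(responses$subject)
  subj_bin <- vapply(subjects, function(s) {
    rows <- responses$subject == s
    vapply(seq_len(n_bins),
           function(k) mean(responses$response[rows & b == k]), 0)
  }, numeric(n_bins))
  subj_bin <- matrix(subj_bin, nrow = n_bins)
  data.frame(bin = seq_len(n_bins), n_pairs = sizes,
             mean_communicability = vapply(seq_len(n_bins),
                                           function(k) mean(cvals[bin == k]), 0),
             mean_response = rowMeans(subj_bin),
             sem_response = apply(subj_bin, 1L, stats::sd) /
               sqrt(length(subjects)))
}
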