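#' Group-average transition matrix
#'
#' Averages per-transition responses across subjects into an n x n matrix:
#' entry (i, j) is the mean response to object j when preceded by object i.
#' Objects never repeat, so the diagonal is fixed at 0.  Because adaptation
#' responses scale with distance, this matrix is effectively a (directed)
#' distance matrix over objects and is the input to map recovery.
#'
#' @param cohort a `transition_cohort` data frame; every subject must cover
#'   the same ordered pairs.
#' @return Square numeric matrix with node labels as dimnames and zero
#'   diagonal.
#' @export
group_transition_matrix <- function(cohort) {
  stopifnot(is.data.frame(cohort),
            all(c("subject", "predecessor", "object", "response") %in%
                  names(cohort)))
  nodes <- attr(cohort, "nodes")
  if (is.null(nodes)) {
    nodes <- sort(unique(c(as.character(cohort$predecessor),
                           as.character(cohort$object))))
  }
  key <- paste(cohort$predecessor, cohort$object, sep = "\r")
  cov_by_subj <- tapply(key, cohort$subject, function(k) sort(unique(k)))
  if (length(unique(vapply(cov_by_subj, paste, "", collapse = ";"))) > 1L) {
    stop("subjects do not cover identical transition pairs")
  }
  means <- tapply(cohort$response, key, mean)
  m <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  pk <- strsplit(names(means), "\r", fixed = TRUE)
  i <- vapply(pk, `[`, "", 1L)
  j <- vapply(pk, `[`, "", 2L)
  m[cbind(i, j)] <- means
  diag(m) <- 0
  m
}

#' Prepare a dissimilarity matrix for multidimensional scaling
#'
#' MDS requires a symmetric matrix of positive dissimilarities.  The group
#' transition matrix is symmetrised by averaging its upper and lower
#' triangles and shifted so the smallest off-diagonal entry is exactly 1;
#' the diagonal is reset to 0 (an object is at distance zero from itself).
#' The shift is a monotone transformation, so it cannot affect nonmetric
#' MDS or rank-based statistics.
#'
#' @param m square matrix (e.g. from [group_transition_matrix()]).
#' @return Symmetric matrix with zero diagonal and off-diagonal minimum 1.
#' @export
prepare_dissimilarity <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("'m' must be square")
  s <- (m + t(m)) / 2
  off <- row(s) != col(s)
  s[off] <- s[off] - min(s[off]) + 1
  diag(s) <- 0
  s
}

#' Embed a dissimilarity matrix by multidimensional scaling
#'
#' Nonmetric (Kruskal stress-1) scaling by default, with multiple seeded
#' restarts: the first initial configuration is the classical (metric)
#' solution, the rest are random Gaussian configurations, and the
#' lowest-stress solution is kept.  Metric (classical) scaling is available
#' via `method = "metric"`.
#'
#' @param dissimilarity symmetric non-negative matrix with zero diagonal.
#' @param n_dims embedding dimension (2 for map recovery).
#' @param seed integer seed (used for the random restarts).
#' @param method `"nonmetric"` (default) or `"metric"`.
#' @param restarts number of initial configurations for nonmetric scaling.
#' @return Numeric matrix of coordinates (nodes x n_dims) with node labels
#'   as rownames and, for nonmetric scaling, attribute `stress` (Kruskal
#'   stress-1, in percent).
#' @export
mds_embed <- function(dissimilarity, n_dims = 2L, seed = 1L,
                      method = c("nonmetric", "metric"), restarts = 20L) {
  method <- match.arg(method)
  d <- as.matrix(dissimilarity)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-8)) {
    stop("'dissimilarity' must be a symmetric square matrix")
  }
  if (any(diag(d) != 0)) stop("'dissimilarity' must have a zero diagonal")
  off <- d[row(d) != col(d)]
  if (any(off < 0)) stop("dissimilarities must be non-negative")
  if (stats::sd(off) == 0) {
    stop("degenerate dissimilarity matrix: all off-diagonal values equal")
  }
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(d)))

  if (method == "metric") {
    y <- stats::cmdscale(d, k = n_dims)
    rownames(y) <- labels
    return(y)
  }
  n <- nrow(d)
  with_seed(derive_seed(seed, "mds_embed"), {
    best <- NULL
    for (r in seq_len(restarts)) {
      init <- if (r == 1L) {
        stats::cmdscale(d, k = n_dims)
      } else {
        matrix(stats::rnorm(n * n_dims), n, n_dims)
      }
      fit <- tryCatch(
        suppressWarnings(MASS::isoMDS(d, y = init, k = n_dims, trace = FALSE)),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$stress < best$stress)) {
        best <- fit
      }
    }
    if (is.null(best)) stop("nonmetric MDS failed for every restart")
    y <- best$points
    dimnames(y) <- list(labels, NULL)
    attr(y, "stress") <- best$stress
    y
  })
}

#' Permutation test of map recovery against the graph-topology null
#'
#' Quantifies how well a two-dimensional embedding recovers the true graph:
#' the observed statistic is the Pearson correlation between embedded
#' pairwise distances and the graph's link distances (upper-triangle pairs);
#' its significance is the fraction of null-ensemble graphs whose link
#' distances correlate with the same embedding at least as strongly.  As a
#' second characterisation, the graph's links are drawn at the embedding and
#' crossings counted: a faithful 2-D map has none, while only a small
#' fraction of null topologies are crossing-free at the same coordinates.
#'
#' @param embedding coordinates from [mds_embed()] (rownames = node labels).
#' @param graph the true [relational_graph()].
#' @param ensemble a [enumerate_null_graphs()] ensemble on the same nodes.
#' @param method correlation method, `"pearson"` (default) or
#'   `"spearman"`.
#' @return An object of class `map_recovery`: `correlation_with_link`,
#'   `permutation_p`, `observed_crossings`, `null_crossing_fraction`,
#'   `null_correlations`, `embedding`.
#' @export
map_recovery_test <- function(embedding, graph, ensemble,
                              method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(graph, "relational_graph"),
            inherits(ensemble, "null_graph_ensemble"))
  if (!setequal(rownames(embedding), graph$nodes) ||
      !identical(ensemble$labels, graph$nodes)) {
    stop("embedding, graph and ensemble must share the same node set")
  }
  ## ensemble edge order is combn over node *indices*; align everything to it
  embedding <- as.matrix(embedding)[graph$nodes, , drop = FALSE]
  emb_dist <- upper_pairs(as.matrix(stats::dist(embedding)))
  link <- upper_pairs(unclass(link_distance_matrix(graph)))
  observed <- stats::cor(emb_dist, link, method = method)

  if (method == "spearman") {
    null_cor <- apply(ensemble$link_distances, 1L, stats::cor, y = emb_dist,
                      method = "spearman")
  } else {
    ## vectorised Pearson correlation of emb_dist with every null member
    x <- emb_dist - mean(emb_dist)
    ld <- ensemble$link_distances
    ldc <- ld - rowMeans(ld)
    null_cor <- as.vector(ldc %*% x) /
      (sqrt(rowSums(ldc^2)) * sqrt(sum(x^2)))
  }
  perm_p <- mean(null_cor >= observed)

  obs_cross <- count_line_crossings(embedding, graph$edges)
  null_cross <- batch_crossings(ensemble, embedding)
  structure(list(embedding = embedding,
                 correlation_with_link = observed,
                 permutation_p = perm_p,
                 observed_crossings = obs_cross,
                 null_crossing_fraction = mean(null_cross == 0),
                 null_correlations = null_cor,
                 null_crossings = null_cross,
                 method = method, graph = graph),
            class = "map_recovery")
}

#' @export
print.map_recovery <- function(x, digits = 4L, ...) {
  cat("Map recovery against", length(x$null_correlations),
      "null graph topologies\n")
  cat(sprintf("  correlation with link distance: r = %.*g (%s)\n",
              digits, x$correlation_with_link, x$method))
  cat(sprintf("  permutation p (null r >= observed): %.*g\n",
              digits, x$permutation_p))
  cat(sprintf("  line crossings at embedding: %d (%.2f%% of null graphs are crossing-free)\n",
              x$observed_crossings, 100 * x$null_crossing_fraction))
  invisible(x)
}

#' @export
plot.map_recovery <- function(x, ...) {
  g <- x$graph
  lay <- x$embedding
  plot(lay, asp = 1, pch = 21, bg = "grey80", cex = 2.4,
       xlab = "MDS dimension 1", ylab = "MDS dimension 2", ...)
  segments(lay[g$edges[, 1L], 1L], lay[g$edges[, 1L], 2L],
           lay[g$edges[, 2L], 1L], lay[g$edges[, 2L], 2L])
  points(lay, pch = 21, bg = "grey80", cex = 2.4)
  text(lay, labels = rownames(lay), cex = 0.7)
  invisible(x)
}

#' Full map-recovery pipeline from a cohort
#'
#' Convenience wrapper chaining [group_transition_matrix()],
#' [prepare_dissimilarity()], [mds_embed()] and [map_recovery_test()].
#'
#' @param cohort a `transition_cohort`.
#' @param graph the true [relational_graph()].
#' @param ensemble optional pre-computed null ensemble; enumerated from the
#'   graph's node and edge counts when `NULL`.
#' @param seed seed for the MDS restarts.
#' @param mds_method passed to [mds_embed()].
#' @return A `map_recovery` object.
#' @export
recover_map <- function(cohort, graph, ensemble = NULL, seed = 1L,
                        mds_method = "nonmetric") {
  if (is.null(ensemble)) {
    ensemble <- enumerate_null_graphs(length(graph$nodes),
                                      nrow(graph$edges),
                                      labels = graph$nodes)
  }
  diss <- prepare_dissimilarity(group_transition_matrix(cohort))
  emb <- mds_embed(diss, n_dims = 2L, seed = seed, method = mds_method)
  map_recovery_test(emb, graph, ensemble)
}
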