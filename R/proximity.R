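## Pairwise proximity / distance metrics over a relational graph.
##
## All constructors return a plain numeric matrix with node labels as
## dimnames and two attributes: `metric` (character) and `params` (list).
## These matrices are used directly as regressors in the analysis pipelines.

proximity <- function(values, metric, params = list()) {
  structure(values, metric = metric, params = params)
}

#' Link-distance matrix
#'
#' Entry (i, j) is the minimum number of links on a path between nodes i and
#' j; the coarsest notion of distance on the graph (1, 2 or 3 on the default
#' reduced graph).
#'
#' @param graph a [relational_graph()].
#' @return Symmetric integer-valued matrix with zero diagonal; attribute
#'   `metric = "link"`.
#' @export
link_distance_matrix <- function(graph) {
  stopifnot(inherits(graph, "relational_graph"))
  d <- igraph::distances(as_igraph(graph))
  d <- d[graph$nodes, graph$nodes]
  if (any(!is.finite(d))) {
    bad <- which(!is.finite(d), arr.ind = TRUE)[1L, ]
    stop("graph is not connected: no path between nodes '",
         graph$nodes[bad[1L]], "' and '", graph$nodes[bad[2L]], "'")
  }
  proximity(d, "link")
}

#' Euclidean distance matrix from the graph layout
#'
#' Straight-line distances between the layout coordinates of each pair of
#' nodes.  With the default reduced graph's unit-edge layout, all linked
#' pairs are at distance 1, mirroring the idealised planar embedding used as
#' the Euclidean regressor.
#'
#' @param graph a [relational_graph()] with a layout.
#' @return Symmetric matrix with zero diagonal; attribute `metric =
#'   "euclidean"`.
#' @export
euclidean_distance_matrix <- function(graph) {
  stopifnot(inherits(graph, "relational_graph"))
  if (is.null(graph$layout)) {
    stop("graph has no layout; Euclidean distances are undefined")
  }
  d <- as.matrix(stats::dist(graph$layout))
  proximity(d[graph$nodes, graph$nodes], "euclidean")
}

#' Communicability matrix (negative matrix exponential)
#'
#' Communicability sums walks of every length between two nodes, discounting
#' a walk of length n by 1/n!; it is large for well-connected pairs.  Because
#' neural adaptation *increases* with distance, the analysis regressor is the
#' negative of the matrix exponential of the adjacency matrix, and that is
#' what this function returns: entry (i, j) = -[exp(A)]_{ij}.
#'
#' @param graph a [relational_graph()].
#' @return Symmetric matrix; attribute `metric = "communicability"`.
#' @export
communicability_matrix <- function(graph) {
  stopifnot(inherits(graph, "relational_graph"))
  a <- adjacency_matrix(graph)
  e <- as.matrix(Matrix::expm(Matrix::Matrix(a)))
  dimnames(e) <- dimnames(a)
  proximity(-e, "communicability")
}

#' Successor-representation matrix
#'
#' The successor representation is the discounted expected occupancy of
#' future states, \eqn{\sum_n \gamma^n A^n = (I - \gamma A)^{-1}} for
#' adjacency matrix A and discount \eqn{\gamma}; in graph theory the same
#' object is the matrix resolvent.  The geometric series converges only for
#' \eqn{\gamma \lambda_{max} < 1}, where \eqn{\lambda_{max}} is the spectral
#' radius of A, so the discount is parameterised as a *fraction* of the
#' critical value: \eqn{\gamma = } `gamma_fraction` \eqn{/ \lambda_{max}}.
#' The conventional choice is `gamma_fraction = 0.85`.
#'
#' This function returns the resolvent itself.  As an analysis regressor the
#' *negative* successor representation is used (adaptation responses grow
#' with distance); see [proximity_regressor()].
#'
#' @param graph a [relational_graph()].
#' @param gamma_fraction discount as a fraction of `1 / lambda_max`, in
#'   `[0, 1)`.
#' @return Symmetric matrix; attribute `metric = "successor"`, with
#'   `params$gamma` and `params$lambda_max`.
#' @export
successor_representation_matrix <- function(graph, gamma_fraction = 0.85) {
  stopifnot(inherits(graph, "relational_graph"),
            is.numeric(gamma_fraction), length(gamma_fraction) == 1L)
  if (gamma_fraction < 0 || gamma_fraction >= 1) {
    stop("'gamma_fraction' must lie in [0, 1): the successor series ",
         "diverges at or beyond the spectral radius")
  }
  a <- adjacency_matrix(graph)
  lambda_max <- max(abs(eigen(a, symmetric = TRUE,
                              only.values = TRUE)$values))
  gamma <- gamma_fraction / lambda_max
  sr <- solve(diag(nrow(a)) - gamma * a)
  dimnames(sr) <- dimnames(a)
  proximity(sr, "successor",
            params = list(gamma = gamma, gamma_fraction = gamma_fraction,
                          lambda_max = lambda_max))
}

#' Proximity regressor by name
#'
#' Convenience dispatcher returning the matrix used as an analysis regressor
#' for a named metric.  For `"successor"` this is the negative of
#' [successor_representation_matrix()] (responses scale with distance, i.e.
#' against expected future occupancy); `"communicability"` is already
#' returned in its negative-exponential regressor form.
#'
#' @param graph a [relational_graph()].
#' @param metric one of `"link"`, `"euclidean"`, `"communicability"`,
#'   `"successor"`.
#' @param gamma_fraction discount fraction for the successor metric.
#' @return A proximity matrix (see [link_distance_matrix()]).
#' @export
proximity_regressor <- function(graph, metric, gamma_fraction = 0.85) {
  switch(match.arg(metric, c("link", "euclidean", "communicability",
                             "successor")),
         link = link_distance_matrix(graph),
         euclidean = euclidean_distance_matrix(graph),
         communicability = communicability_matrix(graph),
         successor = {
           m <- successor_representation_matrix(graph, gamma_fraction)
           proximity(-unclass(m), "successor", attr(m, "params"))
         })
}

#' Asymmetry index of a transition pair
#'
#' For directed transition counts \eqn{xy} (j preceded by i) and \eqn{yx}
#' (i preceded by j), the asymmetry index is
#' \eqn{a = |xy - yx| / (xy + yx)}: 0 when the pair was experienced equally
#' often in both directions, 1 when only ever in one direction.
#'
#' @param counts square matrix of directed transition counts (entry (i, j) =
#'   number of times j was preceded by i).
#' @param i,j node labels or indices.
#' @return A number in `[0, 1]`.
#' @export
asymmetry_index <- function(counts, i, j) {
  counts <- as.matrix(counts)
  xy <- counts[i, j]
  yx <- counts[j, i]
  if (xy < 0 || yx < 0) stop("transition counts must be non-negative")
  if (xy + yx == 0) {
    stop("asymmetry index undefined: pair (", i, ", ", j,
         ") was never experienced in either direction")
  }
  abs(xy - yx) / (xy + yx)
}

#' Experience-weighted edge lengths
#'
#' Converts directed transition counts on the graph's links into directed
#' edge lengths via \eqn{d = 1 - c / (1 + c_{max})}, where c is the count for
#' that directed link and \eqn{c_{max}} the largest directed count over all
#' links.  Frequently experienced links become short; a link never
#' experienced in a given direction keeps length 1.
#'
#' @param counts square matrix of directed transition counts.
#' @param graph a [relational_graph()]; only its links receive lengths.
#' @return Data frame with columns `from`, `to`, `count`, `length`, one row
#'   per directed link (two per undirected edge).
#' @export
empirical_edge_lengths <- function(counts, graph) {
  stopifnot(inherits(graph, "relational_graph"))
  counts <- as.matrix(counts)
  e <- graph$edges
  from <- c(e[, 1L], e[, 2L])
  to <- c(e[, 2L], e[, 1L])
  c_dir <- counts[cbind(from, to)]
  cmax <- max(c_dir)
  if (cmax <= 0) stop("no link was ever experienced: cmax must be positive")
  data.frame(from = from, to = to, count = c_dir,
             length = 1 - c_dir / (1 + cmax),
             stringsAsFactors = FALSE)
}

#' Shortest paths over experience-weighted links
#'
#' Builds the directed graph whose arc weights are the experience-derived
#' edge lengths and returns, for every ordered node pair, the minimum total
#' weight over directed paths.  The symmetrised variant averages the two
#' directions of each pair, yielding the non-directional distance a map-like
#' representation would use.
#'
#' @param edge_weights data frame with columns `from`, `to`, `length`
#'   (e.g. from [empirical_edge_lengths()]); all lengths must be positive.
#' @param graph a [relational_graph()] supplying the node order.
#' @param symmetrise if `TRUE`, return the mean of the (i, j) and (j, i)
#'   path lengths.
#' @return A proximity matrix with attribute `metric =
#'   "weighted_shortest_path"` (symmetric when `symmetrise = TRUE`).
#' @export
directed_shortest_paths <- function(edge_weights, graph, symmetrise = FALSE) {
  stopifnot(inherits(graph, "relational_graph"),
            all(c("from", "to", "length") %in% names(edge_weights)))
  if (any(edge_weights$length <= 0)) {
    stop("all edge lengths must be positive")
  }
  ig <- igraph::make_empty_graph(n = length(graph$nodes), directed = TRUE)
  ig <- igraph::set_vertex_attr(ig, "name", value = graph$nodes)
  ends <- rbind(match(as.character(edge_weights$from), graph$nodes),
                match(as.character(edge_weights$to), graph$nodes))
  ig <- igraph::add_edges(ig, as.vector(ends))
  d <- igraph::distances(ig, mode = "out", weights = edge_weights$length)
  d <- d[graph$nodes, graph$nodes]
  if (any(!is.finite(d))) {
    bad <- which(!is.finite(d), arr.ind = TRUE)[1L, ]
    stop("no directed path from node '", graph$nodes[bad[1L]],
         "' to node '", graph$nodes[bad[2L]], "'")
  }
  if (symmetrise) d <- (d + t(d)) / 2
  proximity(d, "weighted_shortest_path",
            params = list(symmetrised = symmetrise))
}
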