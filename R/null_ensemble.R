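## Permutation null over graph topologies.
##
## The map-recovery test compares the observed graph against every connected
## simple graph with the same number of nodes and links.  For 7 nodes and 7
## links that is 68,295 graphs out of C(21, 7) = 116,280 candidate edge
## subsets.  Enumeration and per-member statistics are vectorised across the
## whole ensemble: adjacency matrices live in a G x n x n array and
## reachability is propagated by batched boolean matrix products.

## Batched link distances: `inc` is a G x m logical incidence matrix over the
## m = choose(n, 2) possible edges (combn order); returns a G x m matrix of
## pairwise link distances (Inf where unreachable).
batch_link_distances <- function(inc, n_nodes) {
  g <- nrow(inc)
  pairs <- utils::combn(n_nodes, 2L)
  m <- ncol(pairs)
  stopifnot(ncol(inc) == m)
  ## adjacency array
  a <- array(FALSE, dim = c(g, n_nodes, n_nodes))
  for (k in seq_len(m)) {
    a[, pairs[1L, k], pairs[2L, k]] <- inc[, k]
    a[, pairs[2L, k], pairs[1L, k]] <- inc[, k]
  }
  d <- array(Inf, dim = c(g, n_nodes, n_nodes))
  for (i in seq_len(n_nodes)) d[, i, i] <- 0
  reach <- a
  for (i in seq_len(n_nodes)) reach[, i, i] <- TRUE
  d[a] <- 1
  for (step in seq_len(n_nodes - 2L) + 1L) {
    new_reach <- array(FALSE, dim = c(g, n_nodes, n_nodes))
    for (i in seq_len(n_nodes)) {
      for (j in seq_len(n_nodes)) {
        acc <- logical(g)
        for (k in seq_len(n_nodes)) {
          acc <- acc | (reach[, i, k] & a[, k, j])
        }
        new_reach[, i, j] <- acc
      }
    }
    newly <- new_reach & !reach
    d[newly] <- step
    reach <- reach | new_reach
    if (all(reach)) break
  }
  out <- matrix(Inf, g, m)
  for (k in seq_len(m)) out[, k] <- d[, pairs[1L, k], pairs[2L, k]]
  out
}

#' Enumerate the null ensemble of connected graphs
#'
#' Exhaustively enumerates every simple graph on `n_nodes` labelled nodes
#' with exactly `n_edges` edges that is connected (every node reachable from
#' every other).  This is the permutation null for the map-recovery test:
#' the observed graph's links are reallocated to arbitrary node pairs, and
#' only connected reallocations are retained.  For 7 nodes and 7 edges the
#' ensemble has 68,295 members.
#'
#' Link distances for every member are computed during enumeration and
#' stored, so downstream correlation tests are a single vectorised pass.
#'
#' @param n_nodes number of labelled nodes.
#' @param n_edges number of edges; must be at least `n_nodes - 1`.
#' @param labels optional node labels (default `"1" ... "n"`).
#' @return An object of class `null_graph_ensemble`: a list with
#'   `n_nodes`, `n_edges`, `labels`, `edge_index` (m x 2 matrix of node
#'   indices for the m possible edges, combn order), `members` (G x m
#'   logical incidence matrix) and `link_distances` (G x m matrix).
#' @examples
#' enumerate_null_graphs(3, 2)$members
#' @export
enumerate_null_graphs <- function(n_nodes, n_edges,
                                  labels = as.character(seq_len(n_nodes))) {
  stopifnot(n_nodes >= 2L, length(labels) == n_nodes)
  m <- choose(n_nodes, 2L)
  if (n_edges < n_nodes - 1L) {
    stop("no connected graph on ", n_nodes, " nodes has fewer than ",
         n_nodes - 1L, " edges")
  }
  if (n_edges > m) stop("at most ", m, " edges fit on ", n_nodes, " nodes")
  n_cand <- choose(m, n_edges)
  if (n_cand > 5e6) {
    stop("enumeration infeasible: ", format(n_cand, big.mark = ","),
         " candidate edge sets")
  }
  subsets <- utils::combn(m, n_edges)          # n_edges x n_cand
  inc <- matrix(FALSE, ncol(subsets), m)
  inc[cbind(rep(seq_len(ncol(subsets)), each = n_edges),
            as.vector(subsets))] <- TRUE
  d <- batch_link_distances(inc, n_nodes)
  connected <- rowSums(is.finite(d)) == m
  structure(list(n_nodes = n_nodes, n_edges = n_edges, labels = labels,
                 edge_index = t(utils::combn(n_nodes, 2L)),
                 members = inc[connected, , drop = FALSE],
                 link_distances = d[connected, , drop = FALSE]),
            class = "null_graph_ensemble")
}

#' @export
print.null_graph_ensemble <- function(x, ...) {
  cat("Null graph ensemble:", nrow(x$members), "connected graphs on",
      x$n_nodes, "nodes with", x$n_edges, "edges\n")
  invisible(x)
}

#' Number of line crossings in a drawn graph
#'
#' Counts unordered pairs of edges whose open segments intersect when the
#' graph is drawn at the given layout.  A faithful two-dimensional map has
#' none.  Edge pairs sharing an endpoint never count; collinear segments
#' overlapping over a stretch of positive length count as one crossing.
#'
#' @param layout numeric matrix of `(x, y)` coordinates with node labels as
#'   rownames (or a [relational_graph()], whose layout and edges are used).
#' @param edges two-column matrix of node labels; ignored when `layout` is a
#'   graph.
#' @return Integer crossing count.
#' @examples
#' sq <- rbind(a = c(0, 0), b = c(1, 0), c = c(1, 1), d = c(0, 1))
#' count_line_crossings(sq, rbind(c("a", "c"), c("b", "d")))  # the diagonals
#' @export
count_line_crossings <- function(layout, edges) {
  if (inherits(layout, "relational_graph")) {
    edges <- layout$edges
    layout <- layout$layout
  }
  layout <- as.matrix(layout)
  edges <- as.matrix(edges)
  storage.mode(edges) <- "character"
  missing <- setdiff(c(edges), rownames(layout))
  if (length(missing)) {
    stop("layout missing coordinates for node(s): ",
         paste(missing, collapse = ", "))
  }
  ne <- nrow(edges)
  if (ne < 2L) return(0L)
  n_cross <- 0L
  for (i in seq_len(ne - 1L)) {
    for (j in (i + 1L):ne) {
      if (length(intersect(edges[i, ], edges[j, ]))) next
      if (segments_cross(layout[edges[i, 1L], ], layout[edges[i, 2L], ],
                         layout[edges[j, 1L], ], layout[edges[j, 2L], ])) {
        n_cross <- n_cross + 1L
      }
    }
  }
  n_cross
}

## Do the open segments p1-p2 and p3-p4 intersect?  Proper crossings only
## (each segment strictly straddles the other's supporting line), except
## that collinear overlap of positive length also counts.
segments_cross <- function(p1, p2, p3, p4) {
  orient <- function(a, b, c) {
    (b[1L] - a[1L]) * (c[2L] - a[2L]) - (b[2L] - a[2L]) * (c[1L] - a[1L])
  }
  o1 <- orient(p1, p2, p3)
  o2 <- orient(p1, p2, p4)
  o3 <- orient(p3, p4, p1)
  o4 <- orient(p3, p4, p2)
  if (o1 == 0 && o2 == 0 && o3 == 0 && o4 == 0) {
    ## collinear: overlap of positive length?
    d <- p2 - p1
    t3 <- sum((p3 - p1) * d) / sum(d * d)
    t4 <- sum((p4 - p1) * d) / sum(d * d)
    return(min(max(t3, t4), 1) - max(min(t3, t4), 0) > 0)
  }
  (o1 * o2 < 0) && (o3 * o4 < 0)
}

## Crossing counts for every ensemble member at a fixed layout: precompute
## the m x m crossing indicator over possible edges, then each member's count
## is a quadratic form in its incidence vector.
batch_crossings <- function(ensemble, layout) {
  stopifnot(inherits(ensemble, "null_graph_ensemble"))
  layout <- as.matrix(layout)[ensemble$labels, , drop = FALSE]
  ei <- ensemble$edge_index
  m <- nrow(ei)
  cross <- matrix(0, m, m)
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      if (length(intersect(ei[i, ], ei[j, ]))) next
      if (segments_cross(layout[ei[i, 1L], ], layout[ei[i, 2L], ],
                         layout[ei[j, 1L], ], layout[ei[j, 2L], ])) {
        cross[i, j] <- cross[j, i] <- 1
      }
    }
  }
  x <- ensemble$members + 0
  rowSums((x %*% cross) * x) / 2
}
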