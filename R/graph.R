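#' Construct a relational graph
#'
#' A relational graph is the latent structure that organises a set of discrete
#' objects: an undirected, connected, simple graph over labelled nodes, with
#' an optional two-dimensional layout used for Euclidean distances and for
#' plotting.
#'
#' @param nodes character (or coercible) vector of unique node labels.
#' @param edges two-column matrix or data frame of node labels, one undirected
#'   edge per row.  Self-loops and duplicate edges (in either orientation) are
#'   rejected.
#' @param layout optional numeric matrix with one `(x, y)` row per node;
#'   rownames must cover every node label.
#' @return An object of class `relational_graph`: a list with elements
#'   `nodes`, `edges` (canonicalised two-column character matrix) and
#'   `layout` (numeric matrix or `NULL`).
#' @examples
#' g <- relational_graph(1:3, rbind(c(1, 2), c(2, 3)))
#' adjacency_matrix(g)
#' @export
relational_graph <- function(nodes, edges, layout = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("node labels must be unique")
  if (length(nodes) < 2L) stop("a relational graph needs at least two nodes")
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L) stop("'edges' must have two columns")
  storage.mode(edges) <- "character"
  unknown <- setdiff(c(edges), nodes)
  if (length(unknown)) {
    stop("edge endpoints not in node set: ", paste(unknown, collapse = ", "))
  }
  if (any(edges[, 1L] == edges[, 2L])) stop("self-loops are not allowed")
  ## canonical orientation: endpoint with the lower node index first
  ord <- match(edges[, 1L], nodes) > match(edges[, 2L], nodes)
  edges[ord, ] <- edges[ord, c(2L, 1L)]
  key <- paste(edges[, 1L], edges[, 2L], sep = "\r")
  if (anyDuplicated(key)) stop("duplicate edges are not allowed")
  edges <- edges[order(match(edges[, 1L], nodes), match(edges[, 2L], nodes)), ,
                 drop = FALSE]
  dimnames(edges) <- NULL

  if (!is.null(layout)) {
    layout <- as.matrix(layout)
    if (ncol(layout) != 2L) stop("'layout' must have two columns (x, y)")
    if (is.null(rownames(layout))) {
      if (nrow(layout) != length(nodes)) {
        stop("unnamed 'layout' must have one row per node")
      }
      rownames(layout) <- nodes
    }
    missing <- setdiff(nodes, rownames(layout))
    if (length(missing)) {
      stop("layout missing coordinates for node(s): ",
           paste(missing, collapse = ", "))
    }
    layout <- layout[nodes, , drop = FALSE]
    colnames(layout) <- c("x", "y")
    storage.mode(layout) <- "double"
  }

  g <- structure(list(nodes = nodes, edges = edges, layout = layout),
                 class = "relational_graph")
  comp <- graph_components(g)
  if (max(comp) > 1L) {
    a <- nodes[match(1L, comp)]
    b <- nodes[match(2L, comp)]
    stop("graph is not connected: no path between nodes '", a, "' and '",
         b, "'")
  }
  g
}

## Connected-component labels (1-based) via igraph.
graph_components <- function(graph) {
  ig <- as_igraph(graph)
  igraph::components(ig)$membership[graph$nodes]
}

as_igraph <- function(graph, directed = FALSE) {
  ig <- igraph::make_empty_graph(n = length(graph$nodes), directed = directed)
  ig <- igraph::set_vertex_attr(ig, "name", value = graph$nodes)
  igraph::add_edges(ig, t(matrix(match(graph$edges, graph$nodes),
                                 ncol = 2L)))
}

#' Adjacency matrix of a relational graph
#'
#' @param graph a [relational_graph()].
#' @return Binary symmetric matrix with node labels as dimnames.
#' @export
adjacency_matrix <- function(graph) {
  stopifnot(inherits(graph, "relational_graph"))
  n <- length(graph$nodes)
  a <- matrix(0, n, n, dimnames = list(graph$nodes, graph$nodes))
  i <- match(graph$edges[, 1L], graph$nodes)
  j <- match(graph$edges[, 2L], graph$nodes)
  a[cbind(i, j)] <- 1
  a[cbind(j, i)] <- 1
  a
}

#' @export
print.relational_graph <- function(x, ...) {
  cat("Relational graph:", length(x$nodes), "nodes,", nrow(x$edges),
      "edges", if (!is.null(x$layout)) "(with 2-D layout)", "\n")
  cat("  nodes:", paste(x$nodes, collapse = " "), "\n")
  cat("  edges:", paste(apply(x$edges, 1L, paste, collapse = "-"),
                        collapse = " "), "\n")
  invisible(x)
}

#' @export
plot.relational_graph <- function(x, ...) {
  if (is.null(x$layout)) stop("graph has no layout to plot")
  plot(x$layout, asp = 1, pch = 21, bg = "grey80", cex = 2.4,
       xlab = "x", ylab = "y", ...)
  segments(x$layout[x$edges[, 1L], 1L], x$layout[x$edges[, 1L], 2L],
           x$layout[x$edges[, 2L], 1L], x$layout[x$edges[, 2L], 2L])
  points(x$layout, pch = 21, bg = "grey80", cex = 2.4)
  text(x$layout, labels = rownames(x$layout), cex = 0.7)
  invisible(x)
}

#' Default 7-node test graph
#'
#' The reduced graph presented during scanning and behavioural testing: seven
#' objects, seven links, connected, diameter 3.  The published figure is not
#' machine-readable, so this is a constraint-satisfying reconstruction: it
#' contains every link named in the text (1-2, 1-5, 3-5, 4-6, 5-7), omits
#' every named non-link (2-4, 4-7, 1-7), and is a 5-cycle (1-4-6-7-5) with
#' pendant nodes 2 and 3.  The layout places the cycle on a regular pentagon
#' with unit sides and the pendants one unit outward, so every linked pair is
#' at Euclidean distance exactly 1.
#'
#' @return A [relational_graph()] with nodes `"1"` to `"7"` and a unit-edge
#'   planar layout.
#' @export
default_reduced_graph <- function() {
  edges <- rbind(c(1, 2), c(1, 4), c(1, 5), c(3, 5), c(4, 6), c(5, 7),
                 c(6, 7))
  ## regular pentagon (unit side) for the cycle 1-4-6-7-5, pendants radial
  r <- 1 / (2 * sin(pi / 5))
  ang <- pi / 2 + 2 * pi * (0:4) / 5
  cyc <- c("1", "4", "6", "7", "5")
  layout <- matrix(NA_real_, 7, 2, dimnames = list(as.character(1:7), NULL))
  layout[cyc, ] <- cbind(r * cos(ang), r * sin(ang))
  layout["2", ] <- layout["1", ] * (r + 1) / r  # unit step radially outward
  layout["3", ] <- layout["5", ] * (r + 1) / r
  relational_graph(1:7, edges, layout)
}

#' Default 12-node training graph
#'
#' The larger graph that generated the day-1 training walks.  Its true
#' topology is only published as a figure, so this default is a
#' reconstruction constrained to contain [default_reduced_graph()] as an
#' induced subgraph on nodes 1-7 (no extra links among those nodes) and to
#' give every node degree at least 3, which keeps constrained random walks
#' from stalling.
#'
#' @return A [relational_graph()] with nodes `"1"` to `"12"`.
#' @export
default_training_graph <- function() {
  reduced <- default_reduced_graph()
  extra <- rbind(c(2, 8), c(2, 9), c(3, 9), c(3, 10), c(4, 10), c(6, 11),
                 c(7, 12), c(8, 9), c(8, 12), c(9, 10), c(10, 11), c(11, 12))
  ## extend the pentagon layout outward for the five new nodes
  base <- reduced$layout
  layout <- rbind(base,
                  "8"  = base["2", ] * 1.8,
                  "9"  = (base["2", ] + base["3", ]) * 0.9,
                  "10" = base["3", ] * 1.8,
                  "11" = (base["6", ] * 2.2 + base["3", ] * 0.4),
                  "12" = (base["7", ] * 2.2 + base["2", ] * 0.4))
  relational_graph(1:12, rbind(reduced$edges, extra), layout)
}

#' Read a relational graph from JSON
#'
#' Expects an object with fields `nodes` (array), `edges` (array of 2-arrays)
#' and optionally `layout` (object mapping node label to `[x, y]`).
#'
#' @param path path to a JSON file.
#' @return A [relational_graph()].
#' @export
read_graph_json <- function(path) {
  spec <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  bad <- setdiff(names(spec), c("nodes", "edges", "layout"))
  if (length(bad)) stop("unknown graph fields: ", paste(bad, collapse = ", "))
  if (is.null(spec$nodes) || is.null(spec$edges)) {
    stop("graph JSON must contain 'nodes' and 'edges'")
  }
  edges <- spec$edges
  if (is.list(edges)) edges <- do.call(rbind, edges)
  layout <- NULL
  if (!is.null(spec$layout)) {
    layout <- do.call(rbind, spec$layout)
    rownames(layout) <- names(spec$layout)
  }
  relational_graph(spec$nodes, edges, layout)
}

#' Write a relational graph to JSON
#'
#' @param graph a [relational_graph()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_graph_json <- function(graph, path) {
  stopifnot(inherits(graph, "relational_graph"))
  obj <- list(nodes = graph$nodes,
              edges = unname(apply(graph$edges, 1L, as.list)))
  if (!is.null(graph$layout)) {
    obj$layout <- stats::setNames(
      lapply(seq_len(nrow(graph$layout)),
             function(i) as.numeric(graph$layout[i, ])),
      rownames(graph$layout))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
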