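## Independent oracles used to check package computations.  These are
## deliberately naive (brute force, truncated series, textbook formulas) and
## share no code with the implementation.

## Breadth-first shortest path lengths from a binary adjacency matrix.
bfs_distances_oracle <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(adj[v, ] > 0)) {
          if (dist[w] > dist[v] + 1) {
            dist[w] <- dist[v] + 1
            nxt <- c(nxt, w)
          }
        }
      }
      frontier <- unique(nxt)
    }
    d[s, ] <- dist
  }
  d
}

## Truncated matrix-exponential series sum_{k<=N} A^k / k!.
truncated_expm_oracle <- function(a, n_terms) {
  acc <- diag(nrow(a))
  term <- diag(nrow(a))
  for (k in seq_len(n_terms)) {
    term <- term %*% a / k
    acc <- acc + term
  }
  acc
}

## Truncated geometric series sum_{k<=N} gamma^k A^k.
truncated_sr_oracle <- function(a, gamma, n_terms) {
  acc <- diag(nrow(a))
  term <- diag(nrow(a))
  for (k in seq_len(n_terms)) {
    term <- gamma * term %*% a
    acc <- acc + term
  }
  acc
}

## Union-find connectivity of an edge list over nodes 1..n.
uf_connected_oracle <- function(edge_mat, n) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  for (r in seq_len(nrow(edge_mat))) {
    a <- find(edge_mat[r, 1L]); b <- find(edge_mat[r, 2L])
    if (a != b) parent[a] <- b
  }
  length(unique(vapply(seq_len(n), find, 0L))) == 1L
}

## Open-segment intersection via explicit parametric solve.
seg_cross_oracle <- function(p1, p2, p3, p4) {
  d1 <- p2 - p1; d2 <- p4 - p3
  den <- d1[1] * d2[2] - d1[2] * d2[1]
  if (abs(den) < 1e-12) {
    ## parallel: collinear overlap of positive length?
    cr <- d1[1] * (p3[2] - p1[2]) - d1[2] * (p3[1] - p1[1])
    if (abs(cr) > 1e-12) return(FALSE)
    t3 <- sum((p3 - p1) * d1) / sum(d1^2)
    t4 <- sum((p4 - p1) * d1) / sum(d1^2)
    return(min(max(t3, t4), 1) - max(min(t3, t4), 0) > 1e-12)
  }
  t <- ((p3[1] - p1[1]) * d2[2] - (p3[2] - p1[2]) * d2[1]) / den
  u <- ((p3[1] - p1[1]) * d1[2] - (p3[2] - p1[2]) * d1[1]) / den
  t > 1e-12 && t < 1 - 1e-12 && u > 1e-12 && u < 1 - 1e-12
}

## Closed-form OLS coefficients.
ols_oracle <- function(x, y) {
  as.vector(solve(t(x) %*% x, t(x) %*% y))
}

## Textbook one-way repeated-measures ANOVA on a subjects x conditions
## matrix of cell means.
rm_anova_oracle <- function(m) {
  n_s <- nrow(m); n_c <- ncol(m)
  grand <- mean(m)
  ss_cond <- n_s * sum((colMeans(m) - grand)^2)
  ss_subj <- n_c * sum((rowMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- n_c - 1L
  df2 <- (n_c - 1L) * (n_s - 1L)
  f <- (ss_cond / df1) / (ss_err / df2)
  list(F = f, df1 = df1, df2 = df2)
}

## Quadratic scan: mean gap from i to j (nearest prior occurrence of i
## before each occurrence of j).
gap_scan_oracle <- function(items, i, j) {
  gaps <- c()
  for (t in seq_along(items)) {
    if (items[t] != j) next
    prior <- which(items[seq_len(t - 1L)] == i)
    if (length(prior)) gaps <- c(gaps, t - max(prior) - 1L)
  }
  if (length(gaps)) mean(gaps) else NA_real_
}

## All simple directed paths between two nodes; minimum total weight.
shortest_path_oracle <- function(wmat, from, to) {
  n <- nrow(wmat)
  best <- Inf
  recurse <- function(v, visited, len) {
    if (v == to) {
      best <<- min(best, len)
      return(invisible())
    }
    for (w in seq_len(n)) {
      if (!visited[w] && is.finite(wmat[v, w])) {
        visited[w] <- TRUE
        recurse(w, visited, len + wmat[v, w])
        visited[w] <- FALSE
      }
    }
  }
  visited <- rep(FALSE, n); visited[from] <- TRUE
  recurse(from, visited, 0)
  best
}
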