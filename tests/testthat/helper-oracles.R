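# Independent brute-force oracles used across the suite. These deliberately
# avoid the implementation paths (and igraph's algorithms) they are checking.

# Adjacency matrix from an edge list (1-based integer vertex ids).
adj_from_edges <- function(n, edges) {
  A <- matrix(0L, n, n)
  if (length(edges) > 0) {
    e <- matrix(edges, ncol = 2, byrow = TRUE)
    A[e] <- 1L
    A[e[, 2:1, drop = FALSE]] <- 1L
  }
  A
}

# All simple paths between s and t by DFS; returns a list of vertex vectors.
all_simple_paths_brute <- function(A, s, t) {
  n <- nrow(A)
  out <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == t) {
      out[[length(out) + 1L]] <<- path
      return(invisible())
    }
    for (w in which(A[v, ] == 1L)) {
      if (!w %in% path) walk(c(path, w))
    }
  }
  walk(s)
  out
}

# Unnormalized undirected betweenness by explicit shortest-path enumeration.
betweenness_brute <- function(A) {
  n <- nrow(A)
  bc <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    paths <- all_simple_paths_brute(A, s, t)
    if (length(paths) == 0) next
    lens <- vapply(paths, length, 1L)
    sp <- paths[lens == min(lens)]
    inner <- lapply(sp, function(p) p[-c(1, length(p))])
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      bc[v] <- bc[v] + mean(vapply(inner, function(iv) v %in% iv, NA))
    }
  }
  bc
}

# Floyd-Warshall all-pairs shortest paths (unit edge weights).
floyd_warshall <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[A == 1L] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# Newman modularity of a partition, straight from the formula
# Q = sum_c (e_c / m - (d_c / 2m)^2).
modularity_brute <- function(A, membership) {
  m <- sum(A) / 2
  q <- 0
  for (cc in unique(membership)) {
    idx <- which(membership == cc)
    e_c <- sum(A[idx, idx]) / 2
    d_c <- sum(A[idx, ])
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  q
}

# Benjamini-Hochberg rejection set by direct definition.
bh_reject_brute <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- which(ps <= seq_len(m) / m * alpha)
  if (length(k) == 0) return(logical(m))
  p <= ps[max(k)]
}

# Random connected simple graph on n vertices as an igraph object plus its
# adjacency matrix; retries until connected.
random_connected_graph <- function(n, p = 0.5) {
  repeat {
    A <- matrix(0L, n, n)
    up <- which(upper.tri(A))
    A[up] <- as.integer(stats::runif(length(up)) < p)
    A <- A + t(A)
    D <- floyd_warshall(A)
    if (all(is.finite(D))) break
  }
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  igraph::V(g)$name <- paste0("v", seq_len(n))
  list(graph = g, A = A)
}

# Small deterministic fixture table used by several io/normalize tests.
fixture_counts <- function() {
  m <- matrix(c(5L, 0L, 3L, 2L,
                1L, 4L, 0L, 6L,
                2L, 2L, 2L, 2L),
              nrow = 3, byrow = TRUE,
              dimnames = list(paste0("s", 1:3), paste0("t", 1:4)))
  count_table(m, provenance = "fixture")
}
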