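# Independent brute-force implementations of the six global graph metrics,
# written against the adjacency matrix only (no igraph), used as oracles.

oracle_density <- function(adj) {
  q <- nrow(adj)
  if (q < 2) return(0)
  sum(adj[upper.tri(adj)]) / (q * (q - 1) / 2)
}

# Pearson correlation over the symmetrized edge-endpoint degree list
oracle_assortativity <- function(adj) {
  deg <- rowSums(adj)
  xs <- c(); ys <- c()
  q <- nrow(adj)
  for (i in seq_len(q)) for (j in seq_len(q)) {
    if (i != j && adj[i, j] == 1) {  # both directions: symmetrized list
      xs <- c(xs, deg[i]); ys <- c(ys, deg[j])
    }
  }
  if (length(xs) == 0 || sd(xs) == 0 || sd(ys) == 0) return(NA_real_)
  cor(xs, ys)
}

oracle_transitivity <- function(adj) {
  q <- nrow(adj)
  tri <- 0
  for (i in seq_len(q)) for (j in seq_len(q)) for (k in seq_len(q)) {
    if (i < j && j < k && adj[i, j] && adj[j, k] && adj[i, k]) tri <- tri + 1
  }
  deg <- rowSums(adj)
  triples <- sum(choose(deg, 2))
  if (triples == 0) return(0)
  3 * tri / triples
}

oracle_distances <- function(adj) {
  q <- nrow(adj)
  d <- matrix(Inf, q, q)
  diag(d) <- 0
  d[adj == 1] <- 1
  for (k in seq_len(q)) for (i in seq_len(q)) for (j in seq_len(q)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

oracle_efficiency <- function(adj) {
  q <- nrow(adj)
  if (q < 2) return(0)
  d <- oracle_distances(adj)
  acc <- 0
  for (i in seq_len(q - 1)) for (j in (i + 1):q) {
    if (is.finite(d[i, j]) && d[i, j] > 0) acc <- acc + 1 / d[i, j]
  }
  acc / (q * (q - 1) / 2)
}

# all shortest paths between s and t by explicit enumeration (DFS pruned by
# the distance matrix); returns the list of node sequences
enumerate_shortest_paths <- function(adj, d, s, t) {
  if (!is.finite(d[s, t])) return(list())
  if (s == t) return(list(s))
  paths <- list()
  walk <- function(path) {
    u <- path[length(path)]
    if (u == t) {
      paths[[length(paths) + 1L]] <<- path
      return(invisible())
    }
    for (v in which(adj[u, ] == 1)) {
      if (d[s, v] == length(path) && d[v, t] == d[s, t] - length(path)) {
        walk(c(path, v))
      }
    }
  }
  walk(s)
  paths
}

# unnormalized betweenness, each unordered pair counted once, endpoints
# excluded, averaged over nodes
oracle_avg_betweenness <- function(adj) {
  q <- nrow(adj)
  if (q < 3) return(0)
  d <- oracle_distances(adj)
  bc <- numeric(q)
  for (s in seq_len(q - 1)) for (t in (s + 1):q) {
    paths <- enumerate_shortest_paths(adj, d, s, t)
    sigma <- length(paths)
    if (sigma == 0) next
    for (v in seq_len(q)) {
      if (v == s || v == t) next
      through <- sum(vapply(paths, function(p) v %in% p, logical(1)))
      bc[v] <- bc[v] + through / sigma
    }
  }
  mean(bc)
}

# Newman modularity of a given node partition (membership vector)
oracle_modularity_q <- function(adj, membership) {
  m <- sum(adj[upper.tri(adj)])
  if (m == 0) return(NA_real_)
  deg <- rowSums(adj)
  qv <- 0
  for (c in unique(membership)) {
    idx <- which(membership == c)
    e_c <- sum(adj[idx, idx, drop = FALSE]) / 2
    d_c <- sum(deg[idx])
    qv <- qv + e_c / m - (d_c / (2 * m))^2
  }
  qv
}

# maximum modularity over ALL partitions (restricted-growth-string
# enumeration); feasible for q <= 8 (Bell(8) = 4140)
oracle_max_modularity <- function(adj) {
  q <- nrow(adj)
  best <- -Inf
  rgs <- integer(q)
  recurse <- function(i, maxc) {
    if (i > q) {
      best <<- max(best, oracle_modularity_q(adj, rgs))
      return(invisible())
    }
    for (c in seq_len(maxc + 1L)) {
      rgs[i] <<- c
      recurse(i + 1L, max(maxc, c))
    }
  }
  recurse(1L, 0L)
  best
}

# seeded Erdos-Renyi adjacency matrix
random_adjacency <- function(q, p = 0.4) {
  adj <- matrix(0L, q, q)
  up <- which(upper.tri(adj))
  adj[up] <- rbinom(length(up), 1, p)
  adj <- adj + t(adj)
  dimnames(adj) <- list(sprintf("roi_%03d", 1:q), sprintf("roi_%03d", 1:q))
  adj
}

adj_to_graph <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
}

graph_from_edges <- function(edges, q) {
  g <- igraph::make_empty_graph(n = q, directed = FALSE)
  if (length(edges) > 0) g <- igraph::add_edges(g, edges)
  g
}
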