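# Brute-force graph oracles, independent of igraph: adjacency-matrix BFS
# for shortest paths, triple enumeration for clustering, explicit path
# counting for betweenness. Only feasible for tiny graphs (n <= 12).

oracle_adjacency <- function(network, directed = TRUE) {
  codes <- sort(igraph::V(network$graph)$name)
  n <- length(codes)
  a <- matrix(0L, n, n, dimnames = list(codes, codes))
  el <- igraph::as_edgelist(network$graph)
  for (i in seq_len(nrow(el))) {
    a[el[i, 1], el[i, 2]] <- 1L
    if (!directed) a[el[i, 2], el[i, 1]] <- 1L
  }
  a
}

# All-pairs geodesic distances by breadth-first search from each node.
oracle_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n, dimnames = dimnames(adj))
  diag(d) <- 0
  for (s in seq_len(n)) {
    frontier <- s
    depth <- 0
    while (length(frontier)) {
      depth <- depth + 1
      nxt <- unique(unlist(lapply(frontier, function(v) which(adj[v, ] == 1L))))
      nxt <- nxt[d[s, nxt] == Inf]
      d[s, nxt] <- depth
      frontier <- nxt
    }
  }
  d
}

oracle_diameter <- function(network, directed = TRUE) {
  d <- oracle_distances(oracle_adjacency(network, directed))
  finite <- d[is.finite(d) & d > 0]
  if (!length(finite)) return(NA_real_)
  max(finite)
}

oracle_apl <- function(network, directed = TRUE) {
  d <- oracle_distances(oracle_adjacency(network, directed))
  vals <- d[row(d) != col(d)]
  vals <- vals[is.finite(vals)]
  if (!length(vals)) return(NA_real_)
  mean(vals)
}

# Local clustering by enumerating neighbour pairs on the undirected graph.
oracle_local_clustering <- function(adj_und) {
  n <- nrow(adj_und)
  vapply(seq_len(n), function(v) {
    nb <- which(adj_und[v, ] == 1L)
    k <- length(nb)
    if (k < 2) return(NA_real_)
    pairs <- combn(nb, 2)
    linked <- sum(adj_und[cbind(pairs[1, ], pairs[2, ])])
    linked / ncol(pairs)
  }, numeric(1))
}

oracle_transitivity <- function(network, variant = "average-local",
                                isolates = "drop") {
  adj <- oracle_adjacency(network, directed = FALSE)
  cc <- oracle_local_clustering(adj)
  if (variant == "global") {
    deg <- rowSums(adj)
    triples <- sum(deg * (deg - 1) / 2)
    triangles <- sum(cc * (deg * (deg - 1) / 2), na.rm = TRUE) / 3
    return(3 * triangles / triples)
  }
  if (isolates == "zero") cc[is.na(cc)] <- 0
  mean(cc, na.rm = TRUE)
}

oracle_assortativity <- function(network) {
  el <- igraph::as_edgelist(network$graph)
  adj <- oracle_adjacency(network, directed = TRUE)
  dout <- rowSums(adj)
  din <- colSums(adj)
  suppressWarnings(cor(dout[el[, 1]], din[el[, 2]]))
}

# Betweenness by explicit enumeration of all shortest paths (Floyd-style
# path counting), plus Freeman centralization with the directed star
# normaliser (n-1)^2 (n-2).
oracle_betweenness <- function(network) {
  adj <- oracle_adjacency(network, directed = TRUE)
  d <- oracle_distances(adj)
  n <- nrow(adj)
  # number of shortest s->t paths
  sigma <- matrix(0, n, n)
  sigma[adj == 1L] <- 1
  for (len in 2:max(1, max(d[is.finite(d)]))) {
    for (s in seq_len(n)) for (t in seq_len(n)) {
      if (s != t && is.finite(d[s, t]) && d[s, t] == len) {
        mids <- which(adj[s, ] == 1L & d[, t] == len - 1)
        sigma[s, t] <- sum(sigma[cbind(mids, t)])
      }
    }
  }
  btw <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n)) for (t in seq_len(n)) {
      if (s != t && s != v && t != v && is.finite(d[s, t])) {
        via <- if (is.finite(d[s, v]) && is.finite(d[v, t]) &&
                   d[s, v] + d[v, t] == d[s, t]) {
          sigma[s, v] * sigma[v, t]
        } else 0
        if (sigma[s, t] > 0) btw[v] <- btw[v] + via / sigma[s, t]
      }
    }
  }
  names(btw) <- rownames(adj)
  btw
}

oracle_betweenness_centralization <- function(network) {
  btw <- oracle_betweenness(network)
  n <- length(btw)
  sum(max(btw) - btw) / ((n - 1)^2 * (n - 2))
}

# Newman modularity evaluated directly from its definition.
oracle_modularity <- function(network, membership) {
  adj <- oracle_adjacency(network, directed = FALSE)
  memb <- membership[rownames(adj)]
  m2 <- sum(adj)  # 2m
  if (m2 == 0) return(0)
  q <- 0
  for (cid in unique(memb)) {
    inside <- which(memb == cid)
    e_ii <- sum(adj[inside, inside, drop = FALSE]) / m2
    a_i <- sum(adj[inside, , drop = FALSE]) / m2
    q <- q + e_ii - a_i^2
  }
  q
}

# Adjusted Rand index between two labelings (for planted-partition tests).
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- sum(tab)
  expected <- sum_a * sum_b / comb2(n)
  maximum <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maximum - expected)
}
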