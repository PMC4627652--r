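# Independent brute-force oracles used to validate the compiled graph
# kernels and the spectral community detection. These deliberately use
# different algorithms from the package implementations.

# Floyd-Warshall all-pairs shortest paths on a 0/1 adjacency matrix.
oracle_floyd_warshall <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj == 1] <- 1
  diag(d) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

oracle_global_eff <- function(adj) {
  n <- nrow(adj)
  if (n < 2) return(0)
  d <- oracle_floyd_warshall(adj)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv[is.finite(inv)]) / (n * (n - 1))
}

oracle_nodal_eff <- function(adj) {
  n <- nrow(adj)
  d <- oracle_floyd_warshall(adj)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  rowSums(inv) / (n - 1)
}

# Rebuilds each neighbour-induced subgraph explicitly.
oracle_local_eff <- function(adj) {
  n <- nrow(adj)
  vals <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] == 1)
    if (length(nb) < 2) return(0)
    oracle_global_eff(adj[nb, nb, drop = FALSE])
  }, numeric(1))
  mean(vals)
}

# Betweenness by explicit enumeration of every shortest path.
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- oracle_floyd_warshall(adj)
  bc <- numeric(n)
  paths_to <- function(j, k) {
    if (j == k) return(list(j))
    out <- list()
    for (u in which(adj[, k] == 1)) {
      if (is.finite(d[j, u]) && d[j, u] + 1 == d[j, k]) {
        for (p in paths_to(j, u)) out[[length(out) + 1L]] <- c(p, k)
      }
    }
    out
  }
  for (j in seq_len(n - 1)) for (k in seq.int(j + 1, n)) {
    if (!is.finite(d[j, k])) next
    ps <- paths_to(j, k)
    for (p in ps) {
      interior <- p[-c(1L, length(p))]
      bc[interior] <- bc[interior] + 1 / length(ps)
    }
  }
  bc
}

# Newman-Girvan Q by direct double summation.
oracle_q <- function(adj, assignment) {
  n <- nrow(adj)
  k <- colSums(adj)
  m2 <- sum(k)
  q <- 0
  for (i in seq_len(n))
    for (j in seq_len(n))
      if (assignment[i] == assignment[j])
        q <- q + adj[i, j] - k[i] * k[j] / m2
  q / m2
}

# All set partitions of n items as restricted-growth strings.
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, m) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (v in seq_len(m + 1L)) rec(c(prefix, v), max(m, v))
  }
  rec(integer(0), 0L)
  out
}

# Exhaustive maximum of Q over every partition.
oracle_best_q <- function(adj) {
  k <- colSums(adj)
  m2 <- sum(k)
  B <- adj - outer(k, k) / m2
  best <- -Inf
  for (p in all_partitions(nrow(adj))) {
    q <- sum(B[outer(p, p, "==")]) / m2
    if (q > best) best <- q
  }
  best
}

# Benjamini-Hochberg by exhaustively checking every rejection threshold.
oracle_bh_flags <- function(p, q) {
  n <- length(p)
  ord <- order(p)
  k_max <- 0L
  for (k in seq_len(n)) if (p[ord[k]] <= q * k / n) k_max <- k
  flags <- rep(FALSE, n)
  if (k_max > 0L) flags[ord[seq_len(k_max)]] <- TRUE
  flags
}

# Erdos-Renyi adjacency matrix.
random_adjacency <- function(n, p) {
  a <- matrix(0L, n, n)
  up <- which(upper.tri(a))
  a[up] <- as.integer(runif(length(up)) < p)
  a[lower.tri(a)] <- t(a)[lower.tri(a)]
  a
}
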