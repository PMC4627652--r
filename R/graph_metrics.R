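adjacency_of <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  net$adjacency
}

#' Shortest-path distance matrix of a binary network
#'
#' Breadth-first distances of the unweighted, undirected graph. Unreachable
#' pairs carry `Inf`; the diagonal is 0.
#'
#' @param net a `binary_network`.
#' @return numeric N x N matrix of path lengths (in edges).
#' @export
shortest_paths <- function(net) {
  bfs_distance_matrix_cpp(adjacency_of(net))
}

#' Efficiency metrics of a binary network
#'
#' Global efficiency is the mean inverse shortest-path length over all
#' ordered node pairs, `E_glob = 1/(N(N-1)) * sum_{i != j} 1/L_ij`, with
#' unreachable pairs contributing 0 (the efficiency formalism's resolution
#' of disconnected graphs). Nodal efficiency `E_i` is the same mean taken
#' from one node; `mean(E_i) == E_glob` identically. Local efficiency is
#' the mean over nodes of the global efficiency of each node's
#' neighbour-induced subgraph (the node itself excluded); subgraphs with
#' fewer than two nodes contribute 0.
#'
#' @param net a `binary_network` with at least 2 nodes.
#' @return `global_efficiency()` and `local_efficiency()` return a scalar in
#'   \[0, 1\]; `nodal_efficiency()` a length-N vector.
#' @export
global_efficiency <- function(net) {
  a <- adjacency_of(net)
  if (nrow(a) < 2L) stop("efficiency needs at least 2 nodes")
  global_efficiency_cpp(a)
}

#' @rdname global_efficiency
#' @export
nodal_efficiency <- function(net) {
  a <- adjacency_of(net)
  if (nrow(a) < 2L) stop("efficiency needs at least 2 nodes")
  as.numeric(nodal_efficiency_cpp(a))
}

#' @rdname global_efficiency
#' @export
local_efficiency <- function(net) {
  local_efficiency_cpp(adjacency_of(net))
}

#' Nodal degree
#'
#' `K_i`: number of edges incident to each node; `sum(K_i)` equals twice
#' the edge count.
#'
#' @param net a `binary_network`.
#' @return numeric length-N vector.
#' @export
nodal_degree <- function(net) {
  as.numeric(colSums(adjacency_of(net)))
}

#' Betweenness centrality
#'
#' `B_i`: for every unordered pair of other nodes, the fraction of shortest
#' paths that pass through node i, summed over pairs (pairs with no
#' connecting path contribute 0). Computed by Brandes' accumulation;
#' regions with consistently high `B_i` are the network's hubs.
#'
#' @param net a `binary_network`.
#' @return numeric length-N vector of non-negative values.
#' @export
betweenness_centrality <- function(net) {
  as.numeric(betweenness_cpp(adjacency_of(net)))
}

#' Newman-Girvan modularity of a partition
#'
#' `Q = 1/(2m) * sum_ij (A_ij - k_i k_j / (2m)) * [c_i == c_j]` for an
#' unweighted graph with m edges; Q of the single-module partition is 0 and
#' Q always lies in \[-0.5, 1\].
#'
#' @param net a `binary_network` with at least one edge.
#' @param assignment integer module id per node; every module nonempty.
#' @return scalar Q.
#' @export
modularity_q <- function(net, assignment) {
  a <- adjacency_of(net)
  n <- nrow(a)
  if (length(assignment) != n) stop("assignment must cover all nodes")
  ids <- unique(assignment)
  if (anyNA(assignment)) stop("assignment has missing module ids")
  k <- colSums(a)
  m2 <- sum(k)
  if (m2 == 0) stop("modularity undefined for an edgeless graph")
  same <- outer(assignment, assignment, "==")
  sum((a - outer(k, k) / m2) * same) / m2
}

# One Kernighan-Lin style refinement of a bisection vector s over the
# (generalized) modularity matrix Bg: each sweep moves every node exactly
# once in greedy order, keeps the best intermediate state, and repeats
# while the objective s' Bg s improves.
kl_refine <- function(Bg, s, max_sweeps = 50L) {
  n <- length(s)
  f <- function(sv) drop(crossprod(sv, Bg %*% sv))
  best_f <- f(s)
  eps <- 1e-9 * max(1, abs(best_f))
  for (sweep_i in seq_len(max_sweeps)) {
    moved <- rep(FALSE, n)
    cur <- s
    Bs <- drop(Bg %*% cur)
    states_f <- numeric(n)
    states_s <- vector("list", n)
    cur_f <- best_f
    for (step in seq_len(n)) {
      gain <- -4 * cur * (Bs - diag(Bg) * cur)
      gain[moved] <- -Inf
      i <- which.max(gain)
      cur_f <- cur_f + gain[i]
      Bs <- Bs - 2 * cur[i] * Bg[, i]
      cur[i] <- -cur[i]
      moved[i] <- TRUE
      states_f[step] <- cur_f
      states_s[[step]] <- cur
    }
    b <- which.max(states_f)
    cand_f <- f(states_s[[b]])  # exact, avoids incremental drift
    if (cand_f > best_f + eps) {
      best_f <- cand_f
      s <- states_s[[b]]
    } else break
  }
  s
}

#' Newman spectral community detection
#'
#' Recursive leading-eigenvector bisection of the modularity matrix
#' `B = A - k k'/(2m)`: each candidate group is split by the sign pattern of
#' the leading eigenvector of its generalized modularity matrix, optionally
#' fine-tuned by Kernighan-Lin single-node moves, and the split is accepted
#' only if it increases Q. The eigenvector sign is fixed (first nonzero
#' component positive) so results are deterministic.
#'
#' @param net a `binary_network` with at least one edge.
#' @param refine apply Kernighan-Lin fine-tuning after each bisection
#'   (default `TRUE`).
#' @return Object of class `module_partition`: list with `assignment`
#'   (integer module ids 1..n_modules), `q`, `n_modules`.
#' @export
newman_partition <- function(net, refine = TRUE) {
  a <- adjacency_of(net)
  n <- nrow(a)
  k <- colSums(a)
  m2 <- sum(k)
  if (m2 == 0) stop("community detection undefined for an edgeless graph")
  B <- a - outer(k, k) / m2
  tol <- 1e-10
  final <- list()
  work <- list(seq_len(n))
  while (length(work)) {
    idx <- work[[1L]]
    work <- work[-1L]
    if (length(idx) < 2L) { final[[length(final) + 1L]] <- idx; next }
    Bg <- B[idx, idx, drop = FALSE]
    diag(Bg) <- diag(Bg) - rowSums(Bg)
    es <- eigen(Bg, symmetric = TRUE)
    if (es$values[1L] <= tol) { final[[length(final) + 1L]] <- idx; next }
    v <- es$vectors[, 1L]
    nz <- which(abs(v) > 1e-12)
    if (length(nz) && v[nz[1L]] < 0) v <- -v
    s <- ifelse(v >= 0, 1, -1)
    if (refine) s <- kl_refine(Bg, s)
    dq <- drop(crossprod(s, Bg %*% s)) / (2 * m2)
    if (dq <= tol || all(s == 1) || all(s == -1)) {
      final[[length(final) + 1L]] <- idx
      next
    }
    work <- c(work, list(idx[s > 0]), list(idx[s < 0]))
  }
  assignment <- integer(n)
  for (g in seq_along(final)) assignment[final[[g]]] <- g
  # renumber modules by first member for stable ids
  first <- vapply(split(seq_len(n), assignment), min, integer(1L))
  relabel <- match(assignment, as.integer(names(sort(first))))
  structure(list(assignment = relabel, q = modularity_q(net, relabel),
                 n_modules = length(final)),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("module_partition: %d modules, Q = %.4f\n", x$n_modules, x$q))
  invisible(x)
}

#' All metric curves for one subject across the sweep
#'
#' Convenience wrapper: binarizes a connectivity matrix at every grid level
#' and evaluates the global metrics (E_glob, E_loc) and nodal metrics
#' (degree K_i, efficiency E_i, betweenness B_i) at each level.
#'
#' @param conn a `z_connectivity` object.
#' @param grid a [sparsity_grid()].
#' @return list with `grid`, `e_glob`, `e_loc` (vectors over levels) and
#'   `degree`, `efficiency`, `betweenness` (N x levels matrices).
#' @export
metric_curves <- function(conn, grid = sparsity_grid()) {
  nets <- sweep_sparsity(conn, grid)
  nl <- length(nets)
  n <- nets[[1L]]$n_nodes
  out <- list(grid = grid,
              e_glob = numeric(nl), e_loc = numeric(nl),
              degree = matrix(0, n, nl), efficiency = matrix(0, n, nl),
              betweenness = matrix(0, n, nl))
  for (k in seq_len(nl)) {
    net <- nets[[k]]
    out$e_glob[k] <- global_efficiency(net)
    out$e_loc[k] <- local_efficiency(net)
    out$degree[, k] <- nodal_degree(net)
    out$efficiency[, k] <- nodal_efficiency(net)
    out$betweenness[, k] <- betweenness_centrality(net)
  }
  rownames(out$degree) <- rownames(out$efficiency) <-
    rownames(out$betweenness) <- conn$region_labels
  out
}

#' Export metric curves as a tidy table
#'
#' @param curves output of [metric_curves()].
#' @param subject_id subject identifier repeated on every row.
#' @return data.frame with columns subject_id, sparsity, metric, region
#'   (`""` for global metrics), value.
#' @export
metrics_table <- function(curves, subject_id = "subject") {
  s <- curves$grid$values
  glob <- data.frame(
    subject_id = subject_id,
    sparsity = rep(s, 2L),
    metric = rep(c("e_glob", "e_loc"), each = length(s)),
    region = "",
    value = c(curves$e_glob, curves$e_loc),
    stringsAsFactors = FALSE)
  nodal <- do.call(rbind, lapply(c("degree", "efficiency", "betweenness"),
    function(m) {
      v <- curves[[m]]
      data.frame(subject_id = subject_id,
                 sparsity = rep(s, each = nrow(v)),
                 metric = m,
                 region = rep(rownames(v), length(s)),
                 value = as.vector(v),
                 stringsAsFactors = FALSE)
    }))
  rbind(glob, nodal)
}
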