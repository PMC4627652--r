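# Small graph fixtures and generators shared across test files.

as_net <- function(adj, sparsity = NA_real_) {
  adj <- as.matrix(adj)
  storage.mode(adj) <- "integer"
  structure(list(adjacency = adj, sparsity = sparsity, n_nodes = nrow(adj)),
            class = "binary_network")
}

path_net <- function(n) {
  a <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) a[i, i + 1] <- a[i + 1, i] <- 1L
  as_net(a)
}

star_net <- function(n_leaves) {
  n <- n_leaves + 1L
  a <- matrix(0L, n, n)
  a[1, -1] <- a[-1, 1] <- 1L
  as_net(a)
}

complete_net <- function(n) {
  a <- matrix(1L, n, n)
  diag(a) <- 0L
  as_net(a)
}

empty_net <- function(n) as_net(matrix(0L, n, n))

# Two k-cliques joined by a single bridge edge (1 -- k+1).
two_cliques_net <- function(k) {
  n <- 2L * k
  a <- matrix(0L, n, n)
  a[1:k, 1:k] <- 1L
  a[(k + 1):n, (k + 1):n] <- 1L
  diag(a) <- 0L
  a[1, k + 1] <- a[k + 1, 1] <- 1L
  as_net(a)
}

# Random symmetric Fisher-z style connectivity with distinct |z| values.
random_connectivity <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  z <- matrix(0, n, n)
  z[upper.tri(z)] <- rnorm(n * (n - 1) / 2)
  z <- z + t(z)
  diag(z) <- 0
  connsweep:::z_connectivity_from_matrix(z)
}

# Small, fast cohort for pipeline-level tests: 20 regions, 60 volumes.
tiny_spec <- function(seed = 1L, ...) {
  cohort_spec(n_patients = 5L, n_controls = 5L,
              n_regions = 20L, n_timepoints = 60L,
              module_sizes_control = c(7L, 7L, 6L),
              module_sizes_patient = c(14L, 6L),
              hub_regions = c(1L, 8L),
              effect_region = 3L,
              seed = seed, ...)
}
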