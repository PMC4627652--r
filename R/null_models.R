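#' Degree-preserving rewiring (Markov-chain null model)
#'
#' Repeated double-edge swaps: two edges (a,b), (c,d) are drawn uniformly
#' and replaced by (a,d), (c,b) unless that would create a self-loop or a
#' duplicate edge, in which case the attempt is skipped and counted. The
#' degree sequence, node count and edge count are preserved exactly; with
#' enough attempted swaps the result is a uniform draw from the
#' degree-matched ensemble.
#'
#' @param net a `binary_network` with at least 2 edges (graphs with fewer
#'   edges are returned unchanged).
#' @param n_swaps attempted swaps; default 10x the edge count, the
#'   community-standard mixing heuristic.
#' @param seed optional integer seed; when supplied the output is
#'   bit-reproducible.
#' @return A rewired `binary_network`; attribute `skipped` on the adjacency
#'   counts rejected attempts.
#' @export
rewire_degree_preserving <- function(net, n_swaps = NULL, seed = NULL) {
  stopifnot(inherits(net, "binary_network"))
  m <- sum(net$adjacency) / 2L
  if (is.null(n_swaps)) n_swaps <- 10L * m
  if (!is.null(seed)) set.seed(seed)
  adj <- rewire_adjacency_cpp(net$adjacency, as.integer(n_swaps))
  structure(list(adjacency = adj, sparsity = net$sparsity,
                 n_nodes = net$n_nodes),
            class = "binary_network")
}

#' Null-ensemble efficiencies for one network
#'
#' Generates `n_random` independently rewired degree-matched random
#' networks and averages their global and local efficiencies. Each null
#' starts from the real network with its own seed derived from
#' `master_seed`, so serial and parallel evaluation agree bit-exactly.
#'
#' @param net a `binary_network`.
#' @param n_random ensemble size (default 100).
#' @param master_seed integer master seed for the ensemble.
#' @param swap_factor attempted swaps per edge for each null (default 10).
#' @return Object of class `null_ensemble`: list with `source_sparsity`,
#'   `n_random`, `mean_e_glob_random`, `mean_e_loc_random`, `rng_seed`.
#' @export
null_efficiencies <- function(net, n_random = 100L, master_seed = 1L,
                              swap_factor = 10L) {
  stopifnot(inherits(net, "binary_network"), n_random >= 1L)
  seeds <- derive_seeds(master_seed, n_random)
  ens <- null_ensemble_cpp(net$adjacency, as.integer(seeds),
                           as.integer(swap_factor))
  structure(list(source_sparsity = net$sparsity, n_random = n_random,
                 mean_e_glob_random = mean(ens$e_glob),
                 mean_e_loc_random = mean(ens$e_loc),
                 rng_seed = master_seed),
            class = "null_ensemble")
}

#' Normalize real efficiencies by their degree-matched null means
#'
#' Small-world organisation in the efficiency formalism shows as
#' `E_loc(real)/E_loc(random) > 1` with `E_glob(real)/E_glob(random)`
#' close to (slightly below) 1.
#'
#' @param e_glob,e_loc real-network global and local efficiency.
#' @param null a `null_ensemble` from [null_efficiencies()].
#' @return list with `e_glob_norm` and `e_loc_norm`.
#' @export
normalize_efficiencies <- function(e_glob, e_loc, null) {
  stopifnot(inherits(null, "null_ensemble"))
  if (null$mean_e_glob_random <= 0 || null$mean_e_loc_random <= 0)
    stop("degenerate network: null-ensemble mean efficiency is zero")
  list(e_glob_norm = e_glob / null$mean_e_glob_random,
       e_loc_norm = e_loc / null$mean_e_loc_random)
}
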