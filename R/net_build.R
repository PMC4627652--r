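#' Regional BOLD time-series container
#'
#' Bundles one subject's cleaned regional time series (rows = time points,
#' columns = regions) with its sampling interval and region labels. Inputs
#' are assumed to have been fully preprocessed upstream; this package never
#' touches voxel-level data.
#'
#' @param values numeric matrix, T time points x N regions.
#' @param subject_id character scalar identifying the subject.
#' @param tr_seconds repetition time (sampling interval) in seconds.
#' @param region_labels character vector of N region names; defaults to the
#'   column names of `values` or `R001..RNNN`.
#' @return An object of class `roi_timeseries`.
#' @export
roi_timeseries <- function(values, subject_id = "subject", tr_seconds = 2,
                           region_labels = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 3L) stop("need at least 3 time points")
  if (ncol(values) < 3L) stop("need at least 3 regions")
  if (anyNA(values) || any(!is.finite(values)))
    stop("time series contain missing or non-finite values")
  if (is.null(region_labels))
    region_labels <- colnames(values)
  if (is.null(region_labels))
    region_labels <- sprintf("R%03d", seq_len(ncol(values)))
  if (length(region_labels) != ncol(values))
    stop("region_labels length must match the number of columns")
  v <- apply(values, 2L, stats::var)
  if (any(v <= 0)) {
    bad <- region_labels[which(v <= 0)]
    stop("zero-variance region(s): ", paste(bad, collapse = ", "))
  }
  colnames(values) <- region_labels
  structure(list(subject_id = subject_id, values = values,
                 tr_seconds = tr_seconds, region_labels = region_labels),
            class = "roi_timeseries")
}

#' Read one subject's regional time series from delimited text
#'
#' Accepts TSV or CSV with T rows and N columns; a header row of region
#' labels is auto-detected.
#'
#' @param path path to the delimited file.
#' @param subject_id subject identifier; defaults to the file stem.
#' @param tr_seconds sampling interval in seconds.
#' @return An [roi_timeseries()] object.
#' @export
read_timeseries <- function(path, subject_id = NULL, tr_seconds = 2) {
  if (is.null(subject_id))
    subject_id <- tools::file_path_sans_ext(basename(path))
  dt <- data.table::fread(path, header = "auto", data.table = FALSE)
  roi_timeseries(as.matrix(dt), subject_id = subject_id,
                 tr_seconds = tr_seconds,
                 region_labels = if (all(grepl("^V[0-9]+$", colnames(dt)))) NULL else colnames(dt))
}

#' Read a region-label table
#'
#' TSV with columns `index`, `name` and optional `x`, `y`, `z` coordinates
#' (1-based indices, anatomical-atlas convention). Coordinates are carried
#' through to reports only.
#'
#' @param path path to the TSV file.
#' @return data.frame with at least `index` and `name`.
#' @export
read_region_labels <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  if (!all(c("index", "name") %in% names(df)))
    stop("region file must have columns 'index' and 'name'")
  df[order(df$index), , drop = FALSE]
}

#' Fisher-z connectivity matrix from regional time series
#'
#' Computes the Pearson correlation between every pair of regional signals
#' and applies the Fisher r-to-z transform `z = atanh(r)`. The diagonal is
#' stored as 0 and excluded from all downstream computation.
#'
#' @param ts an [roi_timeseries()] object.
#' @return An object of class `z_connectivity` with elements `z` (symmetric
#'   N x N matrix, zero diagonal) and `region_labels`.
#' @export
compute_connectivity <- function(ts) {
  stopifnot(inherits(ts, "roi_timeseries"))
  r <- stats::cor(ts$values)
  off <- abs(r[upper.tri(r)])
  if (any(off >= 1 - 1e-12)) {
    idx <- which(upper.tri(r) & abs(r) >= 1 - 1e-12, arr.ind = TRUE)
    stop("perfectly correlated regions (|r| = 1): ",
         paste(ts$region_labels[idx[1, 1]], ts$region_labels[idx[1, 2]],
               sep = " ~ "), "; Fisher transform diverges")
  }
  z <- atanh(r)
  diag(z) <- 0
  z <- (z + t(z)) / 2   # enforce exact symmetry against rounding
  structure(list(z = z, region_labels = ts$region_labels),
            class = "z_connectivity")
}

#' @export
print.z_connectivity <- function(x, ...) {
  cat(sprintf("z_connectivity: %d regions, mean |z| = %.3f\n",
              ncol(x$z), mean(abs(x$z[upper.tri(x$z)]))))
  invisible(x)
}

z_connectivity_from_matrix <- function(z, region_labels = NULL) {
  z <- as.matrix(z)
  if (nrow(z) != ncol(z)) stop("connectivity matrix must be square")
  if (max(abs(z - t(z))) > 1e-8) stop("connectivity matrix must be symmetric")
  diag(z) <- 0
  if (is.null(region_labels))
    region_labels <- colnames(z)
  if (is.null(region_labels))
    region_labels <- sprintf("R%03d", seq_len(ncol(z)))
  dimnames(z) <- list(region_labels, region_labels)
  structure(list(z = z, region_labels = region_labels), class = "z_connectivity")
}

#' Cache a connectivity matrix as a delimited square table
#' @param conn a `z_connectivity` object.
#' @param path output TSV path.
#' @export
write_connectivity <- function(conn, path) {
  stopifnot(inherits(conn, "z_connectivity"))
  m <- conn$z
  colnames(m) <- conn$region_labels
  data.table::fwrite(as.data.frame(m), path, sep = "\t")
  invisible(path)
}

#' @rdname write_connectivity
#' @param path path of a square table written by [write_connectivity()].
#' @export
read_connectivity <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  z_connectivity_from_matrix(as.matrix(df), colnames(df))
}

#' Sparsity grid for the threshold sweep
#'
#' The default grid spans sparsity 0.11 to 0.34 in steps of 0.01
#' (24 levels), the range over which thresholded 90-region networks keep a
#' mean degree above `2 ln(N)` while remaining in the small-world regime.
#'
#' @param s_min,s_max,step sweep limits and increment, each in (0, 1).
#' @return Object of class `sparsity_grid` with element `values`.
#' @export
sparsity_grid <- function(s_min = 0.11, s_max = 0.34, step = 0.01) {
  if (!(s_min > 0 && s_max < 1 && s_max >= s_min && step > 0))
    stop("require 0 < s_min <= s_max < 1 and step > 0")
  values <- seq(s_min, s_max, by = step)
  structure(list(s_min = s_min, s_max = s_max, step = step,
                 values = round(values, 10)),
            class = "sparsity_grid")
}

# Total order on upper-triangular pairs: decreasing |z|, ties broken by
# ascending (i, j). Shared by binarize_at_sparsity() and sweep_sparsity()
# so that edge sets are nested across levels.
pair_ranking <- function(z) {
  n <- ncol(z)
  ut <- which(upper.tri(z), arr.ind = TRUE)
  a <- abs(z[upper.tri(z)])
  ord <- order(-a, ut[, 1L], ut[, 2L])
  list(i = ut[ord, 1L], j = ut[ord, 2L], n = n)
}

edge_count_for <- function(s, n) {
  as.integer(floor(s * n * (n - 1) / 2 + 0.5))  # half-up rounding
}

make_binary_network <- function(rank, k, s) {
  n <- rank$n
  adj <- matrix(0L, n, n)
  if (k > 0L) {
    idx <- seq_len(k)
    adj[cbind(rank$i[idx], rank$j[idx])] <- 1L
    adj[cbind(rank$j[idx], rank$i[idx])] <- 1L
  }
  structure(list(adjacency = adj, sparsity = s, n_nodes = n),
            class = "binary_network")
}

#' Binarize a connectivity matrix at one sparsity level
#'
#' Keeps exactly `round(s * N(N-1)/2)` undirected edges: the pairs with the
#' largest absolute Fisher-z values (equivalently largest |r|, since atanh
#' is strictly increasing). Ties are broken by ascending (i, j) order so the
#' result is deterministic; the correlation sign is discarded.
#'
#' @param conn a `z_connectivity` object.
#' @param s target sparsity, in (0, 1): the fraction of possible edges kept.
#' @return A `binary_network`: list with `adjacency` (0/1, symmetric, zero
#'   diagonal), `sparsity`, `n_nodes`.
#' @export
binarize_at_sparsity <- function(conn, s) {
  stopifnot(inherits(conn, "z_connectivity"))
  if (!(is.numeric(s) && length(s) == 1L && s > 0 && s < 1))
    stop("sparsity must be a single number in (0, 1)")
  rank <- pair_ranking(conn$z)
  n <- rank$n
  k <- edge_count_for(s, n)
  max_k <- n * (n - 1L) / 2L
  if (k == 0L) warning("sparsity ", s, " rounds to an empty graph")
  if (k == max_k) warning("sparsity ", s, " rounds to a complete graph")
  make_binary_network(rank, k, s)
}

#' @export
print.binary_network <- function(x, ...) {
  cat(sprintf("binary_network: %d nodes, %d edges (sparsity %.3f)\n",
              x$n_nodes, sum(x$adjacency) / 2L, x$sparsity))
  invisible(x)
}

#' Threshold sweep: one binary network per sparsity level
#'
#' Sorts the pairs once and takes nested prefixes, so the edge set at each
#' level is a subset of the next (monotone thresholding).
#'
#' @param conn a `z_connectivity` object.
#' @param grid a [sparsity_grid()].
#' @return List of `binary_network` objects, one per grid level.
#' @export
sweep_sparsity <- function(conn, grid = sparsity_grid()) {
  stopifnot(inherits(conn, "z_connectivity"), inherits(grid, "sparsity_grid"))
  rank <- pair_ranking(conn$z)
  lapply(grid$values, function(s) {
    k <- edge_count_for(s, rank$n)
    make_binary_network(rank, k, s)
  })
}

#' Minimum-threshold rule: mean degree above 2 ln(N)
#'
#' Sparse thresholds produce fragmented graphs whose metrics are unstable;
#' the customary lower bound requires the average nodal degree to exceed
#' `2 ln(N)`. Returns `TRUE` when the network satisfies the rule.
#'
#' @param net a `binary_network`.
#' @return logical flag.
#' @export
check_min_sparsity <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  mean(colSums(net$adjacency)) > 2 * log(net$n_nodes)
}
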