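#' Resolved configuration of a full study run
#'
#' Defaults reproduce the canonical analysis: sparsity sweep 0.11-0.34 in
#' steps of 0.01, 100 degree-preserving nulls per network with 10 attempted
#' swaps per edge, 10000 label permutations, FDR at q = 0.05 across regions,
#' hub sign test at corrected alpha = 0.002, and module decomposition at a
#' representative sparsity of 0.15.
#'
#' @param grid a [sparsity_grid()].
#' @param n_random null-ensemble size per network.
#' @param swap_factor attempted swaps per edge when rewiring.
#' @param n_perm label permutations for group tests.
#' @param fdr_q FDR level for nodal contrasts.
#' @param hub_alpha corrected alpha of the hub sign test.
#' @param modularity_sparsity representative sparsity for module
#'   decomposition and per-subject module counts.
#' @param master_seed seed from which every random stream is derived.
#' @param skip_nulls skip null ensembles (normalized efficiencies absent).
#' @param refine Kernighan-Lin refinement in community detection.
#' @param verbose emit progress messages.
#' @return list of class `run_config`.
#' @export
run_config <- function(grid = sparsity_grid(), n_random = 100L,
                       swap_factor = 10L, n_perm = 10000L, fdr_q = 0.05,
                       hub_alpha = 0.002, modularity_sparsity = 0.15,
                       master_seed = 1L, skip_nulls = FALSE,
                       refine = TRUE, verbose = FALSE) {
  structure(as.list(environment()), class = "run_config")
}

#' Load and validate a cohort from a subject manifest
#'
#' The manifest is a TSV with required columns `subject_id`, `file`,
#' `group`, `age`, `sex` and optional `updrs_motor`; `file` paths are
#' resolved relative to the manifest. Exactly two group labels are
#' required, and every subject's region count must agree (and match the
#' region table when one is supplied).
#'
#' @param path manifest TSV path.
#' @param regions optional path to a region-label table
#'   (see [read_region_labels()]).
#' @return list of class `cohort` with `manifest` and `timeseries`.
#' @export
load_manifest <- function(path, regions = NULL) {
  man <- data.table::fread(path, data.table = FALSE)
  required <- c("subject_id", "file", "group", "age", "sex")
  missing_cols <- setdiff(required, names(man))
  if (length(missing_cols))
    stop("manifest is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(man$subject_id))
    stop("duplicate subject_id: ",
         paste(unique(man$subject_id[duplicated(man$subject_id)]), collapse = ", "))
  gl <- unique(man$group)
  if (length(gl) != 2L)
    stop("expected exactly 2 group labels, found: ", paste(gl, collapse = ", "))
  if (!"updrs_motor" %in% names(man)) man$updrs_motor <- NA_real_
  base <- dirname(path)
  reg <- if (!is.null(regions)) read_region_labels(regions) else NULL
  ts <- vector("list", nrow(man))
  names(ts) <- man$subject_id
  for (i in seq_len(nrow(man))) {
    f <- man$file[i]
    if (!file.exists(f)) f <- file.path(base, man$file[i])
    ts[[i]] <- read_timeseries(f, subject_id = man$subject_id[i])
    if (!is.null(reg) && ncol(ts[[i]]$values) != nrow(reg))
      stop("subject ", man$subject_id[i], ": ", ncol(ts[[i]]$values),
           " regions in series but ", nrow(reg), " in region table")
    if (i > 1L && ncol(ts[[i]]$values) != ncol(ts[[1L]]$values))
      stop("subject ", man$subject_id[i], ": region count differs from ",
           man$subject_id[1L])
  }
  structure(list(manifest = man, timeseries = ts), class = "cohort")
}

signif6 <- function(df) {
  for (j in seq_along(df)) if (is.double(df[[j]])) df[[j]] <- signif(df[[j]], 6L)
  df
}

#' Run the full connectome topology study
#'
#' For every subject: Fisher-z connectivity, sparsity sweep, global and
#' nodal metric curves, degree-preserving null normalisation and AUC
#' summaries. Then group inference: covariate-adjusted permutation tests on
#' AUCs (global metrics, and each nodal metric per region with BH-FDR),
#' per-level pooled t-test profiles for the global metrics, per-subject
#' module counts and group-mean network decomposition at the representative
#' sparsity, betweenness hub detection per group, and Pearson correlation
#' of surviving nodal AUCs with the clinical score. Deterministic given
#' `config$master_seed`.
#'
#' @param cohort a `cohort` from [generate_cohort()] or [load_manifest()].
#' @param config a [run_config()].
#' @param out_dir optional directory for result tables and a JSON summary.
#' @return list of class `study_result`.
#' @export
run_study <- function(cohort, config = run_config(), out_dir = NULL) {
  stopifnot(inherits(cohort, "cohort"), inherits(config, "run_config"))
  man <- cohort$manifest
  n_sub <- nrow(man)
  grid <- config$grid
  nl <- length(grid$values)
  say <- function(...) if (isTRUE(config$verbose)) message(sprintf(...))
  groups <- unique(man$group)
  # patient-like group first when present, for a stable contrast direction
  if ("patient" %in% groups) groups <- c("patient", setdiff(groups, "patient"))
  is_a <- man$group == groups[1L]

  say("connectivity + metric curves for %d subjects", n_sub)
  conns <- lapply(seq_len(n_sub), function(i)
    compute_connectivity(cohort$timeseries[[man$subject_id[i]]]))
  if (!check_min_sparsity(binarize_at_sparsity(conns[[1L]], grid$values[1L])))
    warning("mean degree at the lowest sparsity level is below 2 ln(N); ",
            "metrics there may be unstable", call. = FALSE)
  curves <- lapply(conns, metric_curves, grid = grid)
  n_reg <- nrow(curves[[1L]]$degree)
  regions <- rownames(curves[[1L]]$degree)

  null_seeds <- matrix(derive_seeds(config$master_seed, n_sub * nl, salt = 1L),
                       n_sub, nl)
  if (!config$skip_nulls) {
    say("null ensembles: %d subjects x %d levels x %d nulls",
        n_sub, nl, config$n_random)
    for (i in seq_len(n_sub)) {
      nets <- sweep_sparsity(conns[[i]], grid)
      egn <- eln <- numeric(nl)
      for (k in seq_len(nl)) {
        ens <- null_efficiencies(nets[[k]], n_random = config$n_random,
                                 master_seed = null_seeds[i, k],
                                 swap_factor = config$swap_factor)
        nm <- normalize_efficiencies(curves[[i]]$e_glob[k],
                                     curves[[i]]$e_loc[k], ens)
        egn[k] <- nm$e_glob_norm
        eln[k] <- nm$e_loc_norm
      }
      curves[[i]]$e_glob_norm <- egn
      curves[[i]]$e_loc_norm <- eln
    }
  }

  global_names <- c("e_glob", "e_loc",
                    if (!config$skip_nulls) c("e_glob_norm", "e_loc_norm"))
  auc_global <- sapply(global_names, function(m)
    vapply(curves, function(cv) auc_trapezoid(cv[[m]], grid), numeric(1L)))
  nodal_names <- c("degree", "efficiency", "betweenness")
  auc_nodal <- lapply(nodal_names, function(m)
    t(vapply(curves, function(cv)
      apply(cv[[m]], 1L, auc_trapezoid, grid = grid), numeric(n_reg))))
  names(auc_nodal) <- nodal_names

  say("covariate adjustment + %d permutations", config$n_perm)
  X <- cbind(auc_global, do.call(cbind, auc_nodal))
  X_res <- apply(X, 2L, residualize, age = man$age, sex = man$sex)
  perm_seed <- derive_seeds(config$master_seed, 1L, salt = 2L)
  pm <- perm_mean_diffs(X_res, is_a, config$n_perm, perm_seed)
  pvals <- (1 + colSums(sweep(abs(pm$null), 2L, abs(pm$obs), ">="))) /
    (config$n_perm + 1)

  idx_global <- seq_along(global_names)
  global_cmp <- data.frame(metric = global_names, region = "",
                           observed_diff = unname(pm$obs[idx_global]),
                           p_perm = unname(pvals[idx_global]),
                           n_perm = config$n_perm,
                           stringsAsFactors = FALSE)
  nodal_cmp <- do.call(rbind, lapply(seq_along(nodal_names), function(w) {
    off <- length(global_names) + (w - 1L) * n_reg
    p <- pvals[off + seq_len(n_reg)]
    data.frame(metric = nodal_names[w], region = regions,
               observed_diff = unname(pm$obs[off + seq_len(n_reg)]),
               p_perm = unname(p), n_perm = config$n_perm,
               fdr_significant = fdr_correct(p, config$fdr_q),
               stringsAsFactors = FALSE)
  }))

  profile <- do.call(rbind, lapply(global_names, function(m) {
    vals <- t(vapply(curves, `[[`, numeric(nl), m))
    do.call(rbind, lapply(seq_len(nl), function(k) {
      tt <- tryCatch(per_threshold_ttest(vals[is_a, k], vals[!is_a, k]),
                     error = function(e) list(statistic = NA_real_,
                                              p.value = NA_real_))
      data.frame(metric = m, sparsity = grid$values[k],
                 t = tt$statistic, p = tt$p.value)
    }))
  }))

  say("modularity at representative sparsity %.2f", config$modularity_sparsity)
  nets_rep <- lapply(conns, binarize_at_sparsity,
                     s = config$modularity_sparsity)
  mods <- count_modules(nets_rep[is_a], nets_rep[!is_a],
                        refine = config$refine)
  mean_parts <- lapply(groups, function(g) {
    mn <- mean_group_network(conns[man$group == g])
    newman_partition(binarize_at_sparsity(mn, config$modularity_sparsity),
                     refine = config$refine)
  })
  names(mean_parts) <- groups

  say("hub sign tests")
  hubs <- lapply(groups, function(g) {
    bc <- Reduce(`+`, lapply(curves[man$group == g], `[[`, "betweenness")) /
      sum(man$group == g)
    hub_sign_test(bc, grid, alpha = config$hub_alpha)
  })
  names(hubs) <- groups

  clin <- NULL
  scores <- man$updrs_motor[is_a]
  if (sum(is.finite(scores)) >= 4L) {
    sig <- nodal_cmp[nodal_cmp$fdr_significant, , drop = FALSE]
    if (nrow(sig)) {
      clin <- do.call(rbind, lapply(seq_len(nrow(sig)), function(r) {
        aucs <- auc_nodal[[sig$metric[r]]][is_a, match(sig$region[r], regions)]
        cc <- tryCatch(clinical_correlation(aucs, scores),
                       error = function(e) list(r = NA_real_, p = NA_real_,
                                                n = sum(is.finite(scores))))
        data.frame(metric = sig$metric[r], region = sig$region[r],
                   r = cc$r, p = cc$p, n = cc$n, stringsAsFactors = FALSE)
      }))
    }
  }

  res <- structure(list(
    config = config, groups = groups, manifest = man,
    auc_global = auc_global, auc_nodal = auc_nodal, curves = curves,
    global_comparisons = global_cmp, nodal_comparisons = nodal_cmp,
    threshold_profile = profile,
    module_counts = mods, mean_network_partitions = mean_parts,
    hub_tables = hubs, clinical_associations = clin),
    class = "study_result")
  if (!is.null(out_dir)) write_study_result(res, out_dir)
  res
}

#' Write study result tables and a JSON summary
#'
#' Tab-separated tables (floats at 6 significant digits) plus
#' `summary.json` embedding the resolved configuration; output is
#' byte-identical across runs with the same master seed.
#'
#' @param res a `study_result`.
#' @param out_dir output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_study_result <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fw <- function(df, name)
    data.table::fwrite(signif6(df), file.path(out_dir, name), sep = "\t")
  fw(res$global_comparisons, "global_comparisons.tsv")
  fw(res$nodal_comparisons, "nodal_comparisons.tsv")
  fw(res$threshold_profile, "threshold_profile.tsv")
  for (g in res$groups)
    fw(res$hub_tables[[g]], paste0("hubs_", g, ".tsv"))
  counts <- data.frame(
    subject_id = c(res$manifest$subject_id[res$manifest$group == res$groups[1L]],
                   res$manifest$subject_id[res$manifest$group == res$groups[2L]]),
    group = rep(res$groups, c(length(res$module_counts$counts_a),
                              length(res$module_counts$counts_b))),
    n_modules = c(res$module_counts$counts_a, res$module_counts$counts_b))
  fw(counts, "module_counts.tsv")
  parts <- do.call(rbind, lapply(res$groups, function(g) {
    p <- res$mean_network_partitions[[g]]
    data.frame(group = g, region = seq_along(p$assignment),
               module = p$assignment, q = p$q)
  }))
  fw(parts, "mean_network_partitions.tsv")
  if (!is.null(res$clinical_associations))
    fw(res$clinical_associations, "clinical_associations.tsv")
  curves_tab <- do.call(rbind, lapply(seq_along(res$curves), function(i)
    metrics_table(res$curves[[i]], res$manifest$subject_id[i])))
  fw(curves_tab, "metric_curves.tsv")
  tt <- res$module_counts$test
  summary <- list(
    config = res$config[setdiff(names(res$config), "grid")],
    grid = res$config$grid$values,
    groups = res$groups,
    n_subjects = nrow(res$manifest),
    significant_global = res$global_comparisons$metric[
      res$global_comparisons$p_perm < 0.05],
    n_significant_nodal = sum(res$nodal_comparisons$fdr_significant),
    hubs = lapply(res$hub_tables, function(h) h$region[h$is_hub]),
    module_count_means = list(
      mean_a = mean(res$module_counts$counts_a),
      mean_b = mean(res$module_counts$counts_b),
      t = if (inherits(tt, "condition")) NA else tt$statistic,
      p = if (inherits(tt, "condition")) NA else tt$p.value))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(out_dir)
}
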