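#' Specification of a synthetic two-group cohort
#'
#' Describes a resting-state cohort of cleaned regional BOLD series with
#' known ground truth: block-modular correlation structure, designated hub
#' regions with boosted connectivity, a long-range (between-module)
#' correlation deficit in the patient group, age/sex covariates and a
#' clinical score tied to a designated nodal property. Defaults emulate a
#' 90-region, 230-volume, TR = 2 s two-group study (26 patients, 30
#' controls) whose patient group loses one module (two control modules
#' merge) and shows weakened between-module coupling.
#'
#' @param n_patients,n_controls group sizes.
#' @param n_regions,n_timepoints,tr_seconds series dimensions and sampling
#'   interval (seconds).
#' @param module_sizes_control,module_sizes_patient block sizes of the
#'   modular correlation structure; each must sum to `n_regions`. The
#'   patient default merges the first two control modules.
#' @param r_within,r_between within-/between-module correlation.
#' @param delta_between long-range deficit subtracted from the patient
#'   between-module correlation.
#' @param hub_regions region indices whose rows/columns are boosted by
#'   +0.1 (capped at 0.95); default one hub per control module.
#' @param band band-pass limits in Hz applied to the sampled signals.
#' @param effect_updrs correlation-scale slope linking the clinical score
#'   to the designated nodal-efficiency AUC (negative = higher score, lower
#'   efficiency).
#' @param effect_region region index whose nodal-efficiency AUC drives the
#'   clinical score.
#' @param updrs_mean,updrs_sd location/scale of the clinical score before
#'   truncation at 0.
#' @param seed master seed for the whole cohort.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 26L, n_controls = 30L,
                        n_regions = 90L, n_timepoints = 230L,
                        tr_seconds = 2,
                        module_sizes_control = rep(18L, 5L),
                        module_sizes_patient = c(36L, 18L, 18L, 18L),
                        r_within = 0.4, r_between = 0.10,
                        delta_between = 0.05,
                        hub_regions = c(1L, 19L, 37L, 55L, 73L),
                        band = c(0.01, 0.08),
                        effect_updrs = -0.5, effect_region = 10L,
                        updrs_mean = 19, updrs_sd = 9,
                        seed = 42L) {
  if (sum(module_sizes_control) != n_regions ||
      sum(module_sizes_patient) != n_regions)
    stop("module sizes must sum to n_regions")
  if (!(r_between >= 0 && r_between < r_within && r_within < 1))
    stop("require 0 <= r_between < r_within < 1")
  if (r_between - delta_between < 0)
    stop("delta_between exceeds r_between")
  if (any(hub_regions < 1L | hub_regions > n_regions))
    stop("hub_regions out of range")
  structure(as.list(environment()), class = "cohort_spec")
}

# Eigenvalue-clipping repair to the nearest positive-definite correlation
# matrix: clip eigenvalues at `floor_ev`, recompose, rescale to unit
# diagonal.
nearest_pd_correlation <- function(m, floor_ev = 1e-6) {
  es <- eigen((m + t(m)) / 2, symmetric = TRUE)
  if (min(es$values) >= floor_ev) return(m)
  v <- pmax(es$values, floor_ev)
  out <- es$vectors %*% (v * t(es$vectors))
  d <- sqrt(diag(out))
  out <- out / outer(d, d)
  (out + t(out)) / 2
}

#' Ground-truth correlation matrix for one group
#'
#' Block matrix with `r_within` inside modules and `r_between` (minus
#' `delta_between` for patients) between modules; designated hub rows and
#' columns are boosted by +0.1 (capped at 0.95), then the matrix is
#' repaired to the nearest positive-definite correlation matrix.
#'
#' @param spec a [cohort_spec()].
#' @param group `"patient"` or `"control"`.
#' @return n_regions x n_regions correlation matrix.
#' @export
build_covariance <- function(spec, group = c("control", "patient")) {
  group <- match.arg(group)
  sizes <- if (group == "patient") spec$module_sizes_patient else spec$module_sizes_control
  rb <- spec$r_between - if (group == "patient") spec$delta_between else 0
  n <- spec$n_regions
  module <- rep(seq_along(sizes), sizes)
  m <- matrix(rb, n, n)
  same <- outer(module, module, "==")
  m[same] <- spec$r_within
  hubs <- spec$hub_regions
  if (length(hubs)) {
    m[hubs, ] <- pmin(m[hubs, , drop = FALSE] + 0.1, 0.95)
    m[, hubs] <- pmin(m[, hubs, drop = FALSE] + 0.1, 0.95)
  }
  m <- (m + t(m)) / 2
  diag(m) <- 1
  nearest_pd_correlation(m)
}

# Frequency-domain band-pass applied to each column of a T x N matrix
# sampled every tr seconds: Fourier bins with |f| outside [lo, hi] Hz are
# zeroed.
bandpass_columns <- function(x, tr, band) {
  T <- nrow(x)
  k <- 0:(T - 1)
  f <- pmin(k, T - k) / (T * tr)
  keep <- f >= band[1] & f <= band[2]
  if (!any(keep))
    stop("band-pass (", band[1], "-", band[2],
         " Hz) keeps no frequency bins at this T and TR")
  xf <- stats::mvfft(x)
  xf[!keep, ] <- 0
  Re(stats::mvfft(xf, inverse = TRUE)) / T
}

#' Sample band-limited multivariate-normal time series
#'
#' Draws T i.i.d. multivariate-normal rows with the target correlation,
#' then band-passes each column over `band` Hz at the 1/TR sampling rate
#' (emulating the low-frequency content of cleaned BOLD). The empirical
#' correlation converges to the target as T grows; band-passing reduces
#' the effective degrees of freedom and so inflates its sampling variance.
#'
#' @param cor_mat positive-definite target correlation matrix.
#' @param spec a [cohort_spec()] (supplies T, TR and the band).
#' @param seed integer seed.
#' @param subject_id identifier for the returned object.
#' @return An [roi_timeseries()] object.
#' @export
sample_timeseries <- function(cor_mat, spec, seed = 1L,
                              subject_id = "subject") {
  ch <- tryCatch(chol(cor_mat),
                 error = function(e) stop("covariance is not positive definite"))
  set.seed(seed)
  T <- spec$n_timepoints
  n <- spec$n_regions
  x <- matrix(stats::rnorm(T * n), T, n) %*% ch
  x <- bandpass_columns(x, spec$tr_seconds, spec$band)
  roi_timeseries(x, subject_id = subject_id, tr_seconds = spec$tr_seconds,
                 region_labels = sprintf("R%03d", seq_len(n)))
}

truncated_normal <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      v <- stats::rnorm(1L, mean, sd)
      if (v >= lo && v <= hi) break
    }
    out[i] <- v
  }
  out
}

#' Generate a synthetic two-group cohort with ground truth
#'
#' Samples per-subject band-limited time series from the group covariance
#' matrices, assigns ages (Normal(55, 11) truncated to 30-80) and balanced
#' sex, and gives each patient a clinical score
#' `max(0, updrs_mean + updrs_sd * latent)` where the standardized latent
#' combines the subject's designated nodal-efficiency AUC (weight
#' `effect_updrs`) with independent noise. When `dir` is given, the cohort
#' is written in the exact formats the readers consume (`manifest.tsv`,
#' `regions.tsv`, one TSV per subject) together with `ground_truth.json`.
#'
#' @param spec a [cohort_spec()].
#' @param dir optional output directory.
#' @param grid [sparsity_grid()] used for the score-linked nodal AUC.
#' @return list with `spec`, `manifest` (data.frame), `timeseries` (named
#'   list of [roi_timeseries()]), `ground_truth`.
#' @export
generate_cohort <- function(spec, dir = NULL, grid = sparsity_grid()) {
  stopifnot(inherits(spec, "cohort_spec"))
  np <- spec$n_patients; nc <- spec$n_controls
  n_all <- np + nc
  seeds <- derive_seeds(spec$seed, n_all + 2L)
  ids <- c(sprintf("pat%02d", seq_len(np)), sprintf("con%02d", seq_len(nc)))
  group <- c(rep("patient", np), rep("control", nc))
  cov_p <- build_covariance(spec, "patient")
  cov_c <- build_covariance(spec, "control")
  ts <- vector("list", n_all)
  names(ts) <- ids
  for (i in seq_len(n_all))
    ts[[i]] <- sample_timeseries(if (group[i] == "patient") cov_p else cov_c,
                                 spec, seed = seeds[i], subject_id = ids[i])
  set.seed(seeds[n_all + 1L])
  age <- truncated_normal(n_all, 55, 11, 30, 80)
  sex <- rep_len(c("M", "F"), n_all)
  # clinical score tied to the designated region's nodal-efficiency AUC
  set.seed(seeds[n_all + 2L])
  e <- spec$effect_updrs
  eff_auc <- if (e == 0) rep(0, np) else vapply(seq_len(np), function(i) {
    curves <- vapply(sweep_sparsity(compute_connectivity(ts[[i]]), grid),
                     function(net) nodal_efficiency_single_cpp(
                       net$adjacency, spec$effect_region - 1L),
                     numeric(1L))
    auc_trapezoid(curves, grid)
  }, numeric(1L))
  z_auc <- if (stats::sd(eff_auc) > 0) as.numeric(scale(eff_auc)) else rep(0, np)
  latent <- e * z_auc + sqrt(max(0, 1 - e^2)) * stats::rnorm(np)
  updrs <- pmax(0, spec$updrs_mean + spec$updrs_sd * latent)
  manifest <- data.frame(subject_id = ids,
                         file = paste0(ids, ".tsv"),
                         group = group, age = age, sex = sex,
                         updrs_motor = c(updrs, rep(NA_real_, nc)),
                         stringsAsFactors = FALSE)
  ground_truth <- list(
    module_sizes_control = spec$module_sizes_control,
    module_sizes_patient = spec$module_sizes_patient,
    r_within = spec$r_within, r_between = spec$r_between,
    delta_between = spec$delta_between,
    hub_regions = spec$hub_regions,
    effect_updrs = spec$effect_updrs, effect_region = spec$effect_region,
    seed = spec$seed)
  out <- list(spec = spec, manifest = manifest, timeseries = ts,
              ground_truth = ground_truth)
  class(out) <- "cohort"
  if (!is.null(dir)) write_cohort(out, dir)
  out
}

#' Write a generated cohort to disk
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- cohort$manifest
  data.table::fwrite(man, file.path(dir, "manifest.tsv"), sep = "\t")
  n <- cohort$spec$n_regions
  regions <- data.frame(index = seq_len(n),
                        name = sprintf("R%03d", seq_len(n)),
                        x = 0, y = 0, z = 0)
  data.table::fwrite(regions, file.path(dir, "regions.tsv"), sep = "\t")
  for (i in seq_len(nrow(man)))
    data.table::fwrite(as.data.frame(cohort$timeseries[[man$subject_id[i]]]$values),
                       file.path(dir, man$file[i]), sep = "\t")
  jsonlite::write_json(cohort$ground_truth,
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
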