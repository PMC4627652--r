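#' Area under a metric-versus-sparsity curve
#'
#' Trapezoidal summary scalar `sum_k (Y(S_k) + Y(S_k+1)) * dS / 2`, making
#' group contrasts independent of any single threshold choice. On the
#' default grid (0.11 to 0.34) the integration width is 0.23, so a constant
#' curve c integrates to 0.23 c.
#'
#' @param y metric values, one per grid level.
#' @param grid a [sparsity_grid()] (or numeric vector of levels).
#' @return scalar AUC.
#' @export
auc_trapezoid <- function(y, grid = sparsity_grid()) {
  s <- if (inherits(grid, "sparsity_grid")) grid$values else as.numeric(grid)
  if (length(y) != length(s)) stop("curve and grid lengths differ")
  if (length(s) < 2L) stop("need at least 2 grid levels")
  sum((y[-1L] + y[-length(y)]) / 2 * diff(s))
}

#' Remove age and sex effects by linear regression
#'
#' Ordinary-least-squares residuals of a per-subject value on an intercept,
#' age, and a 0/1 sex code; applied to AUC values once, before permutation
#' testing, so group contrasts are adjusted for these confounds.
#'
#' @param values numeric vector, one value per subject.
#' @param age numeric vector of ages (years).
#' @param sex vector coercible to two levels (e.g. "M"/"F" or 0/1).
#' @return numeric residual vector, orthogonal to the covariates.
#' @export
residualize <- function(values, age, sex) {
  n <- length(values)
  if (n < 3L) stop("need at least 3 subjects")
  sex01 <- if (is.numeric(sex)) sex else as.numeric(factor(sex)) - 1
  X <- cbind(intercept = 1, age = age, sex = sex01)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[seq.int(qrX$rank + 1L, ncol(X))]]
    stop("collinear covariate(s): ", paste(dropped, collapse = ", "))
  }
  as.numeric(qr.resid(qrX, values))
}

# Shared machinery: permuted group-mean differences for a matrix of values
# (subjects x variables) under fixed group sizes. Returns the observed
# difference (group A - group B) and the n_perm x n_vars null matrix.
perm_mean_diffs <- function(X, is_a, n_perm, seed) {
  X <- as.matrix(X)
  n <- nrow(X)
  na <- sum(is_a)
  nb <- n - na
  if (na < 2L || nb < 2L) stop("both groups need at least 2 subjects")
  w_obs <- ifelse(is_a, 1 / na, -1 / nb)
  obs <- drop(crossprod(w_obs, X))
  set.seed(seed)
  W <- matrix(-1 / nb, n_perm, n)
  for (p in seq_len(n_perm))
    W[p, sample.int(n, na)] <- 1 / na
  list(obs = obs, null = W %*% X)
}

#' Two-group permutation test on (residualized) AUC values
#'
#' The statistic is the difference of group means. Group labels are
#' shuffled preserving group sizes; the two-tailed p-value is
#' `(1 + #{|null| >= |observed|}) / (n_perm + 1)`, which is valid (never
#' zero) and direction-agnostic.
#'
#' @param a,b numeric vectors for the two groups (order: observed
#'   difference is `mean(a) - mean(b)`).
#' @param n_perm number of label permutations (default 10000).
#' @param seed integer seed for the permutation stream.
#' @return list with `observed_diff`, `p_perm`, `n_perm`.
#' @export
permutation_test <- function(a, b, n_perm = 10000L, seed = 1L) {
  x <- c(a, b)
  is_a <- c(rep(TRUE, length(a)), rep(FALSE, length(b)))
  pm <- perm_mean_diffs(matrix(x, ncol = 1L), is_a, n_perm, seed)
  p <- (1 + sum(abs(pm$null[, 1L]) >= abs(pm$obs))) / (n_perm + 1)
  list(observed_diff = unname(pm$obs), p_perm = p, n_perm = n_perm)
}

#' Pooled-variance two-sample t-test
#'
#' Student's two-tailed t-test assuming equal variances, used for the
#' per-sparsity-level significance profile (the AUC permutation test
#' remains the primary inference) and for comparing module counts.
#'
#' @param a,b numeric vectors for the two groups.
#' @return list with `statistic`, `df`, `p.value`.
#' @export
per_threshold_ttest <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("both groups need at least 2 subjects")
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 <= 0) stop("zero pooled variance: groups are constant")
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(statistic = tstat, df = df,
       p.value = 2 * stats::pt(-abs(tstat), df))
}

#' Benjamini-Hochberg significance flags
#'
#' Step-up false-discovery-rate control at level `q` across a family of
#' p-values (e.g. the 90 regions of a nodal metric).
#'
#' @param pvals numeric p-values in \[0, 1\].
#' @param q FDR level (default 0.05).
#' @return logical vector of rejection flags, monotone in p.
#' @export
fdr_correct <- function(pvals, q = 0.05) {
  stopifnot(all(pvals >= 0 & pvals <= 1))
  stats::p.adjust(pvals, method = "BH") <= q
}

#' Hub detection by sign test on betweenness curves
#'
#' A region counts as exceeding at a sparsity level when its group-level
#' betweenness lies above the across-region mean + SD at that level. Under
#' the null "not a hub" each level exceeds with probability at most 1/2, so
#' the one-tailed sign-test p-value is `P[Binomial(n_levels, 1/2) >=
#' n_exceed]`. P-values are BH-corrected across regions and a region is a
#' hub when the adjusted value falls below `alpha` (default 0.002).
#'
#' @param b_curves numeric regions x levels matrix of group-level
#'   betweenness (subject curves averaged within group).
#' @param grid the [sparsity_grid()] the curves were computed on.
#' @param alpha corrected significance level (default 0.002).
#' @return data.frame with region, n_exceed, p_sign, p_fdr, is_hub.
#' @export
hub_sign_test <- function(b_curves, grid = sparsity_grid(), alpha = 0.002) {
  b_curves <- as.matrix(b_curves)
  nl <- ncol(b_curves)
  if (nl < 2L) stop("need at least 2 grid levels")
  if (inherits(grid, "sparsity_grid") && nl != length(grid$values))
    stop("curve length does not match grid")
  thr <- colMeans(b_curves) + apply(b_curves, 2L, stats::sd)
  n_exceed <- rowSums(sweep(b_curves, 2L, thr, ">"))
  p_sign <- stats::pbinom(n_exceed - 1L, nl, 0.5, lower.tail = FALSE)
  p_fdr <- stats::p.adjust(p_sign, method = "BH")
  data.frame(region = if (is.null(rownames(b_curves)))
               sprintf("R%03d", seq_len(nrow(b_curves))) else rownames(b_curves),
             n_exceed = as.integer(n_exceed),
             p_sign = p_sign, p_fdr = p_fdr,
             is_hub = p_fdr < alpha,
             stringsAsFactors = FALSE)
}

#' Element-wise mean connectivity across subjects
#'
#' Averages Fisher-z matrices over a group; the group-mean network is then
#' binarized at a representative sparsity and decomposed into modules.
#'
#' @param conns list of `z_connectivity` objects with identical regions.
#' @return a `z_connectivity` holding the mean matrix.
#' @export
mean_group_network <- function(conns) {
  if (!length(conns)) stop("need at least one subject")
  labs <- conns[[1L]]$region_labels
  for (cn in conns)
    if (!identical(cn$region_labels, labs))
      stop("subjects have mismatched region sets")
  zsum <- Reduce(`+`, lapply(conns, `[[`, "z"))
  z_connectivity_from_matrix(zsum / length(conns), labs)
}

#' Pearson correlation between a nodal AUC and clinical scores
#'
#' Applied only to metrics/regions that survived group-difference testing.
#' Two-tailed p-value from the t transform of r on n - 2 degrees of
#' freedom.
#'
#' @param aucs per-subject nodal AUC values.
#' @param scores paired clinical scores (e.g. UPDRS motor, higher = worse).
#' @return list with `r`, `p`, `n`.
#' @export
clinical_correlation <- function(aucs, scores) {
  keep <- is.finite(aucs) & is.finite(scores)
  aucs <- aucs[keep]; scores <- scores[keep]
  n <- length(aucs)
  if (n < 4L) stop("need at least 4 paired observations")
  if (stats::sd(aucs) == 0 || stats::sd(scores) == 0)
    stop("zero variance in correlation input")
  ct <- stats::cor.test(aucs, scores, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Module counts per subject with a group contrast
#'
#' Decomposes each subject's network at a representative sparsity and
#' compares the number of modules between groups with the pooled t-test.
#'
#' @param nets_a,nets_b lists of `binary_network` objects (one per subject)
#'   for the two groups.
#' @param refine passed to [newman_partition()].
#' @return list with `counts_a`, `counts_b`, and the t-test result `test`
#'   (or the error condition if the counts are degenerate).
#' @export
count_modules <- function(nets_a, nets_b, refine = TRUE) {
  ca <- vapply(nets_a, function(n) newman_partition(n, refine)$n_modules, integer(1L))
  cb <- vapply(nets_b, function(n) newman_partition(n, refine)$n_modules, integer(1L))
  tt <- tryCatch(per_threshold_ttest(ca, cb), error = function(e) e)
  list(counts_a = ca, counts_b = cb, test = tt)
}
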