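test_that("group covariance matrices have the planted block structure", {
  spec <- cohort_spec()
  # explicit 4x4 block construction, no hubs, no deficit
  s4 <- cohort_spec(n_regions = 4L, n_timepoints = 30L,
                    module_sizes_control = c(2L, 2L),
                    module_sizes_patient = c(2L, 2L),
                    r_within = 0.5, r_between = 0, delta_between = 0,
                    hub_regions = integer(0), effect_region = 1L)
  m <- build_covariance(s4, "control")
  expect_equal(m, rbind(c(1, .5, 0, 0), c(.5, 1, 0, 0),
                        c(0, 0, 1, .5), c(0, 0, .5, 1)), tolerance = 1e-12)
  expect_equal(build_covariance(s4, "patient"), m, tolerance = 1e-12)

  ctl <- build_covariance(spec, "control")
  pat <- build_covariance(spec, "patient")
  expect_equal(diag(ctl), rep(1, 90))
  expect_gt(min(eigen(ctl, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_gt(min(eigen(pat, symmetric = TRUE, only.values = TRUE)$values), 0)
  # hub rows are boosted
  non_hub <- setdiff(2:18, spec$hub_regions)
  expect_gt(mean(ctl[spec$hub_regions[1], non_hub]),
            mean(ctl[non_hub[1], non_hub[-1]]))
  # patient between-module correlation is lower by about delta_between
  modc <- rep(seq_along(spec$module_sizes_control), spec$module_sizes_control)
  modp <- rep(seq_along(spec$module_sizes_patient), spec$module_sizes_patient)
  hub_mask <- outer(seq_len(90) %in% spec$hub_regions,
                    seq_len(90) %in% spec$hub_regions, "|")
  bet_c <- outer(modc, modc, "!=") & upper.tri(ctl) & !hub_mask
  bet_p <- outer(modp, modp, "!=") & upper.tri(pat) & !hub_mask
  expect_equal(mean(ctl[bet_c]) - mean(pat[bet_p]), spec$delta_between,
               tolerance = 0.02)
})

test_that("infeasible specifications are rejected", {
  expect_error(cohort_spec(module_sizes_control = c(50L, 50L)), "sum")
  expect_error(cohort_spec(r_within = 0.2, r_between = 0.3), "r_between")
  expect_error(cohort_spec(delta_between = 0.5), "delta_between")
  expect_error(cohort_spec(hub_regions = 99L), "range")
})

test_that("sampled series are band-limited, deterministic, and track the target", {
  spec <- tiny_spec()
  cov_c <- build_covariance(spec, "control")
  t1 <- sample_timeseries(cov_c, spec, seed = 3)
  t2 <- sample_timeseries(cov_c, spec, seed = 3)
  expect_identical(t1$values, t2$values)
  expect_false(identical(t1$values,
                         sample_timeseries(cov_c, spec, seed = 4)$values))
  # spectrum outside the pass band is (numerically) zero
  sp <- Mod(fft(t1$values[, 1]))^2
  f <- pmin(0:(spec$n_timepoints - 1), spec$n_timepoints - (0:(spec$n_timepoints - 1))) /
    (spec$n_timepoints * spec$tr_seconds)
  out_band <- f < spec$band[1] - 1e-9 | f > spec$band[2] + 1e-9
  expect_lt(max(sp[out_band]) / max(sp), 1e-20)

  # with an identity target and long series, off-diagonal correlations vanish
  spec_id <- cohort_spec(n_patients = 1L, n_controls = 1L, n_regions = 10L,
                         n_timepoints = 5000L,
                         module_sizes_control = rep(5L, 2L),
                         module_sizes_patient = rep(5L, 2L),
                         hub_regions = integer(0), effect_region = 1L)
  # band-passing cuts the effective dof to ~ T * bandwidth / Nyquist (~1400
  # here), so each off-diagonal r has SD ~ 0.027
  ts <- sample_timeseries(diag(10), spec_id, seed = 5)
  r <- cor(ts$values)
  expect_lt(mean(abs(r[upper.tri(r)])), 0.05)
  expect_lt(max(abs(r[upper.tri(r)])), 4 / sqrt(1400))
})

test_that("generated cohorts have the right shape, scores, and files", {
  spec <- tiny_spec(seed = 21)
  dir <- withr::local_tempdir()
  coh <- generate_cohort(spec, dir = dir)
  man <- coh$manifest
  expect_equal(nrow(man), 10L)
  expect_equal(sum(man$group == "patient"), 5L)
  expect_true(all(man$age >= 30 & man$age <= 80))
  expect_true(all(man$sex %in% c("M", "F")))
  expect_true(all(man$updrs_motor[man$group == "patient"] >= 0))
  expect_true(all(is.na(man$updrs_motor[man$group == "control"])))
  # files round-trip through the pipeline readers losslessly
  coh2 <- load_manifest(file.path(dir, "manifest.tsv"),
                        regions = file.path(dir, "regions.tsv"))
  expect_equal(coh2$manifest$subject_id, man$subject_id)
  for (id in man$subject_id)
    expect_equal(coh2$timeseries[[id]]$values, coh$timeseries[[id]]$values,
                 tolerance = 1e-12)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_equal(gt$delta_between, spec$delta_between)
  # determinism of the whole cohort
  coh3 <- generate_cohort(tiny_spec(seed = 21))
  expect_identical(coh3$manifest, coh$manifest)
  expect_identical(coh3$timeseries[[1]]$values, coh$timeseries[[1]]$values)
})

test_that("clinical scores carry the planted negative association", {
  spec <- cohort_spec(n_patients = 26L, n_controls = 2L, seed = 31)
  coh <- generate_cohort(spec)
  pat <- coh$manifest[coh$manifest$group == "patient", ]
  grid <- sparsity_grid()
  aucs <- vapply(pat$subject_id, function(id) {
    nets <- sweep_sparsity(compute_connectivity(coh$timeseries[[id]]), grid)
    auc_trapezoid(vapply(nets, function(nt)
      nodal_efficiency(nt)[spec$effect_region], numeric(1)), grid)
  }, numeric(1))
  expect_lt(cor(aucs, pat$updrs_motor), 0)
})
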