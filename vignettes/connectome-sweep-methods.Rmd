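---
title: "Sparsity-swept topology of functional brain networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparsity-swept topology of functional brain networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(connsweep)
```

# The analysis in one page

`connsweep` implements a complete graph-theoretical analysis of resting-state
functional connectomes for a two-group (patient/control) design:

1. **Network construction.** Each subject contributes a T x N matrix of
   cleaned regional BOLD signals (defaults: T = 230 volumes at TR = 2 s,
   N = 90 regions of an anatomical parcellation). Pearson correlations
   between all region pairs are variance-stabilised with Fisher's
   r-to-z transform, `z = atanh(r)`. Because atanh is odd and strictly
   increasing, ranking pairs by |z| or |r| is equivalent; we operate on |z|.
2. **Proportional thresholding.** At sparsity S the network keeps exactly
   `round(S * N(N-1)/2)` edges — the pairs with largest |z| — so every
   subject's graph has identical node and edge counts and group contrasts
   reflect topology, not overall connectivity strength. Rather than pick one
   S, the analysis sweeps S = 0.11, 0.12, ..., 0.34 (24 levels). The lower
   end keeps the mean degree above `2 ln N` (9.0 at N = 90; mean degree at
   S = 0.11 is 2 x 441/90 = 9.8), a standard estimability rule for
   small-world metrics; `check_min_sparsity()` flags grids that violate it.
3. **Topological metrics.** On each binary graph:
   global efficiency `E_glob = mean over ordered pairs of 1/L_ij`
   (unreachable pairs contribute 0, the efficiency formalism's resolution of
   disconnected graphs — no infinity ever propagates); local efficiency
   `E_loc = mean_i E_glob(G_i)` with `G_i` the subgraph induced on i's
   neighbours (i excluded; fewer than two neighbours contributes 0); nodal
   degree `K_i`; nodal efficiency `E_i` (so `mean(E_i) = E_glob` is an exact
   identity we test at 1e-12); and betweenness `B_i`, the sum over unordered
   pairs of the fraction of shortest paths through i (Brandes' algorithm;
   the unordered convention halves all values uniformly and does not affect
   contrasts).
4. **Degree-matched nulls.** Each graph is compared with 100 random graphs
   produced by Markov-chain double-edge swaps that preserve the exact degree
   sequence (10 attempted swaps per edge; impossible swaps are skipped and
   counted). `E_glob(real)/E_glob(random) ~ 1` together with
   `E_loc(real)/E_loc(random) > 1` is the efficiency-based small-world
   signature. Connectedness is not enforced on nulls; the efficiency
   formalism handles fragmentation.
5. **Modularity.** Newman's spectral algorithm: recursive leading-eigenvector
   bisection of the modularity matrix `B = A - k k'/(2m)`, with
   Kernighan-Lin single-node fine-tuning after each bisection (on by
   default), accepting a split only when it increases the Newman-Girvan
   quality `Q`. Subject networks and the group-mean networks are decomposed
   at a representative sparsity (default 0.15), and per-subject module
   counts are compared between groups with a pooled t-test.
6. **Inference.** Every metric curve is summarised by its trapezoidal area
   under the curve (AUC) over the sweep (width 0.23 for the default grid),
   making conclusions threshold-free. Age and sex effects are removed from
   the AUCs once by OLS residualization; group differences are then tested
   with a label-permutation test (10000 permutations; two-tailed
   `p = (1 + #{|null| >= |obs|}) / (n_perm + 1)`). Nodal metrics are
   corrected across regions with Benjamini-Hochberg FDR at q = 0.05. Hubs
   are regions whose group-level betweenness exceeds the across-region
   mean + SD consistently over levels, assessed with a one-tailed sign test
   (`P[Bin(24, 1/2) >= n_exceed]`), BH-corrected, at alpha = 0.002. Nodal
   AUCs of regions surviving the group contrast are correlated with the
   clinical score (Pearson r, two-tailed p from the t transform).

# Design choices where the design was open

- **Edge-count rounding** uses half-up `floor(x + 0.5)`; the conversion from
  an edge *proportion* to a *count* is otherwise unspecified.
- **Ties at the threshold boundary** are broken by ascending (i, j) pair
  order. Real-valued correlations make ties essentially impossible, but the
  deterministic rule makes the sweep reproducible and gives exactly nested
  edge sets across levels (the sweep sorts pairs once and takes prefixes).
- **Negative correlations** are magnitude-thresholded like positive ones;
  the sign is discarded after binarization.
- **Permutation p-values are two-tailed** with +1 smoothing (never exactly
  zero, valid by construction); the direction of a difference is reported
  separately as `observed_diff` (patients minus controls).
- **Residualization before permutation** (not per-permutation refitting):
  covariate effects are removed once from the AUC vector, then labels are
  permuted on the residuals. With age and sex independent of group labels
  under the null, this is exact in distribution and far cheaper.
- **Spectral determinism.** The leading eigenvector's sign is fixed so its
  first nonzero component is positive; `which.max` tie-breaks are
  first-index; eigen-decomposition is LAPACK-deterministic. The
  Kernighan-Lin refinement recomputes its objective exactly each sweep,
  requires a gain above 1e-9 (scaled), and caps at 50 sweeps — incremental
  floating-point drift otherwise produces endless 1e-12 "improvements".
- **Hub statistic.** The group-level betweenness curve is the within-group
  mean of subject curves at each sparsity. The alternative reading — sum
  each subject's B across thresholds first — collapses each region to one
  scalar and leaves nothing for a sign test *across levels* to count, so it
  is not offered.
- **Representative sparsity for modularity** defaults to 0.15: comfortably
  above the mean-degree bound, low enough that module structure is not
  washed out by between-module edges. It is a config knob
  (`modularity_sparsity`).
- **Seeding.** One master seed fans out to per-subject, per-level,
  per-ensemble and permutation streams through a counter-based derivation
  (`derive_seeds`), so the whole study is byte-reproducible; the
  double-edge-swap kernel draws from R's RNG so C++ and R stay in one
  stream.

# The synthetic cohort generator

No subject data ship with the package; `generate_cohort()` builds cohorts
with known ground truth so that every pipeline stage can be validated:

- **Covariance model.** A block-modular correlation matrix: `r_within = 0.4`
  inside modules, `r_between = 0.10` between; controls have five modules of
  18 regions, patients four (the first two control modules merged, emulating
  the loss of a default-mode-like module); patients additionally lose
  `delta_between = 0.05` from all between-module correlations (the planted
  long-range deficit). Five designated hub regions (one per control module)
  get +0.1 on their rows/columns (capped at 0.95). Eigenvalue clipping at
  1e-6 plus diagonal rescaling repairs the matrix to the nearest
  positive-definite correlation matrix.
- **Signals.** T i.i.d. multivariate-normal rows (Cholesky factor), then a
  frequency-domain band-pass over 0.01-0.08 Hz at the 1/TR sampling rate.
  Band-passing mimics the low-frequency content of cleaned BOLD and — by
  cutting the effective degrees of freedom to roughly
  T x bandwidth/Nyquist ~ 64 at the defaults — reproduces the realistic
  sampling noise of correlation estimates. The generator makes no attempt at
  hemodynamic, autoregressive or motion realism: the pipeline consumes
  correlations only, so temporal realism beyond band-limiting would add
  nothing testable. Passing tests therefore demonstrate statistical
  correctness of the pipeline under a Gaussian block-covariance world, not
  robustness to artefacts of real fMRI.
- **Covariates and scores.** Ages ~ Normal(55, 11) truncated to [30, 80];
  sex alternates for exact balance. Patients receive a clinical severity
  score `max(0, 19 + 9 * latent)` (emulating a motor-scale distribution of
  ~19 +/- 9) where the standardized latent mixes the subject's
  nodal-efficiency AUC at a designated region (weight `effect_updrs = -0.5`)
  with independent noise — so the planted score-topology correlation is
  about -0.5, recoverable at the patients' n = 26.
- With `delta_between = 0` and identical module structure the two groups are
  exchangeable and every downstream statistic is null-distributed; this is
  the calibration configuration.

# Validation design and problem sizes

The test suite checks, among others: kernel-versus-oracle equivalence on 200
random graphs with N <= 12 against independent Floyd-Warshall distances,
explicit shortest-path enumeration, brute-force neighbour-subgraph
efficiencies and direct double-sum Q (tolerance 1e-9); spectral Q against
the exhaustive optimum over all partitions for N <= 9 (sub-optimal
bisections are flagged, never silently accepted, and never exceed the
optimum); exact edge counts and nestedness across the default grid at
N = 90; degree conservation and <= 2% null-normalisation bias on
Erdos-Renyi graphs with 100-graph ensembles; permutation calibration on 200
null cohorts (full 56-subject, 90-region size, 1000 permutations each;
rejection rate at alpha = 0.05 required in [0.02, 0.09]); effect recovery on
20 default cohorts; clinical-association recovery over 100 replicate patient
groups; and byte-identical output of two complete default-scale runs
(56 subjects, 24 levels, 100 nulls, 10000 permutations) under one master
seed. `scripts/acceptance.R` re-runs the full default study from scratch and
writes the headline quantities as JSON.

# Known limitations

- Weighted or directed variants of the metrics are out of scope, as are
  rich-club/assortativity measures and edge-level (NBS-style) statistics.
- The spectral bisection is a heuristic: optima requiring a first split that
  no sequence of accepted bisections can produce are unreachable; the
  validation quantifies how often this occurs on small graphs.
- The generator's merged-module patient structure changes within-module edge
  density under fixed-edge-count thresholding, so group contrasts in *local*
  efficiency mix the planted long-range deficit with the module-count
  difference; isolate the deficit (set both groups to the same module sizes)
  when a pure long-range manipulation is wanted.
- Voxel-level preprocessing, atlas handling and image IO are deliberately
  absent: inputs are cleaned regional time series in delimited text.
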