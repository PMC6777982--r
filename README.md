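# lagnav

Homotopic BOLD synchronization lag and its structural basis in the
post-stroke connectome.

After a stroke, resting-state BOLD activity in mirror-image (homotopic)
cortical and subcortical region pairs desynchronizes: one hemisphere's
signal is best aligned with a *temporally shifted* copy of its partner's.
`lagnav` is an R package for researchers in stroke connectomics and
network neuroscience who want to quantify that synchronization lag from
region-level time series and relate it to how efficiently the individual's
structural connectome can communicate. It covers four stages, each usable
on its own:

1. **Lag estimation.** For standardized homotopic signals the shifted
   cross-correlation over an integer TR grid is

   C(τ) = (1/n_τ) Σ_t s_i(t)·s_j(t+τ),  n_τ = T − |τ|/TR,

   for τ in [−10 s, +10 s]; the lag is the argmax, refined by parabolic
   interpolation of the peak, δ = (C(k−1) − C(k+1)) / (2[C(k−1) − 2C(k) +
   C(k+1)]). Positive lag means the right hemisphere leads.
2. **Connectome communication.** Streamline counts W are remapped to
   lengths L = −log10(W / (max(W)+1)) and routed under shortest paths
   (Λ^sp) and greedy spatial navigation (Λ^nav, navigation distance D^nav =
   Σ Euclidean hop lengths, failure on node revisit). Efficiency
   E = Σ_{i≠j} Λ_ij^{−1} / (N(N−1)) is evaluated across 10–50% proportional
   density thresholds and summarized by its area under the curve.
3. **Lesion geometry.** Per-pair region-to-lesion Euclidean distances
   (ipsilesional hemisphere, nearest lesion) and affected/unaffected
   subnetwork partitions.
4. **Cohort statistics.** Group contrasts (pooled and paired t),
   lag–distance and lag–efficiency correlations on log-remapped lag,
   variance partitioning (R² of Euclidean vs Euclidean + navigation
   distance), partial correlations controlling age/gender, ARAT motor-score
   associations, and Benjamini–Hochberg FDR control.

Clinical imaging data cannot be redistributed, so the package includes a
seeded synthetic-cohort generator (`gen_cohort()`) that plants homotopic
lags in band-limited signals via exact frequency-domain delays, embeds
distance-decaying streamline-count connectomes in space, and applies focal
spherical lesions — every downstream stage runs without any download. The
packaged clinical characteristics table (`table1_fixture()`) provides the
15-subject demographic/lesion fixture used by the analysis layer.

## Worked example

Recover a planted sub-TR lag from a noiseless pair:

```r
library(lagnav)
set.seed(99)
z      <- band_limited_series(240, tr = 2)        # latent BOLD-like process
lagged <- delay_series(z, tr = 2, tau_s = 3.1)    # left hemisphere, delayed
pk <- peak_lag(cross_correlogram(z, lagged, tr = 2, tau_max = 10))
pk$lag_seconds      # 3.100986  (planted 3.1 s, TR = 2 s)
pk$peak_correlation # 0.9920933
```

Run the full pipeline on the default planted cohort (14 stroke + 12
control, 80 regions, TR = 2 s, 240 volumes; about 10 s on one core):

```r
cohort   <- gen_cohort(cohort_config(seed = 1))
analysis <- run_full_analysis(cohort)
print(analysis)
#> <lag_analysis>
#>   group_mean_lag_t                       t =  15.0093  (p = 1.071e-13)
#>   stroke_mean_lag_s                      mean =   1.3055
#>   control_mean_lag_s                     mean =   0.2370
#>   affected_vs_unaffected_t               t =   4.6300  (p = 0.0004713)
#>   affected_mean_lag_s                    mean =   1.4681
#>   unaffected_mean_lag_s                  mean =   1.2661
#>   affected_intact_vs_unaffected_t        t =  -1.1486  (p = 0.2714)
#>   pair_loglag_vs_lesion_distance_r       r =  -0.9922  (p = 5.327e-36)
#>   lag_vs_auc_e_nav_r                     r =  -0.5323  (p = 0.05005)
#>   lag_vs_auc_e_sp_r                      r =  -0.5336  (p = 0.04939)
#>   lag_vs_auc_e_nav_partial_r             r =  -0.4837  (p = 0.1111)
#>   lag_vs_auc_e_sp_partial_r              r =  -0.4778  (p = 0.1162)
#>   pair_lag_vs_nav_efficiency_rho         rho =  -0.2595  (p = 0.1059)
#>   pair_loglag_vs_homotopic_distance_r    r =   0.1469  (p = 0.3656)
#>   pair_loglag_vs_dnav_r                  r =   0.1884  (p = 0.2445)
#>   r2_euclidean                           R2 =   0.0216
#>   r2_euclidean_plus_dnav                 R2 =   0.0960
#>   lag_vs_arat_rho                        rho =  -0.6137  (p = 0.01958)
#>   fc_vs_arat_rho                         rho =   0.6137  (p = 0.01958)
```

Reading the output: the stroke group's mean homotopic lag (1.31 s) far
exceeds the control group's (0.24 s); within stroke subjects, lag shortens
with distance from the lesion (r = −0.99 on the planted field), subjects
with more efficient connectomes lag less under both routing schemes
(r ≈ −0.53), adding navigation distance to Euclidean distance raises the
variance explained in pair-level lag (2.2% → 9.6%), and longer lag
accompanies worse upper-limb motor function (rho = −0.61). The
`affected_intact` contrast is not planted by the generator (synthetic
subnetworks are spatially unclustered) and is reported for completeness.

A file-based run of the same chain — cohort directory, per-subject lag
tables, communication summaries, `results.tsv` — is available as
`run_pipeline(list(out = "run1", seed = 1))`, and a thin command-line
wrapper ships in `inst/cli/lagnav.R`
(`Rscript inst/cli/lagnav.R run --out run1 --seed 1`).

## The methods vignette

`vignettes/lag-navigation-methods.Rmd` documents the estimator and its
numerical behaviour (normalization, interpolation bias, tie-breaking), the
routing and thresholding conventions, the synthetic cohort's generative
model and what it does and does not emulate, and the statistical design
choices.
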