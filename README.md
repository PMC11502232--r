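# lhensemble

Unsupervised analysis of hypothalamic population activity during innate
behaviors: which recorded cells form behavior- and feeding-phase-specific
populations, and do those populations fire together preferentially during
gamma oscillations?

The package is aimed at electrophysiologists with multi-shank
extracellular recordings (spike trains per cell), a scored behavioral
ethogram (feeding / social interaction / object exploration episodes), and
a local field potential channel. It implements the full chain:

1. **Time-warped rate features** — per-cell firing rates r(t) from
   Gaussian-kernel convolution (SD 500 ms), episodes of each behavior
   warped onto a common phase axis (10 ms resolution in the mean episode),
   concatenated per cell as [feeding | social | object], z-scored, and
   reduced by PCA to the minimal *m* components with cumulative explained
   variance >= 90%.
2. **Stability-selected spectral clustering** — mutual k-NN cosine
   affinity, symmetric normalized Laplacian embedding, seeded k-means;
   (k, knn) chosen by a 100-fold bootstrap scan (90% subsamples without
   replacement) scored with the adjusted Rand index and adjusted mutual
   information, maximizing both the mean and the variance-adjusted
   (mean/SD) agreement; cells kept only with silhouette > 0 in >= 95 of
   100 clustering iterations.
3. **Population naming** — clusters named by preferred behavior and
   feeding peak phase (FOn, EF, LF, FOff, Fd, Sol, Exp), with one-sample
   KS uniformity tests of peak times at Bonferroni-adjusted alpha
   (0.05/21 ≈ 0.0023 for 7 populations x 3 behaviors).
4. **Oscillation events** — slow (30–60 Hz) and fast (61–90 Hz) gamma
   events from the band-passed, rectified, smoothed envelope exceeding
   2 SD above the noise mean for >= 25 ms, extended to the 1 SD edges;
   nonrhythmic epochs where five screening bands all stay below 0.5 SD;
   multitaper PSD (NW = 3, window 1024).
5. **Cofiring ratio (CFR)** — epoch-conditioned cross-correlograms of
   cross-shank pairs (1 ms bins, unit mass), cofiring probability = mean
   normalized CCG within ±15 ms of the trigger, and

   CFR = p_cofire(nonrhythmic) / p_cofire(gamma),

   with CFR < 1 meaning stronger cofiring during gamma; significance from
   a null of 1,000 CCGs with every trigger spike shifted by U(−25, 25) s,
   and population-pair group tests (paired t / Wilcoxon signed-rank).

A first-class synthetic-data module plants all of this structure — seven
population templates, lognormal episode durations, 1/f LFP with
band-limited bursts, and gamma-coupled cell pairs — with exact ground
truth, so every stage is testable without recorded data.

## Worked example

```r
library(lhensemble)

sim <- simulate_recording("paper7", seed = 101, lfp_len_s = 0)
sim$dataset
#> <spike_dataset> 350 cells, 10 sessions, 1243969 spikes

fm <- build_feature_matrix(sim$dataset, sim$etho, pipeline_config())
fm
#> <feature_matrix> 350 cells x 3352 bins (feeding: 2486, social: 434,
#>   object: 432); 5 components retained (97.8% variance)

rep <- stability_scan(fm$reduced, 2:9, c(10, 20, 30), n_boot = 100, seed = 7)
rep$selected$by_mean_over_sd
#> $k
#> [1] 7
#> $knn
#> [1] 10

sol <- spectral_cluster(knn_cosine_graph(fm$reduced, 10), 7, seed = 3)
prof <- label_populations(fm$behavior_vectors, sol)
prof[, c("cluster", "name", "preferred_behavior", "median_phase")]
#>   cluster name preferred_behavior median_phase
#> 1       1 FOff            feeding  0.938656476
#> 2       2   EF            feeding  0.296460177
#> 3       3  Sol             social  0.001407884
#> 4       4  Exp             object  0.999798874
#> 5       5   Fd            feeding  0.442477876
#> 6       6   LF            feeding  0.696299276
#> 7       7  FOn            feeding  0.059533387
```

The seven planted populations are recovered and named correctly: the four
feeding-phase clusters peak in the planted order (median phases 0.06,
0.30, 0.70, 0.94), the near-uniform peak-time cluster is identified as the
homogeneous feeding population Fd, and the social/object populations are
Sol and Exp. Against the generator's ground truth this clustering reaches
an adjusted Rand index of 0.91 before silhouette filtering and 0.92 after.

`run_pipeline()` drives the same chain from CSV/flat-binary inputs and
writes labels, stability report, epochs, the per-pair CFR table and a
summary; `inst/cli/ensemble-dynamics` exposes `simulate` and `run`
subcommands for shell use.

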