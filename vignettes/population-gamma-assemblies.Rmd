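---
title: "Behavioral population dynamics and gamma assemblies: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Behavioral population dynamics and gamma assemblies: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`lhensemble` analyses extracellular multi-unit recordings made while an
animal freely engages in innate behaviors — feeding, social interaction,
and novel-object exploration. It answers two questions about a recorded
population: *which cells form behavior- or feeding-phase-specific
populations*, and *do those populations cofire preferentially during gamma
oscillations*? This vignette documents the models, the parameters that
matter, the synthetic data the tests rely on, and the numerical choices
made where the design was genuinely open.

## From spike trains to behavior-phase features

Each cell's firing rate is the convolution of its spike train with a
normalized Gaussian kernel, evaluated on a regular 10 ms grid. The kernel
"size" is interpreted as its standard deviation, 500 ms by default
(`kernel_sd_ms`); this is the most common convention and is configurable.
Spikes are binned to the nearest grid point before the convolution, an
approximation whose error (at most half a grid step of spike position,
0.5% of the kernel SD) is negligible at this smoothing scale. The kernel
is truncated at four standard deviations, so the rate integral conserves
the spike count to well under 1%.

Behavioral episodes of one behavior differ in duration, so rates are
*time-warped* before averaging: the number of phase bins is the mean
episode duration divided by the 10 ms warp resolution, each episode is
split into that many equal sub-intervals, and the smoothed rate is read at
each sub-interval midpoint (the 500 ms kernel makes the rate effectively
constant within a sub-interval, so the midpoint equals the sub-interval
mean for practical purposes). Bins are then averaged across episodes.
Episode intervals are half-open, so phase membership is unambiguous.

Cells from different sessions must end up with equal-length vectors to be
clustered jointly. The bin count per behavior is therefore computed from
the grand-mean episode duration pooled across *all* sessions, and every
session's episodes are warped to that shared length. This is the only
reading that yields a single concatenated vector length for all cells.

Per cell, the feeding, social and object vectors are concatenated in that
fixed order and z-scored along the row; the matrix of rows is then
centered and projected onto principal axes, keeping the smallest number of
components whose cumulative explained variance reaches `variance_target`
(0.9). The retained dimension is data-dependent by design — on recorded
datasets it can run to a hundred or more components, on the synthetic
fixtures it is typically below ten. Cells that lack episodes of some
behavior in their session, and cells with zero-variance concatenated
vectors (silent cells), are excluded with a warning before the projection.

## Stability-selected spectral clustering

The affinity graph is a symmetric binary k-nearest-neighbor graph under
the cosine metric: an edge joins two cells if either is among the other's
`knn` nearest neighbors. Spectral clustering embeds the cells with the
leading eigenvectors of the symmetric normalized graph Laplacian,
row-normalizes the embedding, and runs k-means with a greedy ++-style
initialization, ten restarts, and seeds derived deterministically from the
stage seed, so every run is reproducible. If the graph is disconnected the
affinity is regularized with a uniform 1e-8 edge weight rather than
failing; the event is logged.

The number of clusters and `knn` are chosen by a bootstrap stability scan:
for every grid cell, the full data are clustered once (the reference), and
each of `n_bootstrap` (100) bootstraps clusters a random 90% subsample and
scores the adjusted Rand index (ARI) and adjusted mutual information (AMI)
against the reference restricted to the subsample. Comparing each
replicate against a single full-data anchor costs O(bootstraps) instead of
O(bootstraps^2) for all replicate pairs; the subsamples are shared across
the grid. Both agreement metrics are chance-corrected; AMI uses the
hypergeometric expected-mutual-information correction with arithmetic-mean
normalization, and both implementations are verified in the test suite
against independent brute-force oracles (explicit pair counting;
`dhyper`-based expected MI) and against `mclust`'s ARI.

Two selection criteria are reported, mirroring the two natural readings of
"most stable": the grid argmax of the mean of the two agreement means, and
the argmax of the mean of the variance-adjusted ratios (mean/SD). Ties
break toward the smallest cluster count, then the smallest `knn`. One
boundary case needed a decision: when a grid cell is *perfectly* stable
(agreement exactly 1 in every bootstrap, SD exactly zero), the mean/SD
ratio is the limit of increasing stability, so the package scores it as
+Inf rather than dropping the cell; a cell is skipped only when its ratio
is genuinely undefined (zero mean and zero SD). Dropping zero-SD cells
would discard precisely the most stable parameter setting, which on
well-separated data is the planted one.

Cluster quality is summarized as the mean pairwise Pearson correlation of
the cells' first-five-component score vectors within versus between
clusters. Membership reliability uses silhouette consistency: the
clustering is repeated 100 times varying only the k-means seed (the graph
and embedding are fixed), per-run silhouettes are computed with the cosine
distance — matching the affinity metric, since the silhouette metric was
an open choice — and a cell is retained if its silhouette is positive in
at least 95 runs.

## Naming populations

Clusters are named from raw (Hz) warped vectors. The preferred behavior of
a cluster is the one with the highest mean-across-cells peak rate. Among
feeding-preferring clusters the package must separate the four
feeding-phase populations (FOn, EF, LF, FOff) from the homogeneous feeding
population (Fd); no explicit rule exists in the literature this package
follows, so the package uses the peak-time uniformity statistic itself:
the feeding cluster whose peak-phase distribution is closest to uniform
(smallest one-sample KS D) is Fd, and the remaining feeding clusters are
named FOn/EF/LF/FOff in order of median peak phase (generic names when
there are not exactly four). Social- and object-preferring clusters are
Sol and Exp. Peak-time uniformity is tested per population with a
one-sample KS test against Uniform(0, 1) at a Bonferroni-adjusted alpha;
the family size defaults to populations x behaviors, which reproduces the
printed 0.05 / 21 = 0.0023 for seven populations and three behaviors.

Anatomical enrichment maps are raw normalized 2D histograms (10 x 10 grid
of 70 um mediolateral by 38.8 um dorsoventral bins) of a population's
locations minus the all-cells histogram; no kernel smoothing is applied
because none is specified for the reference analysis, and raw differences
keep the unit-mass cancellation exact (each map sums to zero by
construction). Spike width is measured at 25% of the peak-to-baseline
amplitude with linear interpolation between samples; the baseline is the
waveform median.

## Oscillation events and nonrhythmic epochs

The LFP (1,250 Hz; wide-band inputs are anti-alias filtered at 0.4x the
target rate and resampled) is band-passed, rectified and smoothed to an
amplitude envelope. Filtering uses linear-phase FIR designs (`signal::fir1`)
applied by FFT convolution with group-delay compensation, i.e. zero phase;
an IIR bandpass with forward-backward filtering is numerically fragile for
the 2-4 Hz screening band at this sampling rate. Envelope smoothing is
Gaussian with a 10 ms SD (about half a slow-gamma cycle) — the smoothing
kernel is unstated in the reference analysis and is configurable.

Events in a band are maximal runs with the envelope above the noise mean
plus `detect_sd` (2) SDs lasting at least `min_event_ms` (25 ms), extended
outward to the 1 SD crossings, with overlapping extensions merged. Noise
mean and SD are the whole-session envelope statistics (single pass);
"noise" is not defined more precisely by the source analysis. Slow
(30-60 Hz) and fast (61-90 Hz; the 61 Hz lower edge follows the detailed
methods rather than the rounded abstract) gamma events are detected
independently and may overlap. Nonrhythmic epochs are times when *every*
screening band's envelope (delta 2-4, theta 5-10, beta 15-30, gamma
30-120, fast 120-200 Hz) stays below its own mean + 0.5 SD, kept when at
least 100 ms long (no minimum is stated; 100 ms accommodates a few cycles
of the slowest oscillations of interest), and minus any supplied detected
events — by definition, epochs containing detected oscillations are not
nonrhythmic, and the subtraction makes the event/nonrhythmic partition
exact even though the screening bands are wider than the detection bands.

One behavior of this detector is worth stating plainly: a threshold of
2 SD above the envelope mean is a *relative* criterion. On a stationary,
scale-free background (the pink-noise background of the synthetic tests)
the envelope spends roughly 4% of its time above that threshold at any
smoothing width, so the detector always flags the strongest few percent of
background fluctuations alongside planted bursts. Recall of strong planted
events is excellent; precision against planted truth is bounded near 0.1
on pure noise and is *not* a meaningful performance figure for this rule.
On recorded LFP the tail is dominated by genuine oscillation bursts, which
is the regime the rule is designed for.

Power spectral densities use the multitaper method (time-bandwidth 3, five
Slepian tapers, 1,024-sample windows, half overlap). The Slepian sequences
are computed by the standard symmetric tridiagonal eigenproblem and
cached; the density is one-sided and scaled so its integral matches the
signal variance.

## Cofiring and the shuffle null

Cross-correlograms (CCGs) are computed for cross-shank, within-session
cell pairs, using the spikes of the trigger cell inside a given epoch set
as trigger events; response spikes are *not* epoch-restricted (the literal
reading of the conditioning; an option restricts both). Counts in 1 ms
bins over +/-50 ms are normalized to unit mass — +/-50 ms is an
implementation choice that comfortably contains the +/-15 ms cofiring
window. The cofiring probability is the mean normalized bin value within
+/-15 ms, and the cofiring ratio (CFR) is the nonrhythmic cofiring
probability over the gamma one: CFR < 1 means stronger cofiring during
gamma. Pairs with an undefined CCG or zero gamma cofiring are excluded and
logged rather than imputed.

The null distribution shifts every epoch-selected trigger spike
independently by a uniform draw from [-25, 25] s, wrapped modulo the
session span, and recomputes the CFR; 1,000 shuffles per pair by default.
Independent per-spike shifts (rather than one shift of the whole train)
were chosen because a rigid shift preserves the within-train structure the
null is meant to destroy. Group-level comparisons between original and
control CFR use a paired t test when the paired differences pass a Shapiro
normality check at alpha 0.05 and a Wilcoxon signed-rank test otherwise,
mirroring the mixed usage in the field; the group tables are ordered
(trigger population, response population) pairs, kept separately per gamma
band.

## What the synthetic generator emulates — and what it does not

The generator plants exactly the structure the analysis assumes: seven
population templates (four Gaussian feeding-phase bumps centered at phases
0.05 / 0.30 / 0.70 / 0.95 with width 0.1, plus homogeneous feeding, social
and object populations), baselines of 1.7-3.5 Hz matching the reported
per-population averages, a 3x peak rate multiplier (the modulation depth
is unreported anywhere, so 3x is a fixed simulation choice) and mild
(0.5x) suppression during non-preferred behaviors, matching the strong
negative feeding-versus-other rate correlations of such populations.
Ethograms interleave the three behaviors with unscored gaps; feeding bout
durations are lognormal with median 22 s truncated at the 4.8 s scoring
minimum, social/object episodes lognormal with median 4 s, making feeding
bouts roughly six-fold longer, as reported. Spike trains are inhomogeneous
Poisson, simulated by thinning (exact for bounded rates). LFP background
is 1/f (pink) noise — realistic envelope statistics for threshold
calibration — with band-limited bursts whose envelope peak is calibrated
in the detection rule's own units (background envelope mean + k SD).
Assembly structure is planted by inserting synchronous spike pairs, with
uniform +/-jitter lags, only inside chosen epochs.

What the generator does **not** emulate: refractoriness, bursting and
rate nonstationarity within behaviors; correlated (shared-input) rate
fluctuations between cells beyond the planted synchrony; theta/beta
rhythmic structure in the LFP; electrode drift; spike-sorting errors.
Passing tests therefore demonstrate that the pipeline recovers the
structure it is designed to detect under its own model assumptions — not
that recorded data satisfy those assumptions.

## Problem sizes and numerical choices in the checks

The end-to-end recovery check runs the full emulated study scale — 10
sessions of 1,200 s, 350 cells — through the complete scan (8 cluster
counts x 3 knn values x 100 bootstraps); the knn grid {10, 20, 30} spans
the useful connectivity range at 350 cells. Phase-order recovery repeats
20 seeded runs at a reduced scale (6 sessions x 900 s, 210 cells) with a
single k = 7 clustering per run. CFR calibration uses 100 independent
5 Hz Poisson pairs over 30-minute sessions with the full 1,000-shuffle
null; the group-test size calibration uses 200 replicate all-null groups
of 12 pairs with 60 shuffles per pair (the group test compares original
CFR against the control mean, whose estimator variance — not count — is
what fewer shuffles affect). Degenerate inputs are handled by validation
errors (unsorted spikes, irregular grids, empty parameter ranges,
out-of-band edges), by sentinels (cells without episodes, undefined CCGs),
or by documented conventions (singleton-cluster silhouette = 0).

## Known limitations

- The bootstrap stability reference is the full-data clustering; an
  all-pairs replicate comparison is not implemented.
- Silhouette iterations vary the k-means seed only, not the subsample.
- The Fd-versus-phase-cluster naming rule is this package's own
  formalization of a descriptive practice.
- The event detector's precision on stationary backgrounds is bounded by
  the relative 2 SD threshold, as discussed above.
- CCG computations assume within-session pairs; cross-session pooling is
  not supported (or needed, as pairs are within-session by construction).
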