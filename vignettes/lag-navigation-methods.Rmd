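---
title: "Homotopic synchronization lag and connectome communication: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homotopic synchronization lag and connectome communication: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lagnav)
```

## The scientific problem

After a stroke, the resting-state BOLD signals of mirror-image (homotopic)
region pairs fall out of step: the signal of one hemisphere is best aligned
with a *temporally shifted* copy of its partner's. This synchronization lag
can exceed several seconds near the lesion and has been proposed as a
functional biomarker of post-stroke reorganization. `lagnav` implements the
full analysis chain that links this functional quantity to the structural
connectome: lag estimation from region-level time series, communication
modelling on weighted structural networks under two routing schemes, lesion
geometry, and the cohort-level statistics. Because clinical imaging data
cannot be redistributed, the package also ships a synthetic-cohort
generator that plants every effect the analysis is designed to detect, so
the whole pipeline is exercisable and testable end to end.

## Lag estimation

For a homotopic pair with standardized signals $s_i$ (right hemisphere) and
$s_j$ (left), the shifted cross-correlation over an integer grid of TR
steps is

$$C_{ij}(\tau) = \frac{1}{n_\tau} \sum_t s_i(t)\, s_j(t + \tau),
  \qquad n_\tau = T - |\tau|/\mathrm{TR},$$

with $\tau \in [-\tau_{\max}, \tau_{\max}]$ and $\tau_{\max} = 10$ s by
default (i.e. $\pm 5$ TR at TR = 2 s). The synchronization lag is the
argmax of $C_{ij}$, refined by parabolic interpolation through the three
points around the integer peak:

$$\delta = \frac{C(k^*-1) - C(k^*+1)}
  {2\,[C(k^*-1) - 2C(k^*) + C(k^*+1)]}, \qquad \delta \in [-0.5, 0.5].$$

Positive lag means the right-hemisphere signal leads. Design choices worth
making explicit:

* **Normalization.** Signals are standardized once over the full series
  with the population (1/T) standard deviation and $C$ is divided by
  $n_\tau$. This makes the zero-shift self-correlation exactly 1.
  Per-window re-standardization is *not* applied; consequently $|C(\tau)|$
  for $\tau \neq 0$ is bounded by $T/(T-|\tau|/\mathrm{TR})$, not by 1 — a
  windowed second moment of a globally standardized series can slightly
  exceed 1. The tests assert the exact bounds, not the nominal $[-1, 1]$.
* **Interpolation bias.** Because the two neighbouring correlations use
  overlap windows differing by $O(1)$ edge terms out of $T$, the parabola
  vertex carries an $O(1/T)$ offset even for a noiseless integer-sample
  shift. At $T = 240$ this is a few milliseconds; the integer-grid argmax
  itself is recovered exactly, and interpolated recovery is asserted at
  0.1 TR (noiseless) and 0.25 TR (noise sd 0.1).
* **Boundary peaks** are returned uninterpolated and flagged so saturated
  estimates can be excluded. Argmax ties break toward the smallest
  $|\tau|$, then toward negative $\tau$, for determinism and a bias toward
  synchrony.
* **Averaging** uses the absolute lag: signed averages of left/right leads
  would cancel. Signed lags are retained in the table.

## Communication on the structural connectome

Streamline-count weights $W$ are remapped to connection lengths
$L = -\log_{10}\!\big(W / (\max(W) + 1)\big)$, a strictly positive,
monotone-decreasing transform (the `printed` variant
$-\log_{10}(W/\max(W) + 1)$, which yields non-positive lengths, is exposed
behind an option for audit but never used). $\max(W)$ is taken on the
analyzed (thresholded) matrix so lengths are internally comparable.

Two routing schemes are computed:

* **Shortest paths**: $\Lambda^{sp}_{ij}$ is the globally minimal sum of
  edge lengths (Dijkstra, via igraph).
* **Navigation (greedy spatial routing)**: from $i$, repeatedly move to the
  current node's neighbour closest in Euclidean distance to the target
  $j$. Success yields the navigation path length $\Lambda^{nav}_{ij}$ (sum
  of $L$ along the walk), the navigation distance
  $D^{nav}_{ij} = d_{iu} + \cdots + d_{vj}$ (sum of Euclidean hop lengths)
  and the hop count; revisiting a node or reaching a node with no
  neighbours is a failure, scored $\infty$. Exact distance ties break
  toward the lower region index. Navigation is asymmetric; pair-level
  summaries average the two directions.

Efficiency is the mean inverse path length over ordered pairs,
$E = \sum_{i \neq j} \Lambda_{ij}^{-1} / (N(N-1))$, with failed or
disconnected pairs contributing $1/\infty = 0$. Networks are analyzed
across proportional connection densities 10%–50% in 5% steps (top-$k$
strongest undirected edges, cut-off ties broken lexicographically so nested
densities give nested edge sets), and each efficiency curve is summarized
by its trapezoidal area under the curve (AUC). Whether per-pair navigation
efficiency should be length-weighted or hop-based is ambiguous in the
field; the length-weighted $\Lambda^{nav}$ is used, with hop counts
retained. Per-pair $D^{nav}$ is summarized as the mean over densities of
successful navigations; a pair that never navigates is dropped from
distance analyses rather than imputed.

## The synthetic cohort

The generator emulates the study conditions of a clinical motor-stroke
cohort: 14 stroke + 12 control subjects, 80 regions (40 homotopic pairs),
8-minute runs of 240 volumes at TR = 2 s, band-limited to 0.009–0.08 Hz.
Specifically:

* **Parcellation.** Region centres are drawn uniformly in a brain-sized
  box and mirrored about $x = 0$, so homotopic pairing is an exact
  involution; the seven canonical resting-state subnetworks (default mode,
  executive control, sensorimotor, fronto-parietal, auditory, visual,
  subcortical) are cycled over pairs.
* **Signals.** Each pair shares a latent band-limited Gaussian process
  (white noise filtered in the frequency domain); the left-hemisphere copy
  is delayed by the planted lag via frequency-domain phase rotation, so
  fractional-sample lags are exact, plus independent band-limited noise
  (sd 0.1 against unit-variance signal).
* **Lesions and the lag field.** Each stroke subject receives one
  spherical lesion centred near a subcortical or sensorimotor region
  (right hemisphere with probability 2/3), with log-normal radius (median
  18 mm, log-sd 0.4, clamped to 6–40 mm) reflecting the orders-of-magnitude
  spread of clinical lesion volumes. The planted lag field is
  $\tau^*(p) = 2.4\,e^{-\max(d_p - r, 0)/60\text{ mm}} + 0.25$ s, where
  $d_p$ is the centroid-to-region distance and $r$ the lesion radius:
  controls sit at the 0.25 s baseline (matching sub-second healthy lags)
  and the stroke group mean lands near 1 s. Using the distance to the
  lesion *surface* makes lesion size a single latent dimension that
  simultaneously elevates lag and removes connectome edges, which is what
  induces the interindividual lag–efficiency association downstream.
* **Connectomes.** Edges appear with probability $e^{-d/130\text{ mm}}$
  and carry weights $1 + \mathrm{Poisson}(100\,e^{-d/60\text{ mm}})$, so
  weights decay with distance as streamline counts do and the full-density
  graph sits near 55% density — comfortably above the top of the 10–50%
  threshold grid. Disconnected samples are bridged at the closest
  inter-component gap. Stroke connectomes have all edges within the lesion
  sphere removed.
* **Motor score.** ARAT (0–57) is generated as
  $\mathrm{clamp}(\mathrm{round}(28 - 15\,\bar\tau^* + \varepsilon))$,
  $\varepsilon \sim N(0, 3)$, putting the cohort in the moderate-to-severe
  range (mean near 12) with worse scores for more-lagged subjects.
* **Determinism.** All randomness flows from one integer seed through a
  counter-based splitting scheme, so subject order cannot change results
  and a fixed seed reproduces the cohort byte for byte.

What the generator does **not** emulate: hemodynamic response shapes,
vascular territories, spatially clustered subnetworks, voxelwise lesion
masks (lesion membership is centre-of-mass distance), or tractography
biases. Consequently, passing tests demonstrate that the estimators and
the analysis chain recover planted effects of realistic magnitude — not
that the biological mechanisms are as modelled. One visible consequence:
because synthetic subnetworks are spatially unclustered, the
*intact-pairs-only* affected-vs-unaffected contrast is not planted and can
go either way, while the all-pairs contrast is reliably positive.

## Statistical layer

Group contrasts use two-sided pooled-variance (Student) t tests; the
affected-vs-unaffected contrast is paired across subjects, since both
means come from the same individual. Pair-level Pearson analyses use
natural-log-remapped lag (zeros floored at TR/100), so sub-second lags map
to negative values; Spearman analyses use raw lags (rank-invariant).
Partial correlations residualize both variables on age and gender and
reduce the degrees of freedom accordingly. Variance partitioning compares
OLS $R^2$ for log lag on homotopic Euclidean distance alone vs Euclidean
plus navigation distance. All p values within a family are corrected by
Benjamini–Hochberg FDR at $q = 0.05$ (the 40 per-pair contrasts form their
own family). Homotopic functional connectivity for the motor-score
comparison is the zero-lag Pearson correlation, averaged over pairs.

## Problem sizes and runtime choices

The packaged checks run at deliberately modest sizes: oracle equivalence
uses 50 random signals ($T \le 32$) and 50 random graphs ($N \le 8$, where
exhaustive path enumeration is feasible); parameter recovery uses
10-subject batches at the full $T = 240$; the directional pipeline check
runs the complete default cohort (26 subjects, 80 regions, 9 densities);
null calibration uses 2,000 t-test replicates and 100 null cohorts of
10 + 10 subjects with all 40 pairs. These sizes were chosen so the entire
suite completes in a few minutes on one core while keeping every assertion
at its stated tolerance.

## Known limitations

* The lag estimator assumes preprocessing (motion censoring, nuisance
  regression, bandpass) happened upstream; non-finite inputs are rejected,
  never imputed.
* Navigation efficiency from length-weighted $\Lambda^{nav}$, lesion
  membership by centre-of-mass distance, and centroid-based (rather than
  voxelwise) lesion distances are modelling choices; alternatives exist
  and the building blocks are exposed so users can recombine them.
* Whole-brain efficiency treats failed pairs as zero contribution; on very
  sparse graphs this floors, rather than inflates, efficiency.
* The per-subject lag–distance correlations are available via
  `run_full_analysis(..., per_subject_lag_distance = TRUE)` but are noisy
  at $n = 40$ pairs and are reported without multiplicity control.
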