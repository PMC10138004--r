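---
title: "Methods: cross-recurrence coupling analysis for multi-station sensor series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-recurrence coupling analysis for multi-station sensor series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stcrqa)
```

## The problem

Coastal water-quality monitoring produces synchronously sampled series of
several factors (dissolved oxygen, chlorophyll a, turbidity, blue-green
algae, total dissolved solids, oxygen saturation, temperature, pH) at
several stations. For forecasting one factor at one station, the useful
prior information is which *other* factor-station series co-evolve with it
dynamically — not just linear correlation at lag zero, but shared
nonlinear dynamics possibly displaced in time and space. This package
quantifies that coupling with cross-recurrence plots (CRPs), their
quantification indices (CRQA), and mutual information, and fuses the five
numbers into one composite coupling score per candidate series.

## The procedure

For a target series and each candidate:

1. **Phase-space reconstruction.** Each standardized series is delay-
   embedded, row k of the trajectory being
   \((w_k, w_{k+t}, \dots, w_{k+(n-1)t})\), which yields
   \(N = i - (n-1)t\) states from \(i\) samples. (Some presentations print
   this count with a plus sign; that form would exceed the number of
   samples, so the package uses the standard Takens count above.) The
   delay \(t\) is the first local minimum of the average mutual
   information profile; the dimension \(n\) is the smallest passing the
   false-nearest-neighbour test.
2. **Shared embedding.** A pair must live in one phase space, so the pair
   uses the *best match* of the two parameter sets: the larger dimension
   (neither series is under-embedded) and the smaller delay.
3. **Cross-recurrence.** Cell \((i, j)\) of the CRP is 1 when
   \(\lVert a_i - b_j \rVert \le \varepsilon\), with \(\varepsilon\) a
   fixed fraction of the maximum pairwise distance (diameter) of the
   joint point cloud. A boundary tie counts as recurrent (Heaviside
   convention \(\Theta(0) = 1\)).
4. **CRQA.** From the matrix and its maximal-run histograms: recurrence
   rate RR (density of 1s, computed as a fraction of \(N \times M\) so
   rectangular matrices are covered), determinism DET (share of
   recurrence mass on diagonals of length \(\ge l_{\min} = 2\)),
   laminarity LAM (same for verticals, \(v_{\min} = 2\)), and mean
   diagonal length MDL (mean over diagonals \(\ge l_{\min}\); by
   construction MDL is 0 or \(\ge 2\)). Empty sums are defined as 0, so
   degenerate matrices never error.
5. **Mutual information.** \(I(X;Y) = H(X) + H(Y) - H(X,Y)\) in bits, on
   the raw aligned series with equal-width 16-bin discretization. The log
   base is immaterial downstream because of the normalization in step 6.
6. **Composite score.** Within a panel of candidates the five indices are
   min-max normalized per index and each row is scored by the geometric
   mean of its five normalized values. The per-index minimum row scores 0
   by construction; panels are normalized per station by default (a
   global scope is available in the config).

## Parameter choices

| Parameter | Default | Study value | Why |
|---|---|---|---|
| `epsilon_fraction` | 0.006 | 0.15 | The operation keeps the conventional printed value (0.6% of the joint diameter). On standardized noisy embeddings that value yields RR near 1e-4 — an almost empty matrix whose line indices are degenerate — while reported RR values for such campaigns sit at 0.01–0.16. The study configuration (`study_config()`) therefore uses 0.15, which lands RR mid-band. |
| AMI bins | 16 | 16 | Equal-width 2-D histogram; the minimum location is insensitive to the log base and to affine rescaling of the series. |
| AMI smoothing | loess, span 0.35 | same | The raw histogram AMI of strongly periodic signals carries binning-resonance wiggles that produce spurious first minima far below the quarter period; a quadratic loess fit removes them. `smooth = FALSE` is available for series that decorrelate within a few samples (e.g. strongly chaotic maps), whose sharp lag-1 drop a smoother would blur. |
| FNN | rtol 15, atol 2, threshold 0.01 | threshold 0.05, max_dim 10 | Kennel defaults. Noisy sensor series keep a 2–5% false-neighbour floor at every dimension, so the textbook 1% threshold saturates at the cap; 5% selects dimensions 4–6, in the plausible range for such data. |
| `lmin`, `vmin` | 2 | 2 | Smallest length at which a "line" is more than an isolated point. |
| MI bins | 16 | 16 | Equal-width; min-max normalization absorbs the scale. |
| norm | euclidean | euclidean | Maximum norm available by config. |

Series are z-score standardized before embedding (config flag
`standardize`): the shared \(\varepsilon\) lives on the joint point cloud
of *two different factors*, and without standardization a pH-scale series
against a mg/L-scale series would make the threshold meaningless.
Whether the emulated campaign standardized before thresholding is not
documented anywhere we could check; this is the main reason absolute CRQA
values here are not comparable with that campaign's printed tables.

## The synthetic campaign

Real multi-station buoy records of this kind are not openly available, so
the package ships a generator (`sim_config()`, `simulate_stations()`)
whose defaults emulate the reference campaign's shape: 3 stations x 8
factors x 4320 samples at 30-min cadence (90 days). Each series is

> diurnal sinusoid (period 48 samples, amplitude 1, sun-phase common to
> all series) + slow half-sine trend (amplitude 0.5, common) + unit-sd
> stochastic signal + AR(1) noise (coefficient 0.6, innovation sd 0.22).

The stochastic signal carries the ground-truth coupling. Every driver is
a unit-sd mix of an AR(1) component (coefficient 0.9, 8% of variance)
and an oscillation (92% of variance) whose period comes from a log-spaced
grid over 24–96 samples (the 12–48 h tidal/weather band), randomly
assigned so no two drivers share a spectral band, with random phase. A
factor's signal is \(\sum_g \beta_{fg} d_{fg} + w_f d_f\): one shared
driver per declared coupling plus a private driver topping the variance
up to 1 (\(w_f = \sqrt{1 - \sum \beta^2}\)). Because every candidate has
the same marginal law, \(\beta\) moves only the *shared* fraction — and
because each driver owns a spectral band, sharing a driver visibly
reshapes the pair's joint phase-space geometry, which is the feature
recurrence indices respond to. With `hub = "pH"` (the campaign default)
couplings to pH share pH's own driver: pH acts as a regional forcing the
other factors respond to, and keeps a crisp single-band attractor.
Stations other than the first see all drivers lagged 6 samples (3 h) per
distance rank and attenuated by 0.7 per rank.

The default coupling spread to pH (Temp 0.9, Tds 0.75, DoP 0.6, Do 0.45,
Turb 0.3, Bga 0.15, Chl 0) mirrors the usual field observation that
temperature and total dissolved solids co-vary most with pH while
chlorophyll barely does.

What the generator does **not** emulate: tides with astronomical timing,
weather fronts, sensor drift and spikes, non-stationary variance, or any
real hydrodynamics. Passing the recovery studies below shows the pipeline
can rank planted couplings of this simple additive kind; it does not
certify performance on real buoy data.

## Simulation studies

Sizes were chosen to keep each study in the minutes range on one CPU:

* **Ranking recovery** (`analysis/04_ranking_recovery.R`): single-station
  datasets of 1500 samples with candidates at beta = 0, 0.3, 0.6, 0.9
  against a hub target, 30 seeds. Checked: mean composite score strictly
  increasing in beta; the beta = 0.9 candidate uniquely first, and the
  beta = 0 candidate out of the top 2, in at least 90% of seeds.
* **Length robustness** (`analysis/05_length_sensitivity.R`): for 20
  campaign seeds, Spearman correlation between composite rankings of the
  central station's 7 candidate factors computed on the first 2000
  samples and on the full 4320; the mean should be at least 0.8. The
  panel is restricted to the central station's candidates to keep the
  study inside a few minutes.

## Numerical conventions and degenerate inputs

* Constant series cannot be standardized, discretized or embedded; they
  raise errors, and panel building excludes such candidates with a
  warning rather than failing the panel.
* A zero-diameter joint cloud leaves \(\varepsilon\) undefined and is an
  error.
* Empty-sum conventions: DET, LAM and MDL are 0 on matrices without
  qualifying lines; MI is clipped at 0 against floating-point rounding.
* Min-max over a constant index column maps to all 1 (the column carries
  no ranking information, so no row is penalized); ranking ties are
  broken by factor name.
* All randomness flows from the seed in `sim_config` / the `--seed`
  argument of the analysis entry points; repeated runs are byte-identical.

## Known limitations

* Cross-recurrence indices are functionals of the joint cloud geometry;
  they respond to shared attractor shape, not to temporal alignment. Two
  series with identical marginal dynamics but independent realizations
  score almost the same RR as a strongly synchronized pair (the package's
  own studies demonstrate this). MI supplies the alignment-sensitive part
  of the composite; interpret individual CRQA indices accordingly.
* MDL on a published table of a comparable campaign contains a value
  below 2, which the definition with \(l_{\min} = 2\) cannot produce; the
  package treats MDL < 2 (other than 0) as impossible by construction.
* The embedding search (AMI + FNN) is the runtime bottleneck at campaign
  scale; the pipeline caches per-series parameters within a run.
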