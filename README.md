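# stcrqa

Spatio-temporal coupling analysis for multi-station water-quality time
series, built on cross-recurrence plots (CRPs), cross-recurrence
quantification analysis (CRQA) and mutual information.

## The problem

Coastal monitoring campaigns record several water-quality factors
(dissolved oxygen, chlorophyll a, turbidity, blue-green algae, total
dissolved solids, oxygen saturation, temperature, pH) at several stations
simultaneously. For forecasting one factor at one station, the question
is which *other* factor–station series co-evolve with it dynamically —
across nonlinear dynamics, time displacement and space — so those series
can feed the forecasting model. Linear lag-zero correlation misses most
of this.

## The method

For a target series and each candidate series:

1. **Phase-space reconstruction** — each standardized series is
   delay-embedded, row *k* of the trajectory being
   (w<sub>k</sub>, w<sub>k+t</sub>, …, w<sub>k+(n−1)t</sub>), giving
   N = i − (n−1)t states from i samples. The delay *t* is the first
   local minimum of the average mutual information (AMI) profile; the
   dimension *n* is selected by false nearest neighbours (FNN).
2. **Shared embedding** — a pair must live in one phase space; the pair
   uses the *best match* (max dimension, min delay) of the two parameter
   sets, written `"n/t"`.
3. **Cross-recurrence** — CR<sub>ij</sub> = Θ(ε − ‖a<sub>i</sub> −
   b<sub>j</sub>‖), with ε a fixed fraction of the joint phase-space
   diameter.
4. **CRQA** — recurrence rate RR, determinism DET, laminarity LAM and
   mean diagonal line length MDL from the matrix's maximal-run
   histograms (l<sub>min</sub> = v<sub>min</sub> = 2).
5. **Mutual information** — I(X;Y) = H(X) + H(Y) − H(X,Y) in bits on the
   raw aligned series (equal-width 16-bin histogram).
6. **Composite score** — the five indices are min-max normalized within
   the candidate panel and fused by their geometric mean; candidates are
   ranked by this score.

Because the buoy records such campaigns produce are generally not public,
the package includes a seeded generator of coupled multi-station
surrogate series with known ground truth (`sim_config()`,
`simulate_stations()`), and the analysis scripts under `analysis/`
exercise the full method on it. See the methods vignette
(`vignettes/spatiotemporal-coupling.Rmd`) for the model, parameter
choices and limitations.

## Worked example

Shared-embedding parameters from the published per-series table of the
reference campaign (blue-green algae at station ST3 against pH at the
central station ST1):

```r
library(stcrqa)
p <- reference_embedding_params()
subset(p, station == "ST1" & factor == "pH")
#>   station factor dimension delay
#> 8     ST1     pH         6     9
bga <- subset(p, station == "ST3" & factor == "Bga")   # dimension 17, delay 24
resolve_best_match(embedding_params(6, 9), embedding_params(17, 24))
#> 17/9
```

The pair keeps the larger dimension (17, so neither series is
under-embedded) and the smaller delay (9).

A full coupling panel on synthetic data with planted couplings
β = 0, 0.3, 0.6, 0.9 to the target:

```r
ds <- ranking_study_dataset(seed = 1)
coupling_panel(ds, "ST1:T", config = study_config())
#> <coupling_panel> target ST1:T
#>   station factor    rr   det   lam   mdl    mi score
#> 1     ST1    C09 1.000 1.000 1.000 1.000 1.000  1.00
#> 2     ST1    C03 0.916 0.715 0.783 0.367 0.293  0.56
#> 3     ST1    C06 0.301 0.372 0.308 0.303 0.435  0.34
#> 4     ST1    C00 0.000 0.000 0.000 0.000 0.000  0.00
```

The β = 0.9 candidate tops every index; the uncoupled candidate is
pinned to 0 by the panel normalization. (Middle ranks can swap on a
single seed — C03 above C06 here — which is why the bundled study
averages 30 seeds; across seeds the mean score is strictly increasing in
β and the β = 0.9 candidate ranks first in 97% of them; see
`analysis/04_ranking_recovery.R` and `results/04_ranking_recovery.csv`.)

## The analysis workflow

Numbered scripts under `analysis/` reproduce the package's studies from
scratch (each regenerates its data from fixed seeds):

| script | what it does |
|---|---|
| `01_simulate.R` | generates the default 3-station × 8-factor × 4320-sample campaign |
| `02_embedding.R` | per-series AMI/FNN parameters; best-match table for the published reference parameters |
| `03_crqa_pipeline.R` | full pipeline for the central-station pH target: CRQA table, composite panels, CRP images, heatmaps, length sensitivity |
| `04_ranking_recovery.R` | 30-seed ranking-recovery study over planted β |
| `05_length_sensitivity.R` | 20-seed Spearman robustness of rankings to record truncation |

Outputs go to `results/` (small tables) and `scratch/` (bulky data).

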