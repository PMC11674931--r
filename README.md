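# fastconn

High-temporal-resolution dynamic functional connectivity for multichannel
EEG via **FAST** (filter average short-term) connectivity.

## The problem

ERP-scale cognitive processes unfold over tens of milliseconds, but
functional connectivity estimated in windows that short is dominated by
spurious correlations. Sliding-window methods trade temporal resolution
against noise, and the window length ends up dictating the result.
`fastconn` implements the FAST approach for researchers analyzing
time-locked task EEG (and for methodologists benchmarking dynamic
connectivity estimators): a *long-term* connectivity matrix, averaged over
the whole study cohort, serves as a static support that weights
*instantaneous* signal variation, giving noise-robust connectivity at up to
single-sample resolution.

## The method

For participants $P = 1,\dots,N$, with $r^P_{ij}$ the Pearson correlation
of channels $i, j$ over the full epoch:

$$c^{\mathrm{FAST}}_{ij} = \frac{1}{N}\sum_{P=1}^{N}\lvert r^{P}_{ij}\rvert
\qquad\text{(one filter for the whole cohort)}$$

$$\theta^{\mathrm{FAST}}(x^P_i, x^P_j, t) =
  c^{\mathrm{FAST}}_{ij}\,\bigl(\tilde x^P_i(t)-\tilde x^P_j(t)\bigr)^2,
\qquad \theta_{ii}=0,$$

where $\tilde x(t)$ is the signal z-scored across channels at each time
step. Summed over pairs, a slice is the Dirichlet energy
$\sum_{ij} w_{ij}(x_i - x_j)^2$ of the instantaneous profile on the filter
graph. Slices are averaged within disjoint temporal windows and reduced to
global network metrics — mean edge weight $\sum_{ij}\Delta_{ij}/n^2$ and
average weighted clustering $\operatorname{tr}(\Delta^3)/n$ — which are
compared between groups per window (Wilcoxon rank-sum, Cohen's *d*,
Benjamini–Hochberg FDR across windows).

The package also ships the study's synthetic EEG/ERP generator (1/f
background, jittered N100/P300 components with scalp topographies, trial
averaging, noise sweeps), a Morlet continuous-wavelet power baseline,
band-pass preprocessing, plain-text TSV/JSON formats, an experiment-grid
runner, and a thin CLI (`inst/cli/fastconn`).

## Worked example

Simulate the study's two cohorts (20 participants each, 31 channels,
200 samples at 0.8 s; the ERP group carries an N100 and a P300 averaged
over 100 trials), then run the full comparison:

```r
library(fastconn)

cfg_erp <- sim_config(components = list(erp_n100(), erp_p300()),
                      n_trials = 100L)
cfg_ctl <- sim_config(n_trials = 100L)
man <- simulate_study(c(20, 20), cfg_erp, cfg_ctl, seed = 2024)

cmp <- run_comparison(man, n_windows = 10)
dplyr::filter(tidy(cmp), metric == "mean_edge_weight")
#>    window window_start        p_raw  p_adjusted cohens_d significant_05
#>     <int>        <dbl>        <dbl>       <dbl>    <dbl> <lgl>
#>  1      1         0    0.525        0.656          0.222 FALSE
#>  2      2         0.08 0.0000000680 0.000000340    3.64  TRUE
#>  3      3         0.16 0.818        0.818          0.173 FALSE
#>  4      4         0.24 0.0000000680 0.000000340    7.19  TRUE
#>  5      5         0.32 0.000000222  0.000000739    3.16  TRUE
#>  6      6         0.4  0.425        0.607         -0.216 FALSE
#>  7      7         0.48 0.208        0.417         -0.545 FALSE
#>  8      8         0.56 0.617        0.685         -0.285 FALSE
#>  9      9         0.64 0.262        0.436          0.333 FALSE
#> 10     10         0.72 0.140        0.351          0.425 FALSE
```

Exactly the windows containing ERP activity light up: window 2
(80–160 ms) holds the N100, window 4 (240–320 ms) the P300 center and
window 5 its tail; all ERP-free windows stay non-significant. The large
positive Cohen's *d* means lower filtered signal variation in the ERP
group at those windows — the cohort filter concentrates weight on
channel pairs that move together when the ERP is present.

```r
glance(cmp)
#>   filter_mode n_windows n_tests n_raw_05 min_p_adjusted n_significant_05
#> 1 fast               10      20        5    0.000000340                5
```

`autoplot(cmp)` draws the p-value time course;
`run_comparison(man, filter_mode = "individual")` reproduces the
Type-1-inflated per-participant-filter variant, and
`filter_mode = "unfiltered"` the analytically flat control. The full
trials-by-noise grid of the simulation study is one call:
`run_experiment(out_dir = "grid", seed = 1)`.

## Further reading

The methods vignette
(`vignettes/fast-connectivity-methods.Rmd`) documents the model and its
assumptions, what the synthetic generator does and does not emulate, every
tunable parameter, and the numerical conventions (degenerate time steps,
window partitioning, rank-sum dialect, FDR families).
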