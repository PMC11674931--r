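---
title: "FAST functional connectivity: model, simulator design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FAST functional connectivity: model, simulator design and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fastconn)
library(dplyr)
```

## The problem

Scalp EEG offers millisecond temporal resolution, but functional
connectivity estimated in windows short enough to resolve an event-related
potential (ERP) is dominated by noise: correlations computed over a few
dozen samples are spurious more often than not. Sliding-window dynamic
connectivity trades temporal resolution against this noise, and the window
length ends up driving the result.

Filter average short-term (FAST) functional connectivity decouples the two
ingredients. A *long-term* connectivity estimate — the absolute Pearson
correlation between channel pairs over the whole epoch — is computed per
participant and averaged across the entire study cohort:

$$c^{\mathrm{FAST}}_{ij} = \frac{1}{N}\sum_{P=1}^{N} \lvert r_{ij}^{P}\rvert .$$

This single matrix is stable (it averages over both time and participants)
and acts as a static support, or filter. The *short-term* signal lives in
the instantaneous squared differences of the node-space-normalized signals
$\tilde x$: each time step yields a filtered connectivity slice

$$\theta^{\mathrm{FAST}}(x_i, x_j, t) =
  c^{\mathrm{FAST}}_{ij}\,\bigl(\tilde x_i(t) - \tilde x_j(t)\bigr)^2,
  \qquad \theta_{ii} = 0 .$$

Summing a slice over all pairs gives the (double-sum) Dirichlet energy
$\sum_{ij} w_{ij}(x_i - x_j)^2 = 2\,x^\top L x$ of the instantaneous
profile on the filter graph, so the method measures how much the signal
varies across the cohort's consistently strong connections, at single-sample
resolution. Slices are averaged in disjoint temporal windows (ten by
default, or one window per sample for maximum temporal resolution) and
reduced to two global network metrics per window: the mean edge weight
$\bar W = \sum_{ij}\Delta_{ij}/n^2$ and the average weighted clustering
coefficient $C_{avg} = \operatorname{tr}(\Delta^3)/n$. Group differences are
tested per window with two-sided Wilcoxon rank-sum tests, described by
Cohen's *d* (control minus patient over the pooled SD, so negative means
larger values in patients), and corrected across windows by the
Benjamini–Hochberg step-up procedure.

Two alternative supports delimit the method. The *individual* (graph-variate
dynamic) variant uses each participant's own $\lvert r_{ij}\rvert$ matrix:
the filter then co-varies with that participant's noise, which inflates
Type-1 errors. The *unfiltered* variant uses an all-ones off-diagonal
support and is analytically degenerate (next section).

## Why the unfiltered control carries no information

Node-space normalization forces $\sum_i \tilde x_i(t) = 0$ and
$\sum_i \tilde x_i(t)^2 = n-1$ at every valid time step. Hence

$$\sum_{i,j} (\tilde x_i - \tilde x_j)^2
 = 2n \sum_i \tilde x_i^2 - 2\Bigl(\sum_i \tilde x_i\Bigr)^2 = 2n(n-1),$$

a constant. With the all-ones support the mean edge weight is therefore
exactly $2(n-1)/n$ at every valid time step, for every participant: no
group comparison on it can ever detect anything. The package asserts this
identity to 1e-9 and treats the resulting rank-sum tests as fully tied
(p = 1) rather than ranking floating-point round-off.

The same algebra has a second, less obvious consequence that shaped the
simulator: any signal component added *uniformly* to all channels cancels
exactly in $\tilde x$ (it shifts the node-space mean and leaves deviations
untouched), and likewise in every pairwise difference. FAST connectivity is
blind to spatially uniform activity by construction.

## What the synthetic-data generator emulates

The generator reproduces the structure of a two-group, time-locked ERP
study:

* **Background**: per-channel independent Gaussian noise shaped in the
  frequency domain to a $1/f^{\alpha}$ power spectrum ($\alpha = 1$ by
  default, a 10-Hz alpha bump available but off by default), mimicking the
  broadband spectrum of resting human EEG. Each channel is scaled so its
  peak-to-peak range is twice `background_amplitude` (default 10).
* **Epoch geometry**: 31 channels and 200 samples over 0.8 s — an
  effective 250 samples/s, chosen so that the component center frames 25
  and 75 land at roughly 100 ms and 300 ms. (A 200-Hz rate over 0.8 s
  would give 160 samples and break that frame-to-latency correspondence;
  the array shape wins. Both quantities remain configurable.)
* **ERP components**: half-cycle sinusoidal lobes with peak value equal to
  the signed amplitude; the default N100 (amplitude −5, 15 Hz, frame 25)
  and P300 (amplitude 5, 5 Hz, frame 75). The half-cycle rule makes the
  lobe width `round(fs / 2f)` samples, so frequency controls duration.
* **Latency jitter**: each trial draws an integer offset uniformly on
  ±5 frames, shared by all channels — a scalp-wide latency shift, the
  dominant trial-to-trial variability of real ERPs. Per-channel jitter was
  deliberately rejected: its effect on the trial average shrinks as
  $1/\sqrt{K}$ exactly like the background, which would make detection
  independent of trial count, contrary to how ERP detection behaves.
* **Scalp topography**: every component is projected through a smooth
  per-channel gain vector, by default the average-referenced gradient
  $\gamma_i = \cos(\pi (i-1)/(n-1))$. A topography is *required* for the
  method to see the ERP at all: by the cancellation argument above, a
  channel-uniform component is invisible to node-space-normalized
  connectivity, and real average-referenced ERP topographies indeed sum to
  approximately zero across the scalp with polarity inversions between
  regions. The cosine gradient is the simplest spatial pattern with those
  two properties.
* **Trial averaging and noise**: `n_trials` independent trials are
  averaged (shrinking the background as $1/\sqrt{K}$ while the
  topography-projected ERP persists), then Gaussian white noise of
  standard deviation `noise_sigma` is added per channel and sample to the
  averaged epoch — emulating external recording noise that trial averaging
  cannot remove. The study design adds this noise to the ERP group only;
  because background and noise are both Gaussian and i.i.d. across
  channels, the node-normalized profile at ERP-free time steps is
  distributed identically in both groups regardless of `noise_sigma`, so
  the asymmetry does not by itself create group differences.
* **Study conditions**: two cohorts of 20 participants (ERP and control),
  trial counts 50–300, noise levels swept over {0, 1, 2, 4, 8} (the
  absolute noise units of the original sweep are not published; this
  sweep spans from trivial to failure).

What the generator does *not* emulate: volume conduction and correlated
background across channels, realistic electrode geometry, ocular or
muscular artifacts, non-stationary background, or per-participant
topography variability. Passing the simulation study therefore shows that
the statistical machinery behaves as designed under idealized spatial
independence — not that the method is robust to every property of real
recordings.

## Tunable parameters that matter

| Parameter | Default | Units | Role |
|---|---|---|---|
| `background_amplitude` | 10 | signal units | half peak-to-peak of each channel's background |
| `spectral_exponent` | 1 | — | background spectrum $1/f^{\alpha}$ |
| `n_trials` | 1 | trials | averaging depth; background SD shrinks as $1/\sqrt{K}$ |
| `noise_sigma` | 0 | signal units | post-averaging white noise SD |
| `jitter_frames` | 5 | samples | max latency jitter per trial |
| `n_windows` | 10 | windows | temporal resolution of the metrics (`n_samples` = max) |
| `q` | 0.05, 0.10 | — | FDR levels reported in comparison tables |
| `omega0` | 6 | rad | Morlet central frequency (baseline) |
| wavelet scales | 32 log-spaced, 1–40 Hz | s | pseudo-frequency coverage of the baseline |

## Numerical and procedural choices

* **Degenerate time steps.** Node-space normalization divides by the
  cross-channel SD, undefined when all channels are equal. Such columns
  are zeroed and flagged in a validity mask; downstream slices are zero.
  This preserves epoch length without NaN propagation.
* **Symmetry/diagonal tolerance** for connectivity matrices is absolute
  1e-10; all arithmetic is closed-form, no iterative solvers.
* **Window partition.** When `n_samples` is not divisible by `n_windows`,
  earlier windows get $\lfloor T/n_w \rfloor$ samples and the remainder is
  distributed one sample each to the last windows. The studied designs
  divide evenly; the rule only fixes a deterministic convention.
* **Windowed computation.** Window means of the tensor are computed through
  the identity $\overline{(\tilde x_i - \tilde x_j)^2} = q_i + q_j -
  2S_{ij}/m$ with $S$ the within-window cross-product matrix, avoiding the
  $n \times n \times T$ tensor; the explicit tensor route is kept as the
  reference implementation and the two are asserted equal in the tests.
* **Rank-sum dialect.** Exact enumeration for combined $n \le 20$ without
  ties; tie-corrected normal approximation with continuity correction
  otherwise. Samples whose pooled spread is zero up to relative 1e-9 are
  treated as fully tied (p = 1) so that analytically constant metrics are
  never ranked on round-off noise.
* **FDR family.** Correction runs across the temporal windows within each
  (metric, condition, band) family separately — the correction is for
  *multiple temporal testing*; bands and metrics are separate analyses.
  Pooling across bands would be more conservative but conflates questions.
* **Clinical-interest rule.** "No difference in the shape task" is read on
  the raw p-value at 0.05, not the FDR-corrected one: declaring an absence
  is conservative only if the uncorrected test had its chance to reject.
  The threshold is an argument (`shape_alpha`) for the other reading.
* **Cohen's d** uses the pooled (n−1)-weighted SD without small-sample
  correction.
* **Morlet baseline.** Zero-padded convolution, wavelet truncated at five
  Gaussian SDs, no cone-of-influence masking; scales are 32 log-spaced
  values covering pseudo-frequencies 1–40 Hz at $\omega_0 = 6$. The
  original analysis does not publish its scale set; these are declared
  defaults, not inferred ones.
* **Seeding.** `simulate_study` and `run_experiment` draw one child seed
  per participant (resp. grid cell) from the master seed, so any
  subset of the design can be regenerated independently. Within a
  participant the RNG stream order is fixed (noise, then per-trial
  background, then per-trial jitter) so that seeded runs with and without
  components consume the shared streams identically.

## Problem sizes used in the shipped checks

The test suite runs the full 20-vs-20, 100-trial design for the noise
sweep at {0, 1, 2, 4}, one 20-vs-20, 50-trial run at one window per sample
(200 windows), and 1000 scaled-down null studies (8 channels, 50 samples,
20 vs 20) for the calibration check; the acceptance script repeats the
maximum-resolution design over 10 independent study seeds and reports the
median corrected p-value at the P300 time step. These sizes were chosen so
the whole suite completes in minutes on a single core while keeping the
group sizes of the original design, where the discreteness of the rank-sum
null distribution matters (at 20 vs 20 the achieved size at
$\alpha = 0.05$ is 0.0491; at 10 vs 10 it would be 0.0433 and a 5%
calibration check would be meaningless).

## Known limitations

* The method is blind to channel-uniform activity by construction; an ERP
  with a genuinely flat topography is undetectable, and reference choices
  that add common signal are immaterial but also unhelpful.
* The long-term filter pools both groups; a connection that is strong in
  only one group is half-weighted for everyone, which can dilute localized
  group differences in the filter itself.
* The metric definitions are used exactly as written: the mean edge weight
  divides by $n^2$ (not $n(n-1)$), and the clustering coefficient has no
  degree normalization, so absolute values are not comparable across
  different channel counts.
* The wavelet baseline is a power (not connectivity) analysis; it is
  included for comparison, not as an equivalent estimator.
* Band-pass decomposition applies the long-term correlation to the
  band-passed signal; whether the original analysis computed the filter
  before or after band-passing is not documented, and this package
  band-passes first.

## Reproducing the study figures at desk scale

```{r, eval = FALSE}
summary <- run_experiment(
  trial_counts = c(50, 100, 200),
  noise_sigmas = c(0, 1, 2, 4, 8),
  n_per_group = 20,
  out_dir = "fast_grid",
  seed = 1
)
# adjusted p at the P300 window per (trials, noise) cell
tidyr::pivot_wider(summary[, 1:4], names_from = noise_sigma,
                   values_from = p_adjusted)
```
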