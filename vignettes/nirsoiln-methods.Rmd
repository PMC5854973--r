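---
title: "Methods: synthetic NIR soil spectra and three calibration routes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic NIR soil spectra and three calibration routes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(nirsoiln)
```

# Scope

`nirsoiln` implements a complete chemometric calibration study for soil
nitrogen from near-infrared diffuse reflectance: a generative model for the
spectra, Savitzky–Golay preprocessing, SPXY sample-set partitioning, three
calibration algorithms (PLS, SPA-MLR, CARS-PLS), and R/RMSE/RPD
evaluation. The study design it emulates used three soils (black soil,
loess, calcium soil) spiked to 11 nitrogen gradients with 16 replicates
each (176 samples per cell) and measured after four drying treatments
(ambient 25 °C placement, 50 °C, 80 °C, 95 °C drying) on a 400-point
900–1700 nm grid. No raw spectra were deposited, so the generator is a
first-class module: every downstream claim the tests make is a claim about
this stated synthetic world.

# The generative model

Each sample's reflectance is

$$R(\lambda) = s\,\Big[b_0 + b_1(\lambda - 900)
  - \textstyle\sum_k d_k\,G(\lambda; c_k, w_k)
  - \alpha N\, G(\lambda; c_N, w_N)
  - A\, G(\lambda; c_w, w_w)\Big] + \varepsilon(\lambda),$$

with $G$ a unit-height Gaussian, $s \sim \mathrm{Lognormal}(0,
\sigma_s^2)$ a per-sample multiplicative scatter factor, and
$\varepsilon \sim \mathcal N(0, \sigma_n^2)$ i.i.d. per spectral point.
Reflectance is floored at $10^{-4}$.

Choices and why:

* **Bands are Gaussian in reflectance**, not absorbance. The calibration
  pipeline treats spectra generically, so the shape family only affects
  the simulator; Gaussians keep the nitrogen signal exactly affine in $N$
  at every wavelength, which gives closed-form oracles (the regression
  slope at the band center is exactly $-\alpha$).
* **Scatter is multiplicative log-normal, noise additive Gaussian** — the
  minimal structure that makes smoothing and variable selection
  non-trivial: scatter is a rank-one interference correlated across the
  whole band, noise is white. Defaults $\sigma_s = 0.01$,
  $\sigma_n = 0.002$; both are config keys.
* **Treatment encoding.** All soils share the water O–H band at 1385 nm.
  Its amplitude decreases with drying temperature (25 °C: 0.15 → 95 °C:
  0.02, never zero — soil water cannot be dried away completely), and
  black soil's ambient amplitude is doubled (0.30), placing its 25 °C
  curve visibly lowest. The 25 °C profiles additionally get 3× noise and
  2× scatter. This inflation is a modeling choice, not a measured
  formula: it encodes the empirical fact that ambient, moist samples
  calibrate far worse, and it is what makes the pipeline's qualitative
  invariant (25 °C worst in every cell) hold.
* **Nitrogen design.** 11 equally spaced gradients spanning 0.46–2.15
  (black), 0.09–0.93 (loess), 0.32–1.17 g/kg (calcium), 16 replicates
  each. The source design's printed step sizes are inconsistent with 11
  gradients over those ranges; the range + count pair is what fixes the
  176 → 118/58 split, so the steps were discarded.
* Baseline levels (0.25 black, 0.55 loess, 0.50 calcium) follow the
  field's standard observation that dark, humus-rich soils reflect least;
  two static bands per soil add benign structure. Sensitivities
  (0.04–0.08 per g/kg) were chosen once so band depths stay within a few
  percent reflectance — realistic for N–H/C–H overtone signals — and were
  not revisited.

**What the generator does not emulate:** instrument drift, detector
nonlinearity, particle-size/Kubelka–Munk effects, correlated chemical
interferences (organic matter, carbonates), or per-sample moisture
variation within a treatment. Green tests therefore establish that the
algorithms are implemented correctly and that the stated confounds produce
the expected ordering — not that real soils would yield these RPDs. The
synthetic RPDs (tens) are far above field-realistic values (1–4.5)
precisely because the error budget is idealized.

# Preprocessing

Savitzky–Golay smoothing fits a degree-$p$ polynomial by least squares
over a centered window of $2w+1$ points and takes its value at the center
— equivalently a weighted moving average with the classical smoothing
coefficients. Defaults: window 11, polyorder 2, mild for 400-point
spectra; the source never states its settings, so both are config keys
recorded in every report. Edges use the truncated one-sided window with
the polynomial refitted (degree capped at window length − 1); no
reflection padding, so a global polynomial is reproduced exactly at every
point. An opt-in $\log_{10}(1/R)$ absorbance transform is provided; the
default models reflectance, which is what the emulated study discusses.

# SPXY partitioning

The joint distance $d_{xy}(i,j) = d_x(i,j)/\max d_x + d_y(i,j)/\max d_y$
(Euclidean on spectra, absolute difference on nitrogen) feeds Kennard–
Stone max–min selection: seed with the most distant pair, then repeatedly
add the candidate whose minimal distance to the selected set is largest.
Numerical conventions: ties break to the lowest sample index; if one
normalizer is zero that term is dropped (error only when both vanish);
for a $c{:}v$ ratio the validation size is $\lfloor n\,v/(c+v)\rfloor$ —
the floor rule is what reproduces 118/58 from 176 at 2:1. The split runs
per soil × treatment cell (each cell's summary shows N1 = 118, N2 = 58),
and on the smoothed spectra, mirroring the pipeline order.

# Calibration routes

**PLS.** PLS1 via NIPALS on column-centered $X$ and centered $y$; no
variance scaling (reflectance channels share units). The latent-variable
count is the argmin of RMSECV over 1..10, computed by 10-fold CV with
deterministic contiguous blocks by index — folds are reproducible without
consuming randomness; ties go to fewer components. One NIPALS pass per
fold yields coefficients for every component count, so CV costs
folds × one decomposition.

**SPA-MLR.** For every admissible start column and chain length up to 30,
the chain grows by orthogonal projection (append the column of maximal
residual norm); each prefix is scored by MLR RMSE on the SPXY validation
set — the only held-out set the design defines. The Gram–Schmidt basis
built during projection doubles as the chain's QR factorization, so every
prefix's OLS prediction accumulates one orthogonal component at a time;
this is exact, not an approximation, and is cross-checked against brute
force in the tests. Ties prefer shorter chains, then lower start index.
Columns constant after centering are excluded. SPA operates on centered
columns (a documented choice; the source is silent).

**CARS-PLS.** Each of `n_runs` iterations draws 80 % of calibration rows,
fits PLS on the current subset, keeps the top $\lceil r_i k\rceil$
variables by $|\beta|$ with $r_i = a e^{-bi}$ fixed by $r_1 = 1$ and
$r_{\text{n\_runs}} = 2/k$, then resamples that many draws weighted by
$|\beta|$ and keeps the distinct ones (adaptive reweighted sampling; the
with-replacement draw is what makes it prune further), and records the
10-fold RMSECV of the survivors on the full calibration set (minimum over
the component grid). The minimal-RMSECV subset wins. The canonical
setting is 500 iterations (`cars_select`'s default); the pipeline config
defaults to 100 at desk scale — the subsets stabilize well before that on
these spectra and the cost is linear. A subset collapsing below 2
variables ends the run at the last valid subset. The ceiling in the EDF
is guarded by a $10^{-9}$ downward tolerance so the exact boundary values
$k$ and $2$ survive floating point.

# Evaluation

$R_c$/RMSEC on calibration members, $R_p$/RMSEP on validation members, and
$\mathrm{RPD} = \mathrm{SD}(y_{\mathrm{val}})/\mathrm{RMSEP}$ with the
$n-1$ standard deviation (conventional for RPD; the source is silent).
Category bands: $\ge 3$ agriculture-grade, $(2,3)$ good, $(1.4,2)$
intermediate, else poor; boundaries 1.4 and 2.0 fall to the lower band,
3.0 is agriculture-grade. Degenerate cases are flagged rather than fatal:
RMSEP = 0 reports `RPD = Inf` with an `infinite-rpd` flag; correlations on
constant vectors (or fewer than 3 members) report `NA` with
`undefined-correlation`. Every emitted row satisfies
$\mathrm{RPD}\cdot\mathrm{RMSEP} = \mathrm{SD}(y_{\mathrm{val}})$ to
machine precision, which the acceptance tests verify by regenerating the
splits.

# Orchestration and determinism

`run_experiment()` iterates soil × treatment cells (config order), fans a
single global seed out as `seed + 101 * cell_index` (kept below $2^{31}$),
and runs simulate → smooth → split → fit ×3 → evaluate per cell; a failing
cell is logged and skipped without aborting the rest. All randomness
(generator draws, CARS Monte Carlo) flows through saved-and-restored RNG
state, so identical configurations give byte-identical reports and no call
disturbs the caller's RNG. PLS fold assignment is index-deterministic, so
its `seed` argument is provenance only.

# Known limitations

* The generator's idealized error budget inflates every accuracy metric;
  only orderings and structural counts are meaningful comparisons to real
  studies, and the published per-cell R/RMSE/RPD values are explicitly not
  reproduction targets (the underlying spectra were never deposited).
* SPA scores on the single SPXY validation set, which mildly optimizes
  selection toward it; a CV-scored variant would cost more and is not what
  the emulated design did.
* CARS bounds its per-iteration PLS by the configured `max_components`
  (10); the emulated study reports per-condition component counts without
  stating its bound, so no attempt is made to match them.
* MLR falls back to a minimal-norm pseudoinverse solution on
  rank-deficient designs; SPA's projection step makes this rare by
  construction.
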