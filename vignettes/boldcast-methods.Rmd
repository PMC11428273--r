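---
title: "Frequency-specific adversarial forecasting of BOLD time series: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-specific adversarial forecasting of BOLD time series: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

boldcast forecasts and prolongs region-averaged resting-state fMRI (BOLD)
signals. A scan yields, per subject, an $m \times T$ matrix $Y$: one row per
atlas region, one column per repetition time (TR, seconds). Forecasting asks
for $\hat y_{N+1}, \dots, \hat y_{N+H}$ of a *target* region from the
preceding $D$ timepoints of *all* $m$ regions, the remaining regions acting
as auxiliary inputs — the premise being that functionally connected regions
carry predictive information about each other. This vignette records the
model, its assumptions, and the design decisions taken where the design was
genuinely open.

## Pipeline overview

1. **Variational mode decomposition (VMD).** Each regional series is
   decomposed into $K$ band-limited modes ("IMFs") with center frequencies.
2. **Low-frequency selection.** Modes with center frequency below
   0.05 Hz are kept; resting-state functional connectivity is most stable
   and reproducible in the 0.01–0.05 Hz band, and the retained modes carry
   it.
3. **Per-mode forecasting.** For every (subject, target region, retained
   mode), a generator network is trained adversarially against a
   discriminator on max–min-normalized sliding windows.
4. **Superposition.** Per-mode forecasts are denormalized and summed to
   form the predicted signal; appending them prolongs the scan
   (`extend_series()`).
5. **Evaluation.** RMSE, MAE and dynamic time warping per window;
   test–retest reliability of functional connectivity between predicted
   and ground-truth sessions via per-edge ICC and per-subject Pearson
   agreement.

## Variational mode decomposition

VMD minimizes the summed bandwidth of $K$ analytic mode signals subject to
the modes reconstructing the input, via an augmented Lagrangian solved by
ADMM: a frequency-domain Wiener-style mode update

$$\hat u_k(\omega) \leftarrow
  \frac{\hat x(\omega) - \sum_{i \ne k}\hat u_i(\omega) + \hat\lambda(\omega)/2}
       {1 + 2\alpha(\omega - \omega_k)^2}$$

alternates with a center-of-mass update of each $\omega_k$ over the
positive spectrum, plus optional dual ascent of $\lambda$ with step $\tau$.
Choices the reference formulation leaves open, fixed here:

* **Defaults** `K = 4`, `alpha = 2000`, `tau = 0`, `tol = 1e-7`,
  `max_iter = 500`. $\alpha$, $\tau$ and the stopping rule are exposed in
  `vmd_config()` because no canonical values exist; `tau = 0` relaxes exact
  reconstruction, which is the noise-robust choice for BOLD data, while
  `tau > 0` drives the mode sum back to the input (used when
  reconstruction fidelity itself is evaluated).
* **Boundary handling.** The series is mirror-extended by $T/2$ at each end
  and trimmed after decomposition — standard practice to suppress edge
  ringing.
* **Convergence** is declared when
  $\sum_k \|u_k^{n+1}-u_k^n\|^2 / \|u_k^n\|^2 < \mathrm{tol}$, the
  conventional VMD stopping rule.
* **Initialisation** of $\omega_k$: uniform spacing over $[0, 0.5]$
  cycles/sample by default; zero and seeded-random initialisation exist for
  robustness experiments. Frequencies are stored in cycles/sample and
  converted to Hz only at reporting boundaries using the TR.
* **Full-series decomposition.** Decomposition runs on the complete series
  before windowing and splitting. The training portion of a mode series
  therefore reflects, weakly, frequency content of later samples — a mild
  look-ahead shared by every decompose-then-forecast design; the
  chronological split and training-portion-only normalization bound the
  remaining leakage.

## Windowing, normalization, splitting

Windows of length $L = D + H$ slide with stride 1 (maximizing training
windows). Each regional mode series is max–min normalized,
$\bar y = (y - y_{\min})/(y_{\max} - y_{\min})$, with the range fitted on
the **training fraction of timepoints only** and applied to all splits, so
the test range never informs training; out-of-range forecasts extrapolate
linearly on inversion. The split is **chronological** 7:2:1 (earliest
windows train, latest test). A random-by-window split would let training
windows overlap test timepoints; `split_windows(shuffle = TRUE)` provides
that mode for comparison, but chronological is the default for forecasting
integrity. Consecutive windows still share timepoints across split
boundaries — inherent to overlapping windows and documented rather than
"fixed". $D$ defaults to $2H$; neither value has a canonical setting and
both are task configuration.

## Generator, discriminator, losses

The generator applies, in order:

* **Temporal attention** — a $1 \times m$ convolution mixes the regions at
  each time step into `attn_channels` features; a CBAM block (channel
  attention: average- and max-pooled channel vectors through a shared
  two-layer MLP, summed, sigmoid; spatial attention: channel-wise mean/max
  maps through a width-7 convolution, sigmoid) yields per-time-step gates
  in $(0,1)$ that reweight the input window.
* **Spatial attention** — symmetrically, a $D \times 1$ convolution mixes
  time per region and CBAM yields per-region gates: the *region attention
  vector*, exposed for inspection as each region's contribution to the
  prediction.
* **Encoder** — a $1 \times m$ convolution on the attended block feeds a
  2-layer GRU; the final state passes through a fully-connected ReLU layer
  into the latent representation (latent width tied to `fc_nodes`; no
  separate dimension is prescribed anywhere).
* **Decoder** — a 2-layer GRU initialised from the encoder state, unrolled
  $H$ steps autoregressively on its own output, seeded with the last
  observed target value. The output head is **residual**: each step emits
  an increment on the previous value, and its weights are initialised near
  zero, so an untrained decoder starts at the persistence solution and
  training learns corrections. This choice — the exact decoder wiring is
  not prescribed — stabilises the short training budgets used in testing
  and removes most seed-to-seed variance in untrained behaviour.

The discriminator is a 3-layer GRU over $H$-length windows with a sigmoid
head; it sees the forecast/real horizon window only (conditioning on
history is deliberately not done — window-level discrimination).

The hybrid generator objective is
$\lambda_{ae}\mathcal L_{ae} + \lambda_t\mathcal L_t +
 \lambda_{dis}\mathcal L_{dis} + \lambda_g\mathcal L_g$
with defaults $(50, 3, 1, 1)$:

* $\mathcal L_{ae}$ — per-window Euclidean distance (the unsquared norm,
  not MSE), averaged over the batch;
* $\mathcal L_t$ — trend: mean over the $H$ adjacent steps (anchored at the
  last observed value) of $|\mathrm{sign}(\Delta\hat y) -
  \mathrm{sign}(\Delta y)| \in [0, 2]$. The exact sign form is defined for
  a single step; averaging over the whole horizon extends it to
  horizon-wide direction matching, which is the stated intent of a trend
  term. Since $\mathrm{sign}$ has zero gradient a.e., optimisation uses the
  surrogate $\tanh(\Delta\hat y/\varepsilon)$, $\varepsilon = 0.01$;
  logged and reported trend losses always use the exact form;
* $\mathcal L_{dis}$ — distribution: $|\mathbb E y - \mathbb E\hat y|$ per
  window. The defining formula uses only the first moment even where prose
  mentions the standard deviation; the formula is implemented;
* $\mathcal L_g$ — sigmoid cross-entropy of discriminator logits against
  all-ones (numerically stabilised), with the discriminator trained on the
  complementary objective.

## Training

Two phases, both Adam ($\beta = 0.9, 0.999$) with inverse-time decay
$\mathrm{lr}(s) = 0.01/(1 + s/\mathrm{decay\_steps})$: a supervised phase
(adversarial term excluded) followed by a joint phase alternating
discriminator and generator steps 1:1 (no alternation ratio is prescribed).
After every epoch the validation RMSE is computed and the best-validation
generator parameters are restored at the end; validation RMSE (rather than
the full supervised loss) is the selection criterion, and the initial
(untrained) parameters are a selection candidate too, so a run whose every
epoch hurts validation falls back to its starting point — which, with the
near-zero residual head, is the persistence solution. Setting
`joint_epochs = 0` reproduces the no-adversarial-phase ablation;
`lambda_t = 0` the no-trend-loss ablation — each changes only its
designated loss component, which the test suite verifies on logged traces.
Epoch counts are configuration; the decay constant defaults to
`decay_steps = 50`, freezing the model near the early good solutions that
short budgets find. Training granularity is one model per (subject, target
region, mode): BOLD dynamics are subject- and region-specific, so no
parameters are shared across tasks.

Series prolongation feeds each (region, mode) model the final $D$
normalized mode values, appends the $H$-step forecasts of all regions to
the rolling history, and repeats autoregressively until the requested
extension exists; per-mode forecasts are denormalized and superposed, and
only the selected low-frequency modes contribute (high-frequency modes are
treated as noise and not extended).

## Metrics and reliability

RMSE and MAE quantify pointwise error; DTW — the minimum cumulative
$|y_{i'} - \hat y_{j'}|$ over monotone alignments, computed by dynamic
programming with steps $\{(1,0),(0,1),(1,1)\}$ and no warping window —
quantifies shape similarity. Metrics are reported on the normalized scale,
per window, then averaged (whether published DTW values are summed or
averaged across windows is ambiguous; the mean is reported and documented).
The DP is verified against exhaustive path enumeration in the test suite.

Reliability treats predicted and ground-truth sessions as two raters of
each functional-connectivity edge (Pearson correlation between regions):
per edge, ICC(2,1) — two-way random effects, absolute agreement, single
measures, the convention of the test–retest FC literature — is computed
across subjects, graded poor (< 0.40) / fair / good / excellent (> 0.75);
values exactly at 0.40 and 0.60 take the higher grade and 0.75 is "good".
Zero-variance edges have no defined ICC and are reported as missing with a
count, not coerced to 0. The predicted session is the original history with
the forecast horizon substituted; a horizon-only comparison is what
`subject_pearson()` applies at the individual level.

## Synthetic cohorts

`generate_cohort()` draws, per region and subject, sinusoids with
frequencies uniform in configurable bands (defaults 0.008–0.016 Hz and
0.03–0.05 Hz, mirroring the two lowest empirical IMF bands so the 0.05 Hz
rule retains both), phases uniform, mixed through a coupling matrix (each
region partially driven by the average of the others — the predictability
the dual-attention design presumes), plus AR(1) noise (coefficient 0.3)
emulating BOLD temporal autocorrelation. Per-subject frequency and phase
jitter creates the between-subject variance a meaningful ICC needs. The
cohort is a pure function of `(config, seed)`.

What the generator does **not** emulate: hemodynamic (balloon-model)
dynamics, scanner drift, motion and physiological artifacts,
non-stationarity of coupling, and spatial autocorrelation beyond the
configured mixing. Passing tests therefore demonstrate the machinery is
correct and the method behaves as designed under its own assumptions — not
that those assumptions hold for any particular scanner or population.

## Numerical choices and degenerate inputs

* Constant series: max–min normalization refuses (degenerate range), FC
  and Pearson computations refuse (undefined correlation), naming the
  region.
* The zero signal is a VMD fixed point: all-zero modes, converged at
  iteration 1. Zero-energy modes keep their current center frequency
  rather than dividing by zero.
* Cross-entropy uses the `max(a,0) - ab + log1p(exp(-|a|))` form; the
  per-window Euclidean norm is smoothed as $\sqrt{x + 10^{-12}}$ at zero.
* CBAM channel ties broken toward the first maximum; gradient of `abs`
  uses the sign subgradient (0 at 0).
* Gradient correctness of every tape operation and of the full
  generator-plus-loss graph is enforced by finite-difference tests.

## Problem sizes in the test suite

The suite exercises the full method at desk scale: cohorts of 1–10
subjects, 3–6 regions, 150–600 timepoints, hidden widths 8–32, 1–10
epochs, horizons 6–40. These sizes were chosen to exercise every code path
and the documented behaviours (beating the persistence baseline, ICC
anchors at 1 and 0, 40% prolongation) with tight, seeded tolerances; they
are not the scale of a production analysis, which the same configuration
objects express directly (e.g. hidden 96, batch 128, T = 1200).

## Known limitations

* Pure-R training: minutes per (region, mode) model at test scale; a
  compiled backend would be needed for atlas-scale cohorts.
* Decomposing the full series before splitting admits the mild look-ahead
  discussed above.
* The adversarial phase with very few epochs can leave the discriminator
  near chance on tasks where the supervised generator is already close to
  the data; the ablation switches make the supervised-only configuration a
  first-class citizen.
* ICC is computed per edge; edge-group pooling and graph-theoretic FC
  summaries are out of scope.
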