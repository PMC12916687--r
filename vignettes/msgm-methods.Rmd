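---
title: "Multi-scale spatiotemporal graph state-space modelling of EEG: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale spatiotemporal graph state-space modelling of EEG: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msgm)
```

## The problem

Subject-independent EEG emotion decoding asks a classifier trained on some
people to generalise to a person it has never seen. Two properties of EEG
make this hard: emotional signatures live at several temporal granularities
at once (transient fluctuations and sustained mood), and the informative
structure is spatial — coordinated activity across scalp regions — rather
than anything carried by a single electrode. `msgm` implements an
architecture built around both observations: multi-window relative spectral
features, bimodal (whole-scalp and within-region) channel graphs encoded by
Chebyshev graph convolutions, and a selective state-space sequence model
with linear complexity in the token count.

## Feature extraction

A trial `X` (channels `c` by samples `L` at rate `f_s`) is segmented twice.
The first level slides a 20 s window with a 4 s hop, giving
`floor((L - 20 f_s) / (4 f_s)) + 1` overlapping segments that inherit the
trial label; a trailing remainder is discarded. The second level divides
each segment with `K` shorter windows, one per temporal scale.

Each sub-segment yields a `c x 7` matrix of relative power spectral density
(rPSD): Welch spectra (Hann window, 2 s sub-windows at 50% overlap, mean
averaging, per-window mean detrending) integrated over seven bands — delta
1–4, theta 4–8, alpha 8–12, low beta 12–16, beta 16–20, high beta 20–28 and
gamma 30–45 Hz, all half-open intervals. The denominator is the power over
the union of the band supports (1–45 Hz minus the 28–30 Hz gap), so each
channel's band vector sums to exactly 1 — a strong testable invariant — and
the representation is invariant to per-subject amplitude scaling
(skull-thickness and impedance effects), which is the reason to prefer rPSD
over absolute PSD or differential entropy for cross-subject transfer. A
flag switches the denominator to the full 0–Nyquist power, and absolute PSD
/ differential entropy are available for the feature-type ablation.
Zero-variance channels yield an all-zero row with a warning instead of NaN.

Per scale `k`, features are stacked into a tensor `F_k` of shape
`(b, n_k, c, 7)`: batch, sub-segments, channels, bands.

**Choice of scales.** The number and lengths of the second-level windows
are genuinely open design parameters. The package defaults to `K = 3` with
(length, hop) of (4 s, 2 s), (8 s, 4 s) and (12 s, 6 s) — short, medium and
long granularity inside one 20 s segment, each giving at least two tokens —
and everything is configurable. The shipped `small.yaml` benchmark uses the
first two scales.

## Spatial priors

For each scale the batch-averaged tensor is flattened per channel
(sequence-major, band-minor — a fixed documented order) and passed through
a learnable affine transform `Z' = Z W + V` (`W` Xavier-uniform,
`V` zero-initialised), giving one feature row per channel.

The **global graph** couples every channel pair that is simultaneously
similar in correlation and close in Manhattan distance:

* Pearson correlation `kappa_ij` (1e-6 added to the denominators, so
  constant rows stay finite) must reach its 75th percentile, and
* Manhattan distance `d_ij` must fall below its 25th percentile;

surviving pairs get the Gaussian kernel weight
`exp(-||u_i - u_j||^2 / (2 sigma^2))` with `sigma = (mu_d + sd_d) / 2`
computed from the off-diagonal Euclidean distances. Percentiles are taken
over off-diagonal upper-triangle values only — including the self pairs
(`kappa = 1`, `d = 0`) would distort both thresholds — and the diagonal is
fixed to 1 (the kernel at zero distance with both gates passing). The
**local graph** keeps only same-region pairs of the global graph; region
maps ship as editable JSON for a 62-channel montage (7, 10 and 17-region
lobe groupings) and a 32-channel montage, following standard 10–20 lobe
anatomy. Both adjacencies are duplicated and stacked `(2, c, c)`; slice 1
feeds the shallow encoder and slice 2 the deep one. The duplicates start
equal and the package keeps them equal (nothing trains them apart); the
stacking exists so that encoder-specific transforms *could* diverge.

**Graphs during training and evaluation.** Graphs are rebuilt from each
training batch's averaged features and the current transform parameters, so
they evolve as the transform learns. At evaluation the graphs frozen at the
best-validation training state are reused: averaging test features into the
priors would leak test statistics across samples. Gradients flow into the
transform through the Gaussian kernel and the degree-normalised Laplacian;
the percentile thresholds, the gate mask, `sigma` and `lambda_max` are
treated as constants of the current batch (order statistics have
subgradient zero almost everywhere), which the gradient tests document.

## Graph encoders and fusion

Each stream applies a Chebyshev spectral filter in the rescaled normalised
Laplacian `Lhat = 2 L_sym / lambda_max - I`:
`relu(sum_i theta_i T_i(Lhat) F - B)` with `T_0 = I`, `T_1 = Lhat`,
`T_i = 2 Lhat T_{i-1} - T_{i-2}`. The bias is subtracted, as the operation
is defined; the sign is absorbable into a trainable parameter.
`lambda_max` is computed exactly per graph — at EEG channel counts the
eigen-solve is negligible and removes the usual `lambda_max = 2`
approximation. Four encoders run per scale: shallow (1 layer) and deep
(2 layers) on the global and local graphs; the Chebyshev order defaults to
3 (a literature-standard default, configurable). Degree normalisation makes
the filter invariant to a uniform rescaling of edge weights, and at order 1
it degenerates to a graph-independent dense layer — both pinned by tests.

Encoder outputs `(b, n_k, c, w_out)` are flattened over channels and
affinely projected to the token width `h`; some channel-collapse map is
forced by the shapes, and a trainable projection shared by the shallow and
deep outputs of a stream is the minimal choice. A linear base embedding of
the flattened raw features provides a non-filtered view, and each stream's
token sequence is the unweighted elementwise mean of base, shallow and deep
embeddings.

## Temporal model

Token sequences pass through a pre-norm residual stack:
`x_m = Block_m(RMSNorm(x_{m-1})) + x_{m-1}`, then a final RMSNorm. Each
block expands width by a factor of 2, splits into a convolutional branch
(causal depthwise convolution, kernel 4, left-padded by `kernel - 1` to
preserve causality, then SiLU) and a SiLU gating branch, and runs the
selective scan

```
x_t = exp(Delta_t * A) x_{t-1} + Delta_t * B_t * v_t
y_t = C_t . x_t + D * v_t
```

per expanded channel with a diagonal state matrix. `Delta_t` (softplus of a
rank-`ceiling(h/16)` projection), `B_t` and `C_t` are functions of the
input, which is what lets the recurrence selectively propagate or forget.
The input term uses Euler discretisation (`Delta_t B_t`), exactly as the
recurrence above is written, rather than zero-order hold. `A` is
initialised S4D-real style (`A[, k] = -k`), `D` to ones, and the `Delta`
bias so the initial step size is about 0.01 after softplus — the reference
conventions for this architecture family. The global and local sequences
of every scale share one stack: the classifier consumes "the global and
local outputs" of a single module, sharing halves the parameter count, and
a configuration switch could separate them.

After the stack, every stream/scale is mean-pooled over tokens,
L2-normalised per row (epsilon 1e-12), averaged global-with-local, averaged
over scales, and classified by a single affine layer; softmax lives in the
loss.

## Training protocol

Subject-independent evaluation uses leave-one-subject-out (LOSO) folds —
every subject is the test set exactly once, the rest split 8:2 into
training and validation *by subject* — or leave-n-out folds (`ceiling(S/n)`
groups, 9:1 split) for larger cohorts. Optimisation is AdamW at learning
rate 3e-4 with cross-entropy, label smoothing 0.1, dropout 0.25 applied to
each block output before the residual addition (the conventional pre-residual
spot), batch size 32 and early stopping with patience 5 on validation
accuracy; the best-validation snapshot is tested. Metrics are segment-level
accuracy and macro-averaged F1 (macro is symmetric and robust to
imbalance); no trial-level vote is taken, since the protocol operates on
sliced segments with inherited labels. All subject splits are seeded and
recorded. Valence scores are binarised at 3.0; a score exactly at the
threshold is excluded with a warning rather than assigned — the boundary
rule is otherwise arbitrary and exclusion avoids a class bias.

Because no deep-learning framework is available to R, the package trains
through its own small reverse-mode autodiff tape (`R/autodiff.R`): each
operation records a vector-Jacobian product, and the whole forward pass —
graph construction included — is differentiated by walking the tape
backwards. Finite-difference tests verify every layer's gradients, and a
dedicated test pins the tape-built forward pass to a composition of the
exported numeric operations.

## Ablation switches

Single-flag ablations reproduce the architecture-component analysis:
`no_temporal_multiscale` (longest window only), `no_spatial_multiscale`
(global graph for both streams), `single_gcn` (one depth-1 encoder per
stream), `no_fusion` (base embedding only), `no_mamba` (identity temporal
stack — a forward pass then performs zero scan steps, which a counter
asserts). Capacity strictly decreases under `single_gcn`, `no_fusion` and
`no_mamba`.

## The synthetic benchmark

Licensed EEG corpora cannot ship with the package, so a generator emulates
the statistical structure the method assumes: per scalp region, one
sinusoid per frequency band with trial-random in-band frequency (10% edge
margin) and phase; channels mix their region's standardised latent with
independent `1/f` background noise using weights `sqrt(rho)` and
`sqrt(1 - rho)`, so the within-region correlation is `rho` by construction
and cross-region correlation is near zero; a per-subject log-normal gain
(SD 0.2) emulates the amplitude variability that motivates relative
features and makes LOSO non-trivial; and one class's chosen band amplitude
is scaled by `1 + effect_size`. The background amplitude puts single-trial
band SNR near 1, keeping the task learnable but not degenerate. Every
recording is a deterministic function of (seed, subject, trial).

The benchmark conditions are 8 subjects, 8 trials each, 8 channels in two
regions, 128 Hz, 30 s trials, alpha boosted with `effect_size = 1` — small
enough for a single CPU, large enough that chance is distinguishable from
learning. With the boost present the model reaches essentially perfect
LOSO accuracy (the task is linearly separable in band power by
construction); with `effect_size = 0` accuracy sits at chance, which guards
against information leaking through the pipeline. One caveat is inherent
to relative features: because rPSD rows sum to one, boosting one band's
absolute power necessarily *lowers* every other band's relative share by a
common renormalisation factor. The generator's contrast is therefore
"confined" to the effect band in absolute band power and in the shape of
the non-effect band profile, not in each relative band mean — the tests
assert exactly that.

What passing these tests does **not** show: the generator has no video-locked
dynamics, no eye-blink or muscle artifacts, no volume-conduction mixing
beyond block correlation, and no label noise, so synthetic accuracy says
nothing about accuracy on real corpora. It validates the machinery —
features, graphs, gradients, protocol — not the science of any particular
dataset.

## Numerical choices and degenerate inputs

* Welch: `nperseg = min(2 s * f_s, T)`, 50% overlap, symmetric Hann,
  one-sided density scaled so total power matches variance (Parseval is
  tested to 2%).
* Percentile thresholds use R's default quantile type; ties can push the
  surviving edge fraction slightly above 25%, which tests allow for
  explicitly.
* Isolated graph nodes get zero rows in `L_sym`; an all-diagonal graph
  yields `Lhat = -I` (guarded `lambda_max`).
* Kernel-longer-than-sequence convolutions simply drop the out-of-range
  taps; sequences as short as one token are legal.
* `exp(Delta * A)` is safe because `A < 0` by parameterisation and
  `Delta > 0` after softplus (asserted).
* Training aborts a fold with a diagnostic if the loss turns non-finite.

## Problem sizes used by the shipped checks

The bundled tests and the acceptance script run entirely on synthetic data
at the `small.yaml` scale (8 subjects, two scales, token width 16,
Chebyshev order 2, state dimension 8, at most 10 epochs per fold) and on
desk-scale unit fixtures; the published-statistics check recomputes Welch
t / Cohen's d from the bundled per-dataset summary table (15 LOSO folds for
SEED, 10 leave-n-out folds for THU-EP and FACED). These sizes are the
package's chosen benchmark conditions; scaling any of them up only costs
time.

## Known limitations

* No domain-adversarial adaptation, multimodal fusion or online inference.
* The region maps approximate published montage figures from standard
  10–20 anatomy; they are configuration, not ground truth.
* Whether the stacked graph duplicates are ever trained apart, and whether
  the global/local streams share temporal weights in the original
  formulation, are open questions; the package keeps duplicates equal and
  weights shared, with switches where reasonable.
* The trainer is pure R: correct and deliberately small, not fast. Real
  62-channel corpora at full scale would need hours, not the minutes the
  synthetic benchmark takes.
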