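---
title: "Methods: dual-domain CNN stress detection from wearable signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-domain CNN stress detection from wearable signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

`wearstress` classifies ordinal stress levels (low/medium/high) from
multirate wrist-wearable recordings collected intermittently during work
shifts. The pipeline is: session segmentation at gaps > δ, overlapping
windowing, training-only augmentation, dual-domain feature extraction,
training-fitted standardization, SMOTE rebalancing, and a two-branch 1-D
convolutional classifier with late fusion.

The classification unit is a 60 s window. Each window yields two tensors:

* **Time branch input** `X_t` (`T × F_t`): the window is cut into `T = 12`
  contiguous 5 s sub-frames; per sub-frame and channel we compute mean,
  population standard deviation (the `1/n` form), min and max, plus two
  heart-rate-variability-style columns (sub-frame sd and RMSSD of the 1 Hz
  HR series). True HRV needs beat-to-beat intervals, which a 1 Hz HR stream
  does not contain; sd/RMSSD of the HR series are the honest reduction.
* **Frequency branch input** `X_f` (`F × F_f`): per channel, the
  log-compressed magnitude spectrum `log(1 + |X_k|)` with the DC bin
  excluded, linearly interpolated onto `F = 64` points of the channel's
  normalized-frequency axis `(0, Nyquist]`. Channels run at different rates
  (1–32 Hz), so a common physical-Hz axis would leave most bins empty for
  slow channels; per-channel Nyquist fractions keep every channel's 64 bins
  populated. DC is excluded because window means belong to the time branch —
  this keeps the ablation contrast clean. `log(1+·)` is monotone,
  zero-preserving, and tames magnitudes that span orders of magnitude.

Each branch is `L = 3` blocks of conv(kernel 3, 'same') → batch-norm → ReLU
→ max-pool(2) → dropout, ended by global average pooling (GAP); the fused
vector `z = concat(z_t, z_f)` passes through FC(128)+ReLU → dropout →
FC(64)+ReLU → FC(3)+softmax. Training minimizes cross-entropy plus
`λ Σ‖W‖²` (weights only — not biases or batch-norm parameters) with Adam,
seeded shuffling, and early stopping on validation loss (patience 10,
best-weights restore). Defaults: η = 1e-3, λ = 1e-4, batch 64, dropout 0.3.
The network and its backpropagation are implemented natively (no autodiff
stack is available in the target environment) and are verified against
finite-difference gradients in the test suite.

## Design choices that were genuinely open

**Per-feature (pooled) standardization.** `z = (x − μ)/σ` is applied per
feature — a time-branch statistic column or a frequency-branch channel —
with μ, σ pooled over the sub-frame/bin axis and fitted on training rows
only. The alternative, z-scoring every `(position, feature)` cell
separately, was implemented first and found to be destructive: it inflates
every pure-noise spectral bin to unit variance, so the spectrum loses its
shape and the frequency branch cannot learn at all (it could not even fit
its training split). Pooled scaling preserves relative structure along the
axis, which is what a convolution reads. This mirrors normalization practice
for spectrogram networks, where one normalizes per channel, never per pixel.

**A coordinate channel in the frequency branch.** Convolution followed by
GAP is translation-invariant along its axis. That is the right inductive
bias for the time branch, but spectra are different: the information is the
*absolute* band position, and a tone at bin 26 versus bin 51 is a pure
translation. The frequency branch therefore appends a fixed
normalized-frequency ramp as an extra input channel (`model_config(freq_coord
= TRUE)`), letting `ReLU(a·mag − b·coord + c)` express band-limited
detectors while keeping the stated block structure. Without it the branch
falls back to memorizing noise.

**Split unit.** The default split is stratified by window, matching
dataset-level splitting conventions; it is documented as optimistic, because
overlapping windows from one session land on both sides of the split and
any per-subject idiosyncrasy (baseline offset, session phase) becomes a
memorizable shortcut. `split$by = "subject"` keeps subjects whole and is
what the fusion-property experiment uses — under the window split, a
single-branch model reaches ≈ 0.85 by subject memorization, which says
nothing about feature fusion.

**Other declared rules.** Constant channels min-max scale to 0.5 with a
warning (symmetric, avoids 0/0). Precision/recall/F1 with a zero denominator
are 0 with a flag, keeping reports total. Prediction ties resolve to the
lowest class index. Session gap detection uses the slowest-rate channel
present (it cannot see gaps shorter than its own sampling period, the
conservative choice). Windows are half-open `[start, start + 60)` s,
0-based. SMOTE runs after the split, on standardized training rows only,
with same-class neighbors (k = 5 by convention; clipped with a warning for
tiny classes). Jitter σ defaults to 0.02 in scaled-signal units with one
copy per original; the jitter law is applied per channel to raw windows, not
to features. Grid cells that fail evaluate to missing and are excluded from
the argmax; the dropout × batch heatmap aggregates over learning rates by
mean (the axes omit lr, so a rule must be declared). The Bayesian search
surrogate is a GP with a squared-exponential kernel, unit signal variance
and length-scale 1 on standardized log-scaled hyperparameters — the minimal
standard instantiation behind the closed-form Expected Improvement
`EI = d·Φ(d/s) + s·φ(d/s)`, `d = μ − f_best`, with `max(d, 0)` at `s = 0`.

## What the synthetic generator emulates — and what it does not

`synth_spec()` generates per-channel noisy tones on subject-specific
baselines: `value(t) = mean + offset + A sin(2πft + φ) + N(0, σ²)`, with
`offset ~ N(0, baseline_sd²)` per stream and φ uniform per session so windows
are not phase-locked. Sessions of the stated lengths are separated by gaps
larger than δ; channels keep the real device's rates (ACC 32 Hz, EDA 4 Hz,
HR 1 Hz, TEMP 4 Hz); every sample carries its stream's class label, as in
the source data where stress is labelled per period.

The default class parameters implant a separability design chosen to make
the ablation ordering provable rather than lucky:

* classes 0 vs 1 differ only in EDA/HR baseline mean (EDA 2 vs 6 µS, HR 70
  vs 85 bpm) — invisible to a DC-free spectrum;
* classes 1 vs 2 differ only in EDA oscillation frequency, **0.8 Hz vs
  1.6 Hz** at equal amplitude. At the 4 Hz EDA rate these advance 0.2 and
  0.4 cycles per sample: over any 5 s sub-frame both visit the same
  five-point phase multiset, so every order-invariant sub-frame statistic
  (mean, sd, min, max) is *exactly* equally distributed between the two
  classes, while their DFT bins (normalized 0.4 vs 0.8) are far apart. A
  lower pair such as 0.1 Hz would leak into sub-frame means (its period
  spans two sub-frames) and void the single-branch ceiling.

Under a subject-level split the best a single branch can do is therefore one
of the two distinctions plus a coin flip on the other: accuracy ≈ 2/3. The
end-to-end property test asserts full ≥ 0.90, each single branch ≤ 0.75, on
600 windows (200/class), 30 epochs, one fixed seed.

What the generator does **not** emulate: physiological waveform morphology
(skin-conductance response peaks, RR-interval dynamics, circadian
temperature drift), movement artifacts, label noise, or missing-data
patterns beyond clean session gaps. A green test therefore establishes that
the pipeline's machinery — segmentation, feature separation between domains,
fusion, training — works as designed; it does not establish field accuracy
on real nurses' recordings, which the source study measured on an external
dataset that is out of scope here.

## Numerical and degenerate-input rules

* DFT via the fast transform, contracted (and tested at 1e-9) to the direct
  summation definition; Parseval checked on random inputs.
* Batch-norm ε = 1e-5; running statistics with momentum 0.9; eval mode is
  deterministic (dropout off, running stats).
* Early stopping requires a strict validation-loss improvement; with a
  degenerate zero learning rate training stops after `patience + 1` epochs.
* Windows are emitted only if every channel reaches 95 % of its nominal
  sample count; corrupted (non-numeric/NaN) CSV cells are interpolated
  within sessions only, while empty cells simply mean "channel not sampled
  at this instant" in the multirate wide dialect.
* Seeds: one global seed fans out to per-stage seeds through a string-keyed
  hash, so stages are individually reproducible and do not consume each
  other's RNG streams. Two runs from the same manifest are bit-identical.

## Known limitations

* The native R network is CPU-only and desk-scale; the default experiment
  (600 windows, three variants, 30 epochs) trains in ~2–3 minutes.
* The frequency axis interpolation extends the lowest available bin
  downward for very slow channels (constant extrapolation below the first
  non-DC bin of a 1 Hz channel).
* `read_wide_csv` returns one stream per subject and assumes ISO-8601 or
  numeric timestamps; device-native binary formats are out of scope.
* Grid search trains one model per cell; the packaged tuning objective uses
  a reduced epoch budget by default (5 epochs) to keep the 27-cell sweep
  desk-scale — pass the full budget for experiment-grade sweeps.
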