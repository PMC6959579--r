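---
title: "Correlation-feature decoding of SSVEP: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlation-feature decoding of SSVEP: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssvepdecode)
```

## The decoding problem

A JFPM-coded SSVEP speller flickers K targets simultaneously, target k at
frequency f_k with phase φ_k. Gazing at a target entrains occipital EEG at
f_k and its harmonics. The decoder receives a short multichannel epoch
**X** (M channels × Nt samples, taken 0.14 s after stimulus onset to absorb
the visual-pathway latency) and must return k.

All methods in this package are correlation maximizers that differ in what
they correlate and which spatial filters they use:

* **Standard CCA** correlates **X** with a phase-free sinusoidal reference
  **Y**_k (sin/cos pairs of N_h harmonics). Training-free, and blind to
  phase coding.
* **Extended CCA** adds a subject-specific template **X̂**_k (the mean of
  the training trials of target k) and sums five correlations between
  CCA-filtered projections of **X**, **X̂**_k and **Y**_k.
* **TRCA** learns, per target, the channel weighting that maximizes
  inter-trial reproducibility (a generalized eigenproblem), then
  correlates filtered test data with the filtered template. The ensemble
  variant stacks all K filters and uses a two-dimensional (matrix)
  correlation.
* **Multi-feature CCA (mfcca)** treats the extended-CCA features as five
  arbitrary picks from a much larger space: the three pairwise CCAs among
  {**X**, **X̂**_k, **Y**_k} define six spatial filters and ten canonical
  variables (CVs), every unordered CV pair defines a correlation feature
  (45 in all), and the feature set is *learned* by greedy forward
  selection on other subjects' data. The selection is done once; the
  six-feature set that selection produces is shipped as the frozen
  default and summed unweighted into the score ρ_k = Σᵢ r_k(i).
* **Ensemble mfcca (emfcca)** upgrades feature 5 to an ensemble feature —
  the 2-D correlation of **X** and **X̂**_k projected on the template-side
  filters of *all* K targets — and replaces the unweighted sum with a
  weighted one, α ∈ [0,1]⁶, fitted on other subjects by a genetic
  algorithm. Only feature 5 can be "ensembled": it is the only one whose
  two arguments are projected on the same filter group, and whose filter
  group can include every class.

Why these ten CVs and not more: projections of **X** and **X̂**_k are taken
through the four filters estimated in signal space, and projections of
**Y**_k through the two reference-side filters; correlations that pair a
template projection with a reference projection (8 pairs) contain no test
data beyond the filters, and the pair of the two reference projections is
likewise static, so 45 − 8 − 1 = 36 features remain admissible.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `tw` | user-set (0.2–1 typical) | s | analysis window; ITR trades accuracy against `tw + 0.5` s per selection |
| `latency` | 0.14 | s | visual-pathway delay before the SSVEP settles |
| `band` | (6, 90) | Hz | broadband prefilter; passband corners of a Chebyshev-II design |
| filter `order`, `rs` | 6, 40 | –, dB | per-direction IIR order and stopband attenuation; short transients at 0.2 s windows |
| `n_harmonics` | 3 | – | harmonics in **Y**_k; SSVEP energy above the 3rd harmonic is marginal |
| `filter_bank_config(n, low_base, high, a, b)` | 4, 8, 70, 1, 0 | – / Hz | sub-band n spans n·8–70 Hz; fusion weights n^(−a)+b = 1, 1/2, 1/3, … reflect the SNR decay of higher harmonics |
| `q_mode` (TRCA) | "concatenated" | – | variance normalization over the globally centered concatenation; "pooled" (sum of per-trial covariances) differs only by between-trial mean cross-terms |
| `ga_control()` | pop 50, 100 generations, mutation 0.05, elitism 2 | – | bounded stochastic search for a piecewise-constant objective; any bounded black-box optimizer could stand behind the same contract |

## The synthetic generator

`simulate_dataset()` emulates the structure of the public 40-target
benchmark: JFPM coding (8–15.8 Hz in 0.2 Hz steps; 0.35π phase step, the
spacing used for analysis after circular phase re-coding), block design
with one trial per target per block, 250 Hz sampling, and a response that
is zero before the 0.14 s latency — zeroing rather than circular shifting,
so epoch extraction can be validated against a known onset. The response
is a sum of phase-locked harmonics with amplitudes (1, 0.5, 0.25), mixed
into M channels through a single seeded mixing vector shared by all
targets, consistent with the observation that scalp mixing is nearly
constant over this narrow frequency band (the premise that makes ensemble
filters work). Background noise is 1/f-shaped Gaussian by default (EEG
background is 1/f-like; white noise is available for unit tests), scaled
per channel so that SSVEP variance over the post-latency samples versus
noise variance matches `snr_db` — stated explicitly because "SNR" is used
loosely in this literature.

The default −14 dB per channel matches the mean SSVEP SNR reported for
the benchmark recordings and places the training-based decoders in their
realistic 70–90% range at 0.5 s windows, so method orderings are visible
rather than ceiling-clipped.

What the generator does *not* emulate: spatially correlated EEG background
(its noise is independent across channels, which flatters all spatial
filters), target-dependent mixing, trial-to-trial amplitude/latency
variability, blinks and EMG artifacts, electrode geometry. Consequently,
passing tests demonstrate correctness of the algorithms and their
contracts — recovery in the noiseless limit, correct eigen/canonical
solutions, selection and weighting behaviour — not performance claims
about real recordings.

## Numerical choices

* **CCA solver.** Rows are mean-centered over the window (sample moments;
  the 1/Nt vs 1/(Nt−1) convention cancels in a correlation). Covariances
  are whitened by the symmetric inverse square root with Tikhonov ridge
  ε·trace/dim, ε = 1e−8, then the whitened cross-covariance is SVD'd.
  The ridge keeps 0.2 s windows (50 samples, up to 15 variables) stable;
  it bounds the re-mixing invariance of ρ at ~1e−7 rather than machine
  precision.
* **Sign conventions.** A canonical pair is scaled to unit norm,
  positive mutual correlation, and jointly flipped so the
  largest-magnitude element of w_x is positive; TRCA filters likewise.
  Correlations between projections from *different* CCAs would otherwise
  be sign-random, and several of the 45 features mix CCAs.
* **Filter design.** `band` gives passband corners; stopband edges sit
  2 Hz below / 10 Hz above (the margins of standard filter-bank SSVEP
  code). With the stated band as *stopband* edges instead, a 10 Hz
  fundamental loses ~77% of its amplitude in the 8–70 Hz sub-band, which
  silently cripples filter-bank decoding. Zero-phase filtering is a
  forward–backward pass with odd-reflection padding of length
  min(3·order, Nt−1), so 50-sample epochs remain filterable.
* **Filtering order.** Epochs are filtered after extraction by default
  (the conventional offline order); `filter_first = TRUE` filters the
  continuous trial and then extracts, trading fidelity to that convention
  for freedom from edge transients. The transients matter: on *noiseless*
  40-target data at 0.5 s, per-epoch filtering costs standard CCA 3/40
  targets to their 0.2 Hz neighbours, so the perfect-recovery tests use
  the continuous path.
* **Ties and degeneracies.** All argmax rules break ties toward the
  lowest index and flag the tie. Zero-variance templates or CVs yield
  zero features with a `degenerate` attribute, never NaN. TRCA with one
  training trial raises an explicit error (there is no inter-trial
  covariance to maximize) — unlike mfcca, which runs from a single block.
* **Forward selection** requires a strictly positive improvement
  (tolerance 0, configurable) and breaks ties toward the lower feature
  index; **GA** fitting is seeded and restores the global RNG stream.
* **ITR.** The Wolpaw formula with a 0.5 s gaze-shift added to every
  selection, chance-floored at 0 bits; chosen because it is the standard
  in this literature, flagged because several variants exist.

## Problem sizes

The test suite exercises full-scale structure where it is cheap
(40-target layouts, 6-block designs) and shrinks what is expensive:
decoder cross-validations mostly run at 3–10 targets with 1 Hz spacing,
2–3 blocks and ≤ 1.2 s trials; the perfect-recovery check runs the full
40 targets × 6 blocks in the noiseless limit. `scripts/acceptance.R`
evaluates all six decoders at the benchmark scale (40 targets, 6 blocks,
0.5 s windows, 4 sub-bands, 240 trials) and fits GA weights on two
synthetic training subjects; these sizes keep a complete run in the
minutes range while preserving every structural dimension of the problem.

## Known limitations

* Only the leading canonical pair of each CCA is used (the methods are
  formulated with single-vector filters); multi-component projections are
  out of scope.
* Forward selection and GA fitting transfer hyperparameters across
  *synthetic* subjects here; with identically distributed synthetic
  subjects this cannot exhibit the inter-subject variability that makes
  subject-independent training genuinely hard on real data.
* No artifact rejection, re-referencing or notch filtering — the
  generator produces none of those nuisances, and acquisition-side
  filtering is assumed done.
* The optional reader for the benchmark's own container format is not
  included; `read_epochs()`/`write_epochs()` round-trip the package's own
  self-describing container.
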