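---
title: "Methods: linear source decomposition and sequence classification for EEG emotion recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linear source decomposition and sequence classification for EEG emotion recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Scalp EEG is a volume-conducted mixture of cortical activity: what an
electrode records is a weighted sum of the signals generated in several
brain regions plus sensor noise. `eegemo` works under the standard linear
mixing model

$$X = A S,$$

where $X$ is the 32-channel scalp recording, $S$ the activity of 12
latent cortical sources, and $A$ an unknown $32 \times 12$ mixing matrix.
The package's pipeline has three stages:

1. **Decomposition.** A *linear* stacked autoencoder with encoder widths
   32–64–12 and a mirrored decoder is trained to reconstruct pooled
   32-channel sample vectors through the 12-unit bottleneck. With linear
   activations the encoder composes to a single matrix, so a
   well-reconstructing bottleneck is precisely an (un)mixing estimate of
   the rank-12 source subspace. Reconstruction quality is validated with
   the adjusted coefficient of determination,
   $R^2_{\mathrm{adj}} = 1 - (1 - R^2)\frac{N-1}{N-p-1}$ with $p = 32$
   predictors; a decomposition is accepted once held-out
   $R^2_{\mathrm{adj}} \ge 0.9$.
2. **Feature sequences.** Source signals are framed with a 1 s window and
   0.5 s step (a 63 s trial gives 125 frames). Per frame and channel a
   Hanning-windowed Welch power spectral density is computed and integrated
   over the theta (4–7 Hz), alpha (8–13 Hz), beta (14–30 Hz) and gamma
   (31–50 Hz) bands, yielding a $125 \times 48$ band-power sequence per
   trial. An alternative feature computes per-frame Pearson correlations
   between each channel and a reference channel.
3. **Classification.** An LSTM with 125 hidden units runs across the 125
   frames, *all* per-step hidden outputs are flattened and integrated by a
   125-unit fully connected layer (tanh) and one sigmoid output unit. The
   model is trained on MSE loss against 0/1 labels by mini-batch gradient
   descent with a two-stage learning rate, dropout in the LSTM and FC
   layers, and L2 regularisation. This wiring carries 2,040,376 trainable
   parameters (and the default autoencoder 5,804), both checkable with
   `count_classifier_params()` / `count_sae_params()` and by enumeration of
   an instantiated model with `enumerate_params()`.

Trials are labeled High on an emotion dimension when the 1–9 rating
exceeds 5.5, Low below 4.5, and discarded in between; classes are balanced
by down-sampling before a 10-fold cross-validation whose mean per-fold
accuracy is the headline metric. Arms of the pipeline (decomposition
on/off, feature type, classifier type) are compared with paired t-tests
over fold accuracies.

## What the synthetic generator emulates

Because the package must be fully testable without external recordings,
`simulate_trialset()` produces DEAP-shaped data — 40 trials × 32 channels
× 8064 samples at 128 Hz, ratings on 1–9 — with known ground truth:

* **Sources.** Each of the 12 sources is a sum of within-band sinusoids
  (3 per band, random frequency, phase and amplitude jitter) over the
  active rhythm bands, riding on pink (1/f) noise at 10 % relative power.
  Band amplitudes are drawn per trial from a Rayleigh distribution and ramp
  linearly between independent start and end levels, so band power has
  genuine within-trial dynamics.
* **Mixing.** Channels and sources sit on concentric scalp rings; mixing
  weights decay with squared distance (each channel sees a handful of
  sources strongly) with multiplicative jitter, rejection-sampled to keep
  the condition number of $A$ below 100 so the unmixing problem is well
  posed. Optional i.i.d. gaussian sensor noise is added after mixing.
* **Ratings.** Valence is a monotone function of the late-half minus
  early-half contrast of total alpha+gamma band power, measured frame-wise
  exactly as the feature module measures it; arousal tracks the overall
  beta+gamma level. The standardised contrast is scaled by `effect_size`
  (default 3 rating points per SD), perturbed by gaussian noise (SD 0.5)
  and clipped to [1, 9]. The pooled (source-summed) contrast was chosen
  deliberately: a linear bottleneck recovers the source *subspace*, not
  individual sources, so only remixing-invariant quantities are fair
  targets for the downstream classifier. `effect_size = 0` severs the
  coupling and provides a chance-level control.

The generator does **not** emulate volume-conduction forward physics,
ocular/muscle artifacts, inter-subject variability, or non-stationary
line noise. Passing tests on this data demonstrates that the pipeline's
machinery — subspace recovery, band-power sequence extraction, temporal
classification — works as specified; it does not certify accuracy levels
on real recordings.

## Numerical and design choices

* **Welch estimate.** A 1 s frame at 128 Hz is short; a single
  Hanning-windowed segment keeps 1 Hz resolution, which sub-segmenting
  would halve and thereby blur the 4–7 Hz theta band. The PSD is one-sided
  and normalised so it integrates to signal power (Parseval, verified in
  tests); band edges are inclusive on both sides. Frames are mean-detrended
  so the DC offset does not leak into delta/theta bins.
* **Active bands.** Four bands (theta–gamma) are used for features;
  affective EEG corpora of this layout are band-passed from 4 Hz upward,
  which removes delta.
* **Autoencoder training.** Channel vectors are pooled across trials and
  time, shuffled, capped at 20,000 samples, and z-scored per channel with
  training-split statistics (stored in the model, inverted on
  reconstruction) — gradient descent on raw microvolt scales is
  ill-conditioned. Mini-batch GD uses batch 128, initial learning rate
  0.01 halved every 25 epochs, L2 weight decay $10^{-5}$, and an L1
  sparsity penalty $10^{-4}$ on the code. The last 10 % of the shuffled
  pool is the validation split; training stops at validation
  $R^2_{\mathrm{adj}} \ge 0.9$ (the acceptance criterion) or at the epoch
  cap. An all-zero input makes $R^2$ undefined; this is flagged with a
  warning and `NA` metrics rather than an error.
* **Classifier training.** Features are z-scored per column over the
  training set. Mini-batch GD (batch 16) runs at learning rate 0.05 for
  100 epochs then 0.01, with inverted dropout (default rate 0.2) on the
  flattened LSTM outputs and FC activations, global gradient-norm clipping
  at 5 (a standard LSTM stabiliser), L2 decay $10^{-5}$, and early stop at
  99 % training accuracy. The forget-gate bias starts at 1. Labels are
  coded Low = 0 / High = 1 to match the sigmoid's range under MSE loss; at
  prediction time a tie at the 0.5 threshold is classified Low.
* **Identifiability.** Linear unmixing is only defined up to an invertible
  transform, so decomposition quality is scored by canonical correlation
  between recovered codes and true sources (1.0 in the package's recovery
  tests), never by element-wise comparison.
* **Degenerate inputs.** Constant frames yield a zero PSD; a constant
  channel inside a frame yields correlation features of 0 and a flag;
  zero-variance inputs to `pcc()`/`adjusted_r2()` raise a typed
  undefined-metric condition; constant nonzero differences in the paired
  t-test raise a degenerate-test condition, while identical inputs return
  $t = 0, p = 1$.
* **Open choices resolved.** One autoencoder is trained on the pooled
  dataset (not per subject); cross-validation pools trials and balances
  once globally before splitting; the correlation-feature reference
  channel defaults to channel 1; trials keep their full 63 s so that the
  1 s / 50 % framing yields the canonical 125 steps.

## Problem sizes used in validation

The package's own validation runs at desk scale, chosen so the full suite
completes comfortably on one CPU: autoencoder recovery uses 8 trials of
20 s across 5 seeds (15,000 pooled vectors); the end-to-end experiment
uses 200 trials of the full 63 s with an LSTM of 32 hidden/FC units and a
60-epoch budget — the smallest classifier that cleanly separates the
generator's coupling; the chance-level control reuses the same pipeline on
`effect_size = 0` data. The full-width 125-unit classifier is instantiated
and counted exactly, and trains through the same code path.

## Known limitations

* The linear autoencoder recovers the source subspace, not anatomically
  identified sources; claims about individual brain regions are outside
  what this model can support.
* MSE-on-sigmoid is the specified loss; it is less well-conditioned than
  cross-entropy and relies on the two-stage learning rate and clipping for
  stable training.
* The SVM and (optional) ICA arms are thin adapters over external
  implementations, provided for comparison only.
* Headline accuracies on real affective corpora depend on data this
  package does not ship; the pipeline accepts such data in its HDF5
  container (`save_trialset()` documents the layout) but no figures are
  claimed for it.
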