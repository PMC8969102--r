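---
title: "Multimodal fusion for dementia screening: models, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal fusion for dementia screening: models, choices, limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(demfusion)
```

## The problem and the modelling idea

Dementia alters spontaneous speech on several levels at once: the acoustics
(pausing, speech rate, voice quality) and the language (repetition,
simplified vocabulary, derailed picture descriptions). A screening model
should therefore fuse the audio recording and its transcript. The package
implements three fusion architectures that let the modalities interact
*inside* one trainable network, instead of voting over separately trained
unimodal models: co-attention over token and patch embeddings, a multimodal
shifting gate that perturbs word embeddings with visual/acoustic
information before a second text-encoder pass, and gated self-attention
over the concatenated token-plus-patch sequence. Both tasks share the
front end: binary AD/HC classification (2 logits, cross-entropy) and MMSE
regression (one ReLU output unit — predictions are non-negative by
construction and deliberately not clipped at 30 — trained on squared
error, the RMSE minimiser, with validation loss monitored on the RMSE
scale).

## Audio front end

A recording is resampled to 16 kHz on load and rendered as one image per
file: a log-Mel spectrogram with 224 Mel bands, hop 1024 samples and a
Hanning window, plus its delta and delta-delta along time, each channel
resized to 224 × 224 with bilinear interpolation. Parameters that the
architecture fixes are the band count, hop, window and output size; the
remaining numerical choices are the package's own and configurable:

* **FFT size 2048** — at least twice the hop, standard for this band count.
* **dB reference and floor** — power relative to the per-recording maximum,
  floored at −80 dB. This makes silence well defined: an all-zero recording
  maps to a constant −80 dB image.
* **Delta window 9 frames** — the common local-regression default; inputs
  with fewer frames than the window are rejected with an explicit error.
* **Normalization** — per-channel min–max to [0, 1] followed by
  (mean 0.5, sd 0.5), the convention of ViT-style feature extractors; both
  recorded in the `SpectrogramImage` object and disablable.
* **One image per recording** — the full spectrogram is resized, never
  chunked, so arbitrary durations give the fixed 3 × 224 × 224 shape.

The 88-dimensional acoustic vector summarises each recording with 22
frame-level descriptors (F0 in semitones above 27.5 Hz via FFT-based
autocorrelation, voicing probability, RMS loudness, zero-crossing rate,
spectral moments/entropy/crest, rolloff, flux, slope, alpha ratio,
Hammarberg index, four band energies, harmonicity, jitter/shimmer proxies)
× 4 functionals (mean, SD, 20th/80th percentile). It honours the 88-d
contract of standardized paralinguistic feature sets and the semitone
pitch convention; it is the package's own extractor, not a reimplementation
of any specific toolkit, and the test suite pins its pitch scale with a
pure-tone oracle.

## Transcript front end

CHAT (.cha) files are parsed tier-wise. By default only the participant
tier (`*PAR`) is kept — the patient's speech is the diagnostic object — and
the investigator tier can be added via `speakers = c("PAR", "INV")`.
Inline CHAT markup (retracing scopes, `[/]`-style markers, event codes,
pause codes, time-alignment bullets) is stripped while the spoken word
forms are kept, *including repetitions*, which are clinically informative.
Token encoding wraps the concatenated utterances in `[CLS] … [SEP]`,
truncates the tail (the start of a picture description carries the setup)
and pads to exactly N tokens; the tokenizer is a deterministic
hash-vocabulary word tokenizer, so encodings are reproducible with no
external vocabulary file.

## Encoders and the desk-scale grade

The fusion layers only require the encoder contract: text → N × d,
image → T × d with a shared hidden size d and a class-token-first pooled
vector. The package ships the *tiny grade*: randomly initialised one-layer
transformer encoders (N(0, 0.02) weights, pad-key masking in the text
encoder, 16 × 16-equivalent patch grid in the image encoder), reproducible
from a seed. They are genuine random-feature extractors — informative
enough for desk-scale training — not pretrained models; at the published
scale the same code runs with d = 768, N = 512, T = 197, which the tests
exercise for the shape contract. The embeddings are stored
tokens-by-features everywhere; the co-attention operations transpose
internally, so a single orientation convention holds across modules.
Because no pretrained checkpoints are bundled, the package freezes the
encoders and trains the fusion parameters and heads; the shifting-gate
model keeps its published frozen-first / trainable-second text-encoder
split, with the second encoder initialised from the first's weights plus
its own position table.

All trainable computation runs on a small reverse-mode autodiff tape
implemented in the package (dense matrices; matmul, softmax, layer norm,
sigmoid/tanh/ReLU, dropout, row selection, norms, capping). The tape is
verified against central finite differences, and every fusion equation
block is additionally verified against explicit-loop oracles.

## Fusion-layer choices where the design was open

* **Pad tokens in attention.** Inside the *encoders*, pad keys are masked.
  Inside the *fusion layers* the published equations attend over the full
  sequence, so the package default is no pad masking there (faithful), with
  the encoder-level masking guaranteeing pad rows carry no content.
* **Gate dimensionality (shifting gate).** The element-wise product in the
  shift equation forces gate length d; gates are length-d vectors.
* **α guard.** The norm ratio divides by ‖h_m‖₂ + ε with ε = 1e-9 and is
  capped at 1, so a zero shift gives α = 1 and e_m = e exactly, with no
  gradient blow-up at the cap.
* **Shift bias.** `b_m` is a single shared d-vector broadcast over tokens;
  a per-position bias would be tied to token position, which is
  meaningless for variable content.
* **Order of operations after the shift.** Layer normalization, then
  dropout (rate 0.4), then the second encoder, whose class-token output
  passes dropout 0.2 and the 128-unit ReLU head.
* **Gated self-attention scale.** Attention logits are divided by √d (the
  standard scaled dot product); softmax is row-wise over keys — the only
  convention under which `H = A_g V` is an attention average. The gate's
  two mask channels are tiled across the d feature columns and applied to
  queries and keys.
* **Per-sample semantics.** The equations are per recording; batching is an
  outer loop with shared parameters.

## Training protocol

Defaults follow the published recipe: Adam at 1e-5, reduce-on-plateau
(×0.1 after 3 non-improving validation epochs), early stopping after 6,
best-validation checkpointing, a stratified 65/35 split (half-up rounding
on the train side; stratification keeps both groups represented in small
validation sets), 5 repetitions sharing one split with different
initialisation seeds, and mean ± *population* SD aggregation. Subjects
without an MMSE score are dropped for regression only. Classification
predicts by argmax over the two logits; no threshold tuning.

For desk-scale runs with the tiny encoders the package's tests use
lr = 1e-2 and batch size 8 — the conventional Adam scale for freshly
initialised small networks (1e-5 is a fine-tuning rate for large
pretrained stacks) — and the regression output bias starts at 15, the MMSE
midpoint, so the ReLU output unit is born live mid-range. The learning
*capacity* checks disable the validation-keyed scheduler and stopper (they
measure training-set fit over a fixed 50-epoch budget; with random
features the validation loss rises almost immediately, which would
otherwise halt training by design); the scheduler and stopper behaviours
are tested separately through their exact state machines.

## The synthetic corpus generator

`generateCorpus()` emulates the *structure* of a balanced dementia speech
corpus — one 16 kHz WAV and one CHAT transcript per subject, balanced
AD/HC groups, MMSE 25–30 for controls and below 25 for patients, falling
with a per-subject severity — with a controllable signal: severity scales
the audio pause probability and syllable duration, and the transcript's
pause codes, retracing repetitions and vocabulary shrinkage, through three
dials (`pauseRateDelta`, `speechRateDelta`, `vocabularyShrink`). Setting
all three dials to zero removes every feature–group dependence while
keeping the label structure, which is how the chance-level check is built.
The audio is a harmonic syllable stream with silences, not synthetic
speech; transcripts are templated picture descriptions. Passing tests on
this corpus demonstrates that the architectures, gradients and protocol
work end-to-end — it says nothing about clinical performance on real
speech, which requires the restricted corpus and pretrained encoders.

Desk-scale problem sizes used by the tests and the acceptance script:
encoders d = 32, N = 64, T = 17; 24 subjects (65/35 split) for the
learning checks, 50-epoch budget; five 116-subject null corpora pooling
≥ 200 validation predictions for the exact binomial chance test at
α = 0.01.

## Known limitations

* The tiny grade cannot reproduce published clinical accuracy; it verifies
  mechanics, not medicine. Full replication needs the restricted corpus
  and pretrained encoder checkpoints.
* One limitation is quantified and deliberate: with the published dropout
  rates (0.4 on the shifted sequence, 0.2 on the class vector), the
  shifting-gate model's MMSE regression cannot reach the desk-scale target
  RMSE at d = 32 — dropout noise through a 32-dimensional class-token
  bottleneck is ~5× larger relative to signal than at d = 768. The
  information is demonstrably present (a ridge fit on the same frozen
  features reaches RMSE < 0.1, and disabling dropout reaches the target);
  the package keeps the architecture faithful rather than weakening the
  regularisation, and the corresponding acceptance check documents the
  failure honestly.
* The CHAT parser covers the constructs the generator and common corpora
  use (headers, main tiers with continuations, dependent tiers, retracing,
  events, pauses, shortenings); it is not a full CHAT grammar.
* The acoustic extractor follows the 88-functional convention but is not
  feature-for-feature identical to any published toolkit; models trained
  on its features are not transferable to features from other extractors.
* Single-head, single-layer fusion exactly as published; no multi-head or
  stacked extensions.
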