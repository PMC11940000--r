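---
title: "Predicting cylindrical grasps from surface EMG and task context: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting cylindrical grasps from surface EMG and task context: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

During a reach-to-grasp movement the hand preshapes before object contact:
finger flexor and extensor activity in the forearm already reflects the grasp
about to be performed. **emgrasp** implements a complete pipeline for
predicting whether the upcoming grasp is *cylindrical* (the whole-hand power
grasp, the most frequent grasp in activities of daily living) from two
complementary sources recorded during the reaching phase only:

* **surface EMG** — 7 forearm channels, reduced to a smooth, per-subject
  normalized amplitude envelope; and
* **task/product context** — the grasped cross-section widths (`SPAN_1`,
  `SPAN_2`, mm), the product weight (g) and the categorical task height
  (high–median / median / median–low).

Three small neural architectures are compared: a 1-D convolutional network on
the EMG envelope alone (`M_EMG`), a fully connected network on the encoded
context alone (`M_CONTEXT`), and a late-fusion hybrid (`M_HYBRID`) that
concatenates the two 32-dimensional branch embeddings before a joint
classification head. A systematic ablation removes context variables one at a
time from the hybrid model.

## Signal conditioning

The conditioning chain (`preprocess()`) is, in order: a 25–500 Hz band-pass
(order-4 Butterworth), full-wave rectification, an 8 Hz low-pass (order-4
Butterworth), Gaussian smoothing, and per-subject MVC normalization.

Design choices where the procedure leaves latitude:

* **Filter family** — Butterworth (maximally flat pass-band), the convention
  in the surface-EMG envelope literature. "Fourth order" is the design order
  passed to the filter designer (the band-pass therefore has 8 poles).
* **Causality** — filters are applied zero-phase (forward–backward,
  `zero_phase = TRUE` by default): the analysis is offline and a lagged
  envelope would misalign the reach window. A symmetric test burst's envelope
  peak stays within ±2 frames of its true position (asserted in the tests).
* **Gaussian kernel** — sd 0.05 s (configurable), truncated at ±4σ,
  renormalized to unit sum, reflection padding at the edges. At 1000 Hz this
  is a 401-tap kernel; it removes the residual ripple the 8 Hz low-pass
  leaves on the rectified signal.
* **Nyquist cap** — at the synthetic default of 1000 Hz the 500 Hz band edge
  sits exactly at Nyquist; the design edge is capped at 0.99 × Nyquist
  (495 Hz) and a warning is emitted once per curation run.
* **MVC normalization** — each channel is divided by the subject's maximum
  conditioned amplitude over their maximum-voluntary-contraction movements
  *and all their recorded activity* (`compute_mvc_profile()`). MVC signals
  pass through the same conditioning chain, so numerator and denominator are
  commensurate; maxima are per channel (each electrode site has its own
  physiological ceiling). With an in-sample profile the normalized envelope
  is bounded by 1. The synthetic generator also stores raw-scale MVC maxima
  on the bundle; the pipeline recomputes profiles on the conditioned scale.

## Curation

`curate_bundle()` applies, in order: leading-null trimming (all-channel zero
prefixes from recording-synchronization lag; fully null recordings are
rejected), the reaching-only filter (`ACTION_DH == 1`), removal of "free"
grasps (`GRASP_DH == 9`), a minimum trimmed length of 700 frames, the
conditioning chain, and standardization to exactly 1000 frames — recordings
longer than 1000 frames keep their *last* 1000 frames (the segment nearest
object contact), shorter ones are left-padded with zeros. Retained frames are
never altered (bit-exact suffix equality is asserted in the tests). The
700-frame cutoff is a configuration value; `length_cdf()` exposes the
retention-versus-threshold curve so a user can re-derive a cutoff for other
data. Every input recording ends up exactly once in either the retained set
or a rejection log with reasons
(`all_null`, `non_reaching`, `free_grasp`, `too_short`).

Labels are binarized (`GRASP_DH == 1` → 1, codes 2–8 → 0). Continuous context
variables are min–max scaled **on training subjects only** (fitting the
scaler globally would leak across the subject-wise split); transformed values
outside the training range are extended affinely, not clipped. Task height is
one-hot encoded into three binaries; the encoded order is
`[WEIGHT, SPAN_1, SPAN_2, TH_1, TH_2, TH_3]`.

The subject-wise split ranks subjects by retained-recording count: the 10
with the fewest recordings form the test set, the next 4 the validation set,
the remaining 16 the training set. Ties are broken by ascending subject id
(a deterministic rule the procedure otherwise leaves open). No subject
contributes to more than one split, so no identity leakage is possible.

## Architectures and parameter accounting

All layers use ReLU except the 2-unit softmax outputs. Declarative layer
specs (`build_model()`) carry closed-form trainable-parameter counts
(conv1d: `in_ch·k·filters + filters`; dense: `in·out + out`), and the test
suite asserts they equal the instantiated networks' own counts.

* **EMG branch**: input 1000 × 7 → Conv1D(16 filters, kernel 5, valid) →
  MaxPool(4) → Conv1D(32, kernel 5) → global average pooling → 32-dim
  embedding. The two conv layers contribute exactly 576 and 2,592
  parameters. Global average pooling (rather than flattening) keeps the
  parameter count independent of the input length; flattening would multiply
  the head size by two orders of magnitude.
* **Context branch**: Dense(d → 192) → Dense(192 → 32). The width 192 is
  pinned by the ablation arithmetic: removing one scalar context input must
  change the total count by exactly 192.
* **Heads**: `M_EMG` appends Dense(32→160) → Dense(160→16) → softmax(2);
  `M_CONTEXT` maps its 32-dim embedding straight to softmax(2); `M_HYBRID`
  concatenates both embeddings (64) → Dense(64→160) → Dense(160→16) →
  softmax(2), for 23,698 trainable parameters at the full 6-dim context
  input.

Ablation variants (`MH_NO_SPAN1`, `MH_NO_SPAN2`, `MH_NO_WEIGHT`: d = 5;
`MH_NO_SPAN`: d = 4; `MH_NO_THEIGHT`: d = 3) exclude variables *at the
encoding step* — never by zero-masking — so the first context dense layer
genuinely shrinks: deltas of 192, 192, 192, 384 and 576 parameters
(0.8%, 0.8%, 0.8%, 1.6% and 2.4% of the full model, to one decimal).

## Training

The training engine is implemented in the package (vectorized R over
BLAS matrix products, with the convolution/pooling kernels in C++): Adam
(β₁ = 0.9, β₂ = 0.999, ε = 10⁻⁷), binary cross-entropy over the 2-class
softmax against one-hot targets, 300 epochs and batch size 68 by default,
and a cosine-decayed learning rate

lr(e) = lr₀ · (α + (1 − α) · ½(1 + cos(π e / E))),  lr₀ = 0.001, α = 0.01,

the standard α-floored cosine form, decaying from 0.001 at epoch 0 to 10⁻⁵
at the decay horizon E = total epochs. Weights are Glorot-uniform with zero
biases, drawn in the fixed order EMG branch → context branch → head so that
hybrid variants sharing a seed share EMG-branch initial weights exactly. One
seed controls initialization and batch shuffling; the synthetic generator has
its own. The returned model is the checkpoint with the **best validation
accuracy** (ties to the earliest epoch), not the final epoch; reported
metrics always come from that checkpoint. No early stopping and no extra
regularization are applied. Metrics (accuracy, precision, recall, with the
cylindrical class positive) derive from the confusion matrix (rows = true,
columns = predicted, class order [0, 1]); a 0/0 precision or recall is
reported as 0 with a `degenerate` flag.

## The synthetic-data generator

`generate_dataset()` emulates the structure of the source regime — 30
subjects, ~150 recordings each (~4,500 total), recording lengths log-normal
within 41–6,337 frames, 42% cylindrical prevalence — so that every
downstream stage is exercised without the original recordings. The length
distribution (meanlog 7.2613, sdlog 0.5) is chosen so that ≈7.8% of clean
recordings fall below the 700-frame cutoff, the rejection rate the curation
rule was designed around.

Context is drawn class-conditionally: cylindrical objects have
`SPAN_1 ~ N(65, 15)` mm while non-cylindrical ones follow a
small-object-dominated mixture `0.78·N(24, 10) + 0.22·N(52, 15)` (pinch-type
grasps act on narrow cross-sections, but the ranges overlap visibly);
`SPAN_2` is 0 for 80% of products regardless of class; weights are truncated
exponentials (means 400 g / 300 g, cap 3 kg — sub-kilogram masses dominate
both classes); task heights 2–3 are over-represented in the non-cylindrical
class. The mixture parameters were set so that the context modality's exact
Bayes accuracy at full context strength is 0.87 — the accuracy the
context-only model reaches in the emulated regime — computed from the true
generative posterior, not from any trained network.

EMG channels are band-limited (25–500 Hz) noise carriers shaped by a
monotonically rising reach envelope over the final 500 frames, with
per-subject and per-trial log-normal gains. For cylindrical recordings the
envelope on channels 1–3 (finger-flexor stand-ins) is scaled by

1 + emg_strength · ((1.5)·(1 + 0.004·SPAN_1)·(1 + 0.0003·WEIGHT) − 1),

tying EMG amplitude to grasp preshaping and expected load. The
interpolation form makes `emg_strength = 0` give *exactly* class-independent
EMG (the naive product form would leak span information through the
multiplier even at zero strength). Likewise `context_strength` is a mixture
weight — a cylindrical recording draws its context from the cylindrical
families with that probability, else from the non-cylindrical ones — so 0
gives exactly class-independent context. Artifacts (leading zero-runs, fully
null recordings, free grasps, non-reaching actions) are injected at
configurable rates to exercise every curation filter.

Named presets (`make_fixture()`): `tiny` (3 subjects, 12 recordings),
`default` (the full emulated scale), `separable_context` (EMG uninformative),
`separable_emg` (context uninformative), and `complementary`, in which both
modalities are deliberately weakened (`context_strength = 0.7`,
`emg_strength = 0.2`, ~1,000 recordings surviving curation) so each
unimodal model is limited and the fused model clearly beats both. The
strengths were calibrated with d′-arithmetic on the modality-level oracles
(targeting unimodal accuracies near 0.75 and a fused accuracy near 0.80);
calibration needed care because the span-dependent EMG boost couples the two
dials — raising context strength also strengthens EMG through the larger
cylindrical spans — and because the two evidence channels are partially
redundant for exactly that reason, which limits the fused model's gain.

**What passing on synthetic data does and does not show.** The generator
reproduces the *structure* the analysis assumes — class-conditional context,
amplitude-coded EMG evidence, subject variability, curation artifacts — but
not real electrophysiology: no electrode placement or shift, no motion
artifacts or power-line interference, no non-stationary muscle dynamics, and
an EMG class signal that is purely an amplitude modulation on known channels.
Passing the pipeline's acceptance checks therefore validates the *method and
its implementation* (filters, curation rules, parameter accounting, training
and fusion machinery), not the clinical-scale accuracy figures, which depend
on the original recordings.

## Study drivers and problem sizes

`run_comparison()` trains the three models on byte-identical curated tensors
and split assignments (a paired design, asserted by fingerprinting the
split); `run_ablation()` adds the five exclusion variants with full parameter
accounting; `render_reports()` writes the CSV/text tables and the parameter
ledger. The drivers default to 3 seeds with median reporting — a single run
per model would leave orderings at the mercy of initialization noise on
synthetic data.

The shipped verification runs use the `complementary` fixture (~1,000 curated
recordings) at 60 epochs and 3 seeds, and the `separable_context` fixture at
60 epochs — sizes chosen so the full qualitative reproduction completes in a
few minutes on one CPU while the orderings it checks are stable across
seeds. The 300-epoch default of `train_config()` matches the study setup and
is what a user would run on real data.

## Numerical notes and limitations

* Determinism: given fixed seeds, generation is bit-exact and training is
  reproducible to floating-point noise (asserted at 10⁻⁶). The conv/pool
  kernels are C++ with a fixed summation order and are cross-checked against
  plain-R reference implementations; gradients are verified against numeric
  differentiation.
* Degenerate inputs: all-zero channels make MVC normalization undefined and
  raise an error naming the channel; constant context variables scale to 0
  with a warning; max-pool ties resolve to the earliest frame; argmax ties at
  equal softmax probabilities resolve to class 0.
* The binary task uses a 2-unit softmax (not a 1-unit sigmoid) under binary
  cross-entropy, matching the stated output design.
* Out of scope: kinematic data, multi-class grasp taxonomies, k-fold or
  stratified splitting, hyperparameter search, GPU execution, and real-time
  deployment.
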