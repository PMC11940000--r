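# emgrasp

Predicting **cylindrical grasps** during reach-to-grasp movements from
7-channel forearm surface EMG and task/product context.

When a hand reaches for an object it preshapes: forearm flexor/extensor
activity and the task's physical context (object cross-section width, weight,
working height) already carry information about the grasp that is about to
happen. That signal matters for prosthetic hands, exoskeletons and
human–machine interfaces, which need the grasp decision *before* contact.
`emgrasp` implements the full analysis pipeline as a tested R package:

* **Signal conditioning** — order-4 Butterworth band-pass (25–500 Hz),
  full-wave rectification, order-4 low-pass (8 Hz), Gaussian smoothing
  (σ = 0.05 s), and per-subject **MVC normalization** (each channel divided
  by the subject's maximum conditioned amplitude over MVC movements and all
  recorded activity), applied zero-phase.
* **Curation** — leading-null trimming, reaching-only selection, removal of
  "free" grasps, a 700-frame minimum length, standardization to 1000 frames
  (last-1000 truncation / leading-zero padding), binary labels
  (cylindrical vs. rest), min–max context scaling fitted on training
  subjects only, one-hot task height, and a **subject-wise split** (the 10
  subjects with fewest recordings → test, next 4 → validation, 16 → train).
* **Models** — three architectures with exact trainable-parameter
  accounting:
  * `M_EMG`: Conv1D(16, k=5) → MaxPool(4) → Conv1D(32, k=5) → global average
    pool → Dense(160) → Dense(16) → softmax(2);
  * `M_CONTEXT`: Dense(d→192) → Dense(192→32) → softmax(2);
  * `M_HYBRID`: both branches, embeddings concatenated (late fusion) →
    Dense(64→160) → Dense(160→16) → softmax(2) — 23,698 parameters at the
    full 6-dimensional context input.
* **Training** — a self-contained engine (Adam, binary cross-entropy over
  the 2-class softmax, cosine-decayed learning rate
  `lr(e) = lr₀·(α + (1−α)·½(1+cos(πe/E)))` with lr₀ = 0.001, α = 0.01,
  batch 68, best-validation-accuracy checkpointing). Convolution and pooling
  kernels are compiled C++, cross-checked against plain-R references and
  numeric gradients.
* **Experiments** — the unimodal-vs-multimodal comparison and the
  context-variable ablation (`MH_NO_SPAN1`, `MH_NO_SPAN2`, `MH_NO_SPAN`,
  `MH_NO_WEIGHT`, `MH_NO_THEIGHT`), with a parameter ledger: removing one
  scalar context input removes exactly **192** parameters (0.8%), both spans
  **384** (1.6%), the three-category task height **576** (2.4%).
* **Synthetic data** — a seeded generator emulating the source regime
  (30 subjects, ~4,500 recordings of 41–6,337 frames, 42% cylindrical
  prevalence, class-conditional context, artifact injection) so the entire
  pipeline is testable without the original recordings. See the methods
  vignette (`vignettes/grasp-prediction-methods.Rmd`) for the generative
  model and its limits.

## Worked example

Generate a synthetic dataset in which both modalities are deliberately weak
but complementary, curate it, and run the three-model comparison (60 epochs,
3 seeds — a scaled-down verification run; the study configuration is
`train_config()`'s 300-epoch default):

```r
library(emgrasp)

bundle  <- make_fixture("complementary")       # 1,430 recordings, 30 subjects
curated <- curate_bundle(bundle)               # conditioning + curation
curated
#> <curated_set> 1031 samples retained, 399 rejected (all_null=15,
#>   free_grasp=100, non_reaching=210, too_short=74)

cmp <- run_comparison(curated, train_config(epochs = 60), seeds = 1:3)
cmp$summary[cmp$summary$split == "test", ]
#>       model split      loss  accuracy precision    recall
#> 1 M_CONTEXT  test 0.5160526 0.7482014 0.7087379 0.6491228
#> 2     M_EMG  test 0.4890328 0.7589928 0.6793893 0.7807018
#> 3  M_HYBRID  test 0.4213031 0.8021583 0.7322835 0.8157895
```

Accuracy/precision/recall take the cylindrical class as positive; each row is
the median over the three seeds, evaluated at each run's
best-validation-accuracy checkpoint on the held-out test subjects. Late
fusion (`M_HYBRID`) beats both unimodal models — here by ~4 and ~5 accuracy
points — the central qualitative finding the pipeline reproduces. The
ablation study and parameter ledger come from `run_ablation()` +
`render_reports()`.

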