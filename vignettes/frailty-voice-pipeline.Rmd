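---
title: "Classifying frailty from voice: models, synthetic cohorts and the evaluation protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying frailty from voice: models, synthetic cohorts and the evaluation protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Frailty is a geriatric syndrome of reduced physiological reserve. The
standard screening instruments (phenotype criteria, frailty indices,
questionnaires such as K-FRAIL) require in-person assessment. Speech is an
attractive non-invasive alternative: frail speakers tend to pause more,
speak more slowly, and show rougher, flatter voicing. `frailvoice`
implements a complete pipeline for studying whether frailty status — robust
(K-FRAIL score 0) versus prefrail-or-frail (score ≥ 1, the positive class)
— can be classified from free-speech recordings, and for comparing
speech-based, demographics-based and combined classifiers under a rigorous
cross-validation protocol.

Because clinical speech corpora are rarely shareable, the package ships a
first-class synthetic cohort generator: every experiment in the test suite
and the acceptance script runs end-to-end from seeded synthetic data.

## The synthetic cohort generator

`generate_cohort()` draws participants with:

* a binary outcome at configurable prevalence (default ≈ 51% positive,
  matching a 65/62 split at n = 127);
* class-conditional ages from truncated normals on [50, 95] — robust mean
  64.9 (SD 9.26), positive mean 73.4 (SD 10.84). The underlying normal
  location is adjusted so the *truncated* mean equals the configured mean;
  naive truncation would bias the realized class means by about a year;
* class-conditional sex (female fraction 0.274 robust, 0.40 positive);
* K-FRAIL item patterns consistent with the drawn category. The
  prefrail/frail split within the positive class is not identifiable from
  aggregate tables, so it defaults to 70% prefrail (configurable).

`synthesize_speech()` produces the audio by source–filter synthesis: a
glottal pulse train at a sex-dependent F0 (female 210 Hz, male 120 Hz) with
jitter and shimmer perturbations, filtered through a cascade of unity-DC
formant resonators (500/1500/2500 Hz), and organized into voiced bursts
separated by silent pauses. Severity scales linearly with the K-FRAIL score
between two parameter endpoints: from score 0 (pause fraction 0.15, 2.8
bursts/s, jitter 0.006, shimmer 0.04, F0 spread 12 Hz) to score 5 (pause
fraction 0.45, 1.6 bursts/s, jitter 0.030, shimmer 0.14, F0 spread 4 Hz).

Two realism decisions matter for interpreting results:

* **Between-speaker variability.** Each participant receives seeded
  idiosyncratic offsets (habitual pitch SD 15 Hz, pause-fraction SD 0.06,
  log-normal rate and roughness factors with SD 0.15/0.25). Without these,
  severity maps deterministically to acoustics and every classifier is
  perfect; with them, class distributions overlap the way real cohorts do,
  and cross-validated AUCs land in a clinically plausible range rather than
  at 1.0.
* **What is *not* emulated.** No language, phonetics, room acoustics or
  background noise; no correlation between acoustics and age beyond what
  severity induces. Passing tests on this generator demonstrate that the
  pipeline recovers a planted acoustic signal — not that the models would
  reach any particular performance on real recordings.

Default clips are 10 s at 48 kHz; the desk-scale `fast` profile uses 3 s at
16 kHz. `write_cohort()`/`read_cohort()` round-trip the cohort through mono
16-bit PCM WAV files plus a manifest CSV.

## Acoustic features

`extract_mfcc_features()` computes the classic 60-dimensional MFCC front
end: 25 ms Hann windows with a 10 ms hop at a 16 kHz analysis rate, a
64-band triangular mel filterbank (20 Hz–Nyquist), log compression with a
1e-10 floor, an orthonormal DCT-II, and the first 20 cepstral coefficients
— coefficient 0 (the log-energy-like term) is kept as one of the 20. First-
and second-order regression deltas over a 9-frame window (edge frames
replicated) are appended; the delta width changes values, so it is part of
`feature_config()`. Framing parameters are standard speech practice; they
are configuration, not claims.

`extract_functionals()` produces the fixed-length 126-vector used by the
classical baselines: mean and SD of each of the 60 columns plus six
prosodic functionals (F0 mean/SD over voiced frames via an autocorrelation
tracker restricted to 60–400 Hz, voiced fraction, RMS loudness mean/SD,
and pause fraction from an adaptive RMS threshold at 10% of the
95th-percentile frame RMS). A fully silent clip yields pause fraction 1,
voiced fraction 0, F0 statistics 0, and a `silent` flag.

## The three model assemblies

* **SpeechAI** — transformer speech encoder + classifier. The encoder
  projects 60-dim frames to the model width, adds sinusoidal positions and
  applies post-norm multi-head self-attention blocks; clips longer than
  `chunk_frames` (default 1,000) are split into non-overlapping chunks
  whose mean-pooled embeddings are averaged, which makes the pooled
  representation invariant to chunk order.
* **DemoAI** — demographic embedding + classifier: age is binned by decade
  (50s…90s) into a 2-dimensional lookup table, sex into a 4-dimensional
  one, concatenated to a 6-vector. A 4-dim embedding for a binary variable
  is unusual; it is retained as printed in the architecture this package
  emulates, with the 2D table assigned to age and the 4D table to sex.
* **DemoSpeechAI** — both embeddings concatenated before the classifier.

Each classifier has exactly one hidden layer and two output logits mapped
through a softmax. The conformance hidden widths (373 / 2,889 / 466) were
back-solved from the published classifier budgets (≈25K / ≈26K / ≈34K
parameters) given input widths 64 / 6 / 70; the very wide DemoAI hidden
layer (2,889 units over a 6-dim input) is honored but is an architectural
oddity, not a recommendation. With the conformance encoder (64-dim model,
4 heads, feed-forward 256, 12 layers) the totals are 628,705 / 26,021 /
637,750 parameters with 96% of SpeechAI in the encoder —
`count_parameters()` reports exact integers. Exact third-party counts
(e.g. 587,520) depend on unpublished architectural details and are treated
as conformance brackets, not equality targets.

## Training

**Self-supervised pretraining** (`pretrain_speech_embedding()`): the
canonical masked-frame objective. 15% of frames are replaced by a learned
mask vector; a linear head (discarded afterwards) reconstructs the original
frames under MSE; all encoder parameters train with Adam (1e-3, batch 16).
Per-feature standardization statistics are estimated from the pretraining
corpus and stored with the encoder, since raw cepstral columns differ in
scale by two orders of magnitude. The unlabeled corpus is synthesized at a
severity-neutral midpoint with random sex per clip, so it carries no label
structure. A mask fraction of 0 is rejected as degenerate.

**Fine-tuning** (`finetune()`): the encoder is frozen — bit-identical
before and after, asserted internally — and only the classifier and
demographic tables train (≈4–5% of a speech-bearing model's parameters).
Training folds are balanced by majority-class undersampling, then split
80/20 stratified into an inner training and early-stopping monitor set
(patience 10, max 200 epochs, best-epoch weights restored). Using an inner
monitor split is deliberately stricter than monitoring on the CV validation
fold, which would leak the fold into the stopping decision. Because the
backbone is frozen, speech embeddings are computed once up front; this is
numerically identical to running the full forward pass every step and is
verified by a test.

Optimizer settings (Adam 1e-3, batch 16) and the early-stopping
hyperparameters are package defaults, chosen as conventional values — the
emulated study does not report them.

## Evaluation protocol

* `make_balanced_folds()` — stratified 5-fold assignment by per-class
  shuffling and round-robin dealing with a continued pointer, guaranteeing
  fold sizes within ±1 and per-fold class counts within ±1 of ideal.
* `compute_roc_auc()` — midrank Mann–Whitney concordance (ties count ½),
  exactly the all-pairs count.
* `compute_metrics()` — confusion counts at threshold 0.5, with
  `score >= threshold` counted positive; accuracy in percent, sensitivity
  = recall on the prefrail/frail class.
* `summarize_folds()` — mean, sample SD, and a 95% CI using the normal
  half-width `1.96·SD/√k`. The normal approximation (not a t quantile) is
  the convention of the performance tables this layer reproduces; with
  k = 5 a t quantile would widen CIs by ~42%.
* `paired_auc_ttest()` — two-sided paired t-test on per-fold AUC
  differences, df = k−1; all-zero differences give t = 0, p = 1; zero SD
  with nonzero mean is flagged degenerate with p = 0.
* `evaluate_imbalanced()` — rebuilds validation sets at a 20% positive
  prevalence (all robust kept, positives subsampled to the nearest
  attainable count, flagged when not exact) and averages metrics over 20
  seeded resamples, since a single subsample is high-variance.
* `train_baseline()` — ridge logistic regression (glmnet, alpha 0,
  lambda 1/n, fold-standardized features), depth-5 decision tree (rpart)
  and 100-tree random forest on the functional vectors, under the same
  folds, balancing and metrics.

No multiple-testing correction is applied across the three pairwise model
comparisons, matching the emulated analysis; DeLong-style AUC tests are out
of scope by design.

## Reproducibility and problem sizes

Every random draw derives from a single master seed via `derive_seed()`;
rerunning `run_pipeline()` with the same configuration produces
byte-identical metrics JSON. The `fast` profile (2-layer, 32-dim encoder,
3 s clips, n = 200, 60-clip pretraining corpus) is the package's
desk-scale default and completes in about a minute on one core; the
`conformance` profile carries the full-size encoder used for parameter
accounting. Both share all code paths, and the reduced profile preserves
every shape and probability contract.

On the default synthetic conditions the fast profile typically yields
cross-validated mean AUCs around 0.85–0.90 for SpeechAI, 0.6–0.7 for
DemoAI and ≥ SpeechAI for the combined model — the same ordering regime as
real vocal-biomarker frailty studies. One caveat the synthetic data makes
visible: because the planted signal is low-dimensional prosody, classical
baselines on functional features are far more competitive here than such
baselines tend to be on real speech, where deep features capture structure
functionals miss.

## Known limitations

* The waveform generator is a stylized source–filter model; results on it
  bound nothing about real picture-description-task recordings.
* The SSL objective improves or matches a random frozen backbone on this
  generator's data but is evaluated under non-inferiority, not superiority:
  with a linear-recoverable planted signal, random projections of pooled
  frame statistics are already informative.
* F0 tracking is a plain autocorrelation peak-picker without octave-error
  correction; adequate for synthetic voices, not production pitch tracking.
* Voice-activity detection is RMS thresholding only.
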