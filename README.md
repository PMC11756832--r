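# frailvoice

Frailty — the geriatric syndrome of reduced physiological reserve — is
usually screened with in-person instruments such as the 5-item K-FRAIL
questionnaire (score 0 = robust, 1–2 = prefrail, ≥ 3 = frail). `frailvoice`
is an R package for studying a non-invasive alternative: classifying
robust versus prefrail-or-frail status from free-speech recordings. It is
aimed at digital-health and biostatistics researchers who want a complete,
reproducible, testable version of this analysis — from raw audio to paired
model comparisons — without access to a clinical speech corpus.

## What it implements

**Synthetic cohorts.** A seeded generator draws demographics
(class-conditional truncated-normal ages, class-conditional sex), K-FRAIL
item patterns, and speech audio via source–filter synthesis (glottal pulse
train with jitter/shimmer through formant resonators, voiced bursts
separated by pauses). Acoustic severity scales with the K-FRAIL score;
seeded between-speaker variability keeps classes realistically overlapped.

**Acoustic features.** Frame matrices `X ∈ R^{T×60}`: 20 MFCCs `c_t`
(25 ms Hann windows, 10 ms hop, 64 mel bands, orthonormal DCT-II) plus
first- and second-order regression deltas

    Δc_t = Σ_{k=1..4} k (c_{t+k} − c_{t−k}) / (2 Σ k²),

and 126-dimensional per-clip functional vectors (means/SDs plus F0,
loudness and pause statistics) for classical baselines.

**Models.** Three assemblies: `SpeechAI` (transformer encoder → mean-pooled
embedding → one-hidden-layer softmax classifier), `DemoAI`
(decade-binned age → 2-D and sex → 4-D embedding tables → classifier) and
`DemoSpeechAI` (concatenated embeddings → classifier). The conformance
build carries ~629K / 26K / 638K trainable parameters with 96% of the
speech model in the encoder; `count_parameters()` reports exact counts.
The transformer, Adam optimizer and full backpropagation are implemented
in base R and verified against finite differences.

**Training.** Masked-frame self-supervised pretraining of the encoder on
an unlabeled synthetic corpus (15% of frames replaced by a learned mask
vector, MSE reconstruction), then frozen-backbone fine-tuning: only the
classifier and demographic tables (≈4–5% of parameters) are updated, with
majority-class undersampling and early stopping on an inner stratified
split.

**Evaluation.** Stratified balanced 5-fold cross-validation; accuracy,
Mann–Whitney AUC, sensitivity and specificity per fold; fold summaries
with 95% CIs (`mean ± 1.96·SD/√k`); two-sided paired fold-level t-tests on
AUC (`t = mean(d)/(SD(d)/√k)`, df = k−1); a prevalence-shifted sensitivity
analysis at 20% positives; and ridge-logistic / decision-tree /
random-forest baselines on the functional features.

## Worked example

```r
library(frailvoice)
cfg <- run_config(profile = "fast", n = 120, outdir = "frail_run", seed = 42)
run_pipeline(cfg)   # simulate -> features -> pretrain -> train -> evaluate
run_report("frail_run")
```

which prints (abridged):

```
Cross-validated models (accuracy in %, others fractions)
  SpeechAI
    accuracy      80.00 ( 73.47- 86.53)  min  70.83  max  87.50
    auc            0.87 (  0.83-  0.90)  min   0.81  max   0.92
  DemoAI
    accuracy      60.83 ( 56.67- 65.00)  min  54.17  max  66.67
    auc            0.66 (  0.62-  0.69)  min   0.62  max   0.70
  DemoSpeechAI
    accuracy      84.17 ( 81.11- 87.22)  min  79.17  max  87.50
    auc            0.92 (  0.88-  0.96)  min   0.86  max   0.97

Paired fold-level AUC comparisons
  SpeechAI_vs_DemoAI         t(4) =  6.548, p = 0.002813
  DemoSpeechAI_vs_DemoAI     t(4) =  7.254, p = 0.001918
  SpeechAI_vs_DemoSpeechAI   t(4) = -2.954, p = 0.04179

Prevalence-shifted evaluation (20% positives, 20 repeats)
  accuracy 82.87%, AUC 0.84, sensitivity 0.74, specificity 0.85
```

Reading: on this synthetic cohort the speech-only model (mean AUC 0.87)
clearly beats the demographics-only model (0.66; paired t-test p = 0.003),
combining both helps slightly (0.92), and performance holds up when the
validation prevalence is shifted to a realistic 20%. The run directory
contains the audio, manifest, feature container, encoder checkpoints,
`metrics.json`, per-fold CSVs and ROC curves; rerunning with the same seed
reproduces `metrics.json` byte for byte.

A thin command-line wrapper over the same functions is installed at
`inst/cli/frailvoice.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/frailvoice.R", package="frailvoice"))')" \
    run --profile fast --n 120 --seed 42 --outdir frail_run
```

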