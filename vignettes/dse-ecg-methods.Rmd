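---
title: "Two-dimensional ECG classification with a detached-SE residual network: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-dimensional ECG classification: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the representation

Twelve-lead electrocardiograms record the heart's electrical activity from
twelve viewpoints simultaneously.  Many arrhythmias — atrial fibrillation
(AF), conduction blocks (I-AVB, LBBB, RBBB), premature beats (PAC, PVC) and
ST-segment changes (STD, STE) — express themselves differently across
leads, so a classifier that models each lead in isolation discards
diagnostic structure.  `dseresnet` implements a pipeline that treats the
12-lead record as a single two-dimensional object: the leads
$a \in \mathbb{R}^{L \times 1}$ are spliced as columns of a matrix
$A \in \mathbb{R}^{L \times 12}$, like a tall grayscale image whose pixels
are voltages, and a 2-D convolutional residual network classifies it into
normal rhythm or one of eight arrhythmias.

The training criterion is softmax cross-entropy averaged over the batch,

$$\mathrm{Loss} = -\frac{1}{n}\sum_{i=1}^{n}
  \log \frac{\exp p(x_i, y_i)}{\sum_j \exp p(x_i, y_j)},$$

so a maximally uninformative predictor scores $\ln 9 \approx 2.197$ — a
useful sanity anchor that the test suite checks literally.

## Signal conditioning

Three noise sources dominate raw ECG: baseline wander (below ~0.5 Hz),
power-line interference (50 Hz here), and broadband muscle noise.  All
three are attenuated by a single band-pass filter:

* **Filter.** Butterworth, passband 0.5–49 Hz, order 3, applied
  forward–backward (`signal::filtfilt`), i.e. zero-phase, so P-QRS-T
  morphology is not skewed.  Order and phase behaviour are configurable
  (`filter_spec()`); zero-phase squares the single-pass magnitude
  response.  One consequence worth stating plainly: 50 Hz sits only 2 %
  above the 49 Hz cutoff, where a third-order Butterworth still passes
  roughly half the amplitude.  The filter's value at 50 Hz is therefore
  *verified against its own computed magnitude response*
  (`filter_gain()`) rather than against an arbitrary suppression factor;
  deep suppression is reached above ~60 Hz.
* **Diagnostics.** `welch_psd()` provides Welch spectral estimates
  (Blackman, Hanning or triangular taper; segment lengths 256–1024,
  50 % overlap) to visualize what filtering removed.  The estimator is
  density-scaled; its integral over frequency approximates the signal
  variance, which is how the tests pin it down (Parseval check).
* **Normalization.** Each record's 2-D matrix is affinely rescaled so its
  observed extrema map exactly onto the symmetric interval
  $[-3, 3]$ mV:
  $$A'_{ij} = R_{\min} +
    \frac{(R_{\max}-R_{\min})(A_{ij}-A_{\min})}{A_{\max}-A_{\min}}.$$
  $A_{\min}, A_{\max}$ are taken over the whole record, all twelve leads
  jointly — not per lead and not over the dataset — so every slice of a
  record shares one normalization map and inter-lead amplitude relations
  are preserved.  Constant records are rejected (`zero amplitude range`)
  rather than silently mapped.  The affine output is clamped to the
  target interval to keep the endpoint guarantee exact under floating
  point.

### Slicing

Records vary from ~6 s to ~60 s; the network wants a fixed 8192-sample
(16.384 s at 500 Hz) window, chosen as a power of two so repeated halving
stays integral.  For window length $S = 8192$:

1. $L < S$: one window, zero-padded at the tail.
2. $S \le L < 1.5S$: one window, tail truncated (the head is kept).
3. $L \ge 1.5S$: $n = \lfloor 2L/S \rfloor - 1$ windows with starts
   4096 samples apart — consecutive windows share exactly half their
   samples, which augments the training set with the long records.

Padding happens after normalization in the sense that padded samples are
forced to exactly 0 in the normalized domain (silence), not to the
normalized image of 0 mV.  The reference description ("filled with
zeros") is readable either way; forcing zeros keeps padded regions
identical across records regardless of each record's normalization map.
Slices inherit their record's label.

## The network

`build_dse_resnet()` constructs the classifier and returns an
`architecture_description` that tests verify structurally:

* a trunk of **10 residual blocks** (1 dimension-preserving + 9
  dimension-changing), each with **two convolutions** of kernel
  $(32, 1)$ — 20 trunk convolutions in all, with channel counts
  12-24-48-96-192, doubling every four convolutions;
* each block runs Conv → BatchNorm → ReLU → Dropout twice, then adds a
  shortcut;
* dimension-changing blocks use temporal stride 2 in their first
  convolution (nine halvings: 8192 → 16); the lead axis is never
  downsampled, and the shortcut path uses $(2, 1)$ max pooling to match;
* one **detached squeeze-and-excitation module** outside all blocks:
  global average pooling squeezes the trunk output to one scalar per
  channel, four dense layers ($C \to C/r \to C/r \to C/r \to C$, $r = 4$,
  sigmoid output) produce a channel gate that rescales the trunk output;
* the head pools over **time only**, flattens the twelve per-lead feature
  vectors, appends encoded age and sex, and applies a two-layer dense
  softmax head over the nine classes.

### Design choices the reference description leaves open

* **Downsampling schedule.** Only "multiple 0.5× downsampling" steps and
  the power-of-two input are specified.  Stride 2 in the first
  convolution of each dimension-changing block is the standard ResNet
  reading and yields 8192 → 16 over nine blocks.
* **Shortcut channel growth.** Max pooling cannot change channel count,
  yet blocks double it.  The shortcut zero-pads new channels (classic
  "option A"), adding no parameters, consistent with pooling being the
  only named shortcut operation.
* **Where leads stop being independent.** Kernels of width 1 in the lead
  axis never mix leads, so everything up to the head treats the twelve
  leads as independent series.  Had the head also averaged over leads,
  the whole network would be exactly invariant to lead permutation —
  contradicting both the motivation (inter-lead features) and the
  description of the squeeze as extracting features "for each lead".
  The head therefore pools over time only and lets the dense layers
  weight leads differently; the test suite asserts the resulting
  permutation sensitivity.
* **DSE width.** Four dense layers are specified but not their widths;
  $C \to C/4 \to C/4 \to C/4 \to C$ with a sigmoid gate is the standard
  SE bottleneck stretched to four layers.
* **Age/sex encoding.** Age enters as age/100 (missing → the training-set
  mean); sex as 0/1 (missing → 0.5).  The auxiliary inputs can be ablated
  with `use_age_sex = FALSE`.
* **Optimizer.** SGD with momentum — momentum is one of the screened
  hyper-parameters, which implies a momentum optimizer even though none
  is named.  Weights use seeded truncated-normal He initialization.

The engine itself is plain R: convolutions are one GEMM per kernel tap
against a zero-padded copy, with manual backpropagation, batch
normalization, inverted dropout and max-pool routing.  Analytic gradients
are verified against central finite differences in the test suite.

## Hyper-parameter screening

Rather than a 27-point grid over learning rate {0.05, 0.1, 0.15} ×
dropout {0.3, 0.5, 0.8} × momentum {0.5, 0.7, 0.9}, a strength-2
covering array exercises every cross-factor level pair at least once.
`generate_covering_array()` builds such designs greedily (each row starts
from an uncovered pair and fills remaining factors to maximize newly
covered pairs; ties break by factor then level order, deterministically
per seed).  The fixed 10-run table actually used for the reference
experiments ships as `reference_hparam_table()` and is *verified* (27/27
pairs) rather than regenerated, since greedy construction need not
reproduce it row for row.

## Training protocol and ensembling

For each hyper-parameter combination, `train_combination()` runs
stratified **record-level** k-fold cross-validation (all slices of a
record share a fold — overlapping windows would otherwise leak between
train and validation), trains each fold with the combination's learning
rate, dropout and momentum, and selects the fold with the lowest
validation loss averaged over the final five epochs (the averaging window
damps epoch-to-epoch noise; the reference protocol says only "lowest
average loss").  Within each fold the parameters of the best-validation
epoch are checkpointed, so no later epoch can be selected.  Divergent
folds (non-finite loss) are excluded with a diagnostic; if all folds
diverge the combination errors out.

At inference a record is preprocessed into slices, per-slice softmax
vectors are averaged, and the arg-max is the record's label.  The
ensemble applies every combination's single optimal model and takes the
plurality label ("the minority obeys the majority"); ties break by the
highest summed probability among tied labels, then lowest class index,
with a `tie_broken` flag for audit.  Majority voting does not strictly
dominate the best member, so the desk-scale check asserts
non-degradation (ensemble macro F1 within 0.05 of the best single
model), not strict improvement.

## Evaluation

`metrics_report()` computes the 9×9 confusion matrix (rows = reference),
one-vs-rest per-class
$F_{1i} = 2 F_P F_R / (F_P + F_R)$, macro $F_1$ (the unweighted mean over
the nine classes), accuracy, sensitivity and specificity
($Se_i \equiv F_R$, asserted as an identity in the tests), and four
grouped "sub-abnormal" scores — AF; Block = {I-AVB, LBBB, RBBB};
PC = {PAC, PVC}; ST = {STD, STE} — computed by **merging** the member
rows and columns of the confusion matrix and scoring the merged
super-class one-vs-rest.  Merging (rather than averaging member F1s) is
the only construction under which a single-member group like AF
reproduces that class's own F1, which is how the published tables behave.
When precision and recall are both undefined (no true positives), F1 is
0 by convention — conservative and standard.

## The synthetic generator

`synth_record()` builds each beat as a sum of five Gaussian bumps
(P, Q, R, S, T) with a fixed per-lead polarity/scale table loosely
following standard lead geometry, then adds baseline wander (0.25 Hz
sinusoid), 50 Hz line noise and white (muscle) noise at configurable
amplitudes.  Class-conditioned rules mirror what each diagnosis does to
the waveform: AF jitters RR intervals i.i.d. (cv ≈ 0.2) and removes the
P wave; I-AVB stretches PR to 240 ms; LBBB/RBBB widen the QRS beyond
120 ms (LBBB accentuated in I, V1, V2, V5, V6, aVR; RBBB with a delayed
R′ in V1–V3); PAC/PVC insert premature beats (PVC widened, high
amplitude, no P); STD/STE shift the ST segment by ∓0.1–0.3 mV.
Durations are drawn from a truncated log-normal on [6, 60] s with mean
≈ 16 s and roughly 13 % of records longer than 1.5× the 16.384 s window,
emulating the length profile of the public training corpus the pipeline
was designed around; heart rate is uniform on 50–100 bpm, age
~ N(60, 15) clipped to [18, 95], sex balanced.

What the generator does **not** emulate: realistic QRS micro-morphology,
respiration-modulated wander, electrode artifacts, atrial flutter
waves, or inter-patient morphology variance beyond the scaled template.
A model that learns these synthetic classes has demonstrably learned the
*kind* of rhythm/morphology/ST features the method targets, but passing
desk-scale tests says nothing quantitative about performance on clinical
data.

Gaussian-bump morphology (rather than a dynamical ECG model) was chosen
deliberately: every class-manipulated feature is analytically
controlled, so tests can assert measurable contracts — RR coefficient of
variation, QRS width, ST offset, P amplitude — via the simple detectors
in `ecg_features()`.

## Numerical and reproducibility choices

* All randomness is seeded and scoped (`with_seed` saves and restores the
  caller's RNG state); the same config reproduces a dataset, a fold
  split, or a training run bit for bit on one machine.
* Batch-norm uses running statistics (momentum 0.9) in eval mode;
  predictions are deterministic.
* Softmax subtracts the row maximum; cross-entropy clamps probabilities
  at $10^{-12}$, so divergence is detected as a non-finite loss rather
  than an exception mid-algebra.
* Tie-breaks (vote, covering-array construction) are total and
  documented, never RNG-dependent.

## Desk-scale problem sizes

The packaged tests and the acceptance script run the full-scale
*structure* (the 8192×12 network is built and described, never trained)
and train *reduced* configurations: 256-sample inputs (slices decimated
32×), kernel 8, channels 4–8, two folds, tens of records.  These sizes
were chosen as the smallest at which every contract under test —
learnability, fold selection, ensembling, reproducibility — is
meaningfully exercised.  A full-scale training run uses exactly the same
code path with the default `model_config()` and `train_config()`.

## Known limitations

* The pure-R engine is adequate for desk-scale experiments, not for
  training the full 8192-input network on thousands of records; a
  practitioner reproducing the full study would port `model_config()`
  settings to a GPU framework.
* WFDB support covers the common single-file format-16 dialect only.
* The covering-array generator supports strength 2 without constraints.
* Multi-label records carry their secondary labels, but training and
  evaluation use the first label only (single-softmax design).
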