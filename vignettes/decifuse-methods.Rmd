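---
title: "Methods: decoding decision correctness from EEG and image features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decoding decision correctness from EEG and image features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models and the design
choices behind them: what the synthetic study generator emulates, how each
analysis stage is defined, where the design was genuinely open and which
option we took, and what the passing test suite does and does not establish
about real recordings.

## 1. The task and the decoding problem

A participant searches a camouflaged scene divided into a 2 × 3 grid of
sub-regions (numbered 1–3 across the top row, 4–6 across the bottom, so 2
and 5 form the central column) and reports the sub-region hiding the
target. Chance is 1/6. The decoding problem is binary: predict, per trial,
whether the response will be correct, using (a) stimulus-derived features
and (b) stimulus-locked EEG. A useful predictor must beat the participant's
own *reference accuracy* — the marginal fraction of correct responses —
because the trivial "always predict correct" rule attains exactly that.

## 2. The synthetic study generator

The generator exists so that every downstream stage can be tested against
known ground truth. Its defaults define the study conditions used by the
acceptance experiments.

### Behaviour: a knowledge-plus-guessing link

On each trial the subject *knows* the target location with probability
$\pi = \mathrm{logit}^{-1}(\beta_0 + s_j + \mathbf{w}^\top \mathbf{x}_i)$,
where $s_j \sim N(0, \sigma_s^2)$ is a per-subject skill drawn once and
$\mathbf{x}_i$ holds the image difficulty covariates (size level 0–3,
occlusion flag, central-bias flag). Otherwise the response is a uniform
guess over all six sub-regions, so

$$P(\text{correct}) \;=\; \tfrac{1}{6} + \tfrac{5}{6}\,\pi,$$

which floors at the 1/6 chance level as skill vanishes and makes wrong
responses uniform over the five non-target regions. The floor matters for
the image modality: a very hard image has $P(\text{correct}) \approx 1/6$,
so its outcome is *predictably* incorrect — image features genuinely carry
decision-relevant information, as the behavioural data of this paradigm
show (image-only classifiers score close to the reference accuracy).

Defaults: $\beta_0 = -0.2$, $\sigma_s = 0.4$, weights
(size $+1.6$, occlusion $-2.0$, central bias $+0.8$), occlusion rate 0.3,
size levels sampled with probabilities (0.35, 0.30, 0.25, 0.10) —
very-large targets are rare. These were chosen so that (i) per-subject
reference accuracies land in ≈ 0.66–0.86 with mean ≈ 0.76, matching the
behavioural range this class of task produces, and (ii) image difficulty is
strongly bimodal (small occluded targets are mostly missed, large
unoccluded ones nearly always found), which is what makes the image
modality informative rather than decorative. The calibration targets this
qualitative regime, not any particular accuracy value.

### EEG: injected ERP effects in 1/f noise

Epochs span −100…1000 ms at 250 Hz (276 samples). Background noise is
Gaussian 1/f ("pink", the standard EEG background assumption) plus white
noise, combined at 80%/60% of a total per-sample sd of 5 µV. For each of
nine configured effects a Gaussian-windowed deflection is added to the
three channels of the effect's scalp region, with peak amplitude 5.5 µV on
correct trials and 0.75 µV on incorrect ones — correct-trial amplitudes are
never smaller, the ordering this paradigm exhibits in all significant
components. Effect latencies and widths default to the canonical segment
table (section 4), spread over occipital, parietal, centro-parietal and
central regions; the frontocentral triple is simulated without effects.

Amplitudes were fixed by a power argument: a segment-mean feature averages
roughly 10–20 samples × 3 channels, leaving an effective noise sd near
1.5–2 µV, so a 4.75 µV amplitude gap gives per-feature separations around
d ≈ 1.5 and a multi-segment decoder in the high-0.8s — comfortably above
reference accuracies but far from ceiling, the "strong signal, both
modalities informative" regime the end-to-end checks require.

### Images and masks

Stimulus images (default 1000 × 600 px) have a smoothly textured background
(bilinearly upsampled Gaussian grid plus fine noise) and a low-contrast
rectangular target placed wholly inside its declared sub-region, occupying
a prescribed fraction of image area; occluded images add an occluder patch
overlapping the target. Mask sets emulate a segment-everything model's
output as abstract rectangles — one mask coincides with the target, the
rest are random background segments — because only area, centroid and
quality enter the relational features. What the generator does **not**
emulate: real camouflage texture statistics, eye/muscle artifacts and line
noise (the preprocessing it feeds is correspondingly minimal), non-uniform
response biases, and any dependence of the EEG on *which* image was shown
beyond its correctness. Passing tests therefore certify the pipeline's
correctness and calibration, not field performance on real recordings.

All four generators are deterministic given `sim_config(seed = )`; each
draws from its own derived seed stream so regenerating one artifact never
perturbs another.

## 3. Preprocessing choices

* **Filter family.** 4th-order Butterworth, applied forward–backward
  (`signal::filtfilt`), so latencies are preserved; the high-pass default
  is 1 Hz. A notch filter is provided but off by default — the synthetic
  data contain no line noise.
* **Downsampling.** Anti-alias low-pass at 80% of the new Nyquist, then
  decimation; only integer factors are supported (1000 → 250 Hz is the
  intended use). Event indices are rescaled by integer division.
* **Epoch convention.** Both window endpoints are included when they fall
  exactly on a sample: −100…1000 ms at 250 Hz gives 276 samples, with t = 0
  at the event sample.
* **Baseline correction.** The mean of −100…0 ms is subtracted per trial
  and channel. No baseline rule is inherent to the paradigm description;
  this is the community default and the pipeline applies it before feature
  extraction.
* **Average reference** subtracts the per-sample channel mean (idempotent;
  column sums numerically zero).

## 4. ERP segment selection

The pointwise statistic is the condition difference of means at each time
point of a region waveform (the per-trial average over a three-channel
region). The null is built by permuting trial labels — the standard reading
of a condition-contrast permutation test — and the two-sided p-value uses
the add-one rule $p = (1 + \#\{|\Delta_\pi| \ge |\Delta|\})/(1 + B)$.
Bonferroni divides α by the number of tested time points (m, configurable).

A consequence worth stating explicitly: the smallest attainable p-value is
$1/(1+B)$, so discovery under Bonferroni requires $B > m/\alpha$ — with
m = 276 points and α = 0.05, more than 5520 permutations. The package
default is B = 2000, sufficient for the canonical workflow (which uses the
fixed segment table below rather than rediscovery); the discovery examples
and recovery experiments use B = 10000. The family-wise calibration check
at B = 1000 is structurally conservative — no point can cross α/m — and the
measured FWER of 0 still verifies control at the nominal level.

Maximal runs of significant points at least 20 ms long become segments
(the shortest canonical segment is 33 ms; the default suppresses
single-sample blips). Advisory names use P/N for the sign of the
difference, LC for onsets beyond 450 ms, and a region suffix.

`reference_segments()` stores the canonical nine-segment configuration:

| name | alias | region | window (ms) |
|------|-------|--------|-------------|
| P2o | P2o | occipital | 265–306 |
| LCo | P5o | occipital | 521–595 |
| P3p | P3p | parietal | 295–343 |
| LCp1 | P7p | parietal | 705–750 |
| LCp2 | P8p | parietal | 785–867 |
| LCc | N7c | central | 802–835 |
| N3cp | N3cp | centro-parietal | 295–345 |
| LCcp1 | N7cp | centro-parietal | 702–736 |
| LCcp2 | N8cp | centro-parietal | 794–850 |

Two editorial decisions are embedded here. First, the printed duration of
the first occipital window (51 ms) disagrees with its own boundaries
(306 − 265 = 41 ms); the table keeps the boundaries authoritative and
carries the printed value in `duration_printed`, flagged by a test.
Second, the parietal triple is (P1, Pz, P2): listings of this montage that
repeat Oz inside the parietal triple are treated as a typo for Pz, since Oz
already belongs to the occipital triple and the twelve feature channels are
otherwise disjoint. Each row carries two names because the component
labels appear in two styles (latency-ordered P/N/LC versus figure-style
P5o/P7p/...); feature names use the `alias` (e.g. `PZ_P8p_median`).

## 5. EEG features

Five temporal statistics are computed per segment × channel pair, exactly
as defined: mean; median; standard deviation with the $1/(n-1)$
denominator; *mean square* as the central second moment with $1/n$ (its
verbal description sometimes reads like a raw average, but the formula is
central and the formula wins — the two are linked by
$n \cdot ms = (n-1) \cdot s^2$, a tested identity); and the uncentred RMS.
The cross-product over all twelve channels — not only the segment's home
region — is what yields 9 × 12 × 5 = 540 features.

Pruning scans columns in their canonical order (channels outer, segments
middle, statistics inner) and drops a feature iff its absolute Pearson
correlation with an *earlier kept* feature exceeds 0.80, so the earlier
column of a correlated pair survives. Zero-variance columns have undefined
correlation; they are kept (correlation treated as 0) with a message. The
survivor count is data-dependent — about 207 of 540 on the synthetic
default study — and is reported, never asserted: the generator's nine
shared-amplitude effects induce more cross-segment correlation than real
EEG, where a comparable pipeline retains more features. Features enter the
forest raw: trees are monotone-invariant, so per-feature scaling would
change nothing, and whether any z-scoring happened before pruning in the
original workflow is unstated.

## 6. Image features

* **HSV means** use the hexcone conversion (`grDevices::rgb2hsv`);
  textbook arccos-style hue formulas are numerically fragile (their
  denominator can go negative under rounding), so the standard conversion is used. Mean
  hue is a plain arithmetic mean in degrees, *not* a circular mean —
  faithful to the defining equations even though circular statistics would
  be more principled; achromatic pixels contribute hue 0.
* **Dominant colours**: k-means with k = 10 in RGB space, seeded, 10
  restarts equivalent (seeded centre draw from distinct colours, 50
  iterations), at most 20 000 pixels clustered (a seeded subsample — shares
  estimated on 20 000 pixels have standard error < 0.4%). Fewer distinct
  colours than k reduces k with a message.
* **Contrast**: the spread between the 1st and 99th intensity percentiles
  of the Rec. 709 grey conversion, as a fraction of the 8-bit range;
  flags are 1 when the value reaches 0.75 / 0.85. This is the standard
  low-contrast heuristic; only the thresholds are prescribed.
* **Quality**: a blind proxy on [0, 100], lower = cleaner. Luminance is
  MSCN-transformed (local mean subtracted, stabilised local contrast
  divided out; 7-tap Gaussian window, σ = 7/6) and the score is the
  coefficient spread mapped to [0, 100]. Broadband noise drives the MSCN
  spread toward its saturation value, so the score rises monotonically
  with added noise on textured scenes — the polarity and range of the
  trained evaluator it stands in for, without pretrained weights. The
  moment-matched generalised-Gaussian shape is exposed as an attribute,
  and the operation accepts a pluggable backend so a trained scorer can be
  swapped in. The proxy is *not* expected to rank blur or compression
  artifacts the way a trained model would.
* **Target-object covariates**: size level with left-closed boundaries at
  1/48, 1/24, 1/12 and a top bin closed at 1/6 (a target larger than one
  sub-region cannot exist); occlusion flag; central bias = membership of
  sub-regions {2, 5}.
* **Mask-relational features**: count, summed area, biggest-mask dominance
  (max area / total area), density = the sum of Euclidean distances over
  all unordered centroid pairs divided by the *number of masks* (so it
  scales linearly with coordinate scaling), and mean quality. An empty
  mask set — never produced by the generator — encodes dominance and
  quality as 0 with a degenerate flag.

Sixteen equation-defined features result (8 basic + 3 target + 5
relational). Stated totals of "seven" basic, "seven" relational and "17"
overall cannot be reconciled with the defining equations (8 + 3 + 5 = 16);
the package exposes the sixteen and asserts nothing about 17.

## 7. The decision model

The forest uses the prescribed configuration: 100 trees, depth ≤ 10,
minimum split 2 / leaf 1, bootstrap resampling, Gini impurity, "auto"
feature subsampling mapped to the square-root rule for classification,
fixed random state 42, balanced class weights (kept although behavioural
accuracy near 0.8 makes the classes imbalanced — the setting is part of
the prescribed configuration, with an override), no OOB scoring. The
backend is `ranger`, the installed forest with an explicit tree-depth
control; two backend details needed care:

* `ranger` breaks prediction-vote ties through the R RNG, so predictions
  run under a derived seed — otherwise repeated evaluations with balanced
  (non-integer) weights are not bit-identical;
* stratified fold assignment deals each class round-robin *continuing
  cyclically across classes*, keeping total fold sizes equal to within one.
  With per-class dealing from fold 1, fold sizes like 41/41/40/39/39 let a
  degenerate all-positive classifier's fold-mean accuracy exceed the pooled
  base rate by rounding — a spurious "pass" against reference accuracy that
  the negative-control experiment exposed.

"80% training / 20% testing with 5-fold stratified cross-validation" is
read as plain 5-fold CV (each fold is the 20% test split, no outer
hold-out), and the fold mean is the reported result. Precision and F1 take
the *correct* class as positive — the convention under which F1 exceeds
accuracy, as the per-subject result tables of this paradigm show; macro
averaging is the documented alternative but not the default. Comparison to
reference accuracy uses a strict inequality: a model that only ever
predicts "correct" reproduces the reference exactly and must not pass.

Feature rankings (fold-averaged, normalised impurity importances;
deterministic name tie-break) are computed once on the group-level
evaluations and reused for the subject-level selected sets, matching a
workflow that fixes one overall top-10 ranking; `rerank_per_subject =
TRUE` recomputes them inside each subject's data. Group-level ranking on
the full data does leak information into the *selected-set* cells (the
original workflow is silent on this); the leakage-safe option exists, off
by default, and the all-features cells are unaffected.

The fused set concatenates the top-5 EEG and top-5 image features — ten
multimodal features. `run_pipeline()` executes
{all, selected} × {eeg, image, multimodal} × {group, subject}, emits
per-subject tables with a mean row, a group summary, reference-accuracy
pass counts and paired t-tests (two-sided, df = n − 1; zero-variance
differences reported as degenerate rather than NaN).

## 8. What the experiments assert, at which sizes

Problem sizes are the package's own choices, balancing statistical
resolution against desk-scale runtimes:

* **Null calibration**: 500 replicates of 100 trials × 276 points,
  B = 1000 — pointwise type-I error within the binomial envelope of 0.05,
  FWER after Bonferroni ≤ 0.05.
* **Segment recovery**: 20 runs, a boxcar 300–350 ms effect with gap 4 ×
  the single-channel pointwise SE, analysed as the three-channel region
  average (the √3 channel-averaging gain any real region analysis has),
  B = 10000 and no minimum segment length (a coverage experiment on a known
  boxcar keeps every detected point) — ≥ 80% window coverage in ≥ 19/20
  runs.
* **Formula oracles**: every statistic, the size binning, the relational
  features and the pruning rule against independent brute-force
  implementations on ≥ 100 random instances, 10⁻⁹ relative.
* **End-to-end**: the 14-subject × 200-trial default study — the
  ten-feature fusion's mean accuracy ≥ each unimodal selected mean, fused >
  reference in ≥ 13/14 subjects, decisive paired t-tests against image-only
  and reference; with difficulty weights zeroed and label-independent
  amplitudes, the pass rate collapses (negative control). The all-features
  multimodal concatenation is reported but not order-asserted against
  EEG-only: with one modality much stronger, concatenation dilutes as often
  as it helps, and the fusion construct of interest is the selected one.

## 9. Known limitations

* The generator's difficulty model is a stand-in; real per-image difficulty
  is not a three-covariate logistic, and real reference accuracies are not
  exchangeable across subjects the way simulated skills are.
* The EEG noise model has no artifacts, no inter-channel correlation beyond
  shared effects, and stationary variance; artifact rejection (independent
  component analysis and eye-component removal) is deliberately outside the
  pipeline.
* The quality proxy shares range and noise polarity with trained blind
  quality evaluators but not their regressor; scores are comparable within
  this pipeline, not across evaluators.
* Bonferroni over time points is intentionally the only correction offered
  (no cluster-mass or FDR), and permutation resolution bounds discovery as
  described in section 4.
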