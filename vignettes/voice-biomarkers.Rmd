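---
title: "Phonatory voice biomarkers for bulbar involvement: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phonatory voice biomarkers for bulbar involvement: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(phonatory)
```

## The problem

Bulbar involvement in amyotrophic lateral sclerosis (ALS) — degeneration of
the corticobulbar motor neurons that drive speech and swallowing — shows up
early as subtle voice deterioration, often before it is audible to a
clinician. Sustained-vowel phonation is a convenient elicitation task: a
patient holds /a/, /e/, /i/, /o/ or /u/ at steady loudness for a few
seconds, and the stability of the resulting quasi-periodic waveform carries
information about vocal-fold control.

`phonatory` implements a complete screening pipeline over such recordings:

1. **Feature extraction** — 15 phonatory features per utterance: four
   jitter variants (absolute, relative, rap, ppq5), five shimmer variants
   (relative, dB, apq3, apq5, apq11), four pitch statistics (mean, SD, min,
   max) and two harmonics-to-noise ratio (HNR) statistics (mean, SD).
2. **Preprocessing** — within-subject imputation of undefined
   shimmer(apq11), removal of normal-aging trends fitted on controls,
   standardization, and PCA by singular value decomposition, keeping the
   leading eight components.
3. **Classification** — six supervised models (SVM, neural network, LDA,
   logistic regression, naive Bayes, random forest) evaluated by 10x10-fold
   cross-validation with training-fold upsampling, at decision thresholds
   of 50% and 95%, for the four group comparisons C vs B, C vs NB,
   B vs NB and C vs ALS (C = control, B = ALS with bulbar involvement,
   NB = ALS without).

Because clinical voice recordings of this kind are not publicly
distributable, the package also contains a first-class synthetic-voice
module that generates cohorts with known ground truth, so that every stage
of the pipeline can be validated quantitatively offline.

## The signal model and the feature definitions

A sustained vowel is modelled as a glottal pulse train. Let `T_i` denote the
duration of the i-th glottal cycle and `A_i` its peak-to-peak amplitude,
with `N` cycles in total. The features are:

- **jitter(absolute)** `= mean_i |T_i - T_{i-1}|` (seconds), over valid
  consecutive pairs;
- **jitter(relative)** `= jitter(absolute) / mean(T) x 100%`;
- **jitter(rap)** `= mean_i |T_i - (T_{i-1}+T_i+T_{i+1})/3| / mean(T) x 100%`;
- **jitter(ppq5)** — as rap with a centred five-period window;
- **shimmer(dB)** `= mean_i |20 log10(A_i / A_{i-1})|`;
- **shimmer(relative)** `= mean_i |A_i - A_{i-1}| / mean(A) x 100%`;
- **shimmer(apq3/apq5/apq11)** `= mean_i |A_i - w_i| / mean(A) x 100%`,
  where `w_i` is the mean over the centred 3-, 5- or 11-cycle window;
- **pitch(mean/SD/min/max)** over voiced frames of the pitch track;
- **HNR(mean/SD)** over retained frames, where the frame HNR is
  `10 log10(r / (1 - r))` with `r` the second local maximum of the
  normalized autocorrelation.

Exclusion rules: cycles must lie within the period floor/ceiling
(0.002–0.025 s); a consecutive pair whose period factor (larger/smaller
ratio) exceeds 1.3 is dropped from consecutive-difference statistics, with
the effective cycle count lowered by one per exclusion; windowed quotients
use only windows that fit entirely inside the sequence with all periods in
range. Whenever fewer than two usable cycles (or zero windows) remain, the
statistic is the distinguished value *undefined*, carried as `NA` through
the whole pipeline and serialized as an empty CSV cell. Only
shimmer(apq11) is ever imputed, by the mean of the same subject's defined
apq11 values across the other vowels; a subject with no defined apq11 at
all is an error, since no defensible rule exists.

### Analysis parameters

| parameter | default | notes |
|---|---|---|
| pitch floor / ceiling (male) | 60 / 300 Hz | search range; out-of-range F0 is reported unvoiced |
| pitch floor / ceiling (female) | 100 / 500 Hz | |
| pitch time step | 0.0125 s (M), 0.0075 s (F) | frame hop |
| silence threshold | 0.1 | fraction of global peak amplitude |
| period floor / ceiling | 0.002 / 0.025 s | cycle admissibility |
| maximum period factor | 1.3 | consecutive-pair exclusion |
| HNR time step | 0.01 s | |
| HNR pitch floor | 60 Hz | fixed for both sexes |
| HNR periods per window | 4.5 | 75 ms windows at 60 Hz |
| principal components kept | 8 | near-total variance in practice |
| CV scheme | 10 folds x 10 trials | contiguous chunks after permutation |
| decision thresholds | 0.50, 0.95 | positive iff p >= threshold |
| SVM cost grid | 1e-4 … 1 | six values, inner 3-fold CV |
| random forest | 500 trees | mtry over {2, 5, 8} by OOB error |
| neural network | 3 tanh hidden units | bold-driver adaptive learning rate |

## Numerical design choices

**Pitch tracking.** Each Hann-windowed frame is autocorrelated via FFT and
normalized by lag 0. The raw normalized autocorrelation of a windowed frame
is biased downward at larger lags by the window taper; we divide by the
analytic autocorrelation of the Hann window itself, which makes the peaks
of a perfectly periodic frame equal-height near 1 regardless of the
period-to-window ratio. The fundamental is then the *smallest-lag* local
maximum within 85% of the strongest peak, refined by parabolic
interpolation. Preferring the smallest strong lag resolves octave
ambiguity: a 440 Hz tone analysed with a 300 Hz ceiling has period-multiple
peaks at 220 Hz, 147 Hz, … inside the search range, but its true
fundamental lag identifies it as out of range, and the frame is correctly
reported unvoiced rather than folded down an octave. Sustained vowels are
near-stationary, so a single best candidate per frame suffices; no Viterbi
path search is used. The voicing threshold on the corrected peak is 0.35.

**Harmonicity.** The same taper-corrected autocorrelation underlies the
frame HNR. The correction is essential, not cosmetic: with 75 ms windows
and a 150 Hz voice the uncorrected taper caps the measurable peak near
r = 0.95, i.e. 13 dB, making any harder HNR unmeasurable. With the
correction the package recovers injected harmonic/noise power ratios of
10–30 dB within 2 dB. `r` is clamped at `1 - 1e-6` (60 dB) to keep the log
finite; frames below the silence threshold, or with no positive peak, are
skipped.

**Cycle marking.** Marks are placed on dominant waveform extrema found
within ±30% of the locally expected period, walked outward from the
strongest peak, each refined to sub-sample precision by parabolic
interpolation (the light-weight equivalent of cross-correlating
neighbouring cycles, which the smooth synthetic pulses do not need).
Peak-to-peak amplitudes are taken between midpoints towards the
neighbouring marks, so that each amplitude window contains exactly one
excitation peak: windows delimited at the marks themselves would let the
rising edge of the *next* pulse contaminate the maximum whenever the next
cycle is stronger, biasing shimmer.

**Conventions.** All standard deviations use the sample (n − 1)
denominator. Frames and cycles are indexed by start time on half-open
intervals. The SVD loading signs are fixed by making each loading's
largest-magnitude entry positive, so exports are reproducible. Scores are
`U S` of the SVD `X = U S V'` of the standardized matrix; per-component
SDs are `s_i / sqrt(n - 1)`, so the PC variances sum exactly to the total
feature variance.

**Row granularity.** The default analysis row is one utterance
(subject × vowel), which is what the apq11 imputation rule presumes; a
per-subject vowel-averaged mode (`aggregate_by_subject()`,
`row_granularity = "subject"`) is available. Note that with utterance rows
the default cross-validation splits utterances, so vowels of one subject
can appear on both sides of a fold; this inflates accuracy through subject
memorisation. `cv_scheme(group_by_subject = TRUE)` provides the
leakage-free alternative and is what the package's own type-I error checks
use, since with per-utterance folds a flexible classifier can score above
chance even when group labels carry no information at all.

**Classifier probabilities.** The 95% threshold requires probabilities
from every model. LDA and naive Bayes use posteriors, logistic regression
its fitted response, the random forest its vote fraction, the neural
network its logistic output unit. The linear-kernel SVM produces decision
values, which are mapped through a logistic (Platt-style) calibration
fitted on the training fold. The tanh multilayer perceptron (one hidden
layer of three units) is trained by full-batch backpropagation with a
bold-driver adaptive learning rate (grow 5% on improvement, halve and
retract on worsening), a small L2 penalty for stability, and an early stop
after 25 stalled epochs.

**Fold construction.** Each trial permutes the rows with the trial's
seeded RNG and cuts them into 10 contiguous chunks of near-equal size. A
training fold containing a single class raises an error rather than being
silently redrawn. Upsampling (minority class resampled with replacement to
equality) applies to training folds only. Aggregation over the 100
fold evaluations is the mean of fold-level metrics, which is what paired
t tests between classifiers require; the Bonferroni family is the 15 model
pairs within one (comparison, threshold) cell.

## The synthetic-voice module

The generator emulates what the analysis assumes about real sustained
vowels:

- a raised-cosine glottal pulse per cycle, of **fixed** width (0.6 of the
  nominal period). Scaling the pulse with each perturbed cycle would shift
  its peak by half the width change and demonstrably bias measured jitter
  downward by tens of percent, so fixed width is a deliberate design
  choice making waveform peaks unbiased markers of the injected onsets;
- cycle onsets spaced `T(1 + eps_i)`, `eps_i ~ N(0, jitter_frac)`;
  amplitudes `1 + delta_i`, `delta_i ~ N(0, shimmer_frac)`. For such
  i.i.d. Gaussian perturbations the expected relative jitter/shimmer has
  the closed form `100 * 2 * sigma / sqrt(pi)` percent
  (`expected_perturbation()`), the analytic oracle used in recovery tests;
- optional cascaded two-pole resonators at vowel-typical formant
  frequencies (e.g. /a/ near 700, 1100, 2600 Hz), bandwidth 90 Hz;
- white Gaussian noise scaled to the realized harmonic power so that the
  injected harmonic/noise ratio equals the target HNR exactly;
- per-cycle periods and amplitudes retained as ground truth.

The cohort generator reproduces the structure of a bulbar-involvement
study: 18 control, 14 bulbar, 31 non-bulbar subjects by default, five
vowels each (315 recordings); controls average 45.2 (SD 12.2) years versus
56.8 (12.3) and 58.3 (11.7) for the patient groups, so age correction has
real work to do; male/female counts per group of 9/9, 3/11 and 23/8;
male F0 near 120 Hz, female near 210 Hz; 3 s recordings at 44.1 kHz.

The published evidence for the group feature distributions is graphical
only, so the default effect sizes are calibration choices fixed once:
latent jitter fractions 0.005 / 0.010 / 0.020 (C / NB / B), shimmer
fractions 0.025 / 0.045 / 0.070, HNR 22 / 17 / 12 dB, with NB given
deliberately inflated SDs to mimic its clinically ambiguous, intermediate
character. Linear aging (+5e-5 jitter, +2e-4 shimmer, −0.06 dB HNR per
year, centred at age 50) is injected additively into all groups, matching
the linear model the correction assumes. Under these defaults the Bayes
accuracy of the latent C-vs-B distributions exceeds 95%
(`cohort_bayes_rate()`), so a correctly implemented pipeline should push
every classifier above 90% accuracy for C vs B at the 50% threshold, with
B vs NB clearly harder — the qualitative ordering expected of real
cohorts.

What the generator does **not** emulate: onset/offset transients,
amplitude drift, vibrato or tremor, aspiration-noise modulation,
inter-harmonic subharmonics, room acoustics, or microphone coloration.
Passing recovery tests therefore demonstrates correctness of the
measurement and modelling chain, not clinical performance on real voices.

## Problem sizes used in the automated checks

The package's checks run on scaled problem sizes chosen to exercise every
code path: recovery tests use single 2–4 s recordings (300+ cycles);
the end-to-end classification check runs the full default cohort
(315 recordings, full 6 × 4 × 2 grid); the type-I (null-cohort) check uses
12/10/14 subjects at 22.05 kHz, 1.5 s, with subject-grouped folds; the
byte-level determinism check uses a 14-subject cohort at 16 kHz with two
models and two comparisons run twice.

## Known limitations

- The paired Student t test on repeated cross-validation folds — the
  model-comparison procedure this pipeline mirrors — is anti-conservative:
  fold-level estimates share training data, which violates the test's
  independence assumption (Dietterich 1998; Nadeau & Bengio 2003), and the
  inflation does not shrink with cohort size. On label-uninformative
  cohorts the package's own checks confirm that fold accuracies stay
  within sampling noise of 50%, yet some Bonferroni-corrected pairs still
  reach p < .05. Significance flags from `compare_models()` should
  therefore be read as descriptive of this dataset-and-procedure, not as
  calibrated error rates; the function is kept faithful to the procedure
  it models.
- A null comparison cohort must equalize not only the latent group
  effects but also the sex ratios and age distributions across groups;
  sex drives fundamental frequency, so unequal sex mixes make the pitch
  features genuinely predictive of the group label.
- The pitch tracker and HNR stage are validated by property tests against
  analytic oracles, not bit-compatibility with any external analyzer;
  octave-cost parameters of such tools are intentionally not replicated.
- Probability calibration for the SVM under the 95% threshold is a design
  choice; other calibrations would shift Table-2-style results.
- Whether age correction should be fitted inside each training fold (to
  avoid a mild leakage of control statistics) is a legitimate question;
  the default fits it once on the full control set, as the screening
  procedure it models does.
- apq11 imputation fails loudly for a subject with no defined apq11 value
  in any vowel; such subjects must be handled upstream.

## Reproducing a full run

```{r}
library(phonatory)
res <- run_voice_pipeline(run_config(seed = 1, out_dir = "run1"))
res$tables$threshold_50pct
autoplot(res$pca)
```

Every output in the run directory is reproducible from the manifest's
config and seed alone; rerunning with the same seed gives byte-identical
CSVs.
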