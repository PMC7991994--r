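# phonatory

Voice-based screening of **bulbar involvement in amyotrophic lateral
sclerosis (ALS)** from sustained-vowel recordings.

Bulbar involvement — degeneration of the corticobulbar motor neurons that
drive speech and swallowing — announces itself in the voice before it is
reliably audible to a clinician. This package implements, end to end, a
phonatory-biomarker pipeline for detecting it from the five sustained
Spanish vowels, aimed at clinical-speech researchers and biomedical data
scientists:

1. **Acoustic feature extraction.** From each mono WAV utterance, 15
   phonatory features: jitter(absolute, relative, rap, ppq5),
   shimmer(relative, dB, apq3, apq5, apq11), pitch(mean, SD, min, max) and
   HNR(mean, SD). Pitch is tracked by windowed, taper-corrected
   autocorrelation with sex-specific ranges (60–300 Hz male, 100–500 Hz
   female); glottal cycles are marked on waveform peaks with sub-sample
   refinement; the per-cycle periods `T_i` and peak-to-peak amplitudes
   `A_i` feed the perturbation statistics, e.g.

   - jitter(relative) = mean |T_i − T_{i−1}| / mean(T) × 100 %
   - shimmer(dB) = mean |20 log10(A_i / A_{i−1})|
   - HNR = 10 log10( r / (1 − r) ), r the second local maximum of the
     normalized autocorrelation.

   Cycles outside 0.002–0.025 s, and consecutive pairs whose period ratio
   exceeds 1.3, are excluded; if fewer than two usable cycles remain the
   statistic is *undefined* and stays undefined (empty CSV cell).
2. **Preprocessing.** Within-subject imputation of undefined
   shimmer(apq11); removal of "normal aging" via per-feature linear slopes
   fitted on controls only and subtracted from all rows; standardization
   (x − mean)/SD; PCA by SVD (`X = U S Vᵀ`, scores `U S`); the first 8
   components — effectively 100 % of the variance — go to the classifiers.
3. **Classification.** Six models — linear-kernel SVM (cost tuned over
   1e-4…1), a 3-unit tanh neural network, LDA, logistic regression, naive
   Bayes, and a 500-tree random forest — evaluated by 10×10-fold
   cross-validation with minority upsampling of training folds, at decision
   thresholds 50 % and 95 %, for the comparisons C vs B, C vs NB, B vs NB
   and C vs ALS, with paired Bonferroni-corrected t tests between models.

Because clinical recordings of this kind are not distributable, the package
includes a **synthetic sustained-vowel generator** (glottal pulse trains
with controllable jitter, shimmer, HNR, formants, and full cohort
structure including group effects, sex-dependent F0 and linear aging) that
provides exact ground truth for validating every stage.

## Worked example

```r
library(phonatory)

# one synthetic phonation with known 2% jitter
rec <- generate_glottal_waveform(glottal_spec(
  f0_hz = 100, duration_s = 3, jitter_frac = 0.02, shimmer_frac = 0.03,
  hnr_db = Inf, formant_freqs_hz = NULL, seed = 3))
extract_features(rec, trim = FALSE)[, c("jitter_relative_pct",
                                        "shimmer_relative_pct",
                                        "pitch_mean_hz")]
#> # A tibble: 1 × 3
#>   jitter_relative_pct shimmer_relative_pct pitch_mean_hz
#>                 <dbl>                <dbl>         <dbl>
#> 1                2.30                 3.38          99.9
expected_perturbation(0.02)   # closed-form oracle, in %
#> [1] 2.256758
```

The measured 2.30 % jitter matches the analytic expectation
100·2σ/√π for the injected σ = 0.02 — the generator and the measurement
chain agree.

A full study-shaped run (63 subjects, 315 recordings, complete model grid):

```r
res <- run_voice_pipeline(run_config(seed = 1, out_dir = "run1"))
res$tables$threshold_50pct
```

writes `features.csv`, `scores.csv`, `pca_model.json`, biplot exports,
two metrics tables (one per threshold, in %) and the Bonferroni-corrected
model-comparison p values into `run1/`. On the default synthetic cohort the
qualitative pattern of a real study reappears: C vs B is nearly separable
(accuracy ≳ 95 % for all models at the 50 % threshold), B vs NB is much
harder, and raising the threshold to 95 % trades sensitivity for
specificity.

`autoplot(res$pca)` draws the PC1/PC2 biplot; `tidy()`/`glance()` methods
expose PCA and evaluation results as tibbles.

A command-line front end with `simulate`, `extract`, `preprocess`,
`evaluate`, `run-all` and `validate` subcommands lives at
`inst/cli/phonatory.R`.

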