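---
title: "Weakly supervised severity staging from wearable IMU bags"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly supervised severity staging from wearable IMU bags}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A subject wearing a wrist IMU (tri-axial accelerometer + gyroscope,
200 Hz) performs a battery of scripted activities.  The only label is a
subject-level severity stage — healthy (0), mild (1), moderate (2),
severe (3) — assigned clinically from the whole session.  Which moments
of the recording actually show Parkinsonian motor signs is unknown, and
most recorded moments of a symptomatic subject may look perfectly
normal.  This is a multiple-instance learning (MIL) problem: the *bag*
is the subject's full set of 1.5 s signal windows (*instances*), the
label attaches to the bag, and instance labels do not exist.  A second
obstacle is class imbalance: clinical cohorts are dominated by the mild
stage.

`pdmil` implements a complete bag-level pipeline for this setting plus a
synthetic cohort generator that stands in for clinical data, so that
every claim the package makes is backed by a test that runs from
scratch.

## The pipeline

1. **Preprocess** (`bandpass_filter()`, `zscore_normalize()`,
   `segment_windows()`): causal 4th-order Butterworth bandpass
   0.3–20 Hz (removes gravity/DC, keeps all tremor bands), per-recording
   per-channel z-scoring, then 300-sample (1.5 s) windows with 50%
   overlap.  The filter is realized as second-order sections; the 0.3 Hz
   edge makes the transfer-function polynomial form ill-conditioned.
   It is single-pass by design — a forward–backward pass would double
   the effective order — so a causal warm-up transient of a few seconds
   remains in the signal; window statistics are insensitive to it.
2. **Featurize** (`extract_window_features()`, `cohort_features()`):
   per channel, eight population-normalized statistics (std, variance,
   skewness, excess kurtosis, RMS, energy = sum of squares, median,
   range) plus Pearson correlations within the accelerometer and
   gyroscope triads: 8 × 6 + 6 = 54 values.  Correlation is triad-wise
   rather than all-15-pairs because cross-sensor pairs mix units;
   `features.correlation_scope = "all_pairs"` switches.  Degenerate
   zero-variance channels yield 0 for shape statistics and correlations,
   with a warning — never NaN.
3. **Symbolize** (`fit_activity_codebooks()`, `build_document()`):
   windows of each activity are pooled over training subjects,
   standardized, and clustered with k-means (k = 8 by default, 10
   restarts, seeded).  A window becomes the *word* (activity, cluster);
   words are activity-qualified, so the vocabulary has A × k entries.
   A subject's chronological word sequence is its *document*.
   Nearest-centroid ties resolve to the lowest cluster id.
4. **Topic features** (`fit_topic_model()`, `topic_vector()`): latent
   Dirichlet allocation over the training documents' word counts,
   collapsed Gibbs sampling (own Rcpp implementation: no LDA package is
   available in the supported environment).  t = 4 topics, symmetric
   priors α = 1/t, β = 0.01, 200 sweeps with posterior means averaged
   over the second half of the chain; held-out documents are folded in
   against a frozen topic–word distribution, so transforming a test
   subject cannot touch the model.  An empty document gets the uniform
   topic vector with a warning.
5. **Fuse and classify** (`fuse_bag_vector()`, `loocv()`): the bag
   vector is the word-count histogram concatenated with the topic
   distribution (A·k + t = 36 dimensions at the defaults); `use_lda =
   FALSE` gives the counts-only ablation.  Counts are kept raw
   (`counts_norm = "relative"` switches); all bags over the same
   activities have equal length, so the choice is mostly cosmetic.
   One numerical subtlety: against a raw-count block (entries of order
   10) a unit-sum topic block is invisible to Euclidean kNN except
   through exact distance ties, which would make the with-LDA /
   counts-only comparison a coin flip.  When assembling classifier
   inputs the topic block is therefore rescaled to count units
   (θ × bag length, the expected words per topic); `fuse_bag_vector()`
   itself always returns the literal `[counts ‖ θ]`.
   Classification is subject-level leave-one-out: codebooks, LDA,
   augmentation and the classifier are refit for every fold on the
   training subjects only.  Fitting them once globally would leak the
   held-out subject's windows into the codebooks; both modes exist
   (`fit_fold_model()` is fold-local by construction), fold-local is
   the default and the only mode used in tests.
6. **Bag augmentation** (`hamming_distance()`, `select_similar_pairs()`,
   `mix_pair()`, `shuffle_bag()`, `augment_training_set()`): minority
   classes are grown to the majority count by (i) crossing
   Hamming-nearest same-class document pairs position-wise (each
   position of the common chronological prefix copies parent A or B
   with probability ½; the remainder copies the longer parent) and (ii)
   shuffling instance order within activity blocks.  Labels are
   inherited; every synthetic bag records its parents.  Distances
   between unequal-length bags truncate to the common prefix per
   activity.  Augmentation runs inside the training fold only, and
   synthetic bags receive topic vectors from the already-fitted LDA —
   the topic model is never refit on synthetic data.

Classifiers: kNN (5 neighbours, uniform weights, Minkowski p = 2;
deterministic lowest-class tie-break) implemented natively, and a
one-vs-one polynomial-kernel C-SVM (C = 1) solved with `quadprog`.
Gradient-boosting configurations (XGBoost, LightGBM) are accepted by
`classifier_config()` for completeness but raise a classed error at
training time: no offline R backend exists in the supported
environment.  All experiments use kNN, the default.

Metrics (`compute_metrics()`): accuracy = correct/total; per-class
one-vs-rest precision/recall/F1, summarized by support-weighted
averaging.  Under weighted averaging, recall is identically equal to
accuracy for any multiclass prediction — the suite asserts this on
random label sets.  A never-predicted class has precision 0 (warning).

## The synthetic cohort: what it emulates, and what a green test means

The study population this generator emulates is private, so all tests
run on simulated cohorts (`generate_cohort()`, default class sizes
15/41/17/12).  Design of the stated world:

* **Signal model.** Per activity, a voluntary base oscillation
  (activity-specific fundamental 0.6–2.8 Hz, axis-specific phases) plus
  white noise and a gravity offset on one accelerometer axis.  Each
  recording carries a random session gain U(0.6, 1.5): sensor placement
  and posture make absolute amplitudes incomparable across sessions,
  which is exactly why the pipeline z-scores per recording.
* **Episodic symptoms.** Severity expresses through symptom *load*:
  a fraction `duty_cycle` of each recording, arranged as one or two
  contiguous multi-second episodes (3 s blocks), is symptomatic.  During
  ON episodes a tremor sinusoid (clinical bands: rest 3–6 Hz, postural
  4–12 Hz, kinetic 2–7 Hz; coherent in phase across the axes of a triad)
  is added and the base motion slows and shrinks by the bradykinesia
  factor.  OFF stretches look healthy — the weak-label structure the
  method exists for.  The ON fraction is severity-graded (0.5/0.75/1 ×
  the preset anchor), while per-episode tremor amplitude and slowing
  fluctuate (multiplier U(1 ± j)) and the class-conditional amplitude
  ranges overlap between adjacent stages: a single window is genuinely
  ambiguous, the composition of the whole bag is not.  This choice is
  what gives bag-level methods their edge over propagating the bag label
  to every window; in a world where each window identifies its class,
  majority voting is unbeatable and the comparison is meaningless.
* **Presets.** `easy` (duty anchor 0.9, low noise, nearly disjoint
  amplitude ranges) is the validation world: the pipeline must recover
  labels almost perfectly there.  `default` (anchor 0.6, overlapping
  ranges) is the weak-label world for the comparative claims.  `hard`
  (anchor 0.3, heavy overlap, high noise) is used for the imbalance /
  augmentation experiments.  The study quantifies none of these
  parameters; they are calibration knobs chosen once, not claims about
  the source data.

What the generator does *not* model: biomechanically realistic limb
kinematics, harmonics of voluntary movement, device-specific noise,
sensor drift or clipping, or label noise in the clinical rating.  A
green acceptance suite therefore establishes that the implementation is
internally correct and that the method behaves as described *in a world
with the stated weak-label structure* — it does not certify clinical
accuracy numbers.

## Numerical and degenerate-input policies

* Window count: `floor((N − 300)/150) + 1`; trailing partial windows
  are discarded, never padded.  0-based window indices and half-open
  sample ranges.
* Filter edges at exactly −3 dB (|H| = 0.7071) by construction; the
  magnitude tests compare empirical sinusoid gains against the analytic
  Butterworth response.
* k-means: restarts under a derived seed; a rare empty-cluster failure
  retries with a fresh derived seed (up to 5 times) before erroring.
* All randomness flows from user-visible integer seeds through a
  multiplicative hash (`derive_seed`), keeping every stream in 32-bit
  range; the Gibbs samplers use their own splitmix64 PRNG so results
  are identical across platforms and independent of R's RNG state.
* Subjects with zero windows in the in-scope activities are excluded
  from LOOCV with a warning (mirroring the ≥ 20 s inclusion rule of the
  emulated protocol).

## Known limitations

* The permuted-label control sits *below* the binomial chance band:
  under subject-level LOOCV the held-out subject's label is removed
  from its own neighbourhood, biasing plurality votes away from it
  (LOOCV permutation anti-learning).  The acceptance test asserts the
  absence of above-chance signal, which is the leakage-relevant half.
* With the uniform-duty override (`generate_cohort(duty_cycle =)`),
  stages differ only through episode expression; in the easy preset
  those ranges barely overlap and the instance-level baseline becomes
  as strong as the bag pipeline.  The comparative claims are therefore
  evaluated in the graded-load default preset.
* The SVM backend is a dense QP per class pair — fine for dozens of
  bags, not for instance-level problems with thousands of windows.
* LDA topic features are a deterministic compression of the word
  counts; their contribution under a kNN classifier is a modest
  smoothing effect (about 1–2 accuracy points over counts-only on
  synthetic default-preset cohorts), not new information.
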