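---
title: "Connected-speech markers of early Alzheimer's disease: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connected-speech markers of early Alzheimer's disease: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Spontaneous connected speech deteriorates early in Alzheimer's disease:
utterances shorten, vocabulary narrows toward high-frequency words, complex
constructions disappear, and silent word-finding pauses multiply. Picture
description is the standard elicitation task — participants describe a fixed
set of images, trained transcribers produce tokenized, part-of-speech-tagged,
pause-timed transcripts, and linguistic features computed from those
transcripts serve as candidate digital biomarkers that are cheap and
non-invasive compared with amyloid PET or volumetric MRI.

`speechmarker` implements that analysis for Mandarin picture-description
transcripts end to end: fifteen linguistic features, covariate-adjusted group
comparison, a repeated cross-validated classification protocol over
linguistic features and imaging biomarkers, variance-inflation-screened
regressions onto neuropsychological scores, and a calibrated synthetic-cohort
generator so that every stage is testable without access to clinical
recordings, which are private.

# The fifteen features

Features are computed **per image** and averaged over a participant's (up to
three) picture descriptions. A *word* is any non-filler token, including
particles and the passive markers; an *utterance* is a pause-bounded span of
speech that may be a single word, a phrase or a clause.

Lexical content:

* **TW** — total words; **UW** — unique surface forms; **TTR** = UW / TW
  (lexical diversity).
* **CW** — content words: noun, verb, adjective, pronoun and adverb tokens,
  excluding fragments flagged *incomplete*; **CD** = CW / TW.
* **CWF** — mean corpus frequency over content-word *tokens*, looked up in a
  word-frequency lexicon (higher = more reliance on common words).
  Out-of-vocabulary tokens are dropped from numerator and denominator under
  the default `skip` policy, or given the smallest lexicon frequency under
  `min_frequency`. Averaging over tokens rather than types is a documented
  choice; type-wise averaging can be obtained by deduplicating the lexicon
  lookup upstream.

Syntactic complexity:

* **U** — utterance count; **MLU** — total Chinese characters over all word
  tokens divided by U.
* **S** — utterances containing a complete subject-predicate pattern: some
  noun or pronoun preceding (not necessarily adjacently) a verb or adjective.
  Any verb-class token is accepted as a main verb — Mandarin serial-verb
  disambiguation is out of scope. **MLS** — word tokens within sentences
  divided by S.
* **PCR** — passive constructions per utterance. A *bei* marker counts when a
  noun/pronoun occurs before it and a verb after it (NP + bei + VP); a *ba*
  marker counts when a noun/pronoun follows it with a verb after that
  (ba + NP + VP). A bare marker with no flanking structure does not count;
  this flanking requirement is a documented reading of the construction
  definitions.
* **VR**, **PR** — verb and pronoun tokens over CW.

Disfluency, both against total verbal output (TW + filled pauses):

* **FR** — filled pauses / verbal output. Fillerhood is taken from the
  transcript's `filled_pause` annotation — context decides whether words like
  "this"/"that" are fillers, and that judgement belongs to the annotator, so
  the package never guesses from the surface form.
* **LPR** — long silent pauses / verbal output, where a long pause is an
  inter-utterance gap of **2 s or more** (inclusive).

## Cleaning rules and their order

The pipeline applies, in fixed order: *repetition collapsing* (runs of
surface-identical adjacent words within an utterance, and runs of identical
adjacent utterances, reduce to one copy — "they brew-brew a pot of tea"
becomes "they brew a pot of tea"), then *filler separation* (filled pauses
are removed and counted; an utterance emptied by the removal is dropped and
its silent gap merged additively into the predecessor's), then the sentence,
passive and pause computations. Revision-flagged fragments are retained as
words; incomplete fragments count toward TW and the MLU character total but
never toward CW. When identical adjacent utterances collapse, the surviving
copy keeps the gap to the next distinct utterance.

Two conventions worth stating explicitly: pause thresholds are inclusive
(boundary guideline >= 120 ms for the optional automatic segmenter, long
pause >= 2 s), and undefined ratios (e.g. MLS with zero sentences) are
reported as missing, never as zero, so they cannot bias group means; image
averaging then uses the images where the feature is defined.

# Group comparison

`compare_groups()` fits, per feature, ordinary least squares
`feature ~ group + age + education` and reports the early-AD coefficient,
its standard error and two-sided t-test p-value. Features are z-scored first
so coefficients are comparable across features (p-values are unaffected).
Raw per-feature p-values are the primary report; Benjamini–Hochberg
adjustment is available behind a flag.

# Classification protocol

`run_classification()` implements a repeated stratified-split protocol:

1. **Splits** — 10 stratified 70/30 train/test splits
   (`round(0.7 * n_class)` per class in training).
2. **Predictor sets** — `linguistic` (15 features), `biomarkers` (SUVR and
   hippocampal volume), `combined`; age and education are included in every
   set and *compete in RFE like any predictor* (the reported selection
   frequencies for education make clear the covariates were not protected).
3. **RFE** — for subset sizes 1..p, accuracy under 10-fold cross-validation
   repeated 5 times, the within-fold ranking being recomputed after every
   elimination; best mean accuracy wins, ties to the smaller size. Inside
   the elimination loop the ranking uses the model-intrinsic importance where
   it is cheap (random-forest Gini decrease, logistic |z|) and a univariate
   AUC filter for SVM and KNN, whose stated importance measures would cost a
   refit per feature per step; the stated measures are used for the
   *reported* importances.
4. **Tuning** — grid search with 10 values per tunable hyperparameter
   (SVM cost log-spaced over 0.25–128 and kernel width spanning 0.1–10 times
   a median-heuristic estimate; KNN neighbour counts odd 5–23; RF `mtry`
   integer-spaced over 1..p), scored by mean cross-validated AUC under
   5-fold cross-validation repeated 10 times, refit on the full training
   data. RFE optimizes accuracy while tuning optimizes AUC; both criteria
   are part of the protocol being reproduced, inconsistent as the pair may
   look.
5. **Evaluation** — test-set AUC by the rank statistic (tied pairs count one
   half), plus specificity, precision, recall and F1 at a 0.5 score
   threshold, early-AD being the positive class. SVM decision values are
   mapped to scores through a logistic calibration fit on training data — the
   protocol needs class scores and a margin is not one.
6. **Importance** — random forest: accumulated Gini-impurity decrease; SVM:
   training-AUC drop on removal and refit of each predictor; KNN: mean
   accuracy drop over 10 random permutations per feature. Scores are scaled
   so the per-run maximum is 100, then averaged over the repeats in which
   RFE selected the feature; selection frequency is the percentage of
   repeats selected.

Standardization statistics (center/scale) are always estimated on the rows a
model is fit on and re-applied at prediction, including inside
cross-validation folds.

# Regression protocol

`run_regressions()` applies a single global VIF screen to the 15 features
plus age and education (`VIF_j = 1 / (1 - R2_j)`, iteratively removing the
largest VIF while it exceeds 5 — *strictly* greater, so a VIF of exactly 5
survives; among perfectly collinear pairs the later-listed member is
removed). Screening once globally rather than per outcome follows the
protocol's description of a single retained candidate list. Each of the nine
cognitive outcomes (MMSE, CDR-SB, WLM-I/II, DS, CTT-1/2, VF, BNT) is then
modelled independently on its complete cases: RFE by cross-validated RMSE
(linear fits ranked by |t|, smaller subsets win ties) followed by an OLS fit
of the outcome on the z-scored selected predictors. Standardizing predictors
but not outcomes matches reported coefficient scales whose intercepts sit at
outcome means. AIC/BIC use the full Gaussian log-likelihood (constant
included), so values are comparable with standard software output.
`residual_diagnostics()` reports residual skewness/kurtosis, a Shapiro–Wilk
test and a quadratic curvature check of residuals against fitted values; it
flags violations and never refits automatically.

# The synthetic cohort generator

No public dataset of annotated Mandarin picture-description transcripts with
paired amyloid imaging exists, so the generator is a first-class module: it
emulates the *published group-level statistics* of the study cohort (32
controls, 48 early-AD) and is the ground truth against which the pipeline's
recovery properties are tested.

Generation is parametric-by-construction — transcripts are built token by
token so the cleaning pipeline has real work to do (planted filler tokens,
flagged and unflagged immediate repetitions, utterance perseverations,
bei/ba constructions with valid flanking structure, timed silent gaps).
Per participant and group:

* **Utterance structure** — utterance count per image is Poisson around a
  lognormal per-participant rate (NC mean 21.68, AD 29.81 per image);
  words per utterance are `1 + Poisson(MLU_i / c̄ - 1)` where `c̄` is the
  expected character count of a sampled token, so the extracted MLU is
  unbiased for the participant's latent `MLU_i`, drawn lognormal with group
  mean/SD 8.11/3.02 (NC) and 5.53/1.62 (AD). The per-participant utterance
  rate and utterance length are negatively correlated on the log scale
  (−0.49 NC, −0.68 AD) — values derived from the published group SDs of
  total words, utterance count and MLU, which are incompatible with
  independence.
* **Vocabulary** — a synthetic lexicon (fixed seed: the vocabulary belongs
  to the configuration, not to a cohort draw) with per-class Zipf
  frequencies; tokens are drawn class-stratified (content density 0.48/0.46,
  verb share 0.22, pronoun share 0.03/0.05) with per-participant sampling
  exponent `s_i`. Accidental adjacent duplicates are rejected at sampling
  time so that repetition collapsing removes exactly the planted
  repetitions. `s_i` combines the calibrated group exponent, a small
  stratified jitter, a severity loading, and a negative coupling to log
  verbal output — speakers who produce more sample deeper into their
  vocabulary — whose size was set so the realized TTR dispersion matches the
  published group SDs (0.08/0.11) instead of the ~0.14 that independence
  would produce.
* **Disfluency** — fillers inserted per word with the odds implied by the
  planted filler ratios (FR 0.05/0.06); each inter-utterance gap is long
  with per-participant probability `q_i`, long gaps drawn as 2 s + Exp(1),
  short gaps uniform on [0.12, 1.9) s.
* **Biomarkers and severity** — a standard-normal latent severity factor
  `z` per participant carries 60% of the SD of SUVR (NC 1.08 ± 0.08, AD
  1.47 ± 0.19) and (negatively) of hippocampal volume (5.12 ± 0.48,
  4.36 ± 0.72), modulates the long-pause rate multiplicatively
  (`q_i = q_g · exp(λz - λ²/2)`, mean-preserving) and shifts the lexical
  exponent, planting the reported hippocampus–LPR and hippocampus–UW
  dependences.
* **Cognitive scores** — generated from linear models of the z-scored
  extracted features and covariates using the published standardized
  coefficient table (empty cells as zeros), with Gaussian noise scaled to
  hit each model's published R²; intercepts therefore sit at cohort means.
  Group separation in scores emerges *only* through the features and
  covariates — an explicit modelling assumption.

## Calibration by the planted-truth oracle

Three generator parameters have no closed form because they act through the
full extraction pipeline: the per-group Zipf exponent (targets mean TTR 0.56
NC / 0.51 AD), the per-group long-pause probability (targets mean LPR 0.0035
NC / 0.02 AD — the NC figure is the percentage-scale reading of the
published control-group average), and the severity loading on the long-pause
rate (targets a hippocampus–LPR correlation of −0.489 in a mixed cohort).
`calibrate_synthetic()` tunes them by secant iteration against Monte-Carlo
cohorts (400 participants per evaluation, 600 for the correlation) run
through the real generation + extraction pipeline under a fixed internal
seed with common random numbers, so calibrated configurations are
deterministic and cached per session. The extracted LPR is exactly linear in
the long-pause probability, which that parameter's update exploits.

Per-participant latents are drawn by **stratified sampling** (one draw per
equal-probability stratum, randomly ordered) — a variance-reduction choice
that makes cohort-level planted means recoverable tightly at n = 200 without
changing any marginal distribution; participants are exchangeable but not
independent, which is documented and irrelevant to the pipeline under test.
A master seed drives a per-participant seed sequence, so cohorts are
bit-reproducible.

## What the generator does not emulate

The transcripts are not Mandarin prose: tokens are frequency-plausible
symbol strings with realistic class mixtures, lengths and annotations, not
meaningful sentences. Semantic content, discourse structure, annotator
disagreement, ASR errors and longitudinal progression are all absent.
Passing recovery tests therefore shows that the *pipeline measures what the
generator plants* — it says nothing about clinical sensitivity on real
speech, which requires the original recordings.

# Problem sizes and numerical choices

The test suite and the acceptance script run the recovery studies at the
sizes stated above: 200 synthetic participants per group for mean recovery,
500 for correlation recovery, 100 seeded replicates for the RFE
planted-truth studies, 200 replicates at n = 500 for regression-coverage
checks, and reduced cross-validation designs (3–5 folds, 1–2 repeats, small
grids) for the protocol-structure tests, which check wiring rather than
statistical performance.

One analytic benchmark deserves its own note. With a single informative
Gaussian feature (group shift Δ at common SD σ) the best attainable AUC is
Φ(Δ/(σ√2)), and the end-to-end classifier is checked against it with a
fresh cohort drawn per repeat. Fully grown classification trees are poor
*rankers* in one dimension — their vote fractions saturate at 0/1 in the
tails, creating ties among orderable points — so the forest's terminal-node
size is exposed as a protocol control (`rf_nodesize`, default 1, the
randomForest convention) and the univariate recovery study runs at Δ = 2σ
with `rf_nodesize = 15`, the leaf-growth condition under which forest
probability estimates behave; SVM and KNN need no such adjustment. Ties in RFE go to the smaller subset; ties in grid
search keep the first (least complex) grid point; the VIF threshold and the
two pause thresholds are strict-inequality/inclusive exactly as stated
above; degenerate inputs (one-class folds, constant features, zero verbal
output) yield missing values with warnings rather than silent zeros.

# Known limitations

A consequence of the single-mechanism design worth flagging: because one
latent (the lexical concentration exponent) drives TTR, UW and CWF jointly,
and the utterance-structure latents drive U, TW and MLU jointly, the
synthetic features are more mutually collinear than clinical speech, where
idiosyncratic variation decorrelates them. The VIF screen on a synthetic
cohort therefore prunes a different subset (typically the count features
*and* some of UW/CWF/MLU) than it would on real data. VIF behaviour is
validated on constructed fixtures with known collinearity instead; which
features survive screening on real cohorts is a property of those cohorts.

* The CKIP tagset mapping ships as a documented approximation; tagset
  versions differ and unknown tags fall back to OTHER with a note.
* The bare-marker convention for bei/ba (no flank, no count) is a choice;
  corpora annotated differently should adjust the marker lists or flags.
* SVM probability calibration uses a single logistic map fit on training
  decision values; no probability-calibration research is attempted.
* The latent single-factor dependence structure is an assumption — only two
  feature–biomarker correlations are planted as targets; the remaining joint
  structure is emergent.
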