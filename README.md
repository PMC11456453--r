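# speechmarker

Connected-speech analysis for early Alzheimer's disease (AD) screening in
Mandarin. Spontaneous speech elicited by picture description carries early
signatures of AD: shorter utterances, narrower vocabulary, fewer complex
constructions, more long word-finding pauses. `speechmarker` turns
annotated, part-of-speech-tagged picture-description transcripts into
fifteen linguistic features and runs the complete downstream analysis —
covariate-adjusted group comparison, cross-validated classification against
imaging biomarkers, and regressions onto neuropsychological test scores —
for clinicians and speech scientists studying digital speech biomarkers of
neurodegeneration.

## The measures

Per image (averaged over a participant's three picture descriptions):

| Aspect | Features |
|---|---|
| Lexical content | total words TW, unique words UW, type-token ratio TTR = UW/TW, content words CW, content density CD = CW/TW, mean content-word corpus frequency CWF |
| Syntactic complexity | utterances U, sentences S, mean length of utterance MLU (characters/utterance), mean length of sentence MLS (words/sentence), passive-construction ratio PCR (bei/ba constructions per utterance), verb ratio VR, pronoun ratio PR |
| Disfluency | filler ratio FR and long-pauses ratio LPR, both over total verbal output TW + fillers; a long pause is a silent inter-utterance gap ≥ 2 s |

Cleaning precedes measurement: immediate word/utterance repetitions collapse
("brew-brew a pot of tea" counts as "brew a pot of tea"), filled pauses are
removed and counted (they are not words), and incomplete fragments count as
words but not as content words.

The analysis protocol: per-feature OLS `feature ~ group + age + education`;
10 stratified 70/30 train/test splits with recursive feature elimination
(10-fold CV × 5), grid-tuned SVM (RBF), KNN and random-forest classifiers
over three predictor sets (linguistic features, biomarkers SUVR +
hippocampal volume, combined), reporting AUC/specificity/precision/recall/F1
and scaled feature importances with selection frequencies; and, per
cognitive score, a VIF > 5 multicollinearity screen followed by RFE by
cross-validated RMSE and a standardized-coefficient linear fit.

Because the clinical recordings behind such studies are private, the package
ships a first-class synthetic-cohort generator that builds transcripts token
by token and is calibrated — by running the real extraction pipeline inside
a planted-truth oracle — to published group-level statistics (e.g. MLU
8.11 ± 3.02 vs 5.53 ± 1.62 characters/utterance; SUVR 1.08 ± 0.08 vs
1.47 ± 0.19; a hippocampal-volume/LPR correlation of −0.489). Every stage of
the pipeline is tested against what the generator plants. See the methods
vignette (`vignettes/speechmarker-methods.Rmd`) for the models, assumptions
and limitations.

## Worked example

```r
library(speechmarker)

tr  <- read_transcript(system.file("extdata", "example_transcript.json",
                                   package = "speechmarker"))
lex <- read_lexicon(system.file("extdata", "example_lexicon.tsv",
                                package = "speechmarker"))
round(extract_features(tr, lex), 4)
#>        TW        UW       TTR        CW        CD       CWF         U         S
#>    6.0000    6.0000    1.0000    5.0000    0.8571 1602.0000    2.0000    1.5000
#>       MLU       MLS       PCR        VR        PR        FR       LPR
#>    3.7500    3.2500    0.2500    0.4000    0.1000    0.0833    0.0833
```

The demo transcript has two picture descriptions averaging 6 words each
(all distinct, TTR 1); five of six words are content words (CD 0.857) with a
mean corpus frequency of 1602; one description contains a bei-passive
(PCR 0.25 = one construction over an average of 2 utterances per image, on
one of two images); one filled pause and one 2.5 s silent pause each make up
1/12 of the verbal output on their image (FR = LPR = 0.0833).

A synthetic cohort at the published group sizes, compared with age and
education adjustment:

```r
syn <- generate_cohort(synthetic_config(n_nc = 32, n_ad = 48), seed = 2026)
cmp <- compare_groups(syn$cohort)
cmp[, c("feature", "group_coefficient", "p_value")]
#>    feature group_coefficient  p_value
#>        TW            -0.134 5.87e-01
#>       TTR            -0.462 5.92e-02
#>       MLU            -0.840 1.47e-04
#>       MLS            -0.766 5.88e-04
#>       PCR            -1.170 4.53e-07
#>        PR             0.646 6.38e-03
#>        FR             0.697 4.53e-03
#>       LPR             1.488 1.47e-13   # (selected rows shown)
```

The early-AD group speaks in shorter utterances (negative MLU effect), uses
fewer passives, more pronouns and far more long pauses — the planted
clinical pattern. `run_classification()`, `run_regressions()` and
`run_all()` (or the `inst/scripts/speechmarker` command-line wrapper) drive
the full protocol and write metrics, importance, comparison and regression
tables plus a checksummed manifest.

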