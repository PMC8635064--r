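# sociolex

Linguistic markers of social isolation and loneliness (SI/L) in older
adults, extracted from semi-structured interview transcripts.

Clinical researchers measure loneliness and social support with
self-report scales — the UCLA Loneliness Scale (UCLA-3; totals above 40
categorized as lonely) and the MacArthur support scales (emotional
support, instrumental support, negative interactions, and a social-support
index). `sociolex` asks what the *transcript* of a relationship-focused
interview adds: it parses Q/A-dialect transcripts, localizes the six
relationship-section questions by TF-IDF cosine matching, extracts a named
feature vector per participant (parts of speech, vocabulary richness,
Yngve syntactic complexity, sentence similarity, lexicon sentiment,
response length, pronoun densities, relationship-word and communication
features), ranks features by decision-stump Gini gain, and evaluates
binary classifiers of the scale targets with leave-one-subject-out
cross-validation (LOOCV), reporting a pooled confusion matrix,
sensitivity, specificity, support-weighted F1 and rank-based AUC.

The statistics at the core, briefly: TF-IDF with smoothed
idf = ln((1+N)/(1+df)) + 1; Brunét's W = N^(V^-0.165) and Honoré's
R = 100·ln N/(1 − V₁/V); Yngve depth as the sum of right-to-left child
indices along a word's root-to-leaf path; compound sentiment
s/sqrt(s² + 15) from additive lexicon valences; Gini gain
(1 − p₀² − p₁²) minus the best single-threshold child impurity; weighted
F1 as the support-weighted mean of the two per-class F1 scores.

Because interview corpora of this kind are restricted human-subjects
data, the package includes a synthetic interview-cohort generator
(latent-variable model with controllable effect sizes) so the full
pipeline is testable end to end. See the methods vignette
(`vignettes/methods.Rmd`) for the model, conventions and design choices.

## Worked example

```r
library(sociolex)

# simulate a cohort of 30 with strong planted signal, write it to disk
co <- generate_cohort(generator_config(n_participants = 30, seed = 7))
dir <- tempfile(); write_cohort(co, dir)

# run the whole pipeline: extract -> assemble -> rank -> LOOCV evaluate
report <- run_pipeline(list(
  transcripts_dir = file.path(dir, "transcripts"),
  scores_csv      = file.path(dir, "scores.csv"),
  target = "ucla", cutoff_rule = "fixed", cutoff = 40,
  model_family = "ann_logistic", k_max = 5, seed = 11))

head(report$ranked, 3)
#>                             feature      gain rank
#> 1   pron_density_first_plural_whole 0.2222222    1
#> 2 pron_density_first_singular_whole 0.2202514    2
#> 3 pron_density_first_plural_section 0.2068687    3

report$selection$best
#> <eval_result> 30 participants
#>   confusion TP=11 FP=3 TN=13 FN=3
#>   sensitivity 0.786  specificity 0.812  F1(weighted) 0.800  AUC 0.857
```

The ranked table says which features best separate lonely (UCLA-3 > 40)
from non-lonely participants by Gini gain — here the planted
first-person-plural pronoun signal tops the ranking; the evaluation block
is the pooled LOOCV confusion matrix and its metrics on the selected
top-k subset, strong as expected on a strong-signal synthetic cohort.

Worked example on published-style summary inputs:

```r
confusion_metrics(c(TP = 24, FP = 12, TN = 37, FN = 11))
#> sensitivity specificity f1_weighted
#>   0.6857143   0.7551020   0.7267073
cohens_d(group_summary(63, 81.7, 6.94), group_summary(34, 86.2, 5.90))
#> [1] -0.6821

```

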