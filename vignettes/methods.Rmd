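---
title: "Detecting social isolation and loneliness from interview transcripts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting social isolation and loneliness from interview transcripts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sociolex)
```

## The problem

Social isolation and loneliness (SI/L) in older adults are usually measured
with self-report scales — the UCLA Loneliness Scale (UCLA-3, 20 items,
total 20–80, with totals above 40 categorized as lonely) and the MacArthur
social-support scales (emotional support ESS-E, instrumental support ESS-I,
negative interactions ESS-NI, and a social-support index SSI). How a person
*talks* about their relationships carries complementary signal: pronoun
choice (saying "we" rather than "I"), sentiment, syntactic complexity and
sheer response length all plausibly track social connectedness.

`sociolex` implements a complete transcript-to-classifier pipeline for this
problem: it parses semi-structured interview transcripts, finds the
relationship-section questions, turns the responses into a named feature
vector per participant, ranks features by Gini impurity reduction, and
evaluates binary classifiers of loneliness and social support with
leave-one-subject-out cross-validation (LOOCV). Because real interview
corpora of this kind are restricted human-subjects data, the package also
contains a synthetic cohort generator with controllable effect sizes so
that every stage of the pipeline is testable end to end.

## Transcript dialect and question localization

Transcripts are plain text: interviewer utterances start with `Q`,
participant answers with `A`, and unmarked lines continue the current turn.
The marker may be followed by whitespace, `:` or `.`, tolerating
transcriptionist variants; internal whitespace is collapsed and case
preserved (tagging and sentiment matching are case-folded later, but the
raw text keeps its case). The continuation rule for multi-line answers is a
package convention — transcription services do not standardize this.

The six relationship-section questions are shipped verbatim as an editable
template file. Each template is matched against the interviewer turns of a
transcript with TF-IDF vectors and cosine similarity:

- term frequency: raw within-turn count;
- inverse document frequency: smoothed, $\mathrm{idf}(t) = \ln\frac{1+N}{1+\mathrm{df}(t)} + 1$,
  so a term present in every turn still has weight 1;
- vectors are not pre-normalized; the cosine does the normalization, with
  cosine against a zero vector defined as 0.

Retrieval tokenization lowercases, strips punctuation, and keeps
stop-words: the templates are short and their function words carry real
matching signal. Ties break to the earliest turn, and matches with
similarity below 0.2 (a package convention) are flagged low-confidence.
The participant response is recovered positionally: all participant turns
strictly after the matched question and before the next interviewer turn.

## The feature suite

All linguistic features are computed from the relationship-section
responses; pronoun densities are computed both there and over the whole
interview (all participant turns), the whole-interview scope being the
default for modeling because a conversation section that is *about*
relationships inflates pronoun use on its own.

- **Parts of speech.** A coarse 8-class tagset (noun, verb, adjective,
  adverb, pronoun, interjection, filler, other). Per tag the suite emits a
  frequency (count / all tokens) and a ratio (count / open-class tokens),
  plus the pronoun:noun ratio. No statistical POS tagger ships with the
  package; the default tagger is a deterministic rule-and-lexicon tagger
  (closed-class lookup, then suffix heuristics, noun as open-class
  default). Any tagger honoring the coarse contract can be plugged in; a
  Penn-to-coarse mapping file is included for adapters.
- **Vocabulary richness.** Type-token ratio $V/N$; Brunét's index
  $W = N^{V^{-0.165}}$ (lower = richer); Honoré's statistic
  $R = 100\ln N / (1 - V_1/V)$, which emphasizes hapax legomena. When
  every type is a hapax ($V_1 = V$) the denominator is capped at $10^{-3}$
  and flagged rather than erroring — short responses hit this singularity
  routinely.
- **Filled pauses.** Lexicon hits (multiword entries matched as token
  n-grams) over total tokens.
- **Syntactic complexity.** Yngve depth: indexing each node's children
  right-to-left from 0, a word's depth is the sum of child indices on its
  root-to-leaf path. Statistics are computed per sentence and aggregated:
  mean of per-sentence means, total over all words, median of per-sentence
  means. Without a constituency parser adapter the package uses a
  deterministic right-branching fallback parse, under which every
  non-final word has depth 1; Yngve features then mostly reflect sentence
  length, which is the honest behavior of this fallback and is stated
  here deliberately.
- **Sentence similarity.** Cosine similarity of raw term-count vectors
  over all unordered sentence pairs, aggregated as mean/median/SD/max.
- **Sentiment.** An additive valence lexicon model: the raw sum $s$ of
  token valences is mapped to $s/\sqrt{s^2 + 15}$ (the "compound" score in
  $(-1,1)$); pos/neg/neu are normalized proportions of positive mass,
  absolute negative mass, and neutral token count. Capitalization,
  punctuation and negation heuristics of full sentiment tools are out of
  scope. The shipped valence lexicon is the package's own curated list and
  is plain-text configuration.
- **Response length.** Total/mean words, total/median characters, minimum
  words over the six responses.
- **Pronoun densities.** First-person singular (I, me, my, mine),
  first-person plural (we, our, us, ours) and third person (he, she, they,
  them, their) counts over total tokens; second-person pronouns are
  excluded because they mostly address the interviewer.
- **Relationship and communication features.** Pure dictionary counting of
  relationship words mapped to categories (spouse, children,
  grandchildren, sibling, parent, friend, other-family, professional) with
  simple plural s-stripping and *no* anaphora resolution — "I have
  children. A son and a daughter." counts three mentions, an acknowledged
  overestimate that is inherent to word counting. Communication phrases
  map to approximate times-per-month (e.g. "every day" → 30, "once a
  week" → 4.33); with several matches the maximum is kept, reading the
  most frequent stated contact as the operative one. A none-understood
  detector fires when a negation pattern matches and no relationship word
  co-occurs in the response. All dictionaries are editable two-column text
  files and are treated as configuration, not ground truth.

Throughout, SDs are population SDs, degenerate inputs (zero tokens, zero
nouns, fewer than two sentences) produce zeros with a `flags` attribute
instead of errors, and a missing communication frequency is `NA`, not 0.

## Targets, ranking and evaluation

A scale score becomes a binary target by `label = score > cutoff`, with the
fixed UCLA-3 cutoff of 40, or an empirical median / 75th-percentile cutoff
for the support scales. The modeling table inner-joins features, scores and
sociodemographics on participant id, one-hot encodes categoricals, and
imputes missing numerics by the column median (logged); participants
missing a given target are dropped for that target only.

Features are ranked by decision-stump Gini gain: parent impurity
$1 - p_0^2 - p_1^2$ minus the best support-weighted child impurity over all
single-threshold splits, ties broken alphabetically. Standard binary Gini
has maximum impurity 0.5 at a balanced split; the gain of a perfect
separator of a balanced target is 0.5.

LOOCV fits the model on all participants but one and predicts the held-out
label and decision score; features are z-scored with training-fold
statistics only, to avoid leakage while still giving the scale-sensitive
models (neural nets, kNN, SVM) standardized inputs. Fold scores are pooled
into a single confusion matrix and a single rank-based (Mann–Whitney) AUC —
pooling is the only way one AUC arises from LOOCV. The weighted F1 is the
support-weighted mean of the two per-class F1 scores; this averaging mode
is adopted because it is the one that reconciles published confusion
matrices with their printed F1 values. Incremental selection evaluates the
top-1 … top-k ranked features and keeps the k with the best AUC (ties to
the smaller k); the ranking is computed once on the full table and frozen,
which mirrors the usual incremental procedure but carries an optimistic
selection bias — the null simulations below quantify that it stays small
at these sample sizes.

The classifier grid mirrors a study design common in this literature:
one-hidden-layer neural networks (logistic and tanh activations with 200
hidden units, relu with 100, Adam optimizer, epoch cap 1000 with
early-stopping tolerance $10^{-4}$), an RBF-kernel SVM (cost 1, tolerance
0.001, epsilon 0.1), kNN (k = 9, Chebyshev metric, distance weighting), a
fully grown decision tree (minimum leaf 1), and a small random forest
(8 trees, 4 attributes per split, depth limit 7). The neural network is
implemented in the package (full-batch Adam on cross-entropy with a small
L2 penalty); `nnet` serves as an independent reference in the test suite,
and SVM/tree/forest fits go through `e1071`, `rpart` and `randomForest`.
One training seed is used for every fold, which keeps LOOCV results
invariant to participant row order.

## Cohort statistics

The cohort-table layer works from summary statistics on purpose, so that
published group rows (n, mean, SD) can be checked directly: Cohen's d with
the pooled sample SD, the pooled-variance Student's t (with its exact df
convention $n_1+n_2-2$), Mann–Whitney U with midrank ties and the
normal approximation, Spearman correlation as Pearson on midranks with the
t approximation, and the 2×2 chi-square without continuity correction.

## The synthetic cohort generator

The generator is a latent-variable linear-Gaussian model with clipping —
the simplest structure that reproduces the directional findings this kind
of study reports; it makes no claim of discourse realism. Each participant
draws a latent loneliness $z \sim N(0,1)$. Planted response rates are
`base + beta * z + noise`, clipped to valid ranges:

- share of sentences voiced in the first-person plural
  ($0.5 + 0.45\,\beta_{fpp} z$, the remainder split between first-singular
  and third person by a per-participant style share *independent* of $z$);
- negative-sentence rate ($0.18 + 0.12\,\beta_{neg} z$);
- words per response ($55 + 10\,\beta_{len} z$);
- expected relationship mentions (Poisson with mean $4 + 1.5\,\beta_{rel} z$),
  and the probability of reporting that no one understands them
  (logistic in $-\beta_{rel} z$).

Responses are realized by sampling slotted sentence templates (neutral,
positive, negative, relationship-mention, community, coping pools) at
those rates, so the generated text exercises the tagger, the sentiment
lexicon and the relationship lexicon simultaneously. The UCLA-3 score is
$\mathrm{round}(40 + 10 z + \varepsilon)$ clipped to $[20, 80]$, with
$\varepsilon \sim N(0, 5)$ by default — the slope of 10 per latent SD puts
the >40 cutoff near the cohort median, so default cohorts split roughly in
half. Emotional support and SSI are negatively coupled to $z$, negative
interactions positively. Women (65% of a default cohort of 97) draw
communication-frequency phrases from a more frequent pool than men,
planting the gendered communication difference. Transcripts embed the six
template questions verbatim followed by three non-relationship sections
(aging, technology, daily routine), so the whole-interview pronoun scope
is genuinely wider than the relationship section.

The channel fidelities are deliberately ordered: the pronoun coupling has
the smallest noise relative to its slope, then sentiment and length, then
relationship counts. Pronoun choice is the headline marker this pipeline
is meant to recover, and the noisier channels reflect that word counts and
mention counts are intrinsically noisier measurements in real interviews.
With all betas zero the generator is a true null: no feature carries
information about the score beyond chance.

What the generator does *not* emulate: real discourse structure, topic
drift, disfluency patterns beyond a constant filler rate, item-level scale
responses, or gendered vocabulary. Passing tests on synthetic cohorts
therefore demonstrate that the pipeline recovers what was planted — they
do not validate the feature suite against real speech.

## Numerical and design choices

- Brunét exponent −0.165 and Honoré constant 100 are the standard forms.
- Sentence similarity needs at least two sentences; otherwise zeros with a
  flag. The "frequency" aggregation sometimes listed for pairwise sentence
  similarity has no standard definition; the package exposes
  mean/median/SD/max.
- Gini's binary maximum is 0.5; descriptions of Gini reaching 1 apply to
  many-class problems and are not used here.
- The kNN implementation is in-package because the Chebyshev metric with
  distance weighting is not available in the installed neighbors packages.
- The `rpart` tree depth is capped at 30 (the implementation's hard
  maximum); with minimum leaf size 1 and no complexity pruning it is
  effectively fully grown at these sample sizes, matching a "max depth
  100, min leaf 1" specification in behavior.
- Problem sizes in the test suite (cohorts of 40–100, 20 null replicates,
  100 ranking replicates) were chosen as the smallest sizes at which the
  calibration and recovery properties are stable.

## Known limitations

Word counting overestimates distinct relationships in the presence of
anaphora, by design. The fallback parse makes Yngve features
length-dominated unless a real constituency parser is plugged in. The
frozen-ranking incremental selection is optimistically biased; the
null-cohort simulations bound the bias at these sample sizes. The rule
tagger is approximate outside the generator's vocabulary; it is a
contract-honoring default, not a replacement for a trained tagger on real
transcripts.
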