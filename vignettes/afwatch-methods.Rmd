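---
title: "Methods: weakly supervised surveillance of wearable AF prediagnoses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weakly supervised surveillance of wearable AF prediagnoses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afwatch)
```

## The problem

Consumer wearables (Apple Watch, Fitbit, Kardia, ...) can alert a user to a
possible atrial fibrillation (AF) episode — a *prediagnosis* that may drive
the patient into care before any clinician has made a diagnosis.
Electronic health records carry no billing code for "my watch warned me",
so postmarket surveillance of these devices has to mine free-text clinical
notes.  Hand-labeling notes at scale is prohibitively expensive; `afwatch`
implements the alternative: weak supervision.  Rule-based *labeling
functions* encode how clinicians write about device alerts, a generative
*label model* reconciles their votes into probabilistic labels, a
*noise-aware classifier* trained on those labels generalizes beyond the
rules, and a retrospective cohort analysis compares patients flagged with a
prediagnosis against the rest.

## Gazetteer matching and note filtering

Five term dictionaries drive the rules: wearable devices, AF surface forms
("afib", "a.fib", "irregular heart rhythm", ...), action verbs (alert,
notify, note, show, ...), notification-event nouns (their nominal forms),
and the anticoagulant/rhythm-medication lists used by the cohort stage.
Matching is on normalized text (lowercase, collapsed whitespace) with an
offset map back to the source so every mention is auditable; matches must
sit on token boundaries (alphanumeric/non-alphanumeric transitions, so
"a.fib" is one term and "wearables" does not match "wearable"), overlaps
resolve longest-first, and action terms match by stem plus listed irregular
forms so "notified" and "shown" count.  Candidate notes for manual review
are enriched by the vicinity rule: an action term starting within 30
characters before a wearable mention or ending within 30 characters after
it.  The rule is applied symmetrically on the original (unnormalized)
string — the natural reading, and the one that keeps offsets meaningful
against source notes; it is monotone in the window size.

Cohort filters retain notes with a wearable mention, written on or after
2019-01-01 (the first consumer AF feature shipped in December 2018), for
patients at least 22 completed years old on the note date
(birthday-inclusive, the conservative reading of an age cutoff).

## Labeling functions

Eight one-sided heuristics vote `POSITIVE` or abstain; none ever votes
negative, matching the data-programming convention for positive-pattern
rules.  LF1 is a grammar-free dictionary conjunction: an (unnegated) AF
term, a wearable term and an action/event term anywhere in the note.
LF2–LF8 are ordered slot patterns within one sentence — e.g. "AF noted on
wearable" (AF + verb + preposition + wearable) or "Per wearable, patient
had AF" (wearable + subject + verb + AF) — with at most `gap = 5`
intervening word tokens between consecutive slots, because clinical prose
inserts determiners and modifiers ("AF was noted this morning on his Apple
Watch").  Sentences come from a deterministic rule-based segmenter
(boundaries at terminal punctuation followed by whitespace and a capital,
so dotted abbreviations survive) with a coarse four-class tagger (verb /
preposition / noun / other) built from closed word lists; the patterns only
need verb and preposition distinctions, so a full tagger would add
dependency weight without adding information.

Negation is sentence-scoped: a trigger ("no", "not", "denies", "without",
"negative for", "ruled out", "never") before the AF mention suppresses the
vote unless a contrast conjunction ("but", "however") intervenes.  Note
votes aggregate per function by OR over sentences.

## The generative label model

Votes are combined by a conditionally independent generative model in the
original data-programming spirit.  Each function `j` has a *propensity*
`p_j` (probability it engages with a note at all) and an *accuracy* `a_j`
(probability its internal judgement matches the true label `y`); it emits
`POSITIVE` only when it engages and judges positive:

$$P(v_j = \mathrm{POS} \mid y = 1) = p_j a_j, \qquad
  P(v_j = \mathrm{POS} \mid y = 0) = p_j (1 - a_j),$$

abstaining otherwise.  With a class prior $\pi$, the posterior
$P(y = 1 \mid v)$ follows from Bayes' rule; fitting is plain EM with
closed-form M-steps, a parameter clamp at $\varepsilon = 10^{-3}$,
tolerance $10^{-6}$ on the mean log-likelihood and at most 500 iterations.
The log-likelihood is non-decreasing by construction and asserted in the
tests.  Two limits pin the model down: with a uniform prior and one fully
propense function of accuracy $a$, the posterior after a positive vote is
exactly $a$; with accuracy 1 and propensity 1, abstention is itself
evidence of a negative.  A consequence worth stating: because emission is
one-sided, an all-abstain note has a posterior *near* but not exactly at
the class prior — abstention carries the small amount of information the
propensities encode.  Notes harden at 0.5 for downstream counts.

With a single labeling function the three parameters are not identifiable
(only the marginal positive-vote rate is observed); identifiability comes
from having several functions, and the accuracy-above-one-half
initialization selects the intended mode of the label-swap symmetry.

Model selection mirrors the study protocol: candidate fits from different
random initializations are scored by mean F1 over seeded stratified
k-folds of a gold-labeled set (k = 10), ties breaking to the lowest
candidate index.  The original protocol's "cross-validation on the test
set" is ambiguous; scoring candidates on folds of the gold set is our
documented interpretation.

## The noise-aware classifier

The discriminative stage is a ridge-penalized logistic regression over
word 1–3-grams with sublinear term frequency ($1 + \log \mathrm{tf}$),
trained with per-example weights equal to the label-model confidence
(`p_positive` for hardened positives, `1 - p_positive` for negatives).
Training sets are stratified 1:2 positive:negative — `size/3` positives,
`2·size/3` negatives, sampled uniformly without replacement and never from
the held-out gold notes.  The regularization path stands in for training
epochs: a seeded stratified 10% validation split picks the penalty with
the best validation F1, the analog of keeping the best snapshot.  The
path's smallest penalty is `1e-5` of the largest; a shallower path leaves
the model unable to commit to the minority class at small training sizes.
The full-scale system this replaces — a long-input clinical transformer
(Adam, learning rate warming to 1e-5, linear decay over 3 epochs, 4096
subword-token inputs) — is recorded in `transformer_reference_config()`
for provenance; the package defines the token budget operationally through
its own whitespace/punctuation tokenizer so the 4096-token trimming
contract stays testable without model weights.

## The synthetic EHR generator

`generator_config()` encodes the study conditions: note-level prevalence
of a true prediagnosis 0.18 (the hand-labeled test-set prevalence), an
even mix over the eight positive sentence patterns, negated-AF variants
among the negatives, meditation-boilerplate distractors, wearable-only and
AF-only negatives, notes dated 2019–2022, and published rates wherever one
exists: 11.12% undisclosed race/ethnicity, diagnosis rates 29.41% /
1.58% for the two groups, a mean prediagnosis-to-diagnosis lag of 4.74
days (drawn geometric).  Values the study does not state — comorbidity
rates, medication probabilities, the prior-AF rates that feed the washout
stage — are set once at what a clinical reader would call plausible
magnitudes, with mild age/sex effects (the positivity intercept is
calibrated at generation time so the marginal prevalence equals the
configured one exactly).  Everything is seeded and byte-reproducible.

Structured tables link to the notes by ground truth: conditions carry
synthetic concept codes with an AF hierarchy rooted at code 313217 and two
descendant levels (plus a decoy branch), drugs come exclusively from the
anticoagulant/rhythm lexicons, and cardioversion procedures attach to
diagnosed patients.  All codes are synthetic stand-ins; no real
terminology release ships with the package.

`hard = TRUE` adds the generator's stress condition: a fraction
(default 0.3) of positives carry a concessive prefix ("Though not
symptomatic"), joined to the pattern sentence by a comma in 40% of cases.
The comma variant puts a negation trigger in the same sentence as the AF
term, so the sentence-scoped negation rule wrongly suppresses every
labeling function — a deliberate reproduction of the classic
negation-scoping failure of rule-based clinical NLP.  The period variant
is a separate sentence and labels normally.  Both variants have identical
word-n-gram representations (punctuation is not a token), so the
classifier cannot imitate the rules on these notes and instead learns the
majority behavior, recovering the suppressed positives.  This is the
mechanism by which, on synthetic data, classifier recall exceeds
label-model recall — the desk-scale analog of a transformer generalizing
beyond labeling heuristics.  What passing these tests shows is that the
pipeline's plumbing and the generalization mechanism behave as designed;
it does not certify performance on real clinical text, whose surface
variation, negation dialects and note lengths the template generator does
not attempt to model.

## Cohort analysis

The index note is the oldest classifier-positive note (prediagnosis
group) or the oldest wearable note (comparison group); ties break to the
smallest note id.  The washout removes patients with an
ambulatory/inpatient AF-coded occurrence — code 313217 or any transitive
descendant, computed by traversal with cycle detection — strictly before
the index date, and the diagnosis flag requires an AF-coded occurrence in
the inclusive window `[index, index + 60]` days.  "Strictly before" and
inclusive window ends are documented conventions, boundary-tested, and
configurable.  CHA₂DS₂-VASc is the standard rubric (CHF 1, hypertension 1,
age ≥ 75 2, diabetes 1, stroke/TIA 2, vascular 1, age 65–74 1, female 1;
the two age components mutually exclusive), scored from condition
occurrences on or before the scoring date; patients missing sex score 0 on
the sex component with a flag, and are excluded from comparison tables.

Group comparisons use a one-tailed Welch t test (Welch–Satterthwaite
degrees of freedom) for continuous characteristics, with directions from a
configuration map defaulting to the clinically expected ones (the
prediagnosis group older, higher scores), and Pearson's χ² without
continuity correction for categorical ones; categorical levels absent from
both groups are omitted (so never-prescribed drugs drop out of the
medication block, and the test's degrees of freedom adjust).  P values are
reported unadjusted for multiplicity, as in the original analysis.  The
relative risk offers a `printed_percent` mode that divides the two
percentages after rounding each to two decimals — the display convention
under which the published counts 305/1037 vs 262/16560 reproduce the
published 18.61 ratio exactly (the raw quotient is 18.59).

## Problem sizes and numerical choices

The shipped tests and the acceptance script run the pipeline at the sizes
the package's own experiments use: parameter recovery on 5,000-note vote
matrices over 10 seeds; canonical-corpus recovery on ~2,000 notes;
the training-size sweep on a ~30,000-note hard-mode corpus with sizes
600 / 5,000 / 10,000 and 3 replicates (the largest size requires roughly
3,300 weakly flagged positives, which fixes the corpus size); cohort
plumbing on 500–3,000-patient panels.  Percentage cells print with
half-up rounding, matching how clinical tables display "n (%)"; R's
default round-half-even would turn 105/600 into 0.17.

## Known limitations

* The template generator produces short, regular notes; real notes are
  longer, noisier, and mix section headers, lists and boilerplate the
  segmenter has never seen.
* The linear n-gram classifier has no pretrained knowledge; on real text a
  fine-tuned clinical transformer behind the same interface is the
  intended substitution.
* The label model assumes conditional independence of the labeling
  functions; the eight patterns overlap (a sentence firing LF3 often fires
  LF1), which the model absorbs into its accuracy/propensity estimates
  rather than modeling dependencies explicitly.
* Concept codes, subtype mappings and comorbidity code lists are
  config-driven synthetic stand-ins; deployment against a real terminology
  requires site-specific mappings.
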