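---
title: "Methods: EHR dementia phenotyping with stable topics and max-margin risk scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EHR dementia phenotyping with stable topics and max-margin risk scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Roughly half of older adults living with dementia never receive a formal
diagnosis, and the gap is widest in under-served populations. Electronic
health records contain enough signal — clinical-note language, diagnosis and
procedure codes, medication fills — to flag patients who *look like*
diagnosed dementia patients but carry no dementia code. `phenodem`
implements such a computable phenotype end to end: note text is summarised
by *stable topics* from repeated LDA runs, structured codes become binary
indicators bridged across the ICD-9/ICD-10 transition, a linear
support-vector machine turns the features into an unbounded risk score, and
the score is validated against (simulated) expert chart review under a
stratified verification-sampling design with inverse-probability-weighted
(IPW) estimates.

Because real EHR data of this kind sit behind institutional firewalls, the
package ships a synthetic cohort generator with *planted* signal — a known
topic model, known risk codes, and a latent truth label — so that every
stage of the pipeline can be tested against ground truth.

## Cohort structure and eligibility

The generator emulates a case-control design. Cases receive a first
dementia diagnosis code after age 65 at their *index date*; controls never
carry a dementia code and never fill donepezil, galantamine, rivastigmine
or memantine. Every patient must have at least two note-bearing visits in
each year of the 3-year lookback window, which for cases immediately
precedes — but excludes — the first dementia diagnosis (all date intervals
are half-open `[index - 3y, index)`). For controls the index date is a
randomly chosen qualifying visit. The eligibility rules are exposed as
`check_eligibility()`; the generator satisfies them by construction.

One rule is deliberately looser than the cohort floor of age 65: controls
need three consecutive qualifying years *after age 62*, so a control's
window may legitimately open before their 65th birthday. The generator
keeps index ages at 65+ and `check_eligibility()` flags (rather than
fails) windows opening before 65, which is how we read the ambiguity.

## Note generation and the planted topic model

Notes are drawn from the standard LDA generative process: a per-note topic
mixture from a Dirichlet prior, then a topic and a word per token. The
planted model has `n_topics_true = 20` topics over a 500-word vocabulary,
with topic-word distributions drawn from a sparse Dirichlet
(concentration 0.05) so the planted topics are well separated and
recoverable. Three of the topics are designated *dementia-signal* topics.
Their Dirichlet weight is 0.01 in notes of signal-free patients — dementia
vocabulary is essentially absent from the notes of patients without the
condition — and 1.0 (against a background weight of 0.3) in notes of cases
and of latent-positive validation controls, so signal patients' notes
average roughly a third of their tokens from signal topics. These values
were fixed once as a plausible stylisation of how densely dementia-related
language appears in the records of affected patients during the three
pre-diagnosis years.

Structured events follow the same logic: a small set of *risk* ICD groups,
CPT codes and medications occur with per-visit probability 0.15 in signal
patients and 0.02 otherwise, on top of uniform background coding noise.
Diagnosis events are ICD-9 before the transition date (2015-10-01, the US
transition) and ICD-10 on or after it.

What the generator does **not** emulate: real clinical language (tokens
are abstract vocabulary items), code hierarchies, temporal disease
progression within the window, correlated comorbidity structure, or
informative missingness. Passing tests therefore demonstrate that the
pipeline recovers planted structure of the assumed form — not that it
would perform identically on real notes.

Latent truth is generated for validation controls only (default
prevalence 0.04, the scale of published estimates of undiagnosed
possible/probable dementia). Training controls are generated signal-free;
in reality training controls would themselves contain undiagnosed cases,
which would attenuate the fitted weights. We accept this simplification to
keep planted-signal recovery interpretable.

## Stable topics, pseudo word counts, presence

LDA is fit three times with different seeds (`seed + 1, 2, 3`) by a
collapsed Gibbs sampler (`src/lda_gibbs.cpp`) with symmetric priors
`alpha = 5/K`, `beta = 0.01` — the familiar MALLET-style defaults — and a
configurable number of sweeps. Inference for new notes runs per-note Gibbs
sweeps under the fixed topic-word matrix, averaging the proportions over
the second half of the sweeps.

A *stable topic* is a triple of topics, one per run, that are mutual best
matches under cosine similarity between topic-word distributions with all
three pairwise similarities at or above a threshold (default 0.8; the
choice of metric and threshold is ours — "very similar" is not otherwise
quantified). Its word distribution is the average of the three members.
Unmatched topics are dropped; no topic joins two stable topics.

For each note, a topic's *pseudo word count* (PWC) is its inferred
proportion times the note's word count — the generally non-integer number
of words the topic explains. The stable topic's PWC is the median of its
three members' PWCs, making it invariant to run order. Presence converts
PWC to a bounded score: 0 below 2.0, PWC/10 between 2.0 and 10.0
(closed interval — we take the printed boundaries literally at exactly
2.0 and 10.0), and 1 above 10.0. A patient's presence value for a topic is
the maximum over their notes.

## GEM groups and structured features

The ICD-9/ICD-10 general equivalence mapping is treated as an undirected
bipartite graph (either mapping direction supplies edges) and decomposed
into connected components — the unique finest partition that breaks no
crosswalk edge. Each component becomes one era-spanning group code;
ICD-9 events look up the ICD-9 side, ICD-10 events the ICD-10 side, and
codes absent from the crosswalk become deterministic singleton groups
rather than being dropped. Codes are normalised (dots and whitespace
stripped, upper-cased) before matching, since GEM files omit dots while
event tables often include them.

Structured features are presence indicators (ever in the window, 1/0),
filtered to those supported by at least `min_support = 10` training
patients, computed on the training stratum only and separately per race
stratum. Topic presences and the two demographics (age, sex) bypass the
filter. Age is kept continuous and standardised by the training mean/SD;
binary and presence features are left unscaled. Columns that end up
identically zero are dropped (and the training column set becomes the
fixed schema for validation data).

## The risk model

The classifier is a linear soft-margin SVM (hinge loss, L2 penalty; the
libsvm C-classifier from `e1071` with a linear kernel and no internal
scaling). Its single important hyperparameter, the cost `C`, is chosen by
stratified five-fold cross-validation over a grid (default
`10^(-4..2)`) maximising the mean held-out AUC of the fold models'
decision scores; exact ties break toward the smaller (simpler) cost. The
final model is refit on the full training stratum and a patient's risk
score is exactly `w . x + b` — the signed distance to the separating
hyperplane, unbounded, higher meaning more dementia-like. Percentiles are
always computed against the full validation stratum's scores. CV folds
use decision scores, not hard predictions, since AUC on hard predictions
is degenerate.

## Verification sampling and IPW validation

The chart-review design is two-phase: a simple random sample (default
200) from the full 10,000-score validation frame, then stratified draws
from what remains of each score-percentile band — 100 from (75, 90] and
30 from each 1-percentile band of (90, 100], 600 reviews in total. A
sampled patient's inclusion probability follows the union convention
`pi = 1 - (1 - pi_srs)(1 - pi_band)` with `pi_band` the band's phase-2
draw fraction of its post-phase-1 frame; weights are `1/pi`.

Simulated review converts latent truth to `none`/`possible`/`probable`
labels with configurable reviewer sensitivity and specificity (default
1.0/1.0); `possible` and `probable` together form the positive class.
At a percentile cutoff (type-7 empirical quantile of the full validation
stratum; "above" is strict), the weighted 2-by-2 table yields prevalence,
sensitivity, specificity, PPV, NPV and accuracy; PPV from the table
satisfies the Bayes identity with the same table's prevalence,
sensitivity and specificity to machine precision. The weighted AUC is the
weighted pairwise concordance probability (ties count one half),
identical to the trapezoidal area under the weighted empirical ROC.

Confidence intervals are percentile bootstrap intervals, resampling
reviewed patients with replacement within their *sampling* stratum (the
SRS is one stratum; each phase-2 band draw is its own) at its realised
size, keeping the verification design fixed. A caution from our own
simulations: with ~600 reviews and 4% prevalence the weighted prevalence
is dominated by a handful of large-weight positives from the
below-75th-percentile stratum, and the percentile interval then covers at
a little over 90% rather than the nominal 95% — an intrinsic small-count
limitation of the percentile method under this design, worth remembering
when reading the intervals.

Cohen's kappa for dually reviewed charts uses the standard large-sample
standard error `sqrt(p_o(1 - p_o) / (n (1 - p_e)^2))`; if both raters are
constant and identical, kappa is 1 by convention.

## Numerical and scale choices

Desk-scale defaults are chosen so the full pipeline — generation, three
topic runs, inference over every note, stable extraction, features,
cross-validated SVM, scoring — completes in minutes on one CPU: 1,000
training cases + 1,000 training controls + 2,000 validation controls in
one stratum, ~40 notes per patient of 50-200 tokens, vocabulary 500,
20 planted topics, `K = 30` learned topics, 150 learning sweeps on a
20,000-note learning subsample (topic learning on a subsample with
inference on the full corpus mirrors practice on multi-million-note
corpora), and 20 inference sweeps per note. All samplers are seeded
explicitly (`std::mt19937` in compiled code), so every artifact is
reproducible bit-for-bit from the configuration seed, and the generator
restores the caller's RNG state.

Degenerate inputs are handled explicitly: notes containing only
out-of-vocabulary tokens get uniform topic proportions (logged); empty
notes, single-class training labels, non-finite features, all-zero
feature columns, undated events, infeasible sampling strata and zero
weighted table margins are errors or logged `NA`s rather than silent
results.

## Known limitations

* The synthetic corpus is a stylised LDA world; tokenisation, stopword
  and document-frequency choices (`tokenize_notes()`) matter on real text
  but are untested against clinical language here.
* Three signal topics boosted jointly are correlated in every signal
  note; at small corpus sizes LDA may merge them, which lowers per-topic
  recovery while leaving discrimination largely intact.
* The percentile bootstrap undercovers slightly for low-prevalence
  weighted estimates under this design (see above).
* GEM flag semantics (approximate/combination flags of the real CMS
  files) are out of scope; edges only.
* Scores are raw margins; no probability calibration is attempted.
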