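---
title: "Methods: a BiRNN-CRF de-identifier and its customization scenarios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a BiRNN-CRF de-identifier and its customization scenarios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Free-text clinical notes cannot be shared for research until every word or
phrase that could identify a patient — protected health information (PHI)
under the HIPAA Safe Harbor categories — has been found and replaced.
`deidtag` implements a neural sequence tagger for this task together with the
machinery a deploying organization actually needs around it: evaluation at a
recall-oriented operating point, surrogate generation, and the four
customization regimes that arise when a model trained on one institution's
notes must work on another's.

De-identification is context-sensitive: in "John London complains of chest
pain", *London* is a person, not a place, and only the sentence structure
says so. That is why the core model is contextual rather than lexicon-based.

## Model

Each note is tokenized into maximal letter runs, maximal digit runs, and
single symbols ("Patient prescribed 50mg" becomes *Patient, prescribed, 50,
mg*). Per token the tagger concatenates three representations:

1. a **pretrained token embedding** (default 200-dimensional) looked up by
   the token's normalized form (lowercased, digits mapped to `0`); tokens
   outside the embedding vocabulary receive an all-zero fallback so that
   out-of-vocabulary (OOV) tokens contribute no spurious signal and
   discrimination falls to the character encoder;
2. a **character-level bidirectional recurrent encoding** (default
   25-dimensional): the final states of a forward and a backward recurrent
   pass over the token's characters, concatenated and affinely mapped. This
   is what handles OOV words, abbreviations and shared prefixes/suffixes;
3. **casing and spacing features**: a one-hot casing class (upper / lower /
   mixed / non-alphabetic) plus the counts of spaces and line breaks before
   the token, clipped at 4 and scaled to [0, 1]. The clip value is the
   smallest that still separates same-line, new-line, and
   blank-line-separated tokens; unbounded counts destabilize training.

A **token-level bidirectional recurrent network** (default 100 units per
direction, so a 200-dimensional contextual output) adds sentence context,
and an affine projection produces a score per BIO label. A **linear-chain
conditional random field (CRF)** scores complete label sequences — emission
scores plus learned transition scores with virtual start/stop states — so
that predicted PHI labels cohere as a sequence. Training minimizes the mean
negative CRF log-likelihood (cross-entropy over label sequences) with
Adagrad (learning rate 0.1) on minibatches of 20 notes, with dropout 0.5 on
the concatenated per-token input and on the contextual output.

Design points that were genuinely open, and how they were fixed:

* **Recurrent cell.** LSTM cells by default (`cell = "lstm"`), the standard
  choice for this architecture family; a plain tanh RNN is available as a
  config switch and shares the same exactly-tested backpropagation path.
* **Dropout placement.** "Layers 1 and 2" is read as (1) the concatenated
  per-token input and (2) the contextual output before projection.
* **CRF constraints.** Transitions are unconstrained (no hard BIO mask);
  an ill-formed decoded `I-X` without a preceding `B-X`/`I-X` is repaired to
  `B-X` at span conversion. This matches common practice and keeps training
  simple.
* **Tie-breaking.** Viterbi ties resolve toward the lowest label index at
  every backpointer; label index 1 is `"O"`, so fully uninformative scores
  decode to all-`O` rather than to arbitrary PHI.
* **Early stopping.** A patient-level split (10% of training notes) is held
  out; training keeps the checkpoint with the best development token F1 and
  stops after 5 epochs without improvement. When training continues from a
  pre-trained model (`fine_tune()`), the incoming parameters are evaluated
  as the epoch-0 candidate, so adaptation can never end below its starting
  point on the development set.
* **Numerical core.** The forward algorithm runs in log space; gradients of
  the CRF are expected-minus-observed sufficient statistics from
  forward-backward; all encoder gradients are full backpropagation through
  time, verified against central finite differences to ~1e-9 relative
  error in the test suite. The core is C++ (RcppArmadillo) and draws all
  randomness (dropout masks, negative sampling) from R's RNG, so a single
  seed makes training bit-reproducible.

## Operating points: recall at fixed precision

Recall is the safety-critical metric: a missed identifier is a privacy
breach, while a false positive merely deletes useful text. A scalar bias
added to the `"O"` (not-PHI) emission score at decode time trades recall
against precision without retraining. `recall_at_precision()` sweeps this
bias over a grid (default 41 points, −4 to 4), decodes the test corpus at
each point, and reports the highest recall among points whose precision
meets the cutoff `p` (default 0.85). If no point qualifies the metric "does
not adjust": it reports the recall at bias 0 and flags the cutoff as unmet.
Because of that fallback, R@P is non-increasing in `p` only over the region
where the cutoff is attainable — the property tests assert exactly that.

## Customization scenarios

`run_scenario()` reproduces the deployment regimes, always with
patient-disjoint train/test splits:

* `full_custom` — train and test on the same corpus A;
* `off_the_shelf` — train on A, test on B unchanged;
* `only_b` / `a_then_b` / `a_mix_b` — partial customization from `n` labeled
  target-PHI instances (counted by default in NAME instances, the category
  annotated consistently across guidelines; whole notes are selected because
  annotation happens note-wise);
* `custom_embedding` — train on A with a skip-gram embedding built from B's
  *unlabeled* text (min-count 10), the no-annotation adaptation route.

"A mix B" draws every minibatch half from A and half from the selected B
subset (resampling the smaller side with replacement), which honors
"even mixture" even when B is far smaller than A. `learning_curve()` runs
these strategies over a budget grid with replicate seeds derived as
`seed + replicate - 1`. Scenario comparisons are made in recall at the
R@P(0.85) operating point, the same operating-point metric used to compare
systems throughout.

## Surrogation

`redact_tags()` replaces spans right-to-left with bracketed type tags
(`[PersonNameTag]`, `[DateTag]`, ...). `surrogate_realistic()` substitutes
plausible fictitious values instead: names from bundled public name lists,
dates that preserve the original's format class (month-name, slash, ISO),
IDs and phone numbers regenerated digit-for-digit, locations matching the
original's shape (unit abbreviation vs facility name). Within a note,
identical surfaces of one type can be forced to one surrogate
(`consistent = TRUE`); whether within-note consistency is desirable is
deployment-specific, so it is a flag. `verify_redaction()` audits output
text for verbatim gold surfaces (length ≥ 3, non-dictionary-common),
per note. Note that a *realistic* surrogate can coincidentally equal a
different gold PHI surface in the same note, which the audit would rightly
flag; the corpus-wide safety check therefore uses tag redaction, where
collisions are impossible.

## The synthetic note generator

Gold-annotated clinical corpora are access-controlled, so the package ships
a generator whose corpora stand in for them in every test. What it emulates:

* **Per-type PHI profiles.** Presets reproduce published per-note-type
  instance fractions of NAME/DATE/LOCATION for discharge-record, radiology,
  echocardiogram, discharge and nursing note types (e.g. radiology: 10.2% /
  44.8% / 1.8%). The unreported remainder is split ID 60% / AGE 15% /
  CONTACT 15% / PROFESSION 5% / OTHER 5% of the residual mass — an explicit
  invention, configurable in `gen_config()`. Categories are drawn i.i.d.
  per instance, so empirical fractions converge to the profile; at 1000
  notes (≈6000 instances) every type stays within ±2 points.
* **Token imbalance.** Each note carries ~6 PHI instances embedded in 10–16
  filler sentences (~13% PHI tokens), reflecting the heavy skew toward
  non-PHI tokens in real notes. This imbalance is also what makes ~26 notes
  (50 labeled names) genuinely insufficient to train a model from scratch —
  the regime in which transfer from a source corpus pays off.
* **Template heterogeneity.** Ten name-sentence patterns, eight date leads
  and three or more patterns per remaining type, with varied cue verbs, so
  PHI is learnable from context but no small sample covers every pattern.
* **Structural idiosyncrasies.** The radiology preset opens every note with
  a 7-digit record-number ID span — the classic dataset-specific error
  source for off-the-shelf models. Nursing-style corpora can inject
  unit-jargon abbreviations ("MICU"-style) as LOCATION PHI, in ward-status
  contexts deliberately disjoint from the referral contexts that front
  facility names; with disjoint jargon sets, a domain pair reproduces the
  off-the-shelf "local jargon" failure. Shared filler also contains non-PHI
  uppercase abbreviations (HR, BP, CXR, NPO, ...) as distractors, so
  "uppercase and unknown" alone cannot signal PHI.
* **Domain shift.** `generate_domain_pair()` dials the fraction of filler
  vocabulary shared between two corpora; the rest comes from disjoint
  domain word lists.
* **Difficulty knob.** `dictionary_name_rate` injects dictionary-word
  surnames ("Guy", "Strong") — the canonical hard false negative — and is
  off by default so the standard suite stays stable.

What the generator does **not** emulate: real clinical semantics, spelling
noise, long-range document structure, or annotation disagreement. Passing
tests on synthetic corpora therefore demonstrate that the implementation
learns and transfers as designed, not that any particular recall level
carries over to real notes; deployment still requires evaluation on the
target institution's data.

## Problem sizes and reproducibility

The shipped acceptance checks use a reduced-but-faithful configuration
chosen as a deliberate simulation scale: 50-dimensional skip-gram
embeddings, 15-dimensional character encoder, 50 recurrent units per
direction, 20–30 epoch budgets; corpora of 300/100 notes for full
customization and a 200/150-note domain pair with three replicate seeds for
the transfer, jargon and embedding comparisons. Every training run, sweep
and generated corpus is seed-determined; `scripts/acceptance.R` recomputes
all headline numbers from scratch.

## Known limitations

* The tokenizer is rule-based (letters / digits / single symbols); it
  reproduces the intended splitting behavior but is pluggable if a corpus
  needs different conventions.
* Embeddings are static; contextual encoders are out of scope.
* Rule-based post-filters (e.g. a 7-digit-header heuristic) are
  intentionally absent from the model path to keep the machine-learning
  contribution isolated and measurable.
* CRF decoding is exact but sequence-length-bounded by a line-break-aware
  chunker (default 1000 tokens) to bound memory on pathological inputs.
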