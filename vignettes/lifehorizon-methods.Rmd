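---
title: "Methods: life-expectancy prognostication from EMR histories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: life-expectancy prognostication from EMR histories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(lifehorizon)
```

## The task and the model

`lifehorizon` treats prognostication as supervised sequence
classification: *given a patient's medical history up to some moment,
predict the number of months until death*. Training uses records of
deceased patients, whose death date provides the label.

A history is represented as 61 thirty-day bins anchored backward from the
death date (bin 61 ends at death). Anchoring backward rather than on the
calendar is what makes labels exact: a window of 10 consecutive bins
ending at bin $t$ has months-to-death label $61 - t$. Only labels 1–50
are kept — the window may not contain the death month, and the maximum
label is bounded by the 61-month history minus the 10-month window — so
each patient contributes exactly 50 windows whose labels are a bijection
onto $\{1, \dots, 50\}$. Pooled over a test cohort the label distribution
is therefore flat, with lower median 25 months.

Per bin, the feature vector holds frequency counts over a vocabulary
drawn from eight categories: ICPC diagnosis, ICPC reason for encounter,
ICD code, ICPC intervention, ICPC medical history, medication,
lab result, and consultation type. Counts are normalized per
(month, category) block by the block maximum, bounding every input in
$[0,1]$ and annulling the effect of how many consultations fell in a
month. The alternative reading — dividing by the per-category maximum
over the patient's whole history — is available via
`normalize_monthly(scope = "history")`; the per-month default is used
throughout because it is the variant under which the test-suite
invariants (each non-empty block attains 1) are stated.

The classifier is a two-layer LSTM: per time step the input feeds 50
tanh-activated LSTM units, whose output feeds a second identical layer,
whose final-step output feeds a dense layer with softmax over 50 future
months. The argmax of that distribution is the predicted life expectancy
and its maximum is the *certainty* of the prognosis. Cross-entropy
against the one-hot label is minimized with Adam. Both the forward pass
and backpropagation through time are implemented in compiled code inside
the package and are verified against finite-difference gradients in the
test suite.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `window` | 10 months | input sequence length |
| `horizon` | 50 months | output classes (months-to-death) |
| `hidden_units` | 50 (100/200 variants) | LSTM units per layer |
| `batch_size` | 5 | Adam mini-batch size |
| `learning_rate` | 1e-5 | parity default; convergence experiments use 1e-3 |
| `epochs` | 10 | training passes |
| `init_sd` | 0.1 | truncated-normal (±2 sd) weight init |
| `bias_init` | 0.1 | all biases |

The parity learning rate of 1e-5 with 10 epochs barely moves the loss on
small synthetic cohorts; the signal-recovery experiments therefore use
1e-3, which is an ordinary configuration value, not a change to the
model. Loss is computed on the final time step only; an all-steps variant
(`loss_all_steps = TRUE`) averages a softmax cross-entropy over every
step and is exposed but not part of the tested parity surface.

## Feature engineering choices

* **Code abstraction.** ICPC/ICD codes of form `[letter][number].[dec]`
  are simplified before counting: diagnosis, reason-for-encounter and ICD
  codes to `[letter][number]` (D84.02 → D84); intervention and medical
  history to `letter + thematic element` (D84.02 → D+standard
  procedure). The element lookup maps numeric ranges to broad
  consultation themes and ships as an editable TSV
  (`inst/extdata/icpc_elements.tsv`).
* **Cut-offs.** Four per-category frequency cut-offs are implemented:
  none, absolute occurrence < 100 (the default everywhere), relative
  share < 1%, and dropping the least frequent features covering ≤ 25% of
  category mass (ties keep the lexicographically smaller feature). Each
  is checked against exhaustive enumeration on small instances.
* **Medication and labs.** Medication strings are stripped of dosage and
  usage text by a documented regex set before counting; lab results
  enter the vocabulary only when flagged irregular or abnormal.
* **Degenerate inputs.** Months without events are zero vectors; an
  all-zero (month, category) block stays zero under normalization; an
  empty cohort yields an empty vocabulary rather than an error.

## Free-text features

Documents pass a normalization pipeline — letter boilerplate removal
(pattern-based, configurable; notes pass through), lower-casing and
tokenization, abbreviation expansion (`pt` → `patient`), synonym
canonicalization (`esophagus` → `slokdarm`), and conservative spelling
correction (unique lexicon word within Levenshtein distance 1, otherwise
unchanged). Lemmatization/POS tagging is a pluggable annotator hook with
a pass-through default; reimplementing a Dutch tagger is out of scope.
The composed pipeline is idempotent on its own output, which the suite
checks property-style.

Three keyword strategies produce per-month text features:

1. **Frequency**: top-$n$ content words by corpus frequency.
2. **Entropy**: words ranked ascending by the Kullback–Leibler divergence
   between their pooled temporal distribution over months-to-death
   (additive smoothing, one pseudo-count per bin) and a reference
   distribution. The reference default is exponential decay with
   months-to-death (time constant 6 months). A linear tilt was
   considered and rejected: against a linear reference a uniformly-used
   word scores ≈ 0.27 nats while a word concentrated in the final months
   scores ≈ 1.0, so background words would always outrank terminal
   vocabulary; the exponential reference (uniform ≈ 2.0 nats, terminal
   well below 1) actually selects death-associated words, which is the
   entire point of the method. Any probability vector can be supplied
   instead.
3. **Embeddings**: skip-gram with negative sampling trained in-package
   (window 5, min count 10, 100/200/300 dimensions, 5 negatives,
   linearly decayed learning rate, single-threaded and seeded, so
   identical corpus + seed give identical vectors). A month's text is
   the mean vector of its in-vocabulary tokens; empty months are zero
   vectors.

Keyword counts are treated as a ninth feature category and
max-normalized per month; embedding means pass through unchanged, since
they are already bounded by training dynamics. Keyword counts are
frequency-valued (not binary) per month, consistent with the
frequency-count representation of the structured features.

## Evaluation protocol

The test split is recency-based: the 10% most recently deceased patients
(ties broken by patient id) are held out, mimicking deployment on new
patients; model and feature selection use seeded 10-fold
cross-validation on the remainder. Prognoses are classed by the quotient
$Q = \text{actual}/\text{predicted}$: accurate in $[0.67, 1.33]$
(boundaries inclusive — the interval is read as closed, isolated in one
function so the exclusive reading is a one-line change), overly
optimistic below, overly pessimistic above. Deviation statistics use
$\text{predicted} - \text{actual}$, so a positive mean deviation means
life expectancy is overestimated. Certainty is defined as the maximum of
the softmax distribution. Evaluation is per window sample: each test
patient contributes 50 outcomes.

Because a uniform predictor already attains 29.2% quotient accuracy
against uniform labels (computed by enumerating all 2,500
(actual, predicted) pairs — the asymmetry of the proportional margin
makes late predictions cheap), all claims of learned signal are stated
*relative to that enumerated chance level*, never in absolute terms.

## The synthetic cohort generator

The generator emulates the population that motivated this model family:
52% female; age at death normal (sd 8 years, truncated at 18) with means
81 (F) / 76 (M); 121 consultations per patient over the 61-month
history, Poisson per month with a uniform monthly rate by default (an
optional hazard-ramp multiplier exists for realism experiments);
documents on 75% of consultations, 85% of them notes; letters carry
greeting/signature boilerplate; codes follow the `[letter][number].[dec]`
pattern from small per-category vocabularies. Death dates spread
uniformly over three years so the recency split is meaningful. Two
figures the source population reports disagree slightly — roughly three
consultation events per patient-month versus 121 per five years — and
the generator is calibrated to the explicit 121 figure. The implied
overall mean age at death is the sex mixture 0.52·81 + 0.48·76 ≈ 78.6.

A `signal_spec` plants recoverable prognostic structure: a marker code
emitted (with configurable penetrance) in exactly one death-anchored
month, and terminal keywords whose per-document emission probability
rises linearly from zero at `keyword_ramp_start` months before death to
a peak in the final month. The default configuration plants *no* signal
(penetrance 0), so calibration statistics are measured on an unperturbed
cohort; experiments opt in explicitly. Raw document text also contains
abbreviation variants (`pt`, `pat`) so the text pipeline has real work
to do.

What passing tests show — and what they do not: the pipeline recovers
structure of the kind it is designed to detect (a month-localized code;
death-concentrated vocabulary) from data whose marginals match the
target population. They do not show that real clinical trajectories are
predictable at any particular accuracy: the generator has no disease
progression, no correlated comorbidity structure, and no realistic
language model, so absolute accuracies on synthetic cohorts are not
forecasts of real-data performance.

## Numerical and reproducibility choices

* One master seed fans out to per-stage seeds through a stable hash
  (`derive_seed`), so stages can be rerun in isolation; all seeds stay
  below $2^{31}$.
* The LSTM kernels and the SGNS trainer are deterministic given their
  inputs; all sampling happens in R's RNG (or, for SGNS negatives, an
  internal xorshift stream seeded from R), single-threaded. A full
  `run_experiment` is byte-deterministic: two runs under one seed write
  identical reports.
* Argmax ties break toward the earlier month — the pessimistic
  direction, which in a palliative-care context is the safer error.
* Problem sizes used by the suite: calibration checks on 2,000 synthetic
  patients; signal recovery on 500 patients (≈ 22,500 training windows,
  10 epochs); unit fixtures are hand-built cohorts of 1–40 patients.
  These sizes were chosen so the statistical assertions (3-standard-error
  bands, chance-level comparisons) have adequate power while the whole
  suite stays desk-scale.

## Known limitations

* The spelling corrector is lexicon + Levenshtein with a no-change
  tie-break; it does not model phonetic or keyboard errors.
* Consultations on the same day are kept distinct; the interchange
  format and binning never merge them.
* The hospice-study human reference (20/17/63) is carried as printed
  constants for context next to model results; no attempt is made to
  re-derive it.
* Probabilities are not calibrated; certainty is a relative, not an
  absolute, confidence measure.
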