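# lifehorizon

Life-expectancy prognostication from electronic medical records with an
LSTM horizon classifier.

Accurate prognosis of remaining life expectancy is central to Advance Care
Planning: general practitioners systematically overestimate how long
palliative patients will live and miss the window to discuss end-of-life
care. `lifehorizon` implements an end-to-end machine-learning pipeline that
predicts a patient's remaining life expectancy — in months, 1 to 50 — from
the final five years of EMR history: dated consultations carrying coded
clinical events (ICPC/ICD), lab results, medications, and free-text notes
and letters. It is written for biostatisticians and clinical-NLP
researchers who want to study, extend or stress-test this family of
prognostic models without access to real patient data: a calibrated
synthetic cohort generator with a plantable prognostic signal makes every
stage of the pipeline testable end-to-end.

## The model

Each patient's history is aggregated into 61 thirty-day bins anchored
backward from the death date. Per bin, a feature vector **x**ₜ holds
max-normalized frequency counts over a vocabulary built from eight feature
categories (diagnosis, reason for encounter, ICD, intervention, medical
history, medication, abnormal/irregular labs, consultation type), with
ICPC/ICD code abstraction (e.g. D84.02 → D84, or D + *standard procedure*)
and an absolute-occurrence < 100 cut-off. A sliding window of W = 10
consecutive months forms one input sequence; its label is the number of
months between the window's last month and death, so every patient
contributes exactly 50 samples with labels 1…50.

The classifier is a two-layer LSTM (50 tanh units per layer, truncated
normal init, biases 0.1) unrolled over the 10 time steps; the final step's
dense output is passed through a softmax to give **h**ₜ, a probability
distribution over the next 50 months:

> ŷ = argmax *h*ₜ (predicted life expectancy), certainty = max *h*ₜ.

Training minimizes the cross-entropy between *h*ₜ and the one-hot
months-to-death label with Adam (batch size 5, learning rate 10⁻⁵, 10
epochs in the parity configuration). Free-text features can be appended to
**x**ₜ by three selection strategies: top-*n* frequency keywords, top-*n*
lowest Kullback–Leibler divergence between a word's temporal distribution
over months-to-death and a late-mass reference ("entropy" selection), or
mean skip-gram word-embedding vectors per month (trained in-package, SGNS,
window 5, min count 10, 100/200/300 dimensions).

A prognosis is judged by the quotient criterion of the hospice study used
as the human reference: Q = actual/predicted is *accurate* in
[0.67, 1.33], *overly optimistic* below, *overly pessimistic* above.
Reports carry RMSE, signed mean deviation (positive = overestimation),
the accuracy taxonomy, per-month histograms, and Pearson correlations of
certainty against the actual and predicted horizon.

## Worked example

Generate a 200-patient synthetic cohort with a planted prognostic marker
(penetrance 1, emitted exactly 5 months before death), hold out the 10%
most recently deceased patients, train the LSTM at an elevated learning
rate, and evaluate:

```r
library(lifehorizon)

cohort <- generate_cohort(generator_config(
  n_patients = 200, seed = 42,
  signal = signal_spec(marker_penetrance = 1, marker_offset = 5)))
cohort
#> <emr_cohort> 200 patients, 24258 consultations, 18193 documents

parts <- split_recent(cohort, 0.10)
vocab <- build_vocabulary(parts$dev)          # 46 features
train <- extract_windows(normalize_monthly(monthly_counts(parts$dev, vocab)))
test  <- extract_windows(normalize_monthly(monthly_counts(parts$test, vocab)))

model <- build_model(model_config(learning_rate = 1e-3, epochs = 10, seed = 1),
                     input_dim = dim(train$x)[1])
model <- train_model(model, train)            # mean loss 3.66 -> 0.64

report <- evaluate_outcomes(prognosis_outcomes(predict(model, test)))
report
#> Prognostic evaluation over 1000 window samples
#>   RMSE 19.6 months, mean deviation +5.5 months
#>   accurate 42% | pessimistic 21% | optimistic 38%
#>   (human hospice reference: 20% | 17% | 63%)
#>   actual_vs_predicted: r = +0.24 (p = 3.1e-14)
#>   certainty_vs_actual: r = -0.32 (p = 8.88e-26)
#>   certainty_vs_predicted: r = -0.51 (p = 5.34e-66)
#>   certainty_vs_abs_error: r = -0.32 (p = 7.47e-26)
```

The held-out quotient accuracy (42%) clearly beats the enumerated chance
level of a uniform predictor (`chance_accuracy()` = 0.292) because the
model recovers the planted marker: windows containing it are predicted to
within ±1 month. The correlation pattern — positive between actual and
predicted horizon, negative between certainty and both horizons — mirrors
what this model family shows on real primary-care data. `autoplot(report)`
draws the actual-vs-predicted histogram, `autoplot(model)` the loss curve,
and `tidy()`/`glance()` return the table forms.

A thin command-line wrapper for shell use ships at
`inst/cli/lifehorizon.R` (`generate`, `run`, `evaluate` subcommands).

## Limitations

The synthetic generator matches the first-order descriptive statistics of
a real primary-care cohort but not clinical disease trajectories or
realistic Dutch clinical language; see the methods vignette
(`vignettes/lifehorizon-methods.Rmd`) for what passing tests do and do not
establish about real data.
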