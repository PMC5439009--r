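# rhythmeter

Bayesian meter inference and onset prediction for quantized rhythms.

`rhythmeter` is for researchers in music cognition and computational
musicology who want to model how listeners infer meter from rhythm and how
that inference is shaped by the statistics of the music they have heard.
A monophonic rhythm is a strictly increasing sequence of integer note-onset
times (1 tick = 1/96 whole note; a sixteenth note is 6 ticks). The package
treats meter perception as inversion of a generative model: a metrical
category *m* (a time signature with bar period *T<sub>m</sub>* ticks) is
drawn from a prior *p(m)*, a phase *φ* is drawn uniformly over the
sixteenth-note grid, and onsets are emitted by a per-category variable-order
(PPM\*) sequence model over linked metrical-position / bar-distance
(mp ⊗ bd) symbols. Listening is the incremental posterior update

> p(m, φ | e₀ⁿ) ∝ p(eₙ | m, φ, e₀ⁿ⁻¹) · p(m, φ | e₀ⁿ⁻¹),

and prediction error is the information content −log₂ p(eₙ | e₀ⁿ⁻¹) of
each onset under the posterior-marginalized predictive distribution. The
PPM\* models use escape method C with interpolated smoothing and an
optional order bound, trained per category on annotated corpora — so the
same machinery supports meter classification, onset prediction, manipulated
prior biases, and enculturation simulations in which models trained on
different "cultures" of rhythms are compared on common test sets.

## Worked example

Sample an annotated corpus from the shipped simple-meter culture, train a
generative model, and evaluate held-out rhythms:

```r
library(rhythmeter)

train <- sample_corpus(culture_preset("A", n = 300, seed = 1))
test  <- sample_corpus(culture_preset("A", n = 50, seed = 2), "probe")

model <- train_meter_model(train, order_bound = 1)
model
#> <meter_model> 2 categories (2/4, 3/4), 20 interpretations, order bound 1

ev <- evaluate_rhythm(model, test[[1]])
ev
#> <meter_evaluation 'probe-00001'> classified 2/4@0 (correct); mean IC 3.384 bits over 13 events
round(head(ev$ic, 5), 3)
#> [1] 7.495 3.821 0.401 6.935 2.136
```

The rhythm is classified as 2/4 at phase 0 (its annotated interpretation).
The per-event information contents trace the predictive-coding loop: early
events are expensive (7.5 bits) while category and phase are still
uncertain, and drop sharply once the posterior has converged on an
interpretation that makes the rhythm predictable. Corpus-level scores:

```r
res <- evaluate_corpus(model, test)
cat(sprintf("accuracy: %.2f   mean IC: %.2f bits\n",
            mean(res$correct), mean(res$mean_ic)))
#> accuracy: 0.94   mean IC: 2.67 bits
```

Comparing against a meter-agnostic inter-onset-interval model on identical
folds and events (`run_baseline_comparison` trains both per fold and
scores every event from the second onward):

```r
cmp <- run_baseline_comparison(train[1:120], order_bounds = 0:2, k = 5, seed = 1)
print(cmp, digits = 3)
#>   order_bound meter_ic meter_ic_sd baseline_ic baseline_ic_sd n_events
#> 1           0     2.42      0.0514        2.47         0.0496     2237
#> 2           1     2.27      0.0461        2.39         0.0763     2237
#> 3           2     2.38      0.0624        2.45         0.0707     2237
```

Inferring meter lowers mean prediction error at each order bound: the
positional structure the meter model learns buys it bits the interval-only
model cannot recover.

Other entry points: `run_crossval()` (k-fold classification accuracy and
IC per order bound), `run_bias_experiment()` (two models differing only in
a manually set category prior, contrasted on the exhaustive 2¹¹-pattern
one-bar grid set from `grid_test_set()`), `run_enculturation()` (2×2
train/test matrices across two cultures), `import_kern()` /
`read_rhythm_jsonl()` for corpus input, and a thin command-line dispatcher
at `inst/cli/rhythmeter.R` (subcommands `sample`, `train`, `classify`,
`evaluate`, `crossval`, `compare-baseline`, `bias-exp`, `enculturation`,
`import-kern`, `filter`, `grid-testset`).

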