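---
title: "Probabilistic meter inference from quantized rhythms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic meter inference from quantized rhythms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhythmeter)
```

## The model

`rhythmeter` treats meter perception as Bayesian inversion of a generative
model of rhythms. A *metrical category* $m$ is a time-signature-like class
with a bar period $T_m$ in ticks (1 tick = 1/96 whole note, so a sixteenth
note spans 6 ticks; 2/4 has $T_m = 48$, 3/4 and 6/8 have $T_m = 72$). A
*metrical interpretation* $(m, \varphi)$ adds a phase $\varphi$: the offset
between the rhythm's time origin and the downbeat of the first bar,
searched on the sixteenth-note grid $\varphi \in \{0, 6, \dots, T_m - 6\}$.

A rhythm $e_0^n$ — a strictly increasing sequence of integer onset times —
is modeled as generated by drawing $m$ from a prior $p(m)$, drawing
$\varphi$ uniformly, and emitting onsets one at a time from a
category-specific sequence model. Listening inverts this process:

$$p(m, \varphi \mid e_0^n) \propto p(e_n \mid m, \varphi, e_0^{n-1})\,
  p(m, \varphi \mid e_0^{n-1}),$$

an incremental posterior update whose initial state is the interpretation
prior. The predictive distribution over the next onset marginalizes the
per-interpretation predictions over the posterior, and the *information
content* $-\log_2 p(e_n \mid e_0^{n-1})$ of each observed onset is the
model's operationalization of prediction error. Classification reports the
interpretation with the highest posterior after the whole rhythm; a
classification is correct when the category matches the annotation and the
inferred phase is 0, because annotated corpora are encoded with onset 0 on
a downbeat.

### Metrical viewpoints

Likelihoods are computed over symbol sequences, not raw onsets. An onset is
interpreted under $(m, \varphi)$ through derived viewpoints:

* metrical position `mp` $= (o - \varphi) \bmod T_m$,
* bar number `bn` $= \lfloor (o - \varphi) / T_m \rfloor$,
* bar distance `bd` $=$ `bn`(last) $-$ `bn`(penultimate),

all with **floored** modulo and division, so anacrusis onsets (negative
ticks) map into $[0, T_m)$ and every interpretation is evaluable on any
encoding. The linked symbol `mp` $\otimes$ `bd` pairs position with bar
distance; for a fixed previous onset this pairing maps one-to-one onto
concrete onset times, which is what makes onset prediction from a
position alphabet well defined (`symbol_to_onset()` is the inverse).

For the first event of a rhythm `bd` has no penultimate bar number; the
package uses a virtual previous bar number of 0, so the first event carries
phase evidence (a rhythm starting on versus off the downbeat is
informative). This is configurable: `include_first_event = FALSE` drops
first events from training and scoring, matching the stricter convention
under which the viewpoint is undefined there. One consequence of floored
bar numbers is worth spelling out: under phase 6 in 3/4, the time origin
lies in bar $-1$, so onsets 0 and 30 have bar numbers $-1$ and $0$ and the
linked symbol at onset 30 is $(24, 1)$, not $(24, 0)$; the round-trip
identity `symbol_to_onset(vp_mp_bd(...))` holds exactly under this
convention and is property-tested.

### Sequence model

Per-category symbol sequences are modeled with a variable-order PPM*
model: escape method C (the escape weight of a context equals the number
of distinct symbols observed in it) combined with *interpolated* smoothing,

$$p_k(s) = \frac{c_k(s) + t_k\, p_{k-1}(s)}{n_k + t_k},$$

grounded in a uniform base distribution over the trained alphabet, so
every symbol always receives positive probability. The starting context is
the shortest *deterministic* matching context (one with a single observed
continuation) when one exists, otherwise the longest matching context;
both are capped by the order bound $b$, which limits conditioning to the
last $b$ symbols. Only a corpus-trained (long-term) model is used; there
is no online short-term component, no multiple-viewpoint combination and
no exclusion heuristics. Because several closely related smoothing
variants exist in the literature, the exact semantics above are pinned by
a test that compares the implementation against an independent
literal-recursion oracle at tolerance `1e-12`.

The alphabet of a category's model is the Cartesian product of all
positions $\{0, \dots, T_m - 1\}$ and a bar-distance range wide enough to
cover every inter-onset interval observed in training. Candidate next
onsets for a prediction are the previous onset plus each training IOI;
their symbols are read from the PPM distribution and renormalized over the
candidate set. An observed onset whose IOI never occurred in training
extends the candidate set for that event only, receiving the
escape-to-base mass of a single unseen symbol; such events are counted in
the evaluation record (`n_oov`) but never produce infinite information
content.

### Priors

The category prior is the maximum-likelihood relative frequency
$p(m) = N_m / N$. Interpretation priors assign each $(m, \varphi)$ a mass
proportional to $p(m)$ with a normalizer that compensates for period
length, so categories with many phases are not penalized. The normalizer
can count admissible sixteenth-note phases ($T_m/6$, the default, under
which the grid prior sums to exactly 1) or raw ticks ($T_m$); the two
differ only by a constant factor, hence give identical posteriors — the
`eq4_normalizer` flag exists to make that equivalence explicit and
testable. `set_manual_prior()` replaces $p(m)$ without touching the
trained sequence models, which is how the inferential-bias harness induces
biases that are attributable to the prior alone.

## The meter-agnostic baseline

`train_ioi_model()` fits the same PPM* machinery to raw inter-onset
intervals, with no latent meter or phase. It scores every event from the
second onward (the first has no defined interval). For prediction-error
comparisons the meter model is therefore run with
`include_first_event = FALSE`, so both models score exactly the same
events; `run_baseline_comparison()` enforces this and asserts the counts
match.

## Synthetic cultures

`sample_corpus()` draws annotated corpora from the generative story the
model assumes: category from a prior, phase fixed at 0 (the annotation
convention), the bar-1 downbeat always an onset, and every other
sixteenth-grid position an independent Bernoulli draw from a per-position
onset-probability profile. An optional first-order dependency mixes the
profile with a preference for particular gaps since the previous onset,
giving corpora sequential structure that a zeroth-order model cannot
represent.

Two presets ship with the package. Culture `"A"` is a simple-meter culture
(2/4 with prior 0.7, 3/4 with 0.3); culture `"B"` is a compound-meter
culture (6/8 with 0.7, 2/4 with 0.3) whose profiles peak on ternary
positions and whose gap preference is 3 and 6 sixteenths rather than 2 and
4. The preset profiles were designed around three considerations and then
frozen:

* a deep beat hierarchy (downbeats near 0.92, secondary beats 0.35–0.6,
  weak sixteenths 0.04), mirroring the strongly skewed onset statistics of
  folk-song corpora;
* *asymmetry* across beats within the bar — without it, profiles are
  translation-symmetric and phase is fundamentally unidentifiable;
* moderate onset density with varied intervals, so that neither the
  positional profile nor the interval distribution alone trivializes
  prediction.

Rhythms are eight bars long, which is a typical folk-phrase length and
gives the posterior enough events to resolve phase and category. The
default study sizes used by the tests and the acceptance script are 500
training and 100 test rhythms per culture; at those sizes, order-1
classification accuracy on culture A sits well above 0.9 and the
enculturation contrasts exceed a bit of information content.

What the generator deliberately does **not** emulate: expressive
microtiming (everything is grid-quantized), rests and durations as
distinct symbols, melodic structure, tempo, and long-range form beyond the
bar (the profile is the same for every bar). Passing tests on these
corpora therefore show that the inference machinery recovers the
statistical structure this generator produces; they do not by themselves
establish performance on real folk-song collections, which have richer
sequential regularities. The `**kern` importer exists so users can run the
same harnesses on real corpora they obtain themselves.

## Numerical and design choices

* All likelihood accumulation is in the log2 domain with a max-shift
  renormalization per update; rhythms of 50+ events underflow linear
  products.
* Classification ties are broken deterministically: categories in
  alphabetical label order, then smallest phase.
* Alphabet iteration orders are sorted (pairs lexicographically), so all
  results are reproducible bit for bit under fixed seeds.
* Degenerate inputs: empty rhythms cannot be classified; a corpus of
  single-onset rhythms has no IOI alphabet and is rejected as unusable; a
  one-event rhythm evaluated with first events excluded reports zero
  scored events and an undefined mean IC rather than a fabricated value.
* Fold assignment is a seeded shuffle with round-robin allocation (sizes
  within one of each other, exact partition), unstratified by default with
  a stratified option.
* Cross-validated scores are averaged per fold first and then across folds
  (per-event pooled averaging is available via `aggregate = "pooled"`).

## Known limitations

Metrical categories are independent models; structural similarity between
meters (e.g. 3/4 and 6/8 sharing a bar period) is not shared statistically,
and rhythms can only be interpreted in categories present in the training
data — a cross-cultural model cannot be "correct" on a meter it has never
heard. The phase grid is fixed at sixteenth notes; finer anacrusis offsets
are representable in ticks but not searched. The `**kern` importer is
best-effort (monophonic spines, recip durations, ties, rests, grace notes,
pickup-bar shifting) rather than a full Humdrum implementation; the native
JSON-lines format is the contract.
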