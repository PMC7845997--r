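---
title: "Compressing binary sequences in a language of thought: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compressing binary sequences in a language of thought: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(binlot)
```

## The model

`binlot` implements a compression account of human memory for binary
sequences (two arbitrary items A and B: high/low tones, red/green patches).
The hypothesis is that people do not store such a sequence as a verbatim
chain but re-encode it as a short program in a minimal "language of
thought", and that the length of the shortest program predicts the
sequence's psychological complexity: how complex it is judged to be and how
hard it is to detect rare violations of it.

The language has two primitive instructions over the current state:

* `+0` ("stay"): emit the current item;
* `b` ("flip"): move to the other item and emit it.

Programs are built by *concatenation* (commas) and *repetition*:
`[expr]^n` runs `expr` n times, optionally with a silent transform
`<+0>`/`<b>` applied to the state after **every** repetition (including the
last) without emitting anything. So `[+0]^4` emits `AAAA`, `[+0]^4<b>`
emits `ABAB`, and `[[+0]^8]^2<b>` emits `AAAAAAAABBBBBBBB`. The grammar is
recursive: repetitions of repetitions express "chunks of chunks", which is
the feature that separates this account from flat chunking models.

Two useful structural facts the implementation leans on:

* **Complement symmetry.** Instructions are relative to the current state,
  so running any expression from the flipped start state flips its entire
  output and end state. The item labels are therefore arbitrary and every
  sequence is canonicalized to start with A before analysis.
* **Statefulness of the silent transform.** Because the transform also
  fires after the last repetition, it changes the state seen by whatever is
  concatenated next. This convention is required: it is the only reading
  under which `ABAAAB` has the printed minimal cost via
  `[+0]^2<b>,[+0]^3,b`.

## The cost scheme

The description length of an expression is

$$ C(e) \;=\; w \cdot \#\{\text{instruction occurrences}\} \;+\;
   \sum_{\text{repeats}} \lceil \log_{10} n \rceil , $$

where instruction occurrences count emitting atoms *and* silent transforms,
each once as written, and the digit term charges the decimal digits of each
repetition count, with $n = 1$ free. The defaults are $w = 2$ and a unit
digit weight. These two numbers are not stated as such in the published
account, which defers them to earlier work; they are, however, uniquely
determined by jointly solving the published worked values
(`AAAAAABBBBBB` = 6 "two instructions and two digits", `ABBAAB` = 5,
`ABAAAB` = 10, `ABBAABABBAAB` = 8, LoT-chunk of `ABBAAB` = 9): an
over-determined and consistent linear system. With these weights a single
repetition already compresses (`[+0]^2` costs 3, `+0,+0` costs 4), which
the theory requires.

One literal-minded wrinkle: "rounded-up log10" and "number of written
digits" disagree at $n = 10$ (cost 1 vs 2). No published value
disambiguates; `lot_digit_cost()` implements $\lceil\log_{10} n\rceil$
literally, so $n = 10$ costs 1.

## Exact minimization

`minimal_description()` finds the true minimum by dynamic programming, not
heuristics. The table cell $C(i, j, s, e)$ holds the cheapest expression
emitting the substring $x_{i..j}$ when entered in state $s$ and left in
state $e$ (end states matter because trailing silent transforms change what
a following term sees). Atoms fill length-1 cells; concatenation is a
split over an intermediate state; a repetition of block length $L$ and
count $n$ is admissible iff the $n$ blocks are either all equal
(per-repetition state shift "same") or alternately complemented (shift
"flip") -- a direct consequence of complement symmetry -- with the silent
transform chosen to realise the shift. Count-1 repetitions with a `<b>`
transform are kept in the space as the only silent state change; they never
improve the minimum at the default weights but keep the grammar total.
All cost-tied minimal expressions are reconstructed (concatenations kept
flat, so each distinct tree appears once), and the reported depth is the
minimum hierarchical depth among the ties.

Correctness is defined by oracle equivalence, not by trust in the DP:
`enumerate_descriptions()` generates *every* canonical expression of the
right emission length below a cost budget by structural recursion that
never looks at the target, evaluates each from A, and keeps the matches.
The test suite proves DP = brute force for **all** canonical sequences of
length 1-8, plain and chunk-preserving (the flat atom-by-atom program
bounds the minimum by $2n$, so a budget of $2n$ is always sufficient).

## The chunk-preserving variant

Minimal programs sometimes cut across runs of identical items (for
`ABBAAB` the unrestricted optimum `[+0,b]^3` parses it as `AB|BA|AB`).
The chunk-preserving variant models a parser that first segments the
sequence into runs and only then compresses: expressions whose repetition
boundaries would split a run are excluded. Precisely, for every repetition
whose body emits **two or more** items, the emission boundaries between
consecutive repetitions *and* the outer edges where the repeated span meets
neighbouring emissions must separate different items; repetitions of a
single-item body are exempt, since they are what *builds* a run
(`[+0]^8`). The outer-edge half of the rule is our inference -- only the
single published value (LoT-chunk of `ABBAAB` = 9) pins the rule down --
and the enumeration oracle applies the same rule to every *realized*
repetition span, so the two independent implementations are checked
against each other exhaustively at small lengths. The restricted minimum
is never below the plain one, and the two coincide for sequences whose
optimal parse already respects run boundaries (all four `A^nB^n`
16-item patterns keep cost 6).

## Rival complexity metrics

Six previously proposed measures are implemented for the model race.
Worked examples from the published account are frozen into unit tests.

* **Chunk complexity**: $\sum_i \log_2(1 + L_i)$ over maximal runs.
* **Pair entropy**: Shannon entropy of adjacent pairs factored as
  $p(X)p(Y|X)$, with marginal item frequencies, maximum-likelihood
  transitions from one linear pass, and $0\log 0 = 0$; bounded by 2 bits.
* **LZ78**: phrases of the incremental parse (shortest prefix not yet in
  the vocabulary); a final incomplete phrase counts one entry, behind a
  flag, since the published worked example ends on a complete parse and
  cannot decide the convention.
* **Subsymmetries**: contiguous palindromic substrings of length >= 2,
  counted by centre expansion and verified against an $O(n^3)$ brute force.
* **Change complexity**: see below.
* **ACSS**: algorithmic complexity of short strings is *not* recomputed;
  an exact-string lookup into a user-supplied published table is provided,
  trying both labelings and returning `NA` (never an error) for absent
  patterns, e.g. all 16-item patterns.

### Change complexity is a reconstruction

The change-based measure is described in the published account only by its
properties; the defining reference was not available when this package was
written, and published variants differ. Following the package's stated
policy, `change_complexity()` is a documented reconstruction that
satisfies every printed constraint exactly: the per-item change signal
(XOR of adjacent items) is segmented into maximal change episodes, and each
episode of length $L$ contributes $\log_2(1+L)$ -- the run-encoding cost of
the change signal's active stretches. Constant sequences score 0; the
printed factor-3 relation between `AAABBB` and `AAABBBAAABBB` holds
exactly; the measure is relabeling-invariant, cheap for pure alternations
(one long episode) and periodic patterns, expensive for irregular mixtures,
and bounded near $n/2$. It should **not** be expected to reproduce the
reference implementation's numeric values; conclusions that depend on the
exact published variant should use that variant.

## Surprise from fixed transition probabilities

In the violation paradigm the standard sequence is fully learned during
habituation, so the statistical rival is an observer holding *fixed*
first-order transition probabilities estimated from a single linear pass of
the standard (no wrap-around between repetitions -- forced by the published
$p(A|B) = 0$ for `A^8B^8`, which a circular count would make $1/8$).
Deviant surprise is $-\log_2 p(\text{deviant} \mid \text{previous
original item})$. Exact-zero probabilities are padded to 0.01 (padding
only, no smoothing of non-zero probabilities), capping surprise at about
6.64 bits; a `drop_zero` companion reproduces the control analysis that
excludes those trials instead. Super-deviants (a third item C) have no
transition probability and carry no surprise value. The source prints
$-\log_2(0.875) \approx 0.18$ bits; the true value 0.1926 is what the
formula -- and this package -- returns.

## Behavioral scoring

* **Classification**: on deviant trials a response 200-2500 ms after
  deviant onset (inclusive) is a hit, anything else a miss; on standard
  trials any response is a false alarm. Negative latencies are dropped
  with a warning.
* **Trimming**: within each participant x sequence x deviant-type cell,
  hit RTs further than 2.5 SD from the cell median are excluded from RT
  statistics. The SD is computed *leave-one-out* (over the other RTs of
  the cell): with a plain within-cell SD a single extreme response
  inflates the SD enough to mask itself, and the procedure would remove
  almost nothing. Under Gaussian RTs the leave-one-out rule removes on
  the order of 1-3% of responses, matching the published 1.2-2.4% rates.
  Trimmed trials stay hits for miss-rate purposes, keeping miss rate a
  pure detection measure (the published account is silent on this point).
* **LISAS**: $RT_c + MR \cdot S_{RT}/S_{MR}$ per participant x sequence x
  deviant type, where $S_{RT}$ and $S_{MR}$ are the participant's overall
  SDs across all their deviant trials of the experiment (after trimming),
  the miss indicator being a 0/1 trial-level variable. $MR = 0$ gives
  $RT_c$ exactly; $S_{MR} = 0$ with misses present is an explicit error.
* **Exclusion**: a participant whose mean miss rate, mean RT or mean
  false-alarm count *strictly* exceeds the group median + 2.5 group SD
  (SD taken around the median, as printed) is excluded, with reasons
  logged; ties are kept.

## Model comparison

All mixed models are `response ~ predictor (+ surprise) + (1 |
participant)`, fitted by **maximum likelihood** (never REML) so that
likelihoods, AIC/BIC and likelihood-ratio tests are valid across
fixed-effect structures. The parameter count is fixed effects + 2 variance
components. Kenward-Roger degrees of freedom are deliberately not
replicated; Wald t statistics and ML likelihood-ratio tests are reported
instead -- a documented deviation that leaves the race quantities
(Delta AIC, Akaike weights) untouched, since those are insensitive to any
constant parameter-count offset. A singular fit (zero participant
variance) degrades to ordinary least squares with a flag rather than
failing. Races drop rows with a missing value in any raced predictor
listwise, mirroring the exclusion of sequences without ACSS values, so
every candidate model sees the same data; Akaike weights are computed on
shifted AICs for numerical safety.

## The synthetic generator: what a green test establishes

`simulate_trials()` emulates the deviant-detection design: per participant
x sequence cell it draws deviant trials whose RT is linear in LoT
complexity and deviant surprise with a Gaussian participant intercept and
residual (truncated at 200 ms), misses from a logistic model in the same
predictors, and Poisson false alarms on standard trials. Gaussian RTs were
chosen over lognormal for analytic transparency -- the fitted analyses are
linear either way -- with a lognormal flag provided. Default effect sizes
echo the published fixed-effect estimates (intercepts 357-852 ms by
experiment family, complexity slopes 1.4-52 ms/unit, surprise slopes -15
to -43 ms/bit, published per-sequence false-alarm means), and the five
presets reproduce the published sequence sets where they are listed in
full (all 35 balanced length-8 and all 32 length-6 patterns) and
deterministic, explicitly flagged stand-ins where the stimulus lists live
only in figures. Participant-intercept and residual SDs (150 and 250 ms)
are not printed anywhere and were chosen once as typical of RT studies.

A green parameter-recovery test therefore establishes that the *pipeline*
(simulate -> classify -> trim -> score -> fit -> race) is consistent: the
generating slope is recovered within 2 SE on the RT outcome and the
generating predictor wins the LISAS race decisively. It does **not**
establish anything about real data, which differ in at least: RT skew and
sequential dependencies, attention drift over blocks, strategic delayed
responding, miss/RT coupling beyond the shared linear predictors, and
stimulus-specific acoustic effects. The recovery criterion is run on the
mean-correct-RT outcome because LISAS deliberately mixes the miss model
into the score: its complexity slope is *expected* to exceed the RT-model
slope whenever the miss model also depends on complexity.

## Numerical choices and degenerate inputs

* Digit costs use `ceiling(round(log10(n), 12))` to guard against
  floating-point artefacts at exact powers of ten.
* The DP is exact over integers/halves; no tolerances are involved.
  Tie-breaking: all minimal expressions are returned, sorted by rendered
  notation; reconstruction is capped (`max_expressions`, flagged
  `truncated` when hit).
* Sequences of length 1 are legal everywhere except pair entropy, change
  complexity and transition estimation, which require length >= 2 by
  definition and say so.
* `lmer` fits use a fixed optimizer configuration without derivative
  re-checks, making race results deterministic for a given dataset.
* Empty catalogs, non-AB patterns, malformed notation, non-nested LRT
  pairs, zero-variance predictors and undefined conditionals all raise
  explicit, messaged errors rather than propagating `NA`s.

## Known limitations

* Change complexity is a reconstruction (above), not the published
  algorithm.
* The chunk-preserving boundary rule is pinned by a single published
  value; other readings of the "A][A" exclusion could differ on sequences
  no published number constrains.
* The enumeration oracle is exponential and practical only to length ~10;
  beyond that, correctness rests on the length <= 8 equivalence proof plus
  the structural invariants (round trip, relabeling, dominance) tested to
  length 12-16.
* p-values for single fixed effects are Wald/normal and ML-based LRTs;
  small-sample df corrections are out of scope, so single-coefficient
  p-values near threshold should not be over-read.
* The generator does not simulate the complexity-rating task or EEG/pupil
  measures; it emulates detection behavior only.
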