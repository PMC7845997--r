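# binlot

Language-of-thought compression models for human memory of binary
sequences.

## The problem

How do people hold a sequence like `AABBABABAABBABAB` in working memory?
A long line of evidence says: not as a verbatim chain, but recoded into a
compressed internal description. `binlot` implements a concrete version of
that claim for two-item (binary) sequences and the machinery to test it
against behavior. It is aimed at cognitive scientists modelling sequence
memory, statistical-learning researchers who need the rival metrics, and
anyone who wants an exact minimal-description-length engine for binary
strings.

## The model in brief

Sequences over items {A, B} are generated by programs in a minimal
recursive language with two primitives — `+0` "stay" (emit the current
item) and `b` "flip" (switch and emit) — plus concatenation (`,`) and
nested repetition `[expr]^n<t>`, where the optional silent transform `t`
is applied after every repetition. The cost of a program is

```
cost = 2 * (# instruction occurrences) + sum over repeats of ceil(log10 n)
```

and the **LoT complexity** of a sequence is the cost of its cheapest
program, found by exact search. For example `AAAAAAAABBBBBBBB` is
`[[+0]^8]^2<b>` at cost 6, and all four 16-item `A^nB^n` patterns share
that cost — the model's signature prediction that huge chunks and pure
alternation are equally easy. A **LoT-chunk** variant restricts the search
to programs whose repetition boundaries never split a run of identical
items. Six rival metrics (run/chunk complexity, pair entropy, LZ78,
subsymmetries, change complexity, an external algorithmic-complexity
lookup), a fixed transition-probability surprise model, LISAS
speed–accuracy scoring of deviant-detection trials, and an
AIC/Akaike-weight mixed-model race connect the theory to data.

## Worked example

```r
library(binlot)

enc <- minimal_description("AABBABABAABBABAB")
enc
#> <lot_encoding> AABBABABAABBABAB
#>   complexity: 11 bits | depth: 2 | 2 minimal expression(s)
#>     [[+0]^2,b,[[+0]^1<b>]^5]^2
#>     [[+0]^2,b,[+0]^5<b>]^2
```

The sequence compresses to "twice: two stays, a flip, then five
alternations" at a cost of 11 bits (two structurally distinct programs
tie; the degenerate `[x]^1<b>` form is a legal silent state change in the
grammar). Higher cost means psychologically harder: slower deviant
detection, more misses, higher subjective complexity.

```r
sequence_metrics(c("AAAAAAAABBBBBBBB", "AABBABABAABBABAB"))
#>            pattern lot lot_chunk chunk entropy lz subsym change period depth
#> 1 AAAAAAAABBBBBBBB   6         6  6.34    1.27  8     56   1.00     16     2
#> 2 AABBABABAABBABAB  11        11 14.34    1.84  7     17   6.91      8     2

deviant_surprise("AAAAAAAABBBBBBBB", 11)   # hearing A where B was learned
#> 6.643856                                  # zero-probability, padded at 0.01
```

A full synthetic study — simulate trials whose RTs really are linear in
complexity, score them, and race the predictors:

```r
sim <- simulate_trials(sim_config(n_participants = 25, seed = 42))
trials <- trim_rts(classify_trials(sim$trials))$trials
scores <- sequence_scores(trials,
                          metrics  = sequence_metrics(unique(trials$pattern)),
                          surprise = sim$truth$surprise)
model_race(scores, c("lot", "chunk", "entropy", "lz", "subsym", "change"))
```

The generating predictor (`lot + surprise`) wins with Akaike weight ~1.

There is also a command line (`inst/cli/binlot.R`):

```sh
Rscript inst/cli/binlot.R complexity AABBABABAABBABAB --all-minimal
Rscript inst/cli/binlot.R simulate --preset exp3 --seed 7 --out trials.csv
Rscript inst/cli/binlot.R score trials.csv --out scores.csv
Rscript inst/cli/binlot.R race scores.csv --out race.csv
```

## Documentation

The methods vignette (`vignettes/binary-sequence-lot.Rmd`) documents the
grammar semantics, the derivation of the cost weights, the exact-search
algorithm and its brute-force oracle, the chunk-boundary rule, every
analysis convention (trimming, LISAS, exclusions, ML mixed models), what
the synthetic generator does and does not emulate, and known limitations —
including that change complexity is a documented reconstruction validated
against its published properties rather than the original algorithm.
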