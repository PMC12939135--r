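---
title: "Methods: context-tree stimuli and the SRT reaction-time battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: context-tree stimuli and the SRT reaction-time battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(ctsrt)
```

## The stimulus model

A probabilistic context tree over a finite alphabet is a suffix-free set of
finite histories ("contexts"), each carrying a distribution over the next
symbol. At every step the unique context that is a suffix of the past
sequence determines the law of the next symbol, so memory length varies
with the history — a variable-length Markov chain. The packaged SRT tree
over `{1, 2, 3}`:

```{r}
srt_tree()
```

Because `1` always leads to `2`, and a `2` after `1` leads to either `3`
(74%) or a second `2` (26%) after which a `1` is forced, any realization
started at `1` is a concatenation of triplets `(1,2,3)` and `(1,2,2)`.
This gives the exact structural counts that `summarize_table2()` tabulates:
per 150-trial block, exactly 50 `F1` and 50 `F2` events, and 50 variable
events split stochastically between `V2` and `V3`.

Three structural invariants are enforced by `validate_tree()` and are
treated as data (violation lists), not exceptions: probability vectors sum
to one within `1e-12`; contexts are suffix-free (so the matching context
is unique); the context set is complete, i.e. every positively probable
emission from a context again ends in a context.

The transition out of stimulus 3 is not separately parameterized in the
task description the package models; it is forced to `3 → 1` with
probability one by the triplet structure — any other choice would break the
exact 50-per-block fixed-event counts — and is encoded as the deterministic
context `"3"`.

### Stationary event frequencies

`stationary_event_frequencies()` solves the left stationary vector of the
induced context chain (contexts as states, transitions induced by suffix
matching after each emission) by direct linear solve, after an
irreducibility check via reachability of `(I + P)^{k-1}`. Event label
frequencies fold emission probabilities into the stationary mass:

```{r}
stationary_event_frequencies(srt_tree())
expected_event_counts(srt_tree(), 750)
```

For the SRT tree the chain over `{"1","12","22","3"}` has stationary mass
`1/3, 1/3, 0.26/3, 0.74/3`, giving the 250 / 250 / 65 / 185 expectation per
750 trials. Note that the per-block split of the 65 variable-2 events is a
property of one realization, not of the model; the package reproduces it
in expectation only.

### Labeling conventions

Events are labeled `F<symbol>` when the generating context is
deterministic and `V<symbol>` otherwise. Two edge conventions matter:

* **Leading symbols.** The first stimulus has no history and hence no
  matchable context. A position like this is labeled by the symbol's class
  when that class is unambiguous over the whole tree (symbol 1 is emitted
  only by deterministic contexts, so a leading 1 is `F1`); otherwise it is
  `UNKNOWN`. This keeps the exact per-block counts intact for sessions
  started at `1`.
* **Impossible symbols.** An observed symbol with zero probability under
  its matched context (possible only in externally supplied data) raises a
  warning and falls back to the same symbol-class rule.

`annotate_last_variable()` reports, per position, the label of the most
recent *strictly preceding* `V2`/`V3`, with `"NONE"` before the first
variable event — the conditioning factor of the event-by-last-variable
analysis.

### RNG contract

`generate_sequence(tree, n, seed)` is a pure function of its arguments:
the caller's RNG state is saved and restored, one uniform variate is
consumed per variable-context emission and none per deterministic one, so
fully deterministic trees are seed-independent. Generation runs on a
precomputed context-to-context transition table (integer states), keeping
the per-symbol cost constant.

## The synthetic cohort generator

`simulate_cohort()` exists so that every downstream stage is testable at
the study's design size without participant data: two groups (motor
execution, ME; motor imagery, MI) of 10 subjects, each hearing 750 stimuli
in 5 blocks of 150, with a 2000 ms response window and a per-trial error
probability of 0.001 — the shape and rates of the experiment the package
models. A trial's RT is assembled additively (all units milliseconds):

```
rt = baseline(group) + subject intercept + block effect(group, block)
   + within-block slope(group, block) * (sub_block - 1)
   + event offset(group, event) + last-variable interaction(group, event, last_var)
   + trial noise
```

Default planted effects are demonstration values chosen once to mirror the
qualitative pattern reported for this paradigm, never as estimates of any
participant data: ME baseline 450 ms with no across-block trend but
negative within-block slopes in early blocks; MI baseline 900 ms (imagery
durations run much longer) with a monotone across-block improvement
(0 to −120 ms) and larger event differentiation; a crossed
event × last-variable interaction (±15 ms on `F1`/`F2` for ME, ±25 ms on
`V2`/`V3` for MI, faster after a matching variable event). Trial-level
variance is not reported for the experiment, so `subject_sd_ms = 50` and
`noise_sd_ms = 150` are placeholders at the scale typical of RT tasks, and
are flagged as such. All fields are overridable through
`default_config(...)`; `null_config()` zeroes every planted effect for
type-I calibration.

Further generator choices:

* **Noise family.** Lognormal by default (fixed shape `sdlog = 0.5`,
  scale solved so the residual SD equals `noise_sd_ms`, mean-centered),
  because RT residuals are right-skewed; a Gaussian option exists for
  analytic checks.
* **Censoring.** Draws outside `(0, 2000)` ms are redrawn up to 100 times;
  a trial still outside is marked incorrect rather than clamped, avoiding
  a point mass at the window edge. Incorrect trials keep an RT (the task
  waited for the correct key) and are excluded by `filter_trials()`, not
  deleted.
* **Sequences.** By default each subject receives an independent stimulus
  realization (per-subject seeds derived from the cohort seed);
  `shared_sequence = TRUE` gives all subjects one realization, since the
  paradigm admits either protocol.
* **Timing constants.** The 500 ms anticipatory window and 220 ms stimulus
  duration are carried in the config for documentation only: RT is defined
  from stimulus end, so they never enter generation.

What the generator does *not* emulate: sequential dependence of errors,
fatigue or attention drift within a session, anticipatory (negative-onset)
responses, inter-trial RT autocorrelation, and learning curves within a
cell beyond the linear sub-block trend. Passing tests therefore show the
battery behaves correctly under the planted additive model, not that the
model captures every feature of real RT data.

## Preprocessing

`filter_trials()` keeps correct responses with RT strictly below the 2 s
window ("smaller than 2 s" is read as a strict inequality; a trial at
exactly 2000 ms is excluded). `cell_means()` aggregates to per-subject
mean RTs over any subset of `{block, event, last_var}`; `last_var = "NONE"`
trials are excluded only when `last_var` is a design factor. When the
block factor is collapsed for the mixed design, the default pools trials
with equal weight per trial (`collapse = "pooled"`) rather than averaging
block means, because variable events are unevenly spread over blocks and
block-mean averaging would overweight sparse cells; the alternative is
available behind `collapse = "block_mean"`. Sub-block means partition each
150-trial block into three consecutive 50-trial thirds, disregarding event
type.

Missing cells (a subject with no retained `V2` trial in some block — the
rare 26% event can vanish from a short block after filtering) propagate as
missing: the affected subject is removed from that specific ANOVA
(complete-case repeated measures) with a warning, and the simulation
harness counts such replicates rather than silently absorbing them.

## The statistical battery

* **Rank transform.** `rank_transform()` pools *all* subject × cell means
  entering one ANOVA and assigns ranks `1..N` with average ranks for ties
  (the Conover–Iman RT-1 convention). Pooling over the whole table — the
  scope is a design choice — makes the resulting tests invariant under any
  strictly monotone transform of the RTs.
* **Repeated measures.** `rm_anova2()` computes the classical balanced
  two-way within decomposition; each effect is tested against its own
  subject-by-effect stratum. Degenerate inputs follow fixed conventions:
  a zero effect mean square gives `F = 0` (constant tables), a zero error
  stratum with signal gives `F = Inf`.
* **Sphericity.** For every within effect with more than 1 numerator df,
  the Greenhouse–Geisser epsilon is computed from the covariance of
  orthonormal contrast scores, and Mauchly's test (chi-square
  approximation with the standard second-order term) decides whether the
  corrected p is flagged as applied (Mauchly p < 0.05); both raw and
  corrected p are always reported. With 10 subjects the 12-dimensional
  Block × Event contrast space exceeds the covariance rank, so Mauchly's W
  is undefined there and reported as `NA` — an honest limit of the design
  size, shared by any implementation.
* **Mixed (split-plot).** `mixed_anova()` tests the between factor against
  subjects-within-groups and the within factor and interaction against
  the within-error stratum, with epsilon from the group-pooled covariance.
  Following the analysis convention of the paradigm, the mixed design runs
  on untransformed means (the rank transform is used in the within-group
  designs only).
* **Follow-ups.** `pairwise_bonferroni()` uses paired t-tests for within
  factors and Welch tests between groups; the family is the set of
  comparisons produced in one call (all level pairs, or simple effects via
  `split_by`), `m` is recorded in the output, and adjusted
  `p = min(1, m·p)` with tiers at 0.05/0.01 matching the usual figure bar
  conventions. Two-sided throughout.
* **Sub-block slopes.** Per subject × block, the OLS slope of the three
  sub-block means against index 1..3 (closed form `(y3 − y1)/2` for three
  equally spaced points), then a two-sided one-sample t-test of the
  subjects' slopes against zero, `df = n − 1`. Zero-variance slope sets
  are flagged rather than erroring.
* **Harness.** `error_rate_harness()` simulates cohorts, runs a named
  design per replicate (using the GG-corrected p whenever the correction
  was flagged), and reports rejection fractions with exact binomial
  confidence intervals, fully seeded.

Both ANOVA paths are verified in the test suite against an independent
brute-force oracle (sequential sums of squares of the full `lm()`
factorial, assembled into stratum F ratios) to `1e-8` relative error on
batches of random small designs, and against `aov()` error strata and the
base `mlm` sphericity machinery on selected cases.

## Problem sizes in the test suite

The packaged checks run the structural sequence tests at the full
750-trial session size, transition-probability recovery on 3 × 10^5
symbols (10^5 variable events), type-I calibration with 500 null cohorts
at the full 10-subject design, and power checks with 500 cohorts at a
reduced size (6 subjects per group, 5 blocks of 50 trials) chosen so the
planted effects still saturate the tests; parameter recovery for slopes
uses one full-size cohort. These sizes are the package's own trade-off
between Monte-Carlo resolution and suite runtime.

## Known limitations

* The ANOVA routines require balanced complete-case tables; unbalanced
  between-group sizes are accepted arithmetically but the split-plot
  decomposition is exact only for equal group sizes.
* Huynh–Feldt epsilon is not computed (Greenhouse–Geisser only), and no
  multivariate (MANOVA) alternative is offered.
* Context-tree *estimation* from data (context selection, BIC pruning) is
  out of scope; the tree is an input.
* The generator's additive, homoscedastic planted model is a tool for
  validating the analysis code, not a cognitive model of motor imagery.
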