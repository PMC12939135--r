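# ctsrt

Context-tree stimulus generation and reaction-time analysis for serial
reaction time (SRT) experiments.

## The problem

In SRT sequence-learning studies, participants respond to a stream of
stimuli whose order follows hidden regularities; shrinking reaction times
(RTs) index learning of those regularities. A powerful way to build such
streams is a **probabilistic context tree** (a variable-length Markov
chain): a suffix-free set of contexts `w`, each with a next-symbol
distribution `p(· | w)`, where the generating context of the next symbol is
the unique `w` that is a suffix of the past sequence. This mixes
deterministic transitions with intrinsic variability, emulating the
unpredictability of natural sequential environments.

`ctsrt` packages the computational core of such an experiment comparing
**motor execution (ME)** with **motor imagery (MI)** — imagining rather
than performing the cued finger movement:

* the three-symbol stimulus tree with contexts
  `"1" → 2 (p=1)`, `"12" → 3 (p=0.74) / 2 (p=0.26)`, `"22" → 1 (p=1)`,
  `"3" → 1 (p=1)`, so every realization started at `1` concatenates the
  triplets `(1,2,3)` and `(1,2,2)`;
* event labeling — `F1`, `F2` for deterministically generated stimuli,
  `V2`, `V3` for the variable ones — plus the *last variable event*
  annotation that conditions each trial on the most recent `V2`/`V3`;
* analytic stationary event frequencies (`F1 = F2 = 1/3`,
  `V2 = 0.26/3`, `V3 = 0.74/3`, i.e. 250/250/65/185 expected events per
  750 trials);
* a trial-level synthetic cohort generator (2 groups × 10 subjects ×
  5 blocks × 150 trials, 2 s response window) with planted learning
  effects, subject heterogeneity and right-skewed trial noise;
* the statistical battery: trial filtering (correct responses under 2 s),
  per-subject cell means, rank-transformed two-way repeated-measures
  ANOVA (Block × Event), two-way mixed ANOVA (Group × Event) with
  Mauchly/Greenhouse–Geisser sphericity handling, Bonferroni pairwise
  follow-ups, per-subject 50-trial sub-block slope tests of within-block
  learning, and simulation harnesses for type-I error and power.

## Worked example

```r
library(ctsrt)
tree <- srt_tree()
seq9 <- generate_sequence(tree, 9, seed = 1)
ev   <- label_events(tree, seq9)
rbind(seq9, ev, lastvar = annotate_last_variable(ev))
#> symbols:  1  2  3  1  2  3  1  2  3
#> events:   F1 F2 V3 F1 F2 V3 F1 F2 V3
#> lastvar:  NONE NONE NONE V3 V3 V3 V3 V3 V3

expected_event_counts(tree, 750)
#>  F1  F2  V2  V3
#> 250 250  65 185

coh    <- simulate_cohort(default_config(seed = 20))
trials <- filter_trials(coh)$trials
cm     <- cell_means(trials, c("block", "event"))
rm_anova2(cm[cm$group == "MI", ], use_ranks = TRUE)
#> ANOVA (10 subjects; repeated measures, rank-transformed)
#>       effect df_num df_den       F         p ...
#>        block      4     36  85.370 7.363e-18
#>        event      3     27 119.200 1.102e-15
#>  block:event     12    108   1.394 1.797e-01
```

The rank-transformed repeated-measures ANOVA on the simulated MI group
recovers the planted structure: a strong Block effect (the planted
across-block improvement, up to −120 ms by block 5), a strong Event effect
(planted event offsets, V2 being slowest because it is the rare 26% event),
and no Block × Event interaction (none is planted). The degrees of freedom
(4, 36), (3, 27) and (12, 108) are exactly those of a 10-subject,
5-block × 4-event within design. The mixed Group × Event ANOVA on
block-collapsed means likewise shows the planted group baseline difference
and Group × Event interaction, and `subblock_slope_test()` recovers the
planted within-block slopes (for example, MI block 1:
`mean_slope = -16.9 ms / sub-block, t(9) = -3.47, p = 0.007`).

A full report (sequence, cohort, every ANOVA, slopes, pairwise tables and
an MD5 manifest) is produced by

```r
run_pipeline(default_config(seed = 20), "srt_report")
```

or from the shell via the thin CLI in `inst/cli/ctsrt.R`
(`generate-sequence`, `simulate`, `aggregate`, `analyze`, `table2`, `run`).

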