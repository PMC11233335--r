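# affectlba

Hierarchical Bayesian linear ballistic accumulator (LBA) modelling of
two-choice emotional reports, built around one question from affective
science: does the *anticipated effort* of an upcoming task act as
emotional evidence? In the design this package models, each trial cues an
upcoming visual search that is either easy (a colour or shape feature
search) or difficult (a conjunction search), then shows a normed emotional
picture, and the participant reports whether it makes them feel pleasant
or unpleasant. If anticipated effort feels bad, it should speed the
accumulation of negative emotional evidence — visible not in mean RTs but
in the drift rates of an evidence-accumulation model.

## The model

Each response option has an LBA accumulator: evidence starts at a point
drawn uniformly from `[0, A]`, grows linearly at a trial-specific rate
drawn from `N(v, sv)`, and triggers the response at the boundary
`b = A + B`; observed RT is the winner's finishing time plus a
non-decision time `t0`. Accumulators are coded relative to the picture's
valence norm (1–9 scale): the **normative** accumulator collects evidence
for the report that agrees with the norm (below 5 → "unpleasant"), the
**aberrant** accumulator for the counter-normative report. The *core*
model lets `B` and both drift rates vary over the four design cells
(pleasantness × anticipated difficulty) while sharing `A` and `t0`; the
*null* model shares everything. Subject-level parameters are pooled
through truncated-normal population distributions and estimated jointly by
an ensemble (differential-evolution family) MCMC sampler; model adequacy
uses Gelman–Rubin diagnostics and participant-summed DIC; inference on the
fitted drift rates uses default-prior Bayes factors (2×2 repeated-measures
BANOVA and JZS paired t-tests). A synthetic-experiment generator with the
full counterbalanced design makes every stage testable end to end.

See the methods vignette (`vignettes/anticipated-effort-lba.Rmd`) for the
model's assumptions, the preprocessing rules, the sampler's move set, and
the package's design decisions.

## A worked example

Simulate a small cohort with known truth, preprocess it, and fit the
core model:

```r
library(affectlba)

cohort <- gen_dataset(generator_config(n_participants = 6), seed = 42)
d <- cohort$trials
d$choice <- code_response(d$picture_norm, d$report)
pp <- preprocess(d)
pp$report
#> Preprocessing: 1440 trials in, 1403 out
#>   participants_aberrant_gt_50pct   removed     0 of   1440 (0.00%)
#>   pictures_normative_lt_50pct      removed    18 of   1440 (1.25%)
#>     pictures:  pic142, pic167, pic178
#>   rt_window                        removed     1 of   1422 (0.07%)
#>   rt_zscore                        removed    18 of   1421 (1.27%)
```

With only six participants, a few pleasant pictures legitimately fall
below the 50% normative-response bar, and a fraction of a percent of
trials sits in the RT tails — the filters exist to trim exactly such
cases. Fitting the core model and reading off the population-location
posterior means:

```r
fit <- fit_lba(pp$trials, model = "core",
               control = sampler_control(seed = 1))
round(coef(fit), 2)
#>                           A                          t0
#>                        2.08                        0.25
#>           B.unpleasant.easy      B.unpleasant.difficult
#>                        1.93                        1.63
#>             B.pleasant.easy        B.pleasant.difficult
#>                        1.95                        1.84
#>      v_norm.unpleasant.easy v_norm.unpleasant.difficult
#>                        2.97                        3.12
#>        v_norm.pleasant.easy   v_norm.pleasant.difficult
#>                        2.35                        2.09
#>        v_ab.unpleasant.easy   v_ab.unpleasant.difficult
#>                        0.54                       -0.12
#>          v_ab.pleasant.easy     v_ab.pleasant.difficult
#>                        0.70                        0.64
```

The generating truth for this cohort was the package default (normative
drifts 2.942 / 3.172 / 2.239 / 2.148; aberrant 0.017 unpleasant, 0.742
pleasant; A = 2, t0 = 0.3): even at six subjects the recovered normative
drifts sit within about 0.1–0.2 of it. Downstream inference mirrors the
analysis structure of the study design:

```r
res <- drift_banova(fit)
res$normative
#> 2x2 repeated-measures Bayesian ANOVA (default g-priors)
#>   main effect pleasantness: BF10 = 6.96e+06
#>   main effect difficulty:   BF10 = 0.3153
#>   interaction:              BF10 = 2.674
res$percent_change_unpleasant
#> [1] 3.14
res$t_tests$unpleasant
#> BF10 = 0.4778 (BF01 = 2.093)
#>   t = 0.790, n = 6, prior scale r = 0.707
#>   numerical error ~ 2e-11
```

Unpleasant pictures carry decisively more normative drift than pleasant
ones, while at this small scale the difficulty effect and its follow-up
t-test remain undecided — detecting the few-percent drift increase under
anticipated effort needs the larger cohorts the simulation studies use.

The six-stage pipeline (`run_pipeline()`: simulate → preprocess → fit →
compare → banova → report) writes the same analyses as self-describing
artifact directories with JSON manifests.

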