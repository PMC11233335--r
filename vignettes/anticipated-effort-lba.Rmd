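---
title: "Modelling anticipated effort as emotional evidence with a hierarchical LBA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling anticipated effort as emotional evidence with a hierarchical LBA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question and the model

When people report how a picture makes them feel, the report is a decision:
evidence for "pleasant" and evidence for "unpleasant" accumulate until one
reaches a threshold. `affectlba` implements an analysis of whether the
*anticipated effort* of an upcoming task (an easy feature search versus a
difficult conjunction search, announced by a cue before the picture) acts as
evidence in that decision — specifically, whether anticipating effort speeds
the accumulation of negative emotional evidence.

The decision model is the linear ballistic accumulator (LBA). Each response
option has an accumulator; on each trial accumulator $i$ starts at a point
drawn uniformly from $[0, A]$, accrues evidence linearly at a rate drawn
once per trial from $\mathcal N(v_i, s_v)$, and triggers its response on
reaching the boundary $b = A + B$. The first accumulator to finish
determines the choice, and the reaction time is the winner's finishing time
plus a non-decision time $t_0$ (encoding and motor execution). There is no
within-trial noise: the race is ballistic, and all RT variability comes
from the start-point and drift-rate variability.

The two accumulators are coded *stimulus-relative*: the **normative**
accumulator drives the report that agrees with the picture's population
valence norm (on a 1–9 scale, norms below 5 make "unpleasant" the normative
report), and the **aberrant** accumulator drives the counter-normative
report. The design crosses picture pleasantness (pleasant/unpleasant, from
the norm) with anticipated search difficulty (easy: colour or shape cue;
difficult: conjunction cue), giving four cells.

Two model variants are fitted:

* the **null model** shares all five subject-level parameters ($A$, $B$,
  $t_0$, $v_{\text{norm}}$, $v_{\text{ab}}$) across cells;
* the **core model** shares $A$ and $t_0$ but splits $B$ and both drift
  rates by cell — 14 free parameters per subject. Setting the split
  parameters equal reproduces the null model's likelihood exactly (the
  models are nested), which the test suite checks bit-for-bit.

$s_v$ is fixed at 1 for both accumulators. Some such constraint is
mandatory: multiplying $A$, $B$ and both drifts by a common factor leaves
every finishing time unchanged, so the model is only identified relative to
a fixed scale. Fixing the drift dispersion is the conventional choice.

### Drift-sign conventions

A normal drift distribution puts mass on negative rates, which never reach
the boundary. Two conventions are implemented and exposed as
`convention = "truncated"` (default) or `"defective"`:

* **truncated** — each accumulator's drift is conditioned on being
  positive (densities renormalised by $\Phi(v/s_v)$). Every trial
  terminates, which matches a task in which a response always occurred
  within the 8-second display window.
* **defective** — negative drifts never finish; the race has a
  non-termination probability $\prod_i \Phi(-v_i/s_v)$. Simulated
  non-terminating trials are flagged censored, never silently dropped.

The likelihood of an observed (choice, RT) pair is the *defective density*
$f_w(t - t_0)\,[1 - F_\ell(t - t_0)]$ — the winner's finishing density
times the probability the loser is unfinished. The closed forms, their
normalisation (choice probabilities plus non-termination mass sum to one),
and their agreement with a brute-force simulator are property-tested on
parameter grids under both conventions.

## Preprocessing

`preprocess()` applies four filters in a fixed order, with an audit report
of per-step counts and percentages (relative to the trials remaining
before each step):

1. participants with strictly more than 50% aberrant responses;
2. pictures whose across-participant normative-response rate falls
   strictly below 50%;
3. trials with RT $\ge$ 6.1 s or $\le$ 200 ms (both bounds inclusive);
4. trials beyond 3.5 absolute within-cell z-scores (strict), where a cell
   is participant × pleasantness × difficulty.

Step 4's grouping deserves a note: grouping by individual picture is not
meaningful here because each picture occurs once per participant, so the
cell is defined by the picture's *valence* instead. z-scores are
moment-based (mean/SD), not robust; cells with fewer than two trials are
skipped and logged, and a zero-variance cell removes nothing. Because the
z-score step changes the moments it is computed from, re-running the
pipeline on its own output can remove a few further trials; steps 1–3 are
exactly idempotent and step 4 reaches a fixpoint quickly, which is tested.

With realistic right-skewed RT distributions a large *clean* dataset will
legitimately lose a fraction of a percent of trials to steps 3–4 — these
filters trim tails, and continuous distributions have tails. The exact
round-trip test for contaminant bookkeeping therefore uses a fixture whose
clean decision times are *bounded* (a small drift SD leaves the uniform
start point as the only variability), so that no clean trial can trip any
filter and injected counts must match report counts exactly.

## Hierarchical estimation

Subject-level parameter vectors $\theta_s$ are modelled as draws from
truncated-normal population distributions,
$\theta_{sj} \sim \mathcal N(\mu_j, \sigma_j^2)$ truncated to the
parameter's support ($[0,\infty)$ for $A$, $B$, $t_0$; unbounded for
drifts), on the natural scale — no log transform, so population locations
stay in the units of the priors. The priors on the locations are normal
(truncated to the support): $A, B \sim \mathcal N(2, 0.6)$,
$t_0 \sim \mathcal N(0.3, 0.1)$, normative drift $\mathcal N(2, 0.8)$,
aberrant drift $\mathcal N(0.5, 0.8)$; in the core model each split
parameter inherits its family's prior in every cell. Population scales
carry half-normal(0, 1) hyperpriors — a weakly informative default on the
scale of the location priors.

### The sampler

`fit_lba()` estimates the joint posterior by an ensemble MCMC sampler in
the differential-evolution family. The ensemble is split into two halves
updated alternately; proposals for chains in one half use difference
vectors from the other half only (the parallel "red-black" scheme), which
keeps every half-update a product of valid Metropolis kernels while using
fresh donor states. Each iteration cycles several complementary moves:

* **subject crossover** — full-vector DE proposals per subject, with the
  donor differences taken on residuals (subject value minus the donor
  chain's population location) so that early disagreement between chains
  about the population does not corrupt proposal directions;
* **subject sub-blocks** — the same move restricted to correlated blocks
  (the shared $A, t_0$ pair; per cell the $B$/drift trio);
* **shear moves** — deterministic ridge moves along the model's two
  structural trade-offs: raising $t_0$ while lowering each $B$ by
  $\delta\,v$ (RT distributions nearly invariant), and raising $A$ while
  lowering each $B$ by $\delta/2$ (mean distance to boundary invariant).
  Both are applied per subject and globally (population plus all subjects
  jointly; unit Jacobian);
* **scaling move** — a global multiplicative move along the
  boundary/drift degeneracy described above, applied to $A$, all $B$ and
  drifts, and their population locations and scales, with the appropriate
  Jacobian;
* **population blocks** — conditional on the subjects the
  $(\mu_j, \sigma_j)$ pairs factorise, and each is updated by a 2-d DE
  step plus an independence proposal from the approximate conditional
  (normal for $\mu_j$, inverse-gamma for $\sigma_j^2$) with an exact
  Hastings correction;
* **recentring** — a non-centred move that translates and rescales
  $(\mu_j, \sigma_j)$ together with every subject's $\theta_{sj}$,
  holding standardised residuals fixed. This is the standard remedy for
  the funnel between population scales and weakly identified subject
  parameters (the near-zero aberrant drifts of unpleasant cells);
* **migration** (burn-in only) — cyclic exchanges of subject vectors and
  population pairs between random chain subsets, letting stuck chains
  adopt better-placed states.

Without the shear, scaling and recentring moves the coordinate-wise
kernels stall on exactly these ridges: chains agree with the data but
disagree with each other along $t_0\!\leftrightarrow\!B$ and the global
scale, and the Gelman-Rubin statistic plateaus far above 1.1 no matter how
long the chains run. The move set above was designed against that
diagnosis, and acceptance rates of every move are returned in the fit
object (`fit$acceptance`) so mixing pathologies stay visible.

Two sampler profiles are provided. The `"desk"` profile (default: 24
chains, 500 burn-in + 1500 sampling iterations, thinning 3, two kernel
cycles per iteration) targets simulation studies on a single CPU — a
12-subject × 480-trial core-model fit takes a few minutes. The `"paper"`
profile (42 chains, 1000 + 8000, thinning 12) mirrors the full-scale
settings of the original analysis. Chains initialise from prior draws
(with bounded retries for subjects whose likelihood underflows);
log-densities are floored at −700 per trial so the sampler can compare
degenerate states rather than dividing by zero.

## Model adequacy and comparison

`gelman_diag()` computes the classic two-part potential scale reduction
factor (with the Brooks–Gelman correction) per population parameter and
per subject × parameter, plus per-participant maxima; 1.10 is the
conventional acceptability bound. The split-chain variant is available
behind `split = TRUE`; the classic form is the default to mirror the
era's toolchain. R-hat is affine-invariant, which is tested.

`dic()` computes, for each participant, $\text{DIC} = \bar D + p_D$ with
$\bar D$ the posterior mean deviance of that participant's trials under
their own subject-level draws and $p_D = \bar D - D(\bar\theta)$ at the
posterior-mean parameters (mean plug-in, the standard definition).
Population terms are excluded — the score describes the subject-level
account of each participant's data — and the summed score is exactly the
sum of participant scores. `compare_models()` prefers the lower summed
DIC and reports whether the margin clears the conventional 6-point
decisiveness threshold. $p_D$ can go negative under multimodality; it is
reported, not hidden.

## Bayes-factor inference

The fitted core model yields a participants × cells table of posterior
means for each parameter family (`subject_cell_table()`); inference on
those tables uses default-prior Bayes factors, reimplemented here:

* `jzs_paired_bf()` — the JZS paired t-test: a Cauchy prior with scale
  $r = \sqrt2/2$ on the standardised effect, reduced to a one-dimensional
  integral over $g \sim \text{Inv-}\Gamma(1/2, r^2/2)$ and evaluated by
  adaptive quadrature. The statistic depends on the data only through
  $t$ and $n$, hence is scale-invariant, and is verified against an
  independent quadrature oracle in the non-central-$t$ parameterisation
  to $10^{-6}$ relative error.
* `rm_banova_bf()` — a 2×2 repeated-measures Bayesian ANOVA over the
  model set {subject-only, +A, +B, +A+B, full}: random subject effects
  with g-prior scale 1, fixed effects with scale 0.5 (the cited-era
  defaults, config-exposed). In a balanced design the subject indicators
  and the sum-coded contrast columns are mutually orthogonal, so each
  conditional marginal likelihood has a cheap closed form and the g's are
  integrated by seeded Monte Carlo (default $10^5$ draws) with a reported
  standard error. Draws are shared across models, so stepwise factors
  multiply coherently; main effects compare {subject+factor} against
  subject-only and the interaction compares the full model against the
  two-main-effects model. The tests verify against a dense-matrix grid
  oracle that does none of these simplifications.
* `percent_change()` — drift is ratio-scaled (zero means no
  accumulation), so a difference can be stated as a percentage of the
  lower anchor, to two decimals.

The BANOVA consumes per-subject posterior *means* — point summaries, not
full posterior draws. This matches a two-stage workflow in which the
model is fitted in one tool and the ANOVA run in another; it ignores
per-subject posterior uncertainty, a known limitation of two-stage
pipelines, and `drift_banova()` documents it rather than hiding it.

## The synthetic-experiment generator

`gen_dataset()` produces cohorts with the statistical structure the
analysis assumes: 64 participants by default, 4 blocks × 60 trials, 240
pictures with valence norms uniform in [2, 4] (unpleasant) and
[5.5, 6.5] (pleasant), cues balanced within block (30/30 valence, 20 per
cue, each cue × valence combination exactly 10 per block), subjects drawn
from truncated-normal populations, and responses simulated through the
LBA race with censoring at the 8-s window. Default generating drifts are
the reported cell means of the reference analysis (normative:
unpleasant-easy 2.942, unpleasant-difficult 3.172, pleasant-easy 2.239,
pleasant-difficult 2.148; aberrant: 0.017 unpleasant, 0.742 pleasant);
$A = 2$, $B = 2$, $t_0 = 0.3$ are the prior central values, and the
common between-subject scale of 0.2 is a convention — the true
between-subject dispersion is not recoverable from published summaries,
so recovery claims fix it by configuration. The generating truth is
returned alongside the data so any recovery claim can be scored without
re-simulation.

What the generator does *not* emulate: actual picture content, arousal,
sequential effects (each trial is exchangeable within its cell), response
omissions, and any deviation of real subjects from the LBA itself. A
passing recovery study therefore shows that the estimation machinery
recovers known truth under the model's own assumptions — it cannot show
that the model is true of real data.

`inject_contaminants()` adds the four artefact classes the preprocessing
targets, with exact bookkeeping; `gen_search_data()` adds
manipulation-check columns (lognormal search RTs with condition means
1131/1449/1832 ms and a coefficient of variation of 0.35 — the shape is a
convention, only means and error rates ≈ 0.137/0.135/0.139 are emulated).

## Problem sizes and numerical choices

The test suite exercises recovery at 12 subjects × 480 trials with the
desk profile — the scale at which the package's own simulation studies
are run — and model selection at 5 subjects × 120 trials with a lighter
sampler, sizes chosen so the full suite completes comfortably on one CPU.
Tail shortcuts in the C++ density (the normal CDF via `erfc`, hard 0/1
beyond ±8σ), the A→0 degenerate closed form, the −700 log floor, and the
quadrature tolerances (1e-9 relative for normalisation identities) are
the main numerical guards. CDF limits are approached like $O(1/t)$
(near-zero drifts finish late), so "infinity" checks evaluate far out
rather than at moderate times.

## Interfaces

The package is a library: `fit_lba()` plus its methods are the analysis
surface, and `run_pipeline()` orchestrates the six pipeline stages
(simulate, preprocess, fit, compare, banova, report) as functions writing
self-describing artifact directories — every stage records its
configuration and seed in a JSON manifest, trial tables travel as CSV,
reports as JSON, and fitted posteriors are persisted as an RDS file of
draw arrays next to their manifest. A YAML configuration file
(`read_config()`) carries model choice, drift convention, sampler
profile, generator settings, preprocessing thresholds and BANOVA prior
scales. No shell entry point is shipped; the functions and this document
are the interface.

## Known limitations

* Exact reproduction of the original study's numbers is impossible — its
  trial-level data are not deposited. The acceptance surface is recovery
  of the *printed estimates used as generating truth*, worked-example
  arithmetic, and property suites.
* The original hyperprior family for population scales is not
  recoverable from published material; the half-normal(0, 1) default is
  documented as this package's choice, not asserted as the original.
* Which drift-sign convention the original fit used is likewise
  unstated; both are provided, with truncation as the default because it
  guarantees termination within a response window.
* Two-stage BANOVA on posterior means understates per-subject
  uncertainty (see above).
* The desk sampler profile is tuned for simulation studies at a dozen
  subjects; cohorts at the full 64-subject scale should use the paper
  profile and expect proportionally longer runs.
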