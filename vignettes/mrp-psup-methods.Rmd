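---
title: "Methods: MRP and probability-of-superiority inference for ordinal surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MRP and probability-of-superiority inference for ordinal surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical machinery: the
models, the sampler, the decision rules, what the synthetic-data
generator does and does not emulate, and the numerical and design
choices a maintainer should know about. Everything quantitative stated
here is computed by the test suite or by `scripts/acceptance.R`; nothing
is asserted beyond what those runs check.

## The estimation problem

Online convenience samples are not probability samples: volunteers skew
by education, age, politics, and more, so raw sample summaries are
biased for population attitudes. Multilevel regression and
poststratification (MRP) corrects this in two steps. First a
hierarchical regression predicts the outcome from demographics:

```
y ~ sex + region + z(state hesitancy)                        # population-level
    + (1|age) + (1|education) + (1|income) + (1|race)        # varying intercepts
    + (1|party) + (1|state) + (1|sex:race) + (1|education:age)
```

Second, the fitted model predicts every cell of a poststratification
table — the cross-tabulation of those demographics with population
counts — and the population estimand is the count-weighted average of
cell predictions, per posterior draw. MRP is consistent when selection
operates through the modelled demographics; partial pooling keeps the
many sparse cells (28 800 in the default synthetic geography)
estimable.

Likert outcomes are modelled as cumulative ordinal probit: a latent
normal with unit scale (the standard identification for probit models)
crossed against K−1 ordered cutpoints. Unordered outcomes (2–3
categories, e.g. the greater/equal/less comparison variable) use a
categorical logit with the first category as reference.

### Priors

All priors are weakly informative and zero-centered
(`prior_spec()`): cutpoints and categorical intercepts normal(0, 4),
population-level coefficients normal(0, 2), group standard deviations
half-normal(0, 1). The wide scale on cutpoints matters for extreme
items — when nearly all respondents use the top categories, tighter
intercept priors distort the fit; 4 is wide enough that the data
dominate even then. The remaining scales are conventional
weakly-informative choices for probit/logit-scale effects; all three
are configurable.

## The sampler

Fits use the package's own MCMC, chosen because both model families
admit efficient classical samplers:

* **Ordinal probit** — Albert–Chib data augmentation. Conditional on the
  latent responses, every coefficient and varying intercept is a
  conjugate normal update and the group structure reduces to grouped
  sums, so an iteration is a handful of vectorized passes over the
  data. Cutpoints are updated jointly by a random-walk Metropolis step
  on `(c1, log diffs)` with the latents marginalized out (the
  step size adapts toward 25% acceptance during warmup), after which the
  latents are redrawn from their exact truncated-normal conditional.
* **Categorical logit** — slice sampling within Gibbs on each scalar's
  exact conditional; derivative-free and tuning-free, with each update
  touching only the rows of its own factor level.

Two well-known pathologies of hierarchical Gibbs samplers are addressed
directly:

* **Funnels.** Group sds get a centered slice update interweaved with a
  non-centered one (rescaling effects and sd together; conjugate
  truncated-normal in the probit case). Without the interweaving, small
  sds freeze their effects near zero for many iterations.
* **Location trade-offs.** With no global intercept, cutpoints and the
  eight sets of varying intercepts share likelihood-invariant
  translation directions — as do nested term pairs (region and the
  state covariate versus state; sex versus sex:race; education and age
  versus their interaction). These directions are detected automatically
  from the design (a fixed column or coarse factor that is measurable
  from a finer factor's levels) and resampled exactly from their
  Gaussian conditionals under the priors. These generalized-Gibbs moves
  leave the likelihood untouched and cost O(levels) each; they cut the
  worst split-R-hat on the full model at n = 2000 from ≈1.11 to ≈1.01
  within 500-draw chains.

Defaults are 4 chains × 1000 post-warmup draws with a convergence gate
that errors when any monitored split-R-hat exceeds 1.01; both are
arguments, and reduced-draw fits (with the gate relaxed explicitly) are
used in the simulation sweeps below. Split-R-hat and effective sample
size are computed for every scalar parameter; divergence counts do not
exist for Gibbs/slice samplers and are not reported. One test fits a
small cumulative probit with both this sampler and an independent JAGS
implementation under identical priors and requires posterior means to
agree to Monte-Carlo accuracy.

Poststratification aggregates weighted cumulative probabilities before
differencing and processes draws in chunks, keeping one draws × cells
matrix live at a time. Cells whose levels were never observed in the
sample get effects drawn per posterior draw from the fitted
population-of-effects distribution (standard partial-pooling
prediction), from a dedicated seeded stream so results are reproducible.

## PSup and its three estimators

For paired ratings on a shared ordinal scale,
`PSup = P(a > b) + ½ P(a = b)`. Ties count one half in all three
estimators — this is forced by the anchor that 0.5 means equivalence
(identical ratings must give exactly 0.5) and makes
`PSup(A,B) + PSup(B,A) = 1` an exact identity, which the tests assert
bit-for-bit. Point estimates therefore live on the `k/(2n)` grid; a
published personnel value of .69 at n = 21 is exactly 29/42 under this
convention.

* `psup_point()` — the sample estimate over pairwise-complete pairs.
* `psup_mrp()` — population PSup: the pair is recoded to
  greater/equal/less, a categorical MRP model is fitted, and per draw
  `PSup = P(greater) + ½ P(equal)` from the poststratified
  probabilities. Computing PSup per draw (not from draw-averaged
  probabilities) keeps the HDI an honest reflection of posterior
  uncertainty.
* `psup_pop_vs_fixed()` — a population posterior against a small fixed
  sample: per draw `PSup = Σ_{i>j} p_i q_j + ½ Σ_i p_i q_i`, where `p`
  is the draw's population category simplex and `q` the fixed sample's
  empirical frequencies. The fixed side is never resampled, so the
  result is conditional on that specific sample.

## Decision rules

**ROPE.** PSup in (.47, .53) is treated as practical equivalence. A
comparison is a *reliable difference* only when the whole 95% HDI lies
outside the ROPE; graded flags mark HDIs entirely beyond .53, .60
(supermajority), .67 (2:1), .75 (3:1), mirrored at 1−t for
inferiority. Flags are monotone under HDI shrinkage around a fixed
mean, which the tests check.

**Permutation tests.** For a fixed small sample, each of 1000
permutations independently swaps each respondent's (a, b) pair with
probability ½; the c-value is the fraction of permutations whose PSup
is as or more extreme than observed, two-sided around 0.5 (the package
takes the two-sided reading since effects in both directions are
reported and no direction is privileged). Swapping a pair maps its
contribution c to 1−c, so the permutation distribution is computed
exactly in integer arithmetic on the 2n scale; an exact-enumeration
mode covers n ≤ 25 and anchors the Monte-Carlo path in tests.

**Cumulative budget.** Within a set of comparisons, c-values are sorted
ascending (ties broken by label for determinism) and comparisons are
selected while the running sum of selected c-values stays ≤ 0.05. The
running-sum reading is adopted because it is the interpretation under
which the expected false-positive percentage per set stays below 5%,
which the calibration module verifies by simulation; selecting all
c ≤ budget individually would not control the set-level rate.

## The synthetic-data generator

`population_spec()` defines a compact census: sex (2) × age band (5) ×
education (4) × income (6) × race (5) × state (8 by default, two per
region), with mildly unequal fixed margins, a state-level hesitancy
rate z-scored across states (n−1 denominator, the conventional sample
sd), and party identification drawn per cell from a multinomial-logit
model with race/education/state effects — mirroring, at synthetic
scale, how a real poststratification frame is extended with party from
an election study. Eight states keep full-table poststratification
(28 800 cells with party) affordable while still exercising the
state/region/covariate structure.

Respondents are drawn with probability ∝ count × exp(bias score), bias
being additive log-odds per demographic level — the simplest mechanism
that biases raw means while leaving MRP consistent, since it acts only
through modelled demographics. Responses come from the same cumulative
probit family the fitter assumes: latent = sum of per-level effects
(+ covariate slope) + standard normal noise, cut at the truth's
cutpoints. `true_population_value()` integrates that model in closed
form over the table — category probabilities, mean response, or paired
PSup — and is the oracle all recovery tests compare against (itself
validated against brute-force simulation at n = 10⁶).

What the generator does **not** emulate: real census margins or
demographic correlations (margins are independent products), real
party–demographic structure, item non-response mechanisms,
within-respondent correlation across *different* survey items (each
item gets independent latent noise), or selection on unmodelled
variables. Passing recovery tests therefore show the pipeline is
correct *when selection operates through modelled demographics and the
response model is well specified* — they cannot show robustness to
confounding outside the model, which is exactly MRP's own assumption.

## Calibration simulations

The null model for both calibrations makes items exchangeable within
respondent: a shared trait θ ~ N(0, 1) plus independent unit-normal
item noise, with cutpoints at the marginal quantiles giving equal
category probabilities. The shared trait induces the within-subject
correlation real paired ratings have; exchangeability guarantees any
flagged difference is a false positive.

* **ROPE false-positive rate** (`simulate_rope_fpr()`): 500 null
  comparisons at n = 1500 with 7-point items. The PSup posterior uses a
  conjugate Dirichlet(1,1,1) over the greater/equal/less counts — under
  the null the covariate structure carries no information, so this fast
  path targets the same quantity as a full MRP fit; a test confirms the
  two paths agree on a 10-replicate grid, and the full-MRP path remains
  available (`method = "mrp"`). Measured rate: 0% of 500 (the HDI
  half-width at n = 1500 is ≈.026 against a ROPE half-width of .03, so
  escaping requires a ≈4-sd deviation).
* **Budget-rule false-discovery percentage**
  (`simulate_permutation_fdr()`): 200 replicate sets of 21 pairwise
  comparisons among 7 exchangeable 5-point items at n = 20, each pair
  tested with 1000 permutations. Measured expectation ≈2–2.5% of
  comparisons per set — under the 5% budget, and conservative because
  tied pairs inflate c-values.

A related observation the tests document: c-values are distributed
uniformly under the null only when the PSup lattice (spacing 1/2n) is
fine relative to Monte-Carlo resolution. At personnel scale (n ≈ 20)
they are markedly super-uniform — conservative — because of
discreteness and ties; at public scale (n = 1500, 7-point items) the
Kolmogorov–Smirnov distance from uniform over 2000 null tests is
≈0.03. The uniformity check therefore runs at public scale.

## Numerical choices and degenerate inputs

* HDI: exact narrowest-window scan of the sorted draws; at least 100
  draws are required for a summary. Point-mass draws give a zero-width
  interval.
* Cutpoint updates work on `(c1, log diffs)` with the Jacobian included,
  so ordering is maintained by construction; initial cutpoints come from
  the empirical cumulative frequencies, clamped away from 0 and 1 so
  degenerate items (all responses in one category) start at finite
  values and remain prior-bounded.
* Truncated-normal draws for the latents clamp the uniform variate to
  [1e-15, 1−1e-15] and project back into the interval when cumulative
  probabilities underflow in extreme tails.
* The comparison of permutation statistics uses integers on the 2n
  scale, so "as or more extreme" is exact, never a float comparison.
* `sample_respondents()` subtracts the maximum bias score before
  exponentiating, so extreme log-odds (the "+∞ proxy") cannot overflow.
* Single-level factors, scale mismatches, empty tables, missing flag
  columns, and out-of-range ratings all raise immediate errors naming
  the offending column.
* Missing item responses are dropped per analysis (complete case within
  each outcome), matching how per-outcome sample sizes are reported for
  small expert samples.

## Problem sizes used by the test suite

Simulation sweeps are sized for a desk-class single-CPU run: the
parameter-recovery sweep uses 20 independent truths at n = 2000 with
5-point items, 2 chains × 350 post-warmup draws each, selection bias
proportional to the education and race effects (so the raw mean is
reliably displaced), and requires ≥18/20 HDI coverage of the exact
population mean with the raw mean outside the HDI in the majority of
replicates. The calibration runs use the full 500 / 200 replicate
counts described above. Default fits for real analyses are longer
(4 × 1000) and convergence-gated at split-R-hat ≤ 1.01.

## Known limitations

* The categorical-logit sampler is slower per iteration than the probit
  sampler (slice updates instead of conjugate draws); population PSup
  fits dominate pipeline runtime.
* Party extension of a poststratification table uses posterior-mean
  party probabilities — a deterministic proportional split. Party-model
  uncertainty is not propagated into downstream HDIs; propagating it
  would require carrying the joint posterior through every table, and
  the recovery tests show the deterministic split leaves coverage
  intact at synthetic scale.
* No frequentist or variational fitting path, and no spatial structure
  beyond region + state + state covariate.
* The ROPE bounds, graded thresholds, and the 5% budget are study
  conventions, configurable but not derived from decision theory.
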