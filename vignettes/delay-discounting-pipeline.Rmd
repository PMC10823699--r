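---
title: "The delay-discounting simulation and analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The delay-discounting simulation and analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(discountr)
```

## The task and its model

The task measures how steeply a person devalues future money. On every
titration trial the participant chooses between a present amount and a
constant future amount of $1,000 delivered after one of seven delays:
two weeks, one month, six months, one year, three years, five years,
ten years. The present offer starts at $500 and is adjusted after each
choice by a halving rule: ahead of trial `count` within a delay series
the change amount is `500 / 2^(count − 1)`, subtracted after a
"present" choice and added after a "future" choice. Six such trials
bisect the $0–$1,000 interval down to a final bracket of width
$15.625; the offer a hypothetical seventh trial would have shown — the
midpoint of that bracket — is the **indifference point** for the
delay. Four dominant-option catch trials (one clearly better dated
amount) are interleaved to detect inattention; at or below 50% catch
accuracy a session is excluded.

Scoring assumes hyperbolic discounting, `V = A / (1 + kD)` with `k` in
day⁻¹. Each indifference point inverts to a per-delay rate
`k_D = (1000 / indifference − 1) / D`, the seven rates are averaged
arithmetically into `k`, and the natural log is taken afterwards —
average **then** log, which matters because `log(mean(k_D)) ≥
mean(log(k_D))` whenever the per-delay rates are heterogeneous. Scores
ln(k) are negative, with values closer to 0 meaning steeper
discounting.

Two assumptions deserve flags. First, the task family this design
belongs to does not pin down the discount functional form used at
scoring time; the hyperbolic form is the standard choice and is what
`discountr` implements, but exponential or quasi-hyperbolic scoring
would give different per-delay rates from the same indifference
points. Second, `k` is reported in day⁻¹ because the delays are
specified in days; ln(k) magnitudes are only comparable across studies
under the same unit convention.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `future_amount` | 1000 | $ | constant delayed option |
| `initial_present` | 500 | $ | staircase anchor and step scale |
| `delays` | 14, 30, 182, 365, 1095, 1825, 3650 | days | the seven named periods with month = 30 d, year = 365 d |
| `trials_per_delay` | 6 | trials | bisection depth; final bracket = `500/2^6` |
| `catch_positions` | 12, 23, 34, 45 | trial index | spread across the session |
| `inverse_temperature` | `Inf` | $⁻¹ | choice noise of the logistic agent; `Inf` = deterministic |
| `catch_error_rate` | 0 | probability | attention failure on catch trials |
| group `n` | 57 / 28 / 19 | — | ARFID / AN / HC sizes |
| ln(k) mean (SD) | −6.1 (2.0) / −7.3 (1.7) / −5.4 (1.5) | log day⁻¹ | group outcome distributions |
| age mean (SD) | 17.42 (5.38) / 20.75 (3.76) / 21.32 (7.60) | years | truncated to 10–30 |
| flag marginals | 45 / 18 / 24 | counts | ARFID presentation endorsements |

The delay durations in days, the catch-trial contents, and their
positions are design choices of this package (the task family names
the periods but not a day count, and describes catch trials only as
clearly preferred); all are configurable.

## The staircase as a binary search

Because every step halves, the staircase is exactly a 6-step binary
search on `(0, 1000)`. Three consequences are proved by enumeration in
the test suite:

- all offers stay strictly inside `(0, 1000)` for each of the 2⁶
  choice sequences;
- the reachable indifference estimates are exactly the odd multiples
  of `500/64`, i.e. `{500·m/64 : m odd, 1 ≤ m ≤ 127}` — 64 values, one
  per sequence;
- for a responder with a fixed indifference value `v` the estimate is
  within `500/2^6 = 7.8125` of `v`.

The estimator therefore keeps `k` strictly positive and bounded, so
ln(k) is always defined — including for the all-present responder,
whose score has the closed form `ln(mean(127/D))` used as an exact
end-to-end check.

## Simulated responders

The deterministic hyperbolic agent maximizes hyperbolic value and
breaks exact ties toward the future option (ties occur only on the
measure-zero dyadic grid; the convention is fixed and documented so
sessions are reproducible). The logistic agent chooses the future
option with probability `plogis(β (V_future − V_present))`; at `β = 0`
it is a coin flip and as `β → ∞` it converges to the deterministic
agent (checked by simulation at `β = 10⁷`). Each session draws all its
randomness — logistic choices, catch errors, inattentive picks — from
one seeded stream in trial order, so a `(agent, config, seed)` triple
is bit-reproducible.

## What the cohort generator does and does not emulate

`cohort_spec()` encodes a three-group cross-sectional sample:
per-group normal ln(k), truncated-normal age (resampling out-of-range
draws), optional sex, and ARFID presentation flags. The marginal flag
counts (45, 18, 24 of 57) exceed the group size, so presentations must
co-occur; the true joint distribution is unknown, and the generator
commits to the least-informative choice consistent with the margins:
random allocation repaired so the column sums are exact and every
ARFID participant carries at least one flag (a donor row with two or
more flags always exists while an empty row remains, by pigeonhole, so
the seeded repair terminates).

Direct mode passes the sampled ln(k) straight to the inference stage —
useful for calibration studies. Behavioral mode sets
`k_true = exp(ln(k))`, runs the full 46-trial task per participant,
scores it, and applies the exclusion rule, which adds the staircase's
quantization error and any configured choice noise.

The generator makes no attempt to emulate skewness of ln(k) within
groups, correlation between age and discounting, BMI, race/ethnicity,
recruitment strata, or screening instruments. Tests passing on this
synthetic cohort show that the *pipeline* is correct and calibrated
under the stated model — not that real ARFID/AN/HC data satisfy the
model.

## The inference stack

`ancova_group_effect()` fits `ln_k ~ group + age` by OLS and tests the
group term with a Type II sum of squares (`RSS(age) − RSS(group+age)`);
for a single factor plus covariate under treatment coding this
coincides with Type III. Adjusted (estimated-marginal) means are the
model predictions at the grand mean age of all analyzed participants.
Partial eta squared uses the identity
`η²ₚ = F·df₁ / (F·df₁ + df₂)`, which holds to machine precision for
every fitted model.

`pairwise_adjusted_contrasts()` tests differences of adjusted means
with standard errors from the full model's coefficient covariance — a
single pooled residual variance rather than per-pair refits, matching
the "adjusted means from one fitted model" convention — and
multiplies each raw p by the number of contrasts, capped at 1.
Hedges' g uses the pooled SD and the small-sample correction
`J = 1 − 3/(4(n₁+n₂) − 9)`; by default it standardizes the *raw* group
means of ln(k) (the common way such summaries are published), with the
adjusted-mean numerator available behind `g_adjusted = TRUE`. The two
conventions differ in the second decimal at these sample sizes, which
is why a published g can sit ~0.01 away from the value recomputed from
rounded summary statistics.

`achieved_power()` converts an observed η²ₚ to Cohen's
`f² = η²ₚ/(1 − η²ₚ)`, sets the noncentrality `λ = f²·N`, and integrates
the noncentral `F(groups − 1, N − groups − covariates, λ)` tail beyond
the central critical value. Note the df convention: with N = 104,
three groups and one covariate the denominator df is 100. Published
ANCOVAs sometimes print a denominator df that implies the covariate
was not subtracted (e.g. 101 at the same N); `partial_eta_squared()`
takes F and both dfs as arguments precisely so either convention can
be evaluated as printed, without silently "fixing" it. Power
implementations also differ in whether λ uses N or the residual df —
enough to move the third decimal (≈ 0.89 vs 0.88 at η²ₚ = 0.11,
N = 104) — so small discrepancies with published power values are
expected and documented rather than tuned away.

## Numerical and degenerate-input choices

- Offers are kept as exact dyadic rationals (multiples of `500/64`),
  which doubles represent exactly; no rounding to cents occurs during
  titration, and CSV round-trips are bit-exact.
- Tie-break at exact indifference: future option, always.
- `indifference_point()` rejects series of the wrong length;
  `update_present_offer()` rejects out-of-range step indices and
  offers outside `(0, 1000)`; `k_from_indifference()` rejects
  indifference points on or outside the interval bounds.
- The ANCOVA refuses constant age and singular group/age confounding
  with diagnostics; the presentation regression names collinear
  columns and refuses constant flags; `hedges_g()` refuses a
  degenerate pooled SD.
- Scores with zero catch trials are treated as valid (the rule is a
  ratio test and has nothing to measure).

## Simulation evidence

The test suite backs the pipeline with four simulation studies, sized
to give tight Monte-Carlo error while keeping the default run fast:

- **Staircase oracle.** All 2⁶ choice sequences per delay match an
  independently coded binary-search fold exactly, and deterministic
  agents on the rate grid `k ∈ {0.0005, 0.001, 0.005, 0.01, 0.05,
  0.2}` day⁻¹ land within 7.8125 of the true indifference value at
  every delay.
- **Parameter recovery.** The noiseless behavioral pipeline recovers
  ln(k) exactly up to staircase quantization; the quantization bound
  itself is computed by the oracle over the grid.
- **Null calibration.** 1,000 direct-mode cohorts with identical group
  distributions reject the omnibus test at a rate inside 0.05 ± 0.02.
- **Power consistency.** 1,000 cohorts at the default group
  distributions give an empirical rejection rate within 0.05 of
  `achieved_power()` evaluated at the population η²ₚ implied by the
  generator (between-group variance over between-plus-pooled-within);
  the band allows for Monte-Carlo error plus the heteroskedastic group
  SDs (2.0/1.7/1.5) that the homoskedastic noncentral-F approximation
  ignores. The age-adjusted ordering AN < ARFID < HC is reproduced in
  well over 90% of cohorts.

## Known limitations

- The hyperbolic scoring form is an assumption, not a measurement.
- Whether per-delay rates should be averaged arithmetically or a
  single k fit jointly across delays is a genuine fork; the arithmetic
  mean matches the "average across the seven series" description this
  design follows, and the package implements only that estimator (no
  area-under-curve or logistic indifference fitting).
- The trial order runs delay series contiguously in increasing order;
  for memoryless agents order does not affect scoring, but order
  effects in humans are outside the model.
- Heteroskedastic group SDs make the noncentral-F power value an
  approximation to the simulated rejection rate.
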