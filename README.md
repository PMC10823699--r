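# discountr

Simulation and group analysis of adaptive delay-discounting tasks.

Delay discounting is the decline in the present subjective value of a
reward as the delay to its receipt grows. Under the standard hyperbolic
model the present value of an amount *A* delivered after *D* days is

    V = A / (1 + k·D)

and the discount parameter *k* (per day) indexes impulsive choice:
larger *k* means steeper devaluation of the future. Because raw *k* is
strongly right-skewed, analyses work with its natural log, ln(*k*),
which is negative with values closer to 0 indicating steeper
discounting.

`discountr` is aimed at researchers studying intertemporal choice in
clinical groups — here avoidant/restrictive food intake disorder
(ARFID), restricting-subtype anorexia nervosa (AN), and healthy
controls (HC). It provides, as one tested pipeline:

- **Task engine** — an adaptive monetary-choice titration task: at each
  of seven delays (two weeks to ten years) the participant repeatedly
  chooses between a present amount and a constant $1,000 future amount.
  The present offer starts at $500 and after each choice moves by
  `500 / 2^(count − 1)` (down after a "present" choice, up after a
  "future" choice) — a bisection staircase that brackets the
  indifference point. Six titration trials per delay plus four
  dominant-option catch trials give 46 trials.
- **Agents** — simulated responders (deterministic hyperbolic, logistic
  "softmax" hyperbolic, inattentive) providing ground truth for
  parameter recovery.
- **Scoring** — per-delay indifference points (the offer of a
  hypothetical seventh trial, i.e. the midpoint of the final bracketing
  interval), per-delay rates `k_D = (1000/indifference − 1)/D`, the
  average *k* across the seven series, ln(*k*), and the validity rule
  that excludes participants at ≤ 50% catch accuracy.
- **Synthetic cohorts** — three groups with configurable sizes
  (defaults 57/28/19), normal ln(*k*) and truncated-normal age
  distributions, and ARFID presentation flags (sensory sensitivity,
  fear of aversive consequences, lack of interest) allocated to exact
  marginal counts (45/18/24) with co-occurrence.
- **Inference** — ANCOVA of ln(*k*) on group with an age covariate
  (Type II SS, partial η²), Bonferroni-corrected pairwise t-tests on
  age-adjusted means, Hedges' *g*, multiple regression of ln(*k*) on the
  three presentation flags controlling for age, and achieved power from
  the noncentral F distribution
  (`f² = η²ₚ/(1−η²ₚ)`, `λ = f²·N`).

## Worked example

Simulate a full study at the default cohort composition and analyze it:

```r
library(discountr)

study  <- simulate_study(cohort_spec(), seed = 42)
report <- analyze_study(study$participants, study$scores)
print(report)
```

```
=== Delay-discounting group analysis (N = 104 ) ===

Group summaries of ln(k) and age:
 group  n ln_k_mean ln_k_sd age_mean age_sd
 ARFID 57     -6.12    2.03     17.9   4.27
    AN 28     -7.31    1.54     21.8   2.99
    HC 19     -5.68    1.79     19.7   3.91

ANCOVA of ln(k) on group, age-covaried: F(2, 100) = 5.52, p = 0.00533, partial eta^2 = 0.10
Age-adjusted group means of ln(k):
 group adjusted_mean    se  n
 ARFID         -6.07 0.257 57
    AN         -7.40 0.374 28
    HC         -5.70 0.430 19

Bonferroni-corrected pairwise contrasts on adjusted means:
 contrast difference    se      t  df   p_raw p_bonferroni hedges_g
 ARFID-AN      1.325 0.471  2.815 100 0.00588       0.0176    0.629
 ARFID-HC     -0.376 0.503 -0.747 100 0.45660       1.0000   -0.218
    AN-HC     -1.701 0.566 -3.007 100 0.00334       0.0100   -0.976

Regression of ln(k) on ARFID presentations + age: F = 1.47, p = 0.225, adj. R^2 = 0.03
                          term       B     se     t        p
                   (Intercept) -7.8096 1.3768 -5.67 6.31e-07
           sensory_sensitivity  0.9714 0.7068  1.37 1.75e-01
 fear_of_aversive_consequences  0.3401 0.6297  0.54 5.91e-01
              lack_of_interest -0.8104 0.5398 -1.50 1.39e-01
                           age  0.0649 0.0644  1.01 3.19e-01

Achieved power: eta_p^2 = 0.099 -> f^2 = 0.110, lambda = 11.48, F crit(2, 100) = 3.09, power = 0.857
```

Reading the output: the omnibus ANCOVA says the three groups differ in
ln(*k*) after adjusting for age (here F(2, 100) = 5.52, η²ₚ = 0.10).
The pairwise rows compare age-adjusted group means: the positive
ARFID−AN difference (+1.33 log units, Bonferroni p = 0.018, g = 0.63)
means the synthetic ARFID group discounts the future more steeply than
the AN group, while ARFID does not separate from HC. The presentation
regression asks whether any single ARFID presentation drives ln(*k*)
over and above age (here none does), and the final line reports the
power the design achieves at the observed effect size.

The behavioral mode runs every synthetic participant through the actual
46-trial task instead of passing ln(*k*) through directly:

```r
study <- simulate_study(cohort_spec(mode = "behavioral"), seed = 42,
                        return_sessions = TRUE)
score_session(study$sessions[[1]], task_config())
```

A thin command-line wrapper with `simulate`, `score`, `analyze`, and
`power` subcommands is installed at
`system.file("cli", "discountr.R", package = "discountr")`.

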