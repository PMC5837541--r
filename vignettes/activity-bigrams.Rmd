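---
title: "Activity bigrams: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Activity bigrams: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actibigram)
```

## The problem

Epidemiological analyses of accelerometer data usually reduce a week of
minute-level recording to a handful of summaries: the mean counts per
minute (mCPM) and the time spent in intensity bands such as
moderate-to-vigorous physical activity (MVPA) or sedentary behaviour.
These summaries discard the *order* of the sequence: two children can
spend identical total time in moderate activity while one accumulates it
in sustained bouts and the other in scattered single minutes.

`actibigram` treats the categorized activity sequence the way text
mining treats a document. Each 1-minute epoch is a token over the
four-state alphabet S (sedentary), L (low), M (moderate), V (vigorous),
and each *bigram* AB counts adjacent epoch pairs where state A is
followed by state B. Bigram frequencies capture moment-to-moment change
— how often moderate activity is immediately followed by vigorous
activity, say — which the bag-of-states summaries cannot see.

## From counts to states

Counts per minute are categorized with the waist-worn ActiGraph
cut-points for 11-year-olds: sedentary 0–100, low 101–2019, moderate
2020–5998, vigorous 5999+. All four boundaries are inclusive upper
bounds and are asserted literally in the test suite. The thresholds are
a `cut_points()` parameter, so other calibrations can be substituted.

Non-wear time is identified as maximal runs of zero counts strictly
longer than 60 epochs (one hour): a 61-zero run is masked, a 60-zero
run is kept as genuine sedentary time. Masked epochs are `NA` in the
state sequence, and the mask takes precedence over categorization.
Zeros on worn epochs categorize as sedentary — only the long runs are
treated as device-off.

A day is *valid* with at least 8 h (480 epochs) of wear; a participant
is retained with at least 3 valid days and a wear-time mean of at most
1500 counts/min (higher means are treated as implausible device
output). We read the 1500-cpm rule as applying to the wear-time-only
mean, consistent with how mCPM itself is defined; this is a choice the
source description leaves open, and it is exposed via
`validity_rules()` if a different reading is wanted.

Days are fixed 1440-epoch blocks from the start of recording (devices
start at a programmed clock time), not calendar days. Recordings
shorter than `n_days * epochs_per_day` are rejected by default;
`pad = TRUE` pads the tail as missing instead, for cohorts where
truncated files should be kept.

## Bigram and u-bigram profiles

For a sequence $x_1, \dots, x_n$ over $\{S,L,M,V\}$ recorded over $D$
days, the frequency of bigram $AB$ per day is

$$b(A,B) = \frac{1}{D}\sum_{i=1}^{n-1} \mathbf{1}[x_i = A \wedge x_{i+1} = B].$$

Epoch pairs overlap: the pair at $(t, t+1)$ shares an epoch with the
pairs at $(t-1, t)$ and $(t+1, t+2)$. A consequence worth keeping in
mind is that a bigram's frequency does not correspond to a fixed amount
of time — `SSSLS` and `SSLSS` both contain the SS bigram twice, spanning
3 and 4 distinct minutes respectively (`bigram_minute_span()` reports
this diagnostic).

With four states there are 16 bigrams. The unordered *u-bigram* $[AB]$
pools reciprocal bigrams, $b_u[AB] = b(A,B) + b(B,A)$ for $A \neq B$,
while $[AA]$ equals the AA bigram (each same-state pair counts once).
There are 10 u-bigrams. Reciprocal bigram frequencies are typically
highly correlated within a person, which is the motivation for pooling
them: it roughly halves the number of contrasts and increases power.

Two accounting rules matter and are design choices:

* Pairs that touch a missing epoch contribute to **no** bigram. A
  bigram asserts adjacency in worn time; a pair spanning a non-wear gap
  asserts nothing.
* Pairs spanning a day boundary inside the continuous recording **are**
  counted: the sum above runs over the whole sequence. The recording is
  one continuous week, and minute 1440 of day 1 is genuinely adjacent
  to minute 1 of day 2.

The main analysis divides by the total number of recorded days (7)
regardless of wear time. The `valid_days_only` sensitivity policy
instead removes invalid days entirely (pairs spanning a removed day are
dropped) and divides by the number of valid days.

Per-day state durations $S_d, L_d, M_d, V_d$ (minutes/day) and
mCPM/sdCPM complete the per-participant feature row. Conservation
identities — the 16 frequencies times $D$ equal the number of valid
pairs, and the four durations times $D$ equal the worn minutes — are
enforced as property tests.

## Swap-style regression models

Within a day the state occupancies (and the $n_d - 1 = 1439$ epoch
pairs) are a closed budget: one frequency can only rise if another
falls. The models therefore estimate the effect of *transferring* time
or frequency from a baseline feature to a comparison feature.

For a transfer from baseline state S to comparison state M:

$$\mathrm{outcome} = \beta_1 M_d + \beta_2 r + \epsilon, \qquad
r = n_d - (M_d + S_d),$$

and for a swap from baseline bigram SS to comparison bigram SL:

$$\mathrm{outcome} = \beta_1\, b(S,L) + \beta_2\, r_b + \epsilon, \qquad
r_b = (n_d - 1) - b(S,L) - b(S,S).$$

The baseline feature is deliberately omitted: because baseline =
constant − comparison − remainder, including the comparison and the
remainder makes $\beta_1$ the effect of a one-unit increase in the
comparison feature financed by an equal decrease in the baseline,
holding the combined remainder fixed (collateral shifts *within* the
remainder are allowed). Exchanging baseline and comparison is a linear
reparametrization of the same model, so the estimate negates exactly
and the CI width is unchanged — the test suite asserts this to
floating-point accuracy, and the grid (`run_full_grid()`) fits only one
orientation per pair.

$r_b$ uses the literal $(n_d - 1)$ budget even when non-wear reduces a
participant's observed pairs below 1439. This keeps the remainder a
fixed linear function of the profile; since the three terms are
linearly dependent given the budget, using the observed pair count
instead would only re-centre $\beta_2$, not change $\beta_1$'s meaning
for complete-wear participants, but we follow the fixed-budget form as
the primary definition.

Adjustment sets form a series: **model 1** unadjusted; **model 2** adds
the supplied covariates (in the motivating application: gender, exact
age, parity, household social class, maternal education, maternal
smoking in pregnancy, ethnicity); **model 3** (swap models only) adds
the four state durations; **model 4** (swap models only) adds mCPM.
Model 3/4 answer a sharper question: does the *sequencing* of activity
matter beyond the time spent at each intensity (or beyond mean
activity)? For state-transfer models these extra adjustments would be
collinear with the model's own terms, so the spec constructor rejects
them.

Reported effects are scaled either ×10 (a 10-min/day or 10-epoch-pair
swap, a plausible behavioural change) or by the sample SD of the
*baseline* feature (`per_sd`), since feature SDs vary over two orders
of magnitude and a fixed 10-unit change is unrealistic for rare
bigrams. Confidence intervals are 95% t-intervals using the residual
degrees of freedom; at cohort sizes in the thousands these are
indistinguishable from normal intervals. Categorical covariates are
accepted as whatever coding the caller puts in the table — ordinal
integers in the simplest case, or factor dummy columns prepared
upstream. Every model drops incomplete cases for its own variables and
reports `n_used`. No multiple-testing correction is applied across the
grid; the output is a screen of unadjusted CIs.

mCPM and sdCPM have their own models (`fit_cpm_models()`), reported per
100 counts/min and per 1 SD respectively, individually or mutually
adjusted; the two are strongly correlated in real cohorts, so the
mutually adjusted estimates attenuate.

## The synthetic cohort generator

Restricted cohort data cannot ship with a package, so `actibigram`
includes a generator whose outputs exercise every pipeline stage with
known truth:

* **State paths** are first-order Markov chains over S/L/M/V. This is
  the one modelling choice made *for* testability: under a stationary
  chain the expected bigram frequency has the closed form
  $\pi_A P(A \to B) \times 1439$ per day, so the simulator can be
  validated against an analytic oracle
  (`expected_bigram_frequencies()`).
* The default transition matrix is calibrated so the implied stationary
  pair frequencies resemble a population of 11-year-olds wearing a
  waist accelerometer: dominant S and L states that alternate, moderate
  activity in short bouts, vigorous minutes rare and mostly adjacent to
  moderate ones, about 12 h wear per day.
* **Counts** are drawn uniformly within each state's cut-point band
  (vigorous capped at 10 000 by default, keeping mCPM near 800 —
  comfortably under the 1500 validity cap unless an exclusion path is
  being tested deliberately). Uniform emission is not a realistic count
  distribution; it is enough to make categorization invertible, which
  is what the round-trip tests need.
* **Non-wear** is inserted by overwriting Poisson-many runs of zeros
  per day (default one run of 600–780 min, emulating overnight
  device-off), exercising the >60-zero rule.
* **Outcomes** are linear in any named features and confounders plus
  Gaussian noise, defaulting to a BMI-like variable (intercept 21,
  −0.003 per count/min of mCPM, −0.3 per [MV] pair/day, age/gender/
  maternal-smoking covariates, residual SD 2.5). An optional
  *activity confounder* draws a binary covariate that switches the
  participant's transition matrix **and** shifts the outcome, creating
  genuine confounding so that the model-1-biased / model-2-unbiased
  contrast can be demonstrated.

All randomness flows from one integer seed via fixed stage offsets
(confounders, sequences, outcomes), so a cohort is reproducible
end-to-end and outcome noise is attached to participant ids rather than
row positions.

What the generator does **not** emulate: diurnal/circadian structure,
semi-Markov (heavy-tailed) bout durations, device noise, seasonal or
day-of-week effects, and any non-linear outcome dependence. Passing
tests therefore demonstrate correctness of the *accounting and
inference machinery*, not that real accelerometer data satisfy a
first-order Markov model — they do not, and nothing in the analysis
pipeline assumes they do.

## Numerical choices and problem sizes

* OLS is fitted by `stats::lm` (QR); the test suite cross-checks
  coefficients against independently solved normal equations.
* Degenerate designs fail loudly: zero-variance comparison features and
  rank-deficient designs raise typed errors naming the offending
  columns, and the grid runner converts per-fit failures into flagged
  rows so one rare bigram cannot abort a 45-contrast screen.
* Validation of the simulator against its closed-form oracle uses a
  block-means standard error (100 blocks over $10^5$ pairs) rather than
  a binomial SE, because adjacent-pair indicators are autocorrelated
  under a Markov chain and the naive SE would be anti-conservative.
* The calibration suite fits 200 independent cohorts of n = 1000
  participants with one recorded day each (1440 epochs) and checks that
  the nominal 95% CI covers a known swap coefficient 92–98% of the
  time with bias under 5%. One day per participant is the package's
  chosen problem size for this suite: coverage is a property of the
  fitted model, not of the sequence length, and a week-long sequence
  would only shrink the feature noise.
* Sequences shorter than the declared recording are a hard error unless
  padding is requested; day boundaries are fixed blocks; ties at
  cut-point boundaries are resolved by the inclusive upper bounds
  stated above.

## Limitations

Bigram frequencies are estimated from 7 days and then used as fixed
regressors; the models ignore that estimation uncertainty, so CIs on
associations are, if anything, slightly narrow. Results are
associational — the swap models describe exchange contrasts, not causal
substitution effects. The 1-min epoch is load-bearing: at other epoch
lengths the same sequence yields different bigrams, and cut-points
calibrated for one epoch length do not transfer. Extending to n-grams
beyond 2 is straightforward in principle but the frequency of any
specific n-gram (hence power) decays rapidly with n.
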