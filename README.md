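# actibigram

Physical-activity phenotyping with **activity bigrams**: an R package
for epidemiologists and movement scientists working with minute-level
accelerometer counts who want to ask whether the *sequencing* of
activity — how intensity changes from one minute to the next — is
associated with an outcome, over and above the time spent at each
intensity.

## What it computes

Each 1-min epoch's count is categorized into one of four activity
states via cut-points (defaults for waist-worn ActiGraph data in
11-year-olds): sedentary **S** (0–100 counts/min), low **L**
(101–2019), moderate **M** (2020–5998), vigorous **V** (5999+). Runs of
zeros longer than 60 epochs are masked as non-wear; participants need
at least 3 days with 8 h of wear and a wear-time mean of at most 1500
counts/min.

Borrowing from text mining, the categorized sequence is summarised by
its **bigrams**: for states A and B, the frequency per day over D
recorded days is

    b(A,B) = (1/D) * #{ i : x[i] = A and x[i+1] = B }

counted over all overlapping adjacent epoch pairs (16 bigrams;
pairs touching non-wear are excluded). The 10 **u-bigrams** pool
reciprocal bigrams: `[AB] = b(A,B) + b(B,A)` for A ≠ B, `[AA] = b(A,A)`.

Associations with a continuous outcome (e.g. BMI) use **swap-style
linear models**. For a transfer of time from baseline state S to
comparison state M:

    outcome = β1·Md + β2·r + ε,   r = nd − (Md + Sd),   nd = 1440

and for a swap of frequency from baseline bigram SS to comparison SL:

    outcome = β1·b(S,L) + β2·rb + ε,   rb = (nd − 1) − b(S,L) − b(S,S)

The baseline is omitted, so β1 is the effect of increasing the
comparison feature at the equal expense of the baseline, holding the
combined remainder fixed. Effects are reported ×10 (a 10-min or
10-epoch-pair swap) or per 1 SD of the baseline feature, with 95%
t-intervals, under four adjustment sets (unadjusted; + covariates;
+ state durations; + mCPM). Exchanging baseline and comparison negates
the estimate exactly, so each pair is fitted once.

A first-order Markov **synthetic cohort generator** with a linear
outcome model makes the whole pipeline testable without restricted
cohort data, including closed-form expected bigram frequencies
(`expected_bigram_frequencies()`) and configurable confounding.

## Worked example

```r
library(actibigram)

# bigrams overlap: SSSLS and SSLSS both contain SS twice,
# spanning 3 and 4 distinct minutes
seq <- state_sequence("SSSLS")
count_bigrams(seq)[c("SS", "SL", "LS")]
#> SS SL LS
#>  2  1  1
bigram_minute_span(seq, "SS")                         # 3
bigram_minute_span(state_sequence("SSLSS"), "SS")     # 4

# a synthetic cohort: 300 participants, 7 days x 1440 epochs
cfg <- synthetic_cohort_config(n_participants = 300, seed = 2026)
sim <- simulate_cohort(cfg)
sim$validity[1:3, ]
#>   participant_id valid reasons n_valid_days     mCPM    sdCPM
#> 1          P0001  TRUE                    7 868.7396 1278.758
#> 2          P0002  TRUE                    7 831.2965 1203.985
#> 3          P0003  TRUE                    5 760.1570 1140.236

# swap 10 [SS] epoch pairs/day for 10 [MV] pairs/day, covariate-adjusted
spec <- swap_model_spec("ubigram_swap", baseline = "[SS]",
                        comparison = "[MV]", adjustment = "model2",
                        covariates = c("gender", "age", "maternal_smoking"))
fit_bigram_swap(sim$cohort, spec)
#> <swap_model_result> ubigram_swap: [SS] -> [MV] [model2]
#>   effect per 10-unit swap: -4.2148 (95% CI -7.3528, -1.0768), n = 300
```

The fitted effect says: in this simulated cohort, replacing ten
sedentary-adjacent pairs per day with ten moderate–vigorous-adjacent
pairs is associated with a 4.2 kg/m² lower outcome (the generator's
default outcome model puts a negative coefficient on `[MV]` and on
mCPM, so this is the expected sign). `run_full_grid()` fits all 6
state-transfer and 45 u-bigram contrasts in one call:

```r
head(run_full_grid(sim$cohort, families = "state_transfer",
                   models = "model1")[, 1:8], 3)
#>             kind baseline comparison  model  beta  ci_low ci_high   n
#> 1 state_transfer        L          S model1 0.247 -0.0385   0.532 300
#> 2 state_transfer        M          S model1 0.472 -0.0155   0.958 300
#> 3 state_transfer        V          S model1 4.682  1.4045   7.960 300
```

A command-line interface wrapping these functions (subcommands
`simulate`, `preprocess`, `features`, `associate`, `run`) is installed
at `inst/cli/actibigram.R`.

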