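# Shared fixtures and independent oracles for the test suite.
# Oracles are deliberately written as plain loops / direct summation so
# they stay independent of the vectorized implementation they check.

# random state sequence with missingness, as a state_sequence object
random_state_sequence <- function(n, p_missing = 0.2, n_days = 1) {
  states <- sample(activity_states(), n, replace = TRUE)
  states[stats::runif(n) < p_missing] <- NA_character_
  state_sequence(states, n_days = n_days,
                 epochs_per_day = as.integer(ceiling(n / n_days)))
}

# brute-force bigram counter: explicit O(n) loop over adjacent pairs
brute_force_bigram_counts <- function(states) {
  st <- activity_states()
  m <- matrix(0L, 4, 4, dimnames = list(st, st))
  n <- length(states)
  if (n >= 2) {
    for (i in 1:(n - 1)) {
      if (!is.na(states[i]) && !is.na(states[i + 1])) {
        m[states[i], states[i + 1]] <- m[states[i], states[i + 1]] + 1L
      }
    }
  }
  m
}

# direct-summation mean and sample SD over worn epochs
brute_force_mean_sd <- function(counts, mask) {
  x <- counts[!mask]
  m <- sum(x) / length(x)
  s <- sqrt(sum((x - m)^2) / (length(x) - 1))
  c(mean = m, sd = s)
}

# closed-form OLS via normal equations (independent of stats::lm's QR)
normal_equation_ols <- function(X, y) {
  solve(crossprod(X), crossprod(X, y))
}

# helper epoch series with explicit epochs_per_day = length
make_series <- function(counts, ...) {
  epoch_series("test", counts, n_days = 1,
               epochs_per_day = length(counts), ...)
}

# small fast synthetic cohort (1 recorded day, non-wear off unless asked)
quick_cohort_config <- function(n = 200, seed = 1, nonwear_on = FALSE, ...) {
  synthetic_cohort_config(
    n_participants = n, n_days = 1, seed = seed,
    nonwear = if (nonwear_on) list(runs_per_day = 1,
                                   run_length_range = c(100, 300))
              else list(runs_per_day = 0, run_length_range = c(61, 120)),
    ...)
}

one_day_rules <- function() validity_rules(min_valid_days = 1)
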