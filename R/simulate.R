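#' Configuration for a synthetic accelerometer cohort
#'
#' Describes a cohort of simulated participants whose minute-level
#' activity-state paths follow a first-order Markov chain over
#' S/L/M/V, with counts drawn uniformly within each state's cut-point
#' band, optional non-wear runs of zeros overwritten into each day, and
#' a linear outcome model over the derived features and confounders.
#' First-order Markov generation makes bigram frequencies analytically
#' predictable (stationary pair probabilities), giving the test suite a
#' closed-form oracle.
#'
#' The default transition matrix and non-wear pattern are calibrated to
#' a waist-worn ActiGraph cohort of 11-year-olds: mostly sedentary/low
#' time with occasional moderate bouts and rare vigorous minutes, about
#' 12 h of wear per day (one long overnight non-wear run), and a
#' wear-time mean around 600--900 counts/min. The default outcome is a
#' BMI-like variable centred near 19 kg/m^2 with SD near 3.3, generated
#' from mCPM and the moderate--vigorous adjacency frequency plus
#' age/gender/maternal-smoking confounders and Gaussian noise.
#'
#' @param n_participants Number of participants.
#' @param n_days Recorded days per participant (default 7).
#' @param epochs_per_day Epochs per day (default 1440).
#' @param transition_matrix 4x4 row-stochastic matrix over S, L, M, V
#'   (rows sum to 1 within 1e-12).
#' @param initial_distribution Length-4 probability vector for the first
#'   epoch's state; defaults to the stationary distribution of
#'   `transition_matrix`.
#' @param emission_ranges Named list `S`, `L`, `M`, `V` of integer
#'   `c(lo, hi)` count ranges; each range must lie inside the matching
#'   cut-point band.
#' @param cuts [cut_points()] used to validate the emission ranges.
#' @param nonwear List with `runs_per_day` (expected number of non-wear
#'   runs per day; runs are drawn Poisson) and `run_length_range`
#'   (integer `c(lo, hi)` minutes, uniform). Set `runs_per_day = 0` to
#'   disable non-wear.
#' @param outcome_coefficients Named numeric vector mapping feature
#'   columns (e.g. `u_MV`, `Md`, `mCPM`, or `intercept`) to outcome
#'   units per feature unit.
#' @param confounders Named list; each element is a list with `dist`
#'   (`"normal"` or `"bernoulli"`), its parameters (`mean`/`sd` or
#'   `prob`) and `effect` (outcome units per covariate unit).
#' @param activity_confounder Optional list with `name`, `prob`,
#'   `transition_matrix` (used instead of the default matrix when the
#'   binary confounder is 1) and `effect` (direct outcome effect). This
#'   creates genuine confounding: the covariate shifts both the activity
#'   process and the outcome.
#' @param noise_sd Residual SD of the outcome.
#' @param outcome_name Name of the outcome column (default `"BMI"`).
#' @param seed Integer base seed; all randomness derives from it.
#'
#' @return An object of class `synthetic_cohort_config`.
#' @export
synthetic_cohort_config <- function(n_participants = 100,
                                    n_days = 7,
                                    epochs_per_day = 1440,
                                    transition_matrix = default_transition_matrix(),
                                    initial_distribution = NULL,
                                    emission_ranges = default_emission_ranges(),
                                    cuts = cut_points(),
                                    nonwear = list(runs_per_day = 1,
                                                   run_length_range = c(600, 780)),
                                    outcome_coefficients = c(intercept = 21,
                                                             mCPM = -0.003,
                                                             u_MV = -0.3),
                                    confounders = default_confounders(),
                                    activity_confounder = NULL,
                                    noise_sd = 2.5,
                                    outcome_name = "BMI",
                                    seed = 1L) {
  st <- activity_states()
  P <- as.matrix(transition_matrix)
  if (!all(dim(P) == c(4, 4))) {
    abort_ab("transition_matrix must be 4x4", "actibigram_config_error")
  }
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-12)) {
    abort_ab("transition_matrix rows must be non-negative and sum to 1 (tol 1e-12)",
             "actibigram_config_error")
  }
  dimnames(P) <- list(st, st)
  if (is.null(initial_distribution)) {
    initial_distribution <- stationary_distribution(P)
  }
  if (length(initial_distribution) != 4 ||
      abs(sum(initial_distribution) - 1) > 1e-8) {
    abort_ab("initial_distribution must be a length-4 probability vector",
             "actibigram_config_error")
  }
  check_emission_ranges(emission_ranges, cuts)
  if (!is.null(activity_confounder)) {
    A <- as.matrix(activity_confounder$transition_matrix)
    if (any(A < 0) || any(abs(rowSums(A) - 1) > 1e-12)) {
      abort_ab("activity_confounder transition matrix rows must sum to 1",
               "actibigram_config_error")
    }
    dimnames(A) <- list(st, st)
    activity_confounder$transition_matrix <- A
  }
  seed <- as.integer(seed)
  if (is.na(seed) || abs(seed) > 2^31 - 10) {
    abort_ab("seed must be an integer below 2^31 - 10",
             "actibigram_config_error")
  }
  structure(
    list(n_participants = as.integer(n_participants),
         n_days = as.integer(n_days),
         epochs_per_day = as.integer(epochs_per_day),
         transition_matrix = P,
         initial_distribution = initial_distribution,
         emission_ranges = emission_ranges,
         cuts = cuts,
         nonwear = nonwear,
         outcome_coefficients = outcome_coefficients,
         confounders = confounders,
         activity_confounder = activity_confounder,
         noise_sd = noise_sd,
         outcome_name = outcome_name,
         seed = seed),
    class = "synthetic_cohort_config")
}

#' Default Markov transition matrix for the synthetic cohort
#'
#' Row-stochastic matrix over S, L, M, V calibrated so that the implied
#' stationary pair frequencies resemble a young adolescent cohort:
#' sedentary and low dominate and alternate, moderate occurs in bouts,
#' vigorous minutes are rare and usually adjacent to moderate ones.
#'
#' @return 4x4 numeric matrix with rows/columns named S, L, M, V.
#' @export
default_transition_matrix <- function() {
  st <- activity_states()
  P <- rbind(
    S = c(0.7535, 0.2400, 0.0060, 0.0005),
    L = c(0.2560, 0.6715, 0.0705, 0.0020),
    M = c(0.0430, 0.4280, 0.5100, 0.0190),
    V = c(0.0100, 0.2800, 0.4950, 0.2150))
  dimnames(P) <- list(st, st)
  P
}

#' @rdname default_transition_matrix
#' @export
default_emission_ranges <- function() {
  list(S = c(0L, 100L), L = c(101L, 2019L),
       M = c(2020L, 5998L), V = c(5999L, 10000L))
}

# default confounder spec: roughly age-11 cohort demographics
default_confounders <- function() {
  list(
    gender = list(dist = "bernoulli", prob = 0.52, effect = 0.3),
    age = list(dist = "normal", mean = 11.77, sd = 0.23, effect = 0.5),
    maternal_smoking = list(dist = "bernoulli", prob = 0.17, effect = 0.4))
}

# internal: each emission range must sit inside one cut-point band
check_emission_ranges <- function(er, cuts) {
  bands <- list(S = c(0, cuts$sedentary_max),
                L = c(cuts$sedentary_max + 1, cuts$low_max),
                M = c(cuts$low_max + 1, cuts$moderate_max),
                V = c(cuts$moderate_max + 1, Inf))
  for (stt in activity_states()) {
    r <- er[[stt]]
    if (is.null(r) || length(r) != 2 || r[1] > r[2]) {
      abort_ab(sprintf("emission range for state %s must be c(lo, hi)", stt),
               "actibigram_config_error")
    }
    if (r[1] < bands[[stt]][1] || r[2] > bands[[stt]][2]) {
      abort_ab(sprintf(
        "emission range for state %s (%d-%d) crosses its cut-point band (%s-%s)",
        stt, r[1], r[2], format(bands[[stt]][1]), format(bands[[stt]][2])),
        "actibigram_config_error")
    }
  }
  invisible(TRUE)
}

#' Stationary distribution of a transition matrix
#'
#' Solves pi = pi P for the stationary distribution of an irreducible
#' row-stochastic matrix, via the leading left eigenvector.
#'
#' @param P Row-stochastic square matrix.
#' @return Probability vector, named as `P`'s rows.
#' @export
stationary_distribution <- function(P) {
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  stats::setNames(v / sum(v), rownames(P))
}

#' Expected bigram frequencies under the Markov model
#'
#' Under a stationary first-order Markov chain, the probability that a
#' random adjacent epoch pair is (A, B) is `pi_A * P[A, B]`. Multiplied
#' by the number of epoch pairs per day, this gives the expected bigram
#' frequency per day, the closed-form oracle used to validate the
#' simulator.
#'
#' @param cfg A [synthetic_cohort_config()], or a transition matrix.
#' @param pairs_per_day Number of adjacent epoch pairs per day used for
#'   scaling (default `NULL` returns probabilities).
#'
#' @return 4x4 matrix of pair probabilities (or expected frequencies per
#'   day if `pairs_per_day` is given); rows = first state, columns =
#'   second state.
#' @export
expected_bigram_frequencies <- function(cfg, pairs_per_day = NULL) {
  P <- if (inherits(cfg, "synthetic_cohort_config")) {
    cfg$transition_matrix
  } else {
    as.matrix(cfg)
  }
  pi_ <- stationary_distribution(P)
  out <- diag(pi_) %*% P
  dimnames(out) <- dimnames(P)
  if (!is.null(pairs_per_day)) out <- out * pairs_per_day
  out
}

# internal: draw participant-level confounders; deterministic in cfg$seed
draw_confounders <- function(cfg) {
  set.seed(cfg$seed + 1L)
  n <- cfg$n_participants
  out <- data.frame(participant_id = participant_ids(n),
                    stringsAsFactors = FALSE)
  for (nm in names(cfg$confounders)) {
    sp <- cfg$confounders[[nm]]
    out[[nm]] <- switch(sp$dist,
      normal = stats::rnorm(n, sp$mean, sp$sd),
      bernoulli = stats::rbinom(n, 1, sp$prob),
      abort_ab(sprintf("unknown confounder distribution '%s'", sp$dist),
               "actibigram_config_error"))
  }
  if (!is.null(cfg$activity_confounder)) {
    ac <- cfg$activity_confounder
    out[[ac$name]] <- stats::rbinom(n, 1, ac$prob)
  }
  out
}

participant_ids <- function(n) sprintf("P%04d", seq_len(n))

# internal: vectorized Markov chain over participants sharing matrix P.
# Returns integer matrix (participants x epochs), states coded 1..4.
markov_state_matrix <- function(n_part, n_epochs, P, init) {
  cumP <- t(apply(P, 1, cumsum))
  c1 <- cumP[, 1]; c2 <- cumP[, 2]; c3 <- cumP[, 3]
  states <- matrix(0L, nrow = n_part, ncol = n_epochs)
  u <- stats::runif(n_part)
  cum0 <- cumsum(init)
  prev <- 1L + (u > cum0[1]) + (u > cum0[2]) + (u > cum0[3])
  states[, 1] <- prev
  for (t in 2:n_epochs) {
    u <- stats::runif(n_part)
    prev <- 1L + (u > c1[prev]) + (u > c2[prev]) + (u > c3[prev])
    states[, t] <- prev
  }
  states
}

#' Simulate per-minute count sequences for a synthetic cohort
#'
#' Generates each participant's activity-state path as a first-order
#' Markov chain, draws counts uniformly within the state's emission
#' range, then overwrites non-wear runs of zeros (drawn per day) so the
#' non-wear detector has something to find. Fully reproducible from
#' `cfg$seed`.
#'
#' @param cfg A [synthetic_cohort_config()].
#' @param keep_states If `TRUE`, attach the generating state matrix as
#'   attribute `"true_states"` (integer codes 1--4 = S--V).
#'
#' @return A list of [epoch_series()] (raw: `missing_mask` all `FALSE`),
#'   with the drawn confounder table attached as attribute
#'   `"confounders"`.
#' @export
simulate_sequences <- function(cfg, keep_states = FALSE) {
  stopifnot(inherits(cfg, "synthetic_cohort_config"))
  conf <- draw_confounders(cfg)
  set.seed(cfg$seed + 2L)
  n <- cfg$n_participants
  n_epochs <- cfg$n_days * cfg$epochs_per_day
  if (!is.null(cfg$activity_confounder)) {
    ac <- cfg$activity_confounder
    grp <- conf[[ac$name]] == 1
    states <- matrix(0L, nrow = n, ncol = n_epochs)
    if (any(!grp)) {
      states[!grp, ] <- markov_state_matrix(sum(!grp), n_epochs,
                                            cfg$transition_matrix,
                                            cfg$initial_distribution)
    }
    if (any(grp)) {
      states[grp, ] <- markov_state_matrix(sum(grp), n_epochs,
                                           ac$transition_matrix,
                                           stationary_distribution(ac$transition_matrix))
    }
  } else {
    states <- markov_state_matrix(n, n_epochs, cfg$transition_matrix,
                                  cfg$initial_distribution)
  }
  lo <- vapply(cfg$emission_ranges, `[`, numeric(1), 1)
  hi <- vapply(cfg$emission_ranges, `[`, numeric(1), 2)
  counts <- matrix(
    as.integer(lo[states] +
                 floor(stats::runif(length(states)) *
                         (hi[states] - lo[states] + 1))),
    nrow = n, ncol = n_epochs)
  # overwrite non-wear runs of zeros, day by day
  nw <- cfg$nonwear
  if (!is.null(nw) && nw$runs_per_day > 0) {
    for (i in seq_len(n)) {
      for (d in seq_len(cfg$n_days)) {
        n_runs <- stats::rpois(1, nw$runs_per_day)
        if (n_runs == 0) next
        day_start <- (d - 1L) * cfg$epochs_per_day
        for (r in seq_len(n_runs)) {
          len <- sample(nw$run_length_range[1]:nw$run_length_range[2], 1)
          start <- sample(seq_len(cfg$epochs_per_day), 1)
          idx <- day_start + start:min(start + len - 1L, cfg$epochs_per_day)
          counts[i, idx] <- 0L
        }
      }
    }
  }
  ids <- participant_ids(n)
  out <- lapply(seq_len(n), function(i) {
    epoch_series(ids[i], counts[i, ], n_days = cfg$n_days,
                 epochs_per_day = cfg$epochs_per_day)
  })
  attr(out, "confounders") <- conf
  if (keep_states) attr(out, "true_states") <- states
  out
}

#' Generate outcomes from features and confounders
#'
#' Builds the outcome as a linear combination of feature columns and
#' confounder effects plus Gaussian noise:
#' `outcome = intercept + sum(coef * feature) + sum(effect * confounder)
#' + N(0, noise_sd)`. Reproducible from `cfg$seed`.
#'
#' @param features Feature `data.frame` from [build_feature_table()].
#' @param cfg The [synthetic_cohort_config()] used to generate the
#'   sequences.
#' @param confounders Optional confounder table (as attached by
#'   [simulate_sequences()]); re-drawn deterministically from the seed
#'   when omitted.
#'
#' @return A cohort `data.frame`: features joined with confounders and
#'   the outcome column `cfg$outcome_name`.
#' @export
simulate_outcomes <- function(features, cfg, confounders = NULL) {
  stopifnot(inherits(cfg, "synthetic_cohort_config"))
  if (is.null(confounders)) confounders <- draw_confounders(cfg)
  tab <- merge(features, confounders, by = "participant_id")
  coefs <- cfg$outcome_coefficients
  mu <- rep(0, nrow(tab))
  for (nm in names(coefs)) {
    if (nm == "intercept") {
      mu <- mu + coefs[[nm]]
    } else {
      if (!nm %in% names(tab)) {
        abort_ab(sprintf("outcome coefficient references unknown feature '%s'",
                         nm), "actibigram_config_error")
      }
      mu <- mu + coefs[[nm]] * tab[[nm]]
    }
  }
  for (nm in names(cfg$confounders)) {
    mu <- mu + cfg$confounders[[nm]]$effect * tab[[nm]]
  }
  if (!is.null(cfg$activity_confounder)) {
    ac <- cfg$activity_confounder
    mu <- mu + ac$effect * tab[[ac$name]]
  }
  set.seed(cfg$seed + 3L)
  noise <- stats::rnorm(cfg$n_participants, 0, cfg$noise_sd)
  # noise is drawn per participant id so that dropping invalid
  # participants upstream does not shift other participants' outcomes
  idx <- match(tab$participant_id, participant_ids(cfg$n_participants))
  tab[[cfg$outcome_name]] <- mu + noise[idx]
  tab
}

#' Simulate a complete analysis-ready cohort
#'
#' Convenience wrapper: simulates sequences, runs non-wear detection,
#' validity screening and feature extraction, then generates outcomes.
#'
#' @param cfg A [synthetic_cohort_config()].
#' @param rules [validity_rules()] applied during screening.
#' @param day_policy Passed to [build_feature_table()].
#'
#' @return A list with `series` (raw epoch series), `features`,
#'   `validity` and `cohort` (the analysis table including outcome and
#'   confounders).
#' @export
simulate_cohort <- function(cfg, rules = validity_rules(),
                            day_policy = "all_days") {
  series <- simulate_sequences(cfg)
  ft <- build_feature_table(series, cuts = cfg$cuts, rules = rules,
                            day_policy = day_policy)
  cohort <- simulate_outcomes(ft$features, cfg,
                              confounders = attr(series, "confounders"))
  list(series = series, features = ft$features, validity = ft$validity,
       cohort = cohort)
}
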