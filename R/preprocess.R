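#' Activity intensity cut-points
#'
#' Count-per-minute thresholds separating the four activity states:
#' sedentary 0--`sedentary_max`, low up to `low_max`, moderate up to
#' `moderate_max`, vigorous above. Defaults are the age-11 ActiGraph
#' cut-points: sedentary 0--100, low 101--2019, moderate 2020--5998,
#' vigorous 5999+.
#'
#' @param sedentary_max Upper bound (inclusive) of the sedentary band.
#' @param low_max Upper bound (inclusive) of the low band.
#' @param moderate_max Upper bound (inclusive) of the moderate band.
#'
#' @return An object of class `cut_points`.
#' @export
#' @examples
#' cut_points()
cut_points <- function(sedentary_max = 100, low_max = 2019,
                       moderate_max = 5998) {
  if (!(0 <= sedentary_max && sedentary_max < low_max &&
        low_max < moderate_max)) {
    abort_ab("cut-points must satisfy 0 <= sedentary_max < low_max < moderate_max",
             "actibigram_invalid_input")
  }
  structure(list(sedentary_max = sedentary_max, low_max = low_max,
                 moderate_max = moderate_max),
            class = "cut_points")
}

#' Wear-time validity rules
#'
#' Rules used to mask non-wear time and decide whether a participant's
#' recording is valid: a maximal run of zero counts strictly longer than
#' 60 epochs (1 h) is non-wear; a day is valid with at least 8 h
#' (480 epochs) of wear; a participant is valid with at least 3 valid
#' days and a wear-time mean count per minute of at most 1500.
#'
#' @param nonwear_run_min_epochs Minimum zero-run length (epochs) that
#'   counts as non-wear; default 61, i.e. runs strictly longer than 60.
#' @param valid_day_min_wear_epochs Minimum wear epochs for a valid day
#'   (default 480 = 8 h).
#' @param min_valid_days Minimum number of valid days (default 3).
#' @param max_mean_cpm Maximum plausible wear-time mean counts/min
#'   (default 1500).
#'
#' @return An object of class `validity_rules`.
#' @export
#' @examples
#' validity_rules()
validity_rules <- function(nonwear_run_min_epochs = 61,
                           valid_day_min_wear_epochs = 480,
                           min_valid_days = 3,
                           max_mean_cpm = 1500) {
  vals <- c(nonwear_run_min_epochs, valid_day_min_wear_epochs,
            min_valid_days, max_mean_cpm)
  if (any(vals <= 0)) {
    abort_ab("all validity rule fields must be positive",
             "actibigram_invalid_input")
  }
  structure(list(nonwear_run_min_epochs = as.integer(nonwear_run_min_epochs),
                 valid_day_min_wear_epochs = as.integer(valid_day_min_wear_epochs),
                 min_valid_days = as.integer(min_valid_days),
                 max_mean_cpm = max_mean_cpm),
            class = "validity_rules")
}

#' Detect non-wear time from runs of zero counts
#'
#' Marks as missing every epoch belonging to a maximal run of zero counts
#' whose length is at least `rules$nonwear_run_min_epochs` (default 61,
#' i.e. strictly longer than one hour of zeros). Epochs already flagged
#' missing (e.g. padding) stay missing, so the operation is idempotent.
#'
#' @param series An [epoch_series()].
#' @param rules A [validity_rules()] object.
#'
#' @return The series with `missing_mask` updated.
#' @export
#' @examples
#' es <- epoch_series("p", c(rep(100, 10), rep(0, 70), rep(100, 1360)),
#'                    n_days = 1)
#' sum(detect_nonwear(es)$missing_mask)  # 70
detect_nonwear <- function(series, rules = validity_rules()) {
  stopifnot(inherits(series, "epoch_series"))
  if (length(series$counts) == 0) {
    abort_ab("empty counts sequence", "actibigram_empty_input")
  }
  r <- rle(series$counts == 0)
  nonwear <- rep(r$values & r$lengths >= rules$nonwear_run_min_epochs,
                 r$lengths)
  series$missing_mask <- series$missing_mask | nonwear
  series
}

#' Categorize counts into activity states
#'
#' Maps each worn epoch's count to one of the four activity states via
#' the cut-points (default: 0--100 sedentary, 101--2019 low, 2020--5998
#' moderate, 5999+ vigorous). Epochs flagged missing become `NA`
#' regardless of their stored count. Zero counts on worn epochs are
#' sedentary; only long zero runs are masked as non-wear.
#'
#' @param series An [epoch_series()] whose `missing_mask` has been
#'   finalized (see [detect_nonwear()]).
#' @param cuts A [cut_points()] object.
#'
#' @return A [state_sequence()] aligned 1:1 with the epochs.
#' @export
#' @examples
#' es <- epoch_series("p", c(0, 100, 101, 2019, 2020, 5998, 5999),
#'                    n_days = 1, epochs_per_day = 7)
#' categorize(es)$states
categorize <- function(series, cuts = cut_points()) {
  stopifnot(inherits(series, "epoch_series"))
  if (any(series$counts < 0)) {
    abort_ab("negative activity count", "actibigram_invalid_input")
  }
  states <- cut(series$counts,
                breaks = c(-Inf, cuts$sedentary_max, cuts$low_max,
                           cuts$moderate_max, Inf),
                labels = activity_states())
  states <- as.character(states)
  states[series$missing_mask] <- NA_character_
  structure(
    list(participant_id = series$participant_id,
         states = states,
         n_days = series$n_days,
         epochs_per_day = series$epochs_per_day),
    class = "state_sequence")
}

#' Wear-time count summaries
#'
#' Computes the wear-time mean counts per minute (mCPM), the sample
#' standard deviation of wear-time counts per minute (sdCPM), and the
#' number of worn epochs in each recording day.
#'
#' @param series An [epoch_series()] with `missing_mask` finalized.
#'
#' @return A list with `mCPM`, `sdCPM` (counts/min) and
#'   `wear_epochs_per_day` (integer vector of length `n_days`).
#' @export
wear_summaries <- function(series) {
  stopifnot(inherits(series, "epoch_series"))
  worn <- series$counts[!series$missing_mask]
  if (length(worn) == 0) {
    abort_ab("no wear epochs: summaries undefined",
             "actibigram_undefined_summary")
  }
  day <- rep(seq_len(series$n_days),
             each = series$epochs_per_day)[seq_along(series$counts)]
  wear_per_day <- tabulate(day[!series$missing_mask],
                           nbins = series$n_days)
  list(mCPM = mean(worn),
       sdCPM = stats::sd(worn),
       wear_epochs_per_day = wear_per_day)
}

#' Apply participant-level validity rules
#'
#' A day is valid if it has at least
#' `rules$valid_day_min_wear_epochs` worn epochs (default 8 h). A
#' participant's recording is valid if at least `rules$min_valid_days`
#' days are valid and the wear-time mean counts per minute does not
#' exceed `rules$max_mean_cpm`. The mean uses worn epochs only,
#' consistent with the definition of mCPM.
#'
#' @param series An [epoch_series()] with `missing_mask` finalized.
#' @param rules A [validity_rules()] object.
#'
#' @return A list with `valid` (logical), `reasons` (character vector of
#'   failed rules, empty when valid), `valid_day_flags` (logical per
#'   day), `n_valid_days` and `mCPM`.
#' @export
validate_participant <- function(series, rules = validity_rules()) {
  stopifnot(inherits(series, "epoch_series"))
  if (series$n_days == 0 || length(series$counts) == 0) {
    abort_ab("no recorded days", "actibigram_empty_input")
  }
  if (all(series$missing_mask)) {
    ws <- list(mCPM = NA_real_,
               wear_epochs_per_day = rep(0L, series$n_days))
  } else {
    ws <- wear_summaries(series)
  }
  flags <- ws$wear_epochs_per_day >= rules$valid_day_min_wear_epochs
  n_valid <- sum(flags)
  reasons <- character(0)
  if (n_valid < rules$min_valid_days) {
    reasons <- c(reasons, sprintf("fewer than %d valid days (%d)",
                                  rules$min_valid_days, n_valid))
  }
  if (!is.na(ws$mCPM) && ws$mCPM > rules$max_mean_cpm) {
    reasons <- c(reasons, sprintf("mean cpm exceeds %s (%.1f)",
                                  format(rules$max_mean_cpm), ws$mCPM))
  }
  list(valid = length(reasons) == 0,
       reasons = reasons,
       valid_day_flags = flags,
       n_valid_days = n_valid,
       mCPM = ws$mCPM)
}
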