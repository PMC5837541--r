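#' Per-minute activity count series for one participant
#'
#' Container for a single participant's accelerometer recording: one
#' integer activity count per 1-minute epoch, organised as `n_days` blocks
#' of `epochs_per_day` epochs counted from the start of the recording
#' (devices are typically programmed to start at a fixed clock time, so
#' "days" are recording days, not calendar days). A logical
#' `missing_mask` marks epochs classified as non-wear time.
#'
#' @param participant_id Scalar identifier (character or coercible).
#' @param counts Integer vector of non-negative activity counts per epoch.
#' @param n_days Number of recorded days (default 7).
#' @param epochs_per_day Epochs per day (default 1440, i.e. 1-min epochs).
#' @param missing_mask Optional logical vector, same length as `counts`;
#'   `TRUE` marks non-wear/missing epochs. Defaults to all-`FALSE`.
#' @param pad If `TRUE`, a recording shorter than
#'   `n_days * epochs_per_day` is padded with trailing zero-count epochs
#'   flagged as missing; if `FALSE` (default) such a recording is
#'   rejected, mirroring the exclusion of participants without complete
#'   recordings.
#'
#' @return An object of class `epoch_series`: a list with elements
#'   `participant_id`, `counts`, `n_days`, `epochs_per_day`,
#'   `missing_mask`.
#' @export
#' @examples
#' es <- epoch_series("p1", rep(c(0, 500), 720), n_days = 1)
#' es
epoch_series <- function(participant_id, counts, n_days = 7,
                         epochs_per_day = 1440, missing_mask = NULL,
                         pad = FALSE) {
  if (length(counts) == 0) {
    abort_ab("empty counts sequence", "actibigram_empty_input")
  }
  if (anyNA(counts)) {
    abort_ab("counts must not contain NA", "actibigram_invalid_input")
  }
  counts <- as.integer(counts)
  if (any(counts < 0)) {
    abort_ab("counts must be non-negative", "actibigram_invalid_input")
  }
  stopifnot(n_days >= 1, epochs_per_day >= 1)
  full_len <- n_days * epochs_per_day
  if (is.null(missing_mask)) {
    missing_mask <- rep(FALSE, length(counts))
  }
  if (length(missing_mask) != length(counts)) {
    abort_ab("missing_mask and counts lengths differ",
             "actibigram_invalid_input")
  }
  if (length(counts) > full_len) {
    abort_ab(sprintf("counts longer (%d) than n_days * epochs_per_day (%d)",
                     length(counts), full_len),
             "actibigram_invalid_input")
  }
  if (length(counts) < full_len) {
    if (!pad) {
      abort_ab(sprintf(
        "counts shorter (%d) than n_days * epochs_per_day (%d); set pad = TRUE to pad trailing epochs as missing",
        length(counts), full_len), "actibigram_invalid_input")
    }
    n_pad <- full_len - length(counts)
    counts <- c(counts, rep(0L, n_pad))
    missing_mask <- c(missing_mask, rep(TRUE, n_pad))
  }
  structure(
    list(participant_id = as.character(participant_id)[1],
         counts = counts,
         n_days = as.integer(n_days),
         epochs_per_day = as.integer(epochs_per_day),
         missing_mask = as.logical(missing_mask)),
    class = "epoch_series")
}

#' @export
print.epoch_series <- function(x, ...) {
  cat(sprintf("<epoch_series> participant %s: %d epochs (%d days x %d/day), %d flagged missing\n",
              x$participant_id, length(x$counts), x$n_days,
              x$epochs_per_day, sum(x$missing_mask)))
  invisible(x)
}

#' Activity-state sequence aligned to an epoch series
#'
#' Categorical sequence over the alphabet S/L/M/V, aligned 1:1 with the
#' epochs of an [epoch_series()]. Missing (non-wear) epochs are `NA`.
#' Usually produced by [categorize()]; this constructor is useful for
#' worked examples and tests.
#'
#' @param states Character vector over `c("S","L","M","V")` with `NA` for
#'   missing epochs, or a single string such as `"SSSLS"`.
#' @param n_days Number of days the sequence spans (divisor for per-day
#'   frequencies; default 1 for short literal sequences).
#' @param epochs_per_day Epochs per day; defaults to
#'   `ceiling(length(states) / n_days)`.
#' @param participant_id Optional identifier.
#'
#' @return An object of class `state_sequence`.
#' @export
#' @examples
#' state_sequence("SSSLS")
state_sequence <- function(states, n_days = 1, epochs_per_day = NULL,
                           participant_id = NA_character_) {
  if (length(states) == 1 && !is.na(states) && nchar(states) > 1) {
    states <- strsplit(states, "")[[1]]
  }
  states[states == "."] <- NA_character_
  bad <- !is.na(states) & !(states %in% activity_states())
  if (any(bad)) {
    abort_ab(sprintf("invalid state symbols: %s",
                     paste(unique(states[bad]), collapse = ", ")),
             "actibigram_invalid_input")
  }
  if (is.null(epochs_per_day)) {
    epochs_per_day <- as.integer(ceiling(length(states) / n_days))
  }
  structure(
    list(participant_id = as.character(participant_id)[1],
         states = as.character(states),
         n_days = as.integer(n_days),
         epochs_per_day = as.integer(epochs_per_day)),
    class = "state_sequence")
}

#' @export
print.state_sequence <- function(x, ...) {
  n <- length(x$states)
  shown <- paste(ifelse(is.na(x$states[seq_len(min(n, 60))]), ".",
                        x$states[seq_len(min(n, 60))]), collapse = "")
  if (n > 60) shown <- paste0(shown, "...")
  cat(sprintf("<state_sequence> %d epochs over %d day(s): %s\n",
              n, x$n_days, shown))
  invisible(x)
}

#' @export
format.state_sequence <- function(x, ...) {
  paste(ifelse(is.na(x$states), ".", x$states), collapse = "")
}
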