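#' Count bigram occurrences in a state sequence
#'
#' Counts, over every adjacent epoch pair (i, i+1) of the full multi-day
#' sequence, the number of occurrences of each of the 16 ordered bigrams.
#' Epoch pairs are overlapping: the pair at (t, t+1) overlaps the pairs
#' at (t-1, t) and (t+1, t+2), so e.g. both `SSSLS` and `SSLSS` contain
#' the SS bigram twice. Pairs where either epoch is missing (non-wear)
#' contribute to no bigram; pairs spanning a day boundary inside the
#' continuous recording are included.
#'
#' @param seq A [state_sequence()].
#'
#' @return Named integer vector of length 16 (raw counts, not divided by
#'   days), in [bigram_names()] order, with attribute `n_valid_pairs`.
#' @export
#' @examples
#' count_bigrams(state_sequence("SSSLS"))[c("SS", "SL", "LS")]
count_bigrams <- function(seq) {
  stopifnot(inherits(seq, "state_sequence"))
  if (length(seq$states) == 0) {
    abort_ab("empty state sequence", "actibigram_empty_input")
  }
  nm <- bigram_names()
  n <- length(seq$states)
  if (n < 2) {
    counts <- stats::setNames(rep(0L, 16), nm)
    attr(counts, "n_valid_pairs") <- 0L
    return(counts)
  }
  s <- match(seq$states, activity_states())  # 1..4, NA for missing
  a <- s[-n]
  b <- s[-1]
  ok <- !is.na(a) & !is.na(b)
  code <- (a[ok] - 1L) * 4L + b[ok]  # row-major: SS=1, SL=2, ..., VV=16
  counts <- stats::setNames(tabulate(code, nbins = 16L), nm)
  attr(counts, "n_valid_pairs") <- sum(ok)
  counts
}

#' Bigram average-per-day frequency profile
#'
#' The frequency of bigram AB per day is the number of adjacent epoch
#' pairs in state A then state B over the whole sequence, divided by the
#' number of days D.
#'
#' @param seq A [state_sequence()].
#' @param D Number of days used as divisor; defaults to `seq$n_days`.
#'
#' @return An object of class `bigram_profile`: list with `b` (named
#'   numeric of length 16, frequencies/day), `D`, and `n_valid_pairs`
#'   (adjacent pairs with both epochs worn).
#' @export
#' @examples
#' bigram_profile(state_sequence("SSSLS"), D = 1)$b[["SS"]]  # 2
bigram_profile <- function(seq, D = NULL) {
  stopifnot(inherits(seq, "state_sequence"))
  if (is.null(D)) D <- seq$n_days
  if (D <= 0) {
    abort_ab("D must be positive", "actibigram_invalid_parameter")
  }
  counts <- count_bigrams(seq)
  structure(
    list(b = counts / D,
         D = D,
         n_valid_pairs = attr(counts, "n_valid_pairs")),
    class = "bigram_profile")
}

#' @export
print.bigram_profile <- function(x, ...) {
  cat(sprintf("<bigram_profile> D = %s, %d valid epoch pairs\n",
              format(x$D), x$n_valid_pairs))
  print(round(x$b, 3))
  invisible(x)
}

#' Unordered-bigram (u-bigram) profile
#'
#' Collapses the 16 ordered bigram frequencies into 10 unordered
#' u-bigram frequencies: `[AB] = b(A,B) + b(B,A)` for distinct states,
#' while `[AA]` equals the bigram AA (each adjacent same-state pair is
#' counted once, not doubled).
#'
#' @param p A [bigram_profile()].
#'
#' @return An object of class `ubigram_profile`: list with `bu` (named
#'   numeric of length 10, names as in [ubigram_names()]) and `D`.
#' @export
#' @examples
#' p <- bigram_profile(state_sequence("SLS"), D = 1)
#' ubigram_profile(p)$bu[["[SL]"]]  # 2
ubigram_profile <- function(p) {
  stopifnot(inherits(p, "bigram_profile"))
  # row-major bigram index of AB and BA for each of the 10 u-bigram keys
  fwd <- c(1L, 2L, 3L, 4L, 6L, 7L, 8L, 11L, 12L, 16L)   # SS SL SM SV LL LM LV MM MV VV
  rev_ <- c(1L, 5L, 9L, 13L, 6L, 10L, 14L, 11L, 15L, 16L)  # SS LS MS VS LL ML VL MM VM VV
  bu <- unname(p$b[fwd]) + ifelse(fwd == rev_, 0, unname(p$b[rev_]))
  bu <- stats::setNames(bu, ubigram_names())
  structure(list(bu = bu, D = p$D), class = "ubigram_profile")
}

#' @export
print.ubigram_profile <- function(x, ...) {
  cat(sprintf("<ubigram_profile> D = %s\n", format(x$D)))
  print(round(x$bu, 3))
  invisible(x)
}

#' Average minutes per day in each activity state
#'
#' Counts worn epochs per state over the whole sequence and divides by
#' the number of days, giving Sd, Ld, Md, Vd in minutes/day.
#'
#' @param seq A [state_sequence()].
#' @param D Number of days used as divisor; defaults to `seq$n_days`.
#'
#' @return An object of class `state_durations`: list with `Sd`, `Ld`,
#'   `Md`, `Vd` (minutes/day) and `D`.
#' @export
#' @examples
#' state_durations(state_sequence("SSSLS"), D = 1)
state_durations <- function(seq, D = NULL) {
  stopifnot(inherits(seq, "state_sequence"))
  if (is.null(D)) D <- seq$n_days
  if (D <= 0) {
    abort_ab("D must be positive", "actibigram_invalid_parameter")
  }
  tab <- table(factor(seq$states, levels = activity_states()))
  structure(
    list(Sd = as.numeric(tab[["S"]]) / D,
         Ld = as.numeric(tab[["L"]]) / D,
         Md = as.numeric(tab[["M"]]) / D,
         Vd = as.numeric(tab[["V"]]) / D,
         D = D),
    class = "state_durations")
}

#' @export
print.state_durations <- function(x, ...) {
  cat(sprintf("<state_durations> min/day over D = %s: S %.1f, L %.1f, M %.1f, V %.1f\n",
              format(x$D), x$Sd, x$Ld, x$Md, x$Vd))
  invisible(x)
}

#' Minutes spanned by the occurrences of one bigram
#'
#' Because epoch pairs overlap, a bigram's frequency does not correspond
#' to a fixed amount of time: SSSLS and SSLSS both contain two SS
#' bigrams, but their occurrences cover 3 and 4 distinct minutes
#' respectively. This diagnostic reports the number of distinct epochs
#' covered by at least one occurrence of the given bigram.
#'
#' @param seq A [state_sequence()].
#' @param pair Two-character bigram such as `"SS"`, or a length-2
#'   character vector.
#'
#' @return Integer number of distinct minutes (epochs).
#' @export
#' @examples
#' bigram_minute_span(state_sequence("SSSLS"), "SS")  # 3
#' bigram_minute_span(state_sequence("SSLSS"), "SS")  # 4
bigram_minute_span <- function(seq, pair) {
  stopifnot(inherits(seq, "state_sequence"))
  if (length(pair) == 1) pair <- strsplit(pair, "")[[1]]
  if (length(pair) != 2 || !all(pair %in% activity_states())) {
    abort_ab("pair must name two activity states, e.g. \"SS\"",
             "actibigram_invalid_input")
  }
  n <- length(seq$states)
  if (n < 2) return(0L)
  a <- seq$states[-n]
  b <- seq$states[-1]
  hit <- which(!is.na(a) & !is.na(b) & a == pair[1] & b == pair[2])
  length(unique(c(hit, hit + 1L)))
}

#' Per-participant feature row
#'
#' Computes the full feature set for one participant's finalized state
#' sequence: the 16 bigram frequencies per day, the 10 u-bigram
#' frequencies, the per-day state durations Sd/Ld/Md/Vd, mCPM and sdCPM,
#' the divisor D and the number of valid epoch pairs.
#'
#' Two day policies are supported. Under `"all_days"` (the main
#' analysis) the divisor is the total number of recorded days. Under
#' `"valid_days_only"` (a sensitivity analysis) days with fewer than 8 h
#' of wear are removed entirely — epoch pairs spanning a removed day are
#' dropped — and the divisor is the number of valid days.
#'
#' @param series An [epoch_series()] with `missing_mask` finalized.
#' @param cuts A [cut_points()] object.
#' @param rules A [validity_rules()] object (used by the valid-day
#'   policy).
#' @param day_policy `"all_days"` or `"valid_days_only"`.
#'
#' @return A one-row `data.frame` with columns `participant_id`, the 16
#'   bigram names, the 10 u-bigram columns (`u_SS` ... `u_VV`), `Sd`,
#'   `Ld`, `Md`, `Vd`, `mCPM`, `sdCPM`, `D`, `n_valid_pairs`.
#' @export
compute_features <- function(series, cuts = cut_points(),
                             rules = validity_rules(),
                             day_policy = c("all_days", "valid_days_only")) {
  vals <- compute_features_core(series, cuts, rules, match.arg(day_policy))
  out <- data.frame(participant_id = series$participant_id,
                    stringsAsFactors = FALSE)
  out[names(vals)] <- as.list(vals)
  out
}

# internal: feature row as a named numeric vector (fast path)
compute_features_core <- function(series, cuts, rules, day_policy) {
  stopifnot(inherits(series, "epoch_series"))
  ws <- wear_summaries(series)
  if (day_policy == "valid_days_only") {
    flags <- ws$wear_epochs_per_day >= rules$valid_day_min_wear_epochs
    if (!any(flags)) {
      abort_ab(sprintf("participant %s has no valid days",
                       series$participant_id),
               "actibigram_no_valid_days")
    }
    day <- rep(seq_len(series$n_days),
               each = series$epochs_per_day)[seq_along(series$counts)]
    series$missing_mask <- series$missing_mask | !flags[day]
    D <- sum(flags)
    ws <- wear_summaries(series)  # summaries over retained days
  } else {
    D <- series$n_days
  }
  seq <- categorize(series, cuts)
  p <- bigram_profile(seq, D = D)
  up <- ubigram_profile(p)
  sd_ <- state_durations(seq, D = D)
  c(p$b,
    stats::setNames(up$bu, ubigram_col(ubigram_names())),
    Sd = sd_$Sd, Ld = sd_$Ld, Md = sd_$Md, Vd = sd_$Vd,
    mCPM = ws$mCPM, sdCPM = ws$sdCPM, D = D,
    n_valid_pairs = p$n_valid_pairs)
}

#' Feature table for a cohort
#'
#' Applies non-wear detection, validity screening and
#' [compute_features()] to a list of raw [epoch_series()], returning one
#' feature row per retained participant.
#'
#' @param series_list List of [epoch_series()] (raw counts; non-wear
#'   detection is applied here).
#' @param cuts,rules,day_policy Passed to [compute_features()].
#' @param keep_invalid If `FALSE` (default) participants failing the
#'   validity rules are dropped; if `TRUE` they are retained and flagged.
#'
#' @return A list with `features` (data.frame, one row per retained
#'   participant) and `validity` (data.frame: participant_id, valid,
#'   reasons, n_valid_days, mCPM, sdCPM).
#' @export
build_feature_table <- function(series_list, cuts = cut_points(),
                                rules = validity_rules(),
                                day_policy = "all_days",
                                keep_invalid = FALSE) {
  stopifnot(length(series_list) > 0)
  n <- length(series_list)
  v_id <- character(n); v_ok <- logical(n); v_why <- character(n)
  v_days <- integer(n); v_mcpm <- numeric(n); v_sdcpm <- numeric(n)
  feats <- vector("list", n)
  f_id <- character(n)
  for (i in seq_len(n)) {
    es <- detect_nonwear(series_list[[i]], rules)
    v <- validate_participant(es, rules)
    v_id[i] <- es$participant_id
    v_ok[i] <- v$valid
    v_why[i] <- paste(v$reasons, collapse = "; ")
    v_days[i] <- v$n_valid_days
    v_mcpm[i] <- v$mCPM
    v_sdcpm[i] <- if (all(es$missing_mask)) NA_real_ else
      wear_summaries(es)$sdCPM
    if (v$valid || keep_invalid) {
      feats[[i]] <- tryCatch(
        compute_features_core(es, cuts, rules, day_policy),
        actibigram_no_valid_days = function(e) NULL)
      f_id[i] <- es$participant_id
    }
  }
  keep <- !vapply(feats, is.null, logical(1))
  features <- NULL
  if (any(keep)) {
    features <- as.data.frame(do.call(rbind, feats[keep]))
    features <- cbind(data.frame(participant_id = f_id[keep],
                                 stringsAsFactors = FALSE),
                      features)
    rownames(features) <- NULL
  }
  list(features = features,
       validity = data.frame(participant_id = v_id, valid = v_ok,
                             reasons = v_why, n_valid_days = v_days,
                             mCPM = v_mcpm, sdCPM = v_sdcpm,
                             stringsAsFactors = FALSE))
}
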