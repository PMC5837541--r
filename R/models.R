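#' Merge features and phenotypes into a cohort analysis table
#'
#' Joins the per-participant feature table (from
#' [build_feature_table()]) with a phenotype table carrying the outcome
#' and covariates, keeping participants present in both.
#'
#' @param features Feature `data.frame` with a `participant_id` column.
#' @param phenotypes Phenotype `data.frame` with a `participant_id`
#'   column, the outcome (e.g. `BMI`) and any covariates.
#'
#' @return A merged `data.frame`, one row per participant.
#' @export
cohort_table <- function(features, phenotypes) {
  stopifnot("participant_id" %in% names(features),
            "participant_id" %in% names(phenotypes))
  merge(features, phenotypes, by = "participant_id")
}

#' Specification of one swap-style regression model
#'
#' Defines a single baseline-versus-comparison contrast: transferring
#' time between two activity states (`state_transfer`), or frequency
#' between two bigrams (`bigram_swap`) or u-bigrams (`ubigram_swap`).
#' The comparison feature and the combined remainder enter the model;
#' the baseline feature does not, so the coefficient on the comparison
#' feature is interpreted as the effect of increasing it at the expense
#' of the baseline, holding the remainder fixed.
#'
#' Adjustment sets follow a fixed series: `model1` unadjusted; `model2`
#' adds the supplied covariates; `model3` (swap kinds only) additionally
#' adjusts for the minutes/day in each activity state (Sd, Ld, Md, Vd);
#' `model4` (swap kinds only) additionally adjusts for mCPM.
#'
#' @param kind One of `"state_transfer"`, `"bigram_swap"`,
#'   `"ubigram_swap"`.
#' @param baseline,comparison State letters (e.g. `"S"`), bigram names
#'   (e.g. `"MV"`) or u-bigram names (e.g. `"[MV]"`), matching `kind`.
#' @param adjustment `"model1"` ... `"model4"`.
#' @param scale `"per_10"` (effect per 10 min/day or 10 epoch pairs/day)
#'   or `"per_sd"` (effect per 1 sample SD of the baseline feature).
#' @param outcome Name of the outcome column (default `"BMI"`).
#' @param covariates Character vector of covariate column names used by
#'   `model2`--`model4`.
#' @param nd Epochs per day (default 1440).
#'
#' @return An object of class `swap_model_spec`.
#' @export
#' @examples
#' swap_model_spec("ubigram_swap", baseline = "[SS]", comparison = "[MV]")
swap_model_spec <- function(kind = c("state_transfer", "bigram_swap",
                                     "ubigram_swap"),
                            baseline, comparison,
                            adjustment = c("model1", "model2", "model3",
                                           "model4"),
                            scale = c("per_10", "per_sd"),
                            outcome = "BMI",
                            covariates = character(),
                            nd = 1440) {
  kind <- match.arg(kind)
  adjustment <- match.arg(adjustment)
  scale <- match.arg(scale)
  valid_keys <- switch(kind,
    state_transfer = activity_states(),
    bigram_swap = bigram_names(),
    ubigram_swap = ubigram_names())
  for (key in c(baseline, comparison)) {
    if (!key %in% valid_keys) {
      abort_ab(sprintf("'%s' is not a valid %s key", key, kind),
               "actibigram_invalid_input")
    }
  }
  if (identical(baseline, comparison)) {
    abort_ab("baseline and comparison must differ",
             "actibigram_invalid_input")
  }
  if (kind == "state_transfer" && adjustment %in% c("model3", "model4")) {
    abort_ab("model3/model4 adjustment applies to bigram/u-bigram swap models only",
             "actibigram_invalid_input")
  }
  structure(list(kind = kind, baseline = baseline,
                 comparison = comparison, adjustment = adjustment,
                 scale = scale, outcome = outcome,
                 covariates = as.character(covariates),
                 nd = nd),
            class = "swap_model_spec")
}

# internal: feature column name for a spec key
feature_column <- function(kind, key) {
  switch(kind,
         state_transfer = paste0(key, "d"),
         bigram_swap = key,
         ubigram_swap = ubigram_col(key))
}

# internal: covariate columns implied by an adjustment set
adjustment_columns <- function(spec) {
  cols <- character(0)
  if (spec$adjustment %in% c("model2", "model3", "model4")) {
    cols <- spec$covariates
  }
  if (spec$adjustment == "model3") cols <- c(cols, "Sd", "Ld", "Md", "Vd")
  if (spec$adjustment == "model4") cols <- c(cols, "mCPM")
  unique(cols)
}

# internal: shared OLS engine for all swap families.
# remainder_total is nd for state transfers (minutes in a day) and
# nd - 1 for bigram swaps (epoch pairs in a day).
fit_swap_ols <- function(table, spec, remainder_total) {
  base_col <- feature_column(spec$kind, spec$baseline)
  comp_col <- feature_column(spec$kind, spec$comparison)
  covs <- adjustment_columns(spec)
  needed <- c(spec$outcome, base_col, comp_col, covs)
  missing_cols <- setdiff(needed, names(table))
  if (length(missing_cols) > 0) {
    abort_ab(sprintf("columns not found in cohort table: %s",
                     paste(missing_cols, collapse = ", ")),
             "actibigram_invalid_input")
  }
  dat <- table[stats::complete.cases(table[needed]), needed, drop = FALSE]
  n <- nrow(dat)
  n_terms <- 3 + length(covs)  # intercept + comparison + remainder + covs
  if (n < n_terms + 2) {
    abort_ab(sprintf("only %d complete cases for %d model terms", n,
                     n_terms), "actibigram_invalid_input")
  }
  if (stats::sd(dat[[comp_col]]) == 0) {
    abort_ab(sprintf("comparison feature '%s' has zero variance",
                     comp_col), "actibigram_degenerate_feature")
  }
  df_fit <- data.frame(
    .outcome = dat[[spec$outcome]],
    .comparison = dat[[comp_col]],
    .remainder = remainder_total - dat[[comp_col]] - dat[[base_col]])
  for (cv in covs) df_fit[[cv]] <- dat[[cv]]
  fit <- stats::lm(.outcome ~ ., data = df_fit)
  coefs <- stats::coef(fit)
  if (anyNA(coefs)) {
    abort_ab(sprintf("rank-deficient design; aliased terms: %s",
                     paste(names(coefs)[is.na(coefs)], collapse = ", ")),
             "actibigram_collinearity_error")
  }
  sm <- summary(fit)$coefficients
  raw_beta <- sm[".comparison", "Estimate"]
  raw_se <- sm[".comparison", "Std. Error"]
  tcrit <- stats::qt(0.975, df = fit$df.residual)
  if (spec$scale == "per_10") {
    mult <- 10
    sd_baseline <- NA_real_
  } else {
    sd_baseline <- stats::sd(dat[[base_col]])
    mult <- sd_baseline
  }
  structure(
    list(kind = spec$kind,
         baseline = spec$baseline,
         comparison = spec$comparison,
         adjustment = spec$adjustment,
         scale = spec$scale,
         beta_scaled = mult * raw_beta,
         ci_low = mult * (raw_beta - tcrit * raw_se),
         ci_high = mult * (raw_beta + tcrit * raw_se),
         raw_beta = raw_beta,
         raw_se = raw_se,
         n_used = n,
         sd_of_baseline = sd_baseline),
    class = "swap_model_result")
}

#' @export
print.swap_model_result <- function(x, ...) {
  unit <- switch(x$scale,
                 per_10 = "per 10-unit swap",
                 per_sd = sprintf("per 1 SD of baseline (%.3f)",
                                  x$sd_of_baseline),
                 x$scale)
  cat(sprintf("<swap_model_result> %s: %s -> %s [%s]\n", x$kind,
              x$baseline, x$comparison, x$adjustment))
  cat(sprintf("  effect %s: %.4f (95%% CI %.4f, %.4f), n = %d\n",
              unit, x$beta_scaled, x$ci_low, x$ci_high, x$n_used))
  invisible(x)
}

#' Fit a state time-transfer model
#'
#' Regresses the outcome on the minutes/day spent in the comparison
#' state and on the remaining time `r = nd - (comparison + baseline)`,
#' plus any adjustment covariates. The baseline state is omitted, so the
#' coefficient on the comparison state estimates the effect of
#' transferring time from the baseline to the comparison state.
#' `beta_scaled` multiplies the coefficient by 10 (a 10-min/day
#' transfer) under `per_10`, or by the sample SD of the baseline
#' feature under `per_sd`. Exchanging baseline and comparison
#' reparametrizes the same model and negates the estimate exactly.
#'
#' @param table Cohort `data.frame` from [cohort_table()].
#' @param spec A [swap_model_spec()] with `kind = "state_transfer"`.
#'
#' @return A `swap_model_result`.
#' @export
fit_state_transfer <- function(table, spec) {
  stopifnot(inherits(spec, "swap_model_spec"))
  if (spec$kind != "state_transfer") {
    abort_ab("spec$kind must be 'state_transfer'",
             "actibigram_invalid_input")
  }
  fit_swap_ols(table, spec, remainder_total = spec$nd)
}

#' Fit a bigram or u-bigram frequency-swap model
#'
#' Regresses the outcome on the comparison (u-)bigram's frequency per
#' day and on the remaining number of epoch pairs per day
#' `rb = (nd - 1) - comparison - baseline`, plus adjustment covariates.
#' The coefficient on the comparison frequency estimates the effect of
#' increasing that frequency at the expense of the baseline (u-)bigram,
#' allowing collateral shifts within the remainder.
#'
#' @param table Cohort `data.frame`.
#' @param spec A [swap_model_spec()] with `kind = "bigram_swap"` or
#'   `"ubigram_swap"`.
#'
#' @return A `swap_model_result`.
#' @export
fit_bigram_swap <- function(table, spec) {
  stopifnot(inherits(spec, "swap_model_spec"))
  if (!spec$kind %in% c("bigram_swap", "ubigram_swap")) {
    abort_ab("spec$kind must be 'bigram_swap' or 'ubigram_swap'",
             "actibigram_invalid_input")
  }
  fit_swap_ols(table, spec, remainder_total = spec$nd - 1)
}

#' Fit the mCPM and sdCPM models
#'
#' Tests the association of the wear-time mean counts per minute (mCPM)
#' and its standard deviation (sdCPM) with the outcome, individually or
#' after mutual adjustment. The mCPM effect is reported per 100
#' counts/min; the sdCPM effect per 1 sample SD of sdCPM.
#'
#' @param table Cohort `data.frame` with `mCPM` and `sdCPM` columns.
#' @param adjustment `"model1"` (unadjusted) or `"model2"` (covariate
#'   adjusted).
#' @param mutual If `TRUE`, each model additionally adjusts for the
#'   other exposure (mCPM for sdCPM and vice versa).
#' @param outcome Outcome column name.
#' @param covariates Covariate columns for `model2`.
#'
#' @return A list with elements `mCPM` and `sdCPM`, each a
#'   `swap_model_result`-like list with `beta_scaled`, `ci_low`,
#'   `ci_high`, `raw_beta`, `raw_se`, `n_used`, `scale_unit`.
#' @export
fit_cpm_models <- function(table, adjustment = c("model1", "model2"),
                           mutual = FALSE, outcome = "BMI",
                           covariates = character()) {
  adjustment <- match.arg(adjustment)
  covs <- if (adjustment == "model2") covariates else character(0)
  fit_one <- function(exposure, other, mult_fn, scale_unit) {
    extra <- if (mutual) other else character(0)
    needed <- c(outcome, exposure, extra, covs)
    missing_cols <- setdiff(needed, names(table))
    if (length(missing_cols) > 0) {
      abort_ab(sprintf("columns not found: %s",
                       paste(missing_cols, collapse = ", ")),
               "actibigram_invalid_input")
    }
    dat <- table[stats::complete.cases(table[needed]), needed,
                 drop = FALSE]
    df_fit <- dat
    names(df_fit)[1] <- ".outcome"
    fit <- stats::lm(.outcome ~ ., data = df_fit)
    coefs <- stats::coef(fit)
    if (anyNA(coefs)) {
      abort_ab(sprintf("rank-deficient design; aliased terms: %s",
                       paste(names(coefs)[is.na(coefs)], collapse = ", ")),
               "actibigram_collinearity_error")
    }
    sm <- summary(fit)$coefficients
    raw_beta <- sm[exposure, "Estimate"]
    raw_se <- sm[exposure, "Std. Error"]
    tcrit <- stats::qt(0.975, df = fit$df.residual)
    mult <- mult_fn(dat)
    list(exposure = exposure,
         adjustment = adjustment,
         mutual = mutual,
         beta_scaled = mult * raw_beta,
         ci_low = mult * (raw_beta - tcrit * raw_se),
         ci_high = mult * (raw_beta + tcrit * raw_se),
         raw_beta = raw_beta, raw_se = raw_se,
         n_used = nrow(dat),
         scale_unit = scale_unit)
  }
  list(mCPM = fit_one("mCPM", "sdCPM", function(d) 100,
                      "per 100 counts/min"),
       sdCPM = fit_one("sdCPM", "mCPM",
                       function(d) stats::sd(d[["sdCPM"]]),
                       "per 1 SD of sdCPM"))
}

#' Fit the full grid of swap contrasts
#'
#' Fits every unordered pair of activity states (6 transfer contrasts)
#' and/or every unordered pair of u-bigrams (45 contrasts; optionally
#' the 120 ordered-bigram contrasts), under each requested adjustment
#' model. Only one orientation per pair is fitted — the reciprocal
#' orientation is the exact negation. Per-fit errors are captured as
#' flagged rows rather than aborting the grid.
#'
#' @param table Cohort `data.frame`.
#' @param families Subset of `c("state_transfer", "ubigram_swap",
#'   "bigram_swap")`.
#' @param models Subset of `c("model1", ..., "model4")` (`model3`/
#'   `model4` are skipped for `state_transfer`).
#' @param scale `"per_10"` or `"per_sd"`.
#' @param outcome,covariates,nd As in [swap_model_spec()].
#'
#' @return A `data.frame` with one row per (family, baseline,
#'   comparison, model): columns `kind`, `baseline`, `comparison`,
#'   `model`, `beta`, `ci_low`, `ci_high`, `n`, `sd_baseline`, `error`.
#' @export
run_full_grid <- function(table,
                          families = c("state_transfer", "ubigram_swap"),
                          models = c("model1", "model2"),
                          scale = "per_10", outcome = "BMI",
                          covariates = character(), nd = 1440) {
  families <- match.arg(families,
                        c("state_transfer", "ubigram_swap", "bigram_swap"),
                        several.ok = TRUE)
  rows <- list()
  for (family in families) {
    keys <- switch(family,
                   state_transfer = activity_states(),
                   ubigram_swap = ubigram_names(),
                   bigram_swap = bigram_names())
    pairs <- utils::combn(keys, 2)
    for (model in models) {
      if (family == "state_transfer" && model %in% c("model3", "model4")) {
        next
      }
      for (k in seq_len(ncol(pairs))) {
        # present each pair once: baseline is the later key in canonical
        # order, comparison the earlier, matching conventional tables
        baseline <- pairs[2, k]
        comparison <- pairs[1, k]
        res <- tryCatch({
          spec <- swap_model_spec(family, baseline = baseline,
                                  comparison = comparison,
                                  adjustment = model, scale = scale,
                                  outcome = outcome,
                                  covariates = covariates, nd = nd)
          if (family == "state_transfer") {
            fit_state_transfer(table, spec)
          } else {
            fit_bigram_swap(table, spec)
          }
        }, error = function(e) e)
        if (inherits(res, "error")) {
          rows[[length(rows) + 1]] <- data.frame(
            kind = family, baseline = baseline, comparison = comparison,
            model = model, beta = NA_real_, ci_low = NA_real_,
            ci_high = NA_real_, n = NA_integer_,
            sd_baseline = NA_real_, error = conditionMessage(res),
            stringsAsFactors = FALSE)
        } else {
          rows[[length(rows) + 1]] <- data.frame(
            kind = family, baseline = baseline, comparison = comparison,
            model = model, beta = res$beta_scaled, ci_low = res$ci_low,
            ci_high = res$ci_high, n = res$n_used,
            sd_baseline = res$sd_of_baseline, error = NA_character_,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}
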