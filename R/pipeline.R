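#' Read per-epoch counts from a long-format CSV
#'
#' Expects columns `participant_id`, `epoch_index` (0-based from
#' recording start) and `counts`. Rows are sorted by epoch index within
#' participant; gaps in the index are not allowed.
#'
#' @param path CSV file path.
#' @param n_days,epochs_per_day Recording structure (defaults 7 and
#'   1440).
#' @param pad Passed to [epoch_series()]: pad short recordings with
#'   trailing missing epochs instead of rejecting them.
#'
#' @return A named list of [epoch_series()].
#' @export
read_counts_csv <- function(path, n_days = 7, epochs_per_day = 1440,
                            pad = FALSE) {
  if (!file.exists(path)) {
    abort_ab(sprintf("counts file not found: %s", path),
             "actibigram_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("participant_id", "epoch_index", "counts")
  if (!all(needed %in% names(df))) {
    abort_ab(sprintf("counts CSV must have columns: %s",
                     paste(needed, collapse = ", ")),
             "actibigram_io_error")
  }
  bad <- which(is.na(df$counts) | is.na(df$epoch_index))
  if (length(bad) > 0) {
    abort_ab(sprintf("malformed counts row at line %d (header is line 1)",
                     bad[1] + 1L), "actibigram_io_error")
  }
  out <- lapply(split(df, df$participant_id), function(d) {
    d <- d[order(d$epoch_index), ]
    if (!identical(as.integer(d$epoch_index),
                   seq_len(nrow(d)) - 1L)) {
      abort_ab(sprintf("participant %s: epoch_index must be 0..n-1 without gaps",
                       d$participant_id[1]), "actibigram_io_error")
    }
    epoch_series(d$participant_id[1], d$counts, n_days = n_days,
                 epochs_per_day = epochs_per_day, pad = pad)
  })
  out[order(names(out))]
}

#' Write per-epoch counts to a long-format CSV
#'
#' Inverse of [read_counts_csv()].
#'
#' @param series_list List of [epoch_series()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_counts_csv <- function(series_list, path) {
  rows <- lapply(series_list, function(es) {
    data.frame(participant_id = es$participant_id,
               epoch_index = seq_along(es$counts) - 1L,
               counts = es$counts)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a phenotype table
#'
#' A CSV with one row per participant: `participant_id`, the outcome
#' and covariates.
#'
#' @param path CSV file path.
#' @return A `data.frame`.
#' @export
read_phenotypes_csv <- function(path) {
  if (!file.exists(path)) {
    abort_ab(sprintf("phenotype file not found: %s", path),
             "actibigram_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"participant_id" %in% names(df)) {
    abort_ab("phenotype CSV must have a participant_id column",
             "actibigram_io_error")
  }
  df
}

#' Write the per-participant validity report
#'
#' TSV with columns participant_id, valid, reasons, n_valid_days, mCPM,
#' sdCPM.
#'
#' @param validity Validity `data.frame` from [build_feature_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_validity_report <- function(validity, path) {
  utils::write.table(validity, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write masked state sequences
#'
#' One row per participant: `participant_id` and the state string, one
#' character per epoch (S/L/M/V, `.` for missing).
#'
#' @param sequences List of [state_sequence()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_state_sequences <- function(sequences, path) {
  df <- data.frame(
    participant_id = vapply(sequences, function(s) s$participant_id,
                            character(1)),
    states = vapply(sequences, format, character(1)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read the per-participant feature table
#'
#' The TSV carries the 16 bigram columns (SS ... VV), the 10 u-bigram
#' columns (written with their bracketed names `[SS]` ... `[VV]`),
#' Sd/Ld/Md/Vd, mCPM, sdCPM, D and n_valid_pairs, in that fixed order.
#'
#' @param features Feature `data.frame` from [build_feature_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly (`read_features_tsv` returns the
#'   `data.frame` with column-safe `u_` names).
#' @export
write_features_tsv <- function(features, path) {
  out <- features
  names(out) <- ifelse(grepl("^u_", names(out)), ubigram_label(names(out)),
                       names(out))
  utils::write.table(out, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_features_tsv
#' @export
read_features_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- ifelse(grepl("^\\[", names(df)), ubigram_col(names(df)),
                      names(df))
  df
}

#' Write association-grid results
#'
#' @param results Result `data.frame` from [run_full_grid()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_associations_tsv <- function(results, path) {
  utils::write.table(results, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles everything one end-to-end run needs: input paths, cut-points,
#' validity rules, the day policy, the model grid request and the
#' outcome/covariate names.
#'
#' @param counts_csv,phenotypes_csv Input file paths.
#' @param output_dir Directory for all outputs (created if absent).
#' @param n_days,epochs_per_day Recording structure.
#' @param cuts,rules [cut_points()] / [validity_rules()].
#' @param day_policy `"all_days"` or `"valid_days_only"`.
#' @param outcome Outcome column in the phenotype table.
#' @param covariates Covariate columns used by model2--model4.
#' @param families,models,scale Model grid request (see
#'   [run_full_grid()]).
#' @param pad Pad short recordings instead of rejecting them.
#'
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(counts_csv, phenotypes_csv, output_dir,
                            n_days = 7, epochs_per_day = 1440,
                            cuts = cut_points(), rules = validity_rules(),
                            day_policy = c("all_days", "valid_days_only"),
                            outcome = "BMI", covariates = character(),
                            families = c("state_transfer", "ubigram_swap"),
                            models = c("model1", "model2"),
                            scale = "per_10", pad = FALSE) {
  day_policy <- match.arg(day_policy)
  structure(
    list(counts_csv = counts_csv, phenotypes_csv = phenotypes_csv,
         output_dir = output_dir, n_days = n_days,
         epochs_per_day = epochs_per_day, cuts = cuts, rules = rules,
         day_policy = day_policy, outcome = outcome,
         covariates = covariates, families = families, models = models,
         scale = scale, pad = pad),
    class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' The file may set any [pipeline_config()] argument; `cut_points` and
#' `validity_rules` are given as nested maps of their fields.
#'
#' @param path Config file (`.yaml`, `.yml` or `.json`).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    abort_ab(sprintf("config file not found: %s", path),
             "actibigram_io_error")
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  args <- raw
  if (!is.null(raw$cut_points)) {
    args$cuts <- do.call(cut_points, raw$cut_points)
    args$cut_points <- NULL
  }
  if (!is.null(raw$validity_rules)) {
    args$rules <- do.call(validity_rules, raw$validity_rules)
    args$validity_rules <- NULL
  }
  do.call(pipeline_config, args)
}

#' Run the full pipeline
#'
#' Executes preprocess (non-wear detection, validity screening) ->
#' feature extraction -> association grid, writing the validity report,
#' masked state sequences, feature table, association results and a run
#' manifest into `config$output_dir`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list of the written file paths plus the in-memory
#'   tables.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  series <- read_counts_csv(config$counts_csv, n_days = config$n_days,
                            epochs_per_day = config$epochs_per_day,
                            pad = config$pad)
  phenotypes <- read_phenotypes_csv(config$phenotypes_csv)
  ft <- build_feature_table(series, cuts = config$cuts,
                            rules = config$rules,
                            day_policy = config$day_policy)
  if (is.null(ft$features) || nrow(ft$features) == 0) {
    abort_ab("no valid participants after screening",
             "actibigram_empty_cohort")
  }
  masked <- lapply(series[ft$features$participant_id], function(es) {
    categorize(detect_nonwear(es, config$rules), config$cuts)
  })
  table <- cohort_table(ft$features, phenotypes)
  results <- run_full_grid(table, families = config$families,
                           models = config$models, scale = config$scale,
                           outcome = config$outcome,
                           covariates = config$covariates,
                           nd = config$epochs_per_day)
  paths <- list(
    validity = file.path(config$output_dir, "validity_report.tsv"),
    sequences = file.path(config$output_dir, "state_sequences.csv"),
    features = file.path(config$output_dir, "features.tsv"),
    associations = file.path(config$output_dir, "associations.tsv"),
    manifest = file.path(config$output_dir, "manifest.json"))
  write_validity_report(ft$validity, paths$validity)
  write_state_sequences(masked, paths$sequences)
  write_features_tsv(ft$features, paths$features)
  write_associations_tsv(results, paths$associations)
  write_manifest(config, paths$manifest,
                 n_participants = length(series),
                 n_retained = nrow(ft$features))
  invisible(list(paths = paths,
                 features = ft$features,
                 validity = ft$validity,
                 associations = results))
}

# internal: run manifest with a config hash for provenance
write_manifest <- function(config, path, n_participants, n_retained) {
  cfg_plain <- unclass(config)
  cfg_plain$cuts <- unclass(cfg_plain$cuts)
  cfg_plain$rules <- unclass(cfg_plain$rules)
  cfg_json <- jsonlite::toJSON(cfg_plain, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  writeLines(cfg_json, tmp)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  manifest <- list(
    config = cfg_plain,
    config_md5 = hash,
    day_policy = config$day_policy,
    n_participants_input = n_participants,
    n_participants_retained = n_retained,
    package_version = as.character(utils::packageVersion("actibigram")),
    r_version = R.version.string)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
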