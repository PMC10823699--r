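# File interchange: session-log / participant / scores CSVs with
# seed+fingerprint header comments, task/cohort configs as JSON or
# YAML, and the analysis report as JSON plus a readable text table.

csv_header <- function(seed, fingerprint) {
  c(sprintf("# seed: %s", paste(seed, collapse = ",")),
    sprintf("# config_fingerprint: %s", fingerprint))
}

write_commented_csv <- function(df, path, seed, fingerprint) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(csv_header(seed, fingerprint), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, qmethod = "double")
  invisible(path)
}

read_commented_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write and read session logs
#'
#' One row per trial: `participant_id`, `global_index`, `is_catch`,
#' `delay_days`, `present_offer`, `future_offer`, `choice`, and (catch
#' trials only) `correct`. Session seeds and the configuration
#' fingerprint are embedded as `#` comment lines. Dyadic offers are
#' written as exact terminating decimals, so the log round-trips
#' bit-exactly.
#'
#' @param sessions A `dd_session` or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_session_log <- function(sessions, path) {
  if (inherits(sessions, "dd_session")) sessions <- list(sessions)
  rows <- do.call(rbind, lapply(sessions, function(s) {
    tr <- s$trials
    data.frame(participant_id = s$participant_id,
               global_index = tr$global_index,
               is_catch = tr$is_catch,
               delay_days = tr$delay_days,
               present_offer = tr$present_offer,
               future_offer = tr$future_offer,
               choice = tr$choice,
               correct = tr$correct)
  }))
  write_commented_csv(rows, path,
                      seed = vapply(sessions, `[[`, integer(1), "seed"),
                      fingerprint = sessions[[1]]$config_fingerprint)
}

#' @rdname write_session_log
#' @param config The [task_config()] the log was produced under; used
#'   to validate the schema when reading.
#' @return `read_session_log()` returns the per-trial data frame.
#' @export
read_session_log <- function(path, config = task_config()) {
  log <- read_commented_csv(path)
  needed <- c("participant_id", "global_index", "is_catch", "delay_days",
              "present_offer", "future_offer", "choice")
  missing <- setdiff(needed, names(log))
  if (length(missing))
    stop_domain("session log is missing column(s): ",
                paste(missing, collapse = ", "))
  if (nrow(log)) {
    tokens <- ifelse(log$is_catch, log$choice %in% c("a", "b"),
                     log$choice %in% c("present", "future"))
    if (any(!tokens))
      stop_domain("invalid choice token in session log at row(s): ",
                  paste(utils::head(which(!tokens), 5), collapse = ", "))
  }
  log
}

#' Score every participant in a session log
#'
#' Splits the per-trial table by participant and scores each complete
#' session. An empty log yields an empty scores table (with a
#' warning).
#'
#' @param log Per-trial data frame from [read_session_log()].
#' @param config The [task_config()] of the sessions.
#' @return A scores data frame as from [scores_table()].
#' @export
score_session_log <- function(log, config = task_config()) {
  if (nrow(log) == 0) {
    warning("empty session log; returning empty scores table")
    return(data.frame(participant_id = character(0), k = numeric(0),
                      ln_k = numeric(0), catch_correct = integer(0),
                      catch_total = integer(0), valid = logical(0)))
  }
  ids <- unique(log$participant_id)
  scores_table(lapply(ids, function(id) {
    score_trials(log[log$participant_id == id, , drop = FALSE], config, id)
  }))
}

#' Write and read participant and scores tables
#'
#' Plain CSVs with the seed and configuration fingerprint as comment
#' lines in the header.
#'
#' @param df The table to write.
#' @param path CSV path.
#' @param seed Seed(s) recorded in the header.
#' @param fingerprint Configuration fingerprint recorded in the header.
#' @return The path (writers) or the table (readers), invisibly for
#'   writers.
#' @export
write_table_csv <- function(df, path, seed, fingerprint) {
  write_commented_csv(df, path, seed, fingerprint)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) read_commented_csv(path)

#' Save and load configurations as JSON or YAML
#'
#' The file format follows the extension: `.json` (default) or
#' `.yaml`/`.yml`. Catch trials and group tables round-trip losslessly.
#'
#' @param config A [task_config()] or [cohort_spec()].
#' @param path Output path.
#' @return `path` invisibly; `read_task_config()` /
#'   `read_cohort_spec()` return the reconstructed object.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  if (inherits(config, "dd_task_config"))
    x$catch_trials <- lapply(x$catch_trials, unclass)
  if (inherits(config, "dd_cohort_spec")) {
    # keep names of atomic vectors through JSON/YAML
    x$flag_marginals <- as.list(x$flag_marginals)
    x$female_fraction <- as.list(x$female_fraction)
  }
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_domain("the yaml package is required for YAML configs")
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns", pretty = TRUE)
  }
  invisible(path)
}

read_config_raw <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_domain("the yaml package is required for YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' @rdname write_config
#' @export
read_task_config <- function(path) {
  x <- read_config_raw(path)
  ct_list <- x$catch_trials
  if (is.data.frame(ct_list))  # jsonlite simplifies uniform object arrays
    ct_list <- lapply(seq_len(nrow(ct_list)), function(i) as.list(ct_list[i, ]))
  catches <- lapply(ct_list, function(ct) {
    catch_spec(ct$a_amount, ct$a_delay, ct$b_amount, ct$b_delay,
               correct = ct$correct)
  })
  task_config(future_amount = x$future_amount,
              initial_present = x$initial_present,
              delays = as.numeric(x$delays),
              trials_per_delay = x$trials_per_delay,
              catch_trials = catches,
              catch_positions = as.integer(x$catch_positions))
}

#' @rdname write_config
#' @export
read_cohort_spec <- function(path) {
  x <- read_config_raw(path)
  cohort_spec(groups = as.data.frame(x$groups),
              flag_marginals = unlist(x$flag_marginals),
              age_range = as.numeric(x$age_range),
              female_fraction = unlist(x$female_fraction),
              mode = x$mode,
              inverse_temperature = as.numeric(x$inverse_temperature),
              catch_error_rate = x$catch_error_rate,
              seed = x$seed)
}

#' Serialize an analysis report
#'
#' `report_to_list()` flattens a `dd_report` into plain lists suitable
#' for JSON; `write_report()` writes the JSON (and, optionally, the
#' human-readable text table produced by `print()`).
#'
#' @param report A `dd_report` from [analyze_study()].
#' @param seed Seed recorded in the report.
#' @return A plain list / the JSON path, invisibly.
#' @export
report_to_list <- function(report, seed = NULL) {
  stopifnot(inherits(report, "dd_report"))
  anc <- report$ancova
  out <- list(
    seed = seed,
    n_analyzed = report$n_analyzed,
    group_summaries = report$group_summaries,
    ancova = list(F = anc$F, df_num = anc$df_num, df_den = anc$df_den,
                  p = anc$p, eta_p2 = anc$eta_p2,
                  covariate_coefficient = anc$covariate_coefficient,
                  residual_variance = anc$residual_variance,
                  grand_mean_age = anc$grand_mean_age,
                  adjusted_means = anc$adjusted_means),
    pairwise = as.data.frame(report$pairwise),
    power = unclass(report$power))
  if (!is.null(report$regression)) {
    reg <- report$regression
    out$regression <- list(coefficients = reg$coefficients, F = reg$F,
                           p_overall = reg$p_overall, r2 = reg$r2,
                           adjusted_r2 = reg$adjusted_r2)
  }
  out
}

#' @rdname report_to_list
#' @param json_path Output path for the JSON report.
#' @param text_path Optional output path for the text tables.
#' @export
write_report <- function(report, json_path, text_path = NULL, seed = NULL) {
  jsonlite::write_json(report_to_list(report, seed = seed), json_path,
                       auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  if (!is.null(text_path)) {
    txt <- utils::capture.output(print(report))
    writeLines(txt, text_path)
  }
  invisible(json_path)
}
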