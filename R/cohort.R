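#' Specify a synthetic study cohort
#'
#' Describes a three-group cohort (ARFID, AN, HC) with the statistical
#' structure of the study sample the package emulates: group sizes,
#' normal `ln(k)` distributions, truncated-normal age distributions,
#' and the marginal counts of the three ARFID presentation flags
#' (sensory sensitivity, fear of aversive consequences, lack of
#' interest in eating or food), which may co-occur. Defaults encode
#' n = 57/28/19, `ln(k)` means -6.1/-7.3/-5.4 (SD 2.0/1.7/1.5), ages
#' 17.42/20.75/21.32 (SD 5.38/3.76/7.60) truncated to 10--30 years,
#' and flag marginals 45/18/24 with every ARFID participant carrying at
#' least one presentation.
#'
#' @param groups Data frame with columns `group`, `n`, `ln_k_mean`,
#'   `ln_k_sd`, `age_mean`, `age_sd`.
#' @param flag_marginals Named integer vector of ARFID presentation
#'   counts; each must be at most the ARFID `n` and their sum at least
#'   the ARFID `n` (so that every participant can carry a flag).
#' @param age_range Plausible age interval; out-of-range draws are
#'   resampled.
#' @param female_fraction Named per-group probability of female sex.
#'   Sex is generated for realism but unused by the statistics.
#' @param mode `"direct"` samples `ln_k` per group and passes it to the
#'   analysis unchanged; `"behavioral"` converts each draw to
#'   `k_true = exp(ln_k)`, runs the full task per participant, and
#'   scores the resulting sessions.
#' @param inverse_temperature Choice-noise scale for behavioral mode;
#'   `Inf` (default) uses deterministic hyperbolic agents.
#' @param catch_error_rate Behavioral-mode catch error probability.
#' @param seed Default seed used when [generate_cohort()] or
#'   [simulate_study()] is called without one.
#' @return An object of class `dd_cohort_spec`.
#' @export
#' @examples
#' cohort_spec()
cohort_spec <- function(groups = data.frame(
                          group = c("ARFID", "AN", "HC"),
                          n = c(57L, 28L, 19L),
                          ln_k_mean = c(-6.1, -7.3, -5.4),
                          ln_k_sd = c(2.0, 1.7, 1.5),
                          age_mean = c(17.42, 20.75, 21.32),
                          age_sd = c(5.38, 3.76, 7.60)),
                        flag_marginals = c(sensory_sensitivity = 45L,
                                           fear_of_aversive_consequences = 18L,
                                           lack_of_interest = 24L),
                        age_range = c(10, 30),
                        female_fraction = c(ARFID = 34 / 57, AN = 1,
                                            HC = 7 / 19),
                        mode = c("direct", "behavioral"),
                        inverse_temperature = Inf,
                        catch_error_rate = 0,
                        seed = 20260101L) {
  mode <- match.arg(mode)
  needed <- c("group", "n", "ln_k_mean", "ln_k_sd", "age_mean", "age_sd")
  if (!all(needed %in% names(groups)))
    stop_domain("`groups` must have columns ", paste(needed, collapse = ", "))
  if (any(groups$n <= 0)) stop_domain("all group sizes must be positive")
  if (any(groups$ln_k_sd <= 0) || any(groups$age_sd <= 0))
    stop_domain("all SDs must be positive")
  if (length(age_range) != 2 || age_range[1] >= age_range[2])
    stop_domain("`age_range` must be an increasing interval")
  if ("ARFID" %in% groups$group && length(flag_marginals)) {
    n_arfid <- groups$n[groups$group == "ARFID"]
    if (any(flag_marginals < 0) || any(flag_marginals > n_arfid))
      stop_domain("infeasible flag marginals: each must lie in [0, n_ARFID]")
    if (sum(flag_marginals) < n_arfid)
      stop_domain("infeasible flag marginals: sum ", sum(flag_marginals),
                  " < n_ARFID = ", n_arfid,
                  " (cannot give every participant a presentation)")
  }
  structure(list(groups = groups, flag_marginals = flag_marginals,
                 age_range = age_range, female_fraction = female_fraction,
                 mode = mode, inverse_temperature = inverse_temperature,
                 catch_error_rate = catch_error_rate, seed = as.integer(seed)),
            class = "dd_cohort_spec")
}

#' @export
print.dd_cohort_spec <- function(x, ...) {
  cat("Synthetic cohort specification (", x$mode, " mode)\n", sep = "")
  print(x$groups, row.names = FALSE)
  if (length(x$flag_marginals))
    cat("  ARFID presentation marginals:",
        paste(names(x$flag_marginals), x$flag_marginals, sep = "=",
              collapse = ", "), "\n")
  invisible(x)
}

# Truncated-normal draws by resampling out-of-range values.
rnorm_trunc <- function(n, mean, sd, range) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < range[1] | x > range[2])
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < range[1] | x[bad] > range[2]]
  }
  x
}

# Random 0/1 flag matrix with exact column marginals and every row
# non-empty: allocate each column uniformly, then repair empty rows by
# moving a flag from a row holding two or more (possible whenever
# sum(marginals) >= n; pigeonhole guarantees a donor).
assign_presentation_flags <- function(n, marginals) {
  m <- matrix(0L, nrow = n, ncol = length(marginals),
              dimnames = list(NULL, names(marginals)))
  for (j in seq_along(marginals))
    m[sample.int(n, marginals[j]), j] <- 1L
  repeat {
    empty <- which(rowSums(m) == 0L)
    if (!length(empty)) break
    z <- empty[1]
    donors <- which(rowSums(m) >= 2L)
    d <- if (length(donors) == 1L) donors else sample(donors, 1)
    cols <- which(m[d, ] == 1L)
    j <- if (length(cols) == 1L) cols else sample(cols, 1)
    m[d, j] <- 0L
    m[z, j] <- 1L
  }
  m
}

#' Generate a synthetic cohort
#'
#' Draws participants group by group: `ln_k ~ Normal(mean, SD)` per
#' group, ages from a truncated normal, optional sex, and ARFID
#' presentation flags allocated at random subject to the exact marginal
#' counts with at least one flag per ARFID participant. Fully
#' reproducible from the seed.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; defaults to the seed stored in the spec.
#' @return A data frame with one row per participant: `participant_id`,
#'   `group`, `age`, `sex`, the three flag columns, and `ln_k` (direct
#'   mode) or `k_true` (behavioral mode).
#' @export
#' @examples
#' table(generate_cohort(cohort_spec(), seed = 7)$group)
generate_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "dd_cohort_spec"))
  with_seed(seed, {
    parts <- lapply(seq_len(nrow(spec$groups)), function(i) {
      g <- spec$groups[i, ]
      ln_k <- stats::rnorm(g$n, g$ln_k_mean, g$ln_k_sd)
      age <- rnorm_trunc(g$n, g$age_mean, g$age_sd, spec$age_range)
      pf <- spec$female_fraction[[as.character(g$group)]]
      sex <- if (is.null(pf)) NA_character_
        else ifelse(stats::runif(g$n) < pf, "female", "male")
      df <- data.frame(group = g$group, age = age, sex = sex,
                       sensory_sensitivity = 0L,
                       fear_of_aversive_consequences = 0L,
                       lack_of_interest = 0L)
      if (g$group == "ARFID" && length(spec$flag_marginals)) {
        flags <- assign_presentation_flags(g$n, spec$flag_marginals)
        df[, colnames(flags)] <- flags
      }
      if (spec$mode == "direct") df$ln_k <- ln_k else df$k_true <- exp(ln_k)
      df
    })
    cohort <- do.call(rbind, parts)
    cohort <- cbind(participant_id = sprintf("P%03d", seq_len(nrow(cohort))),
                    cohort)
    rownames(cohort) <- NULL
    cohort
  })
}

#' Simulate a full study
#'
#' In direct mode the sampled `ln_k` is the outcome and the scores
#' table simply mirrors it. In behavioral mode every participant is
#' turned into an agent with `k_true` from the cohort draw, runs a
#' complete session of the task, is scored, and the catch-trial
#' exclusion rule is applied; the returned tables join on
#' `participant_id`.
#'
#' @param spec A [cohort_spec()].
#' @param config A [task_config()]; required for behavioral mode.
#' @param seed Master seed; cohort draws and per-participant session
#'   streams use independent child seeds derived from it.
#' @param return_sessions Keep the raw `dd_session` objects (behavioral
#'   mode only).
#' @return A list with `participants` (the cohort table), `scores`
#'   (retained scores), `excluded` (scores failing the catch rule), and
#'   optionally `sessions`.
#' @export
#' @examples
#' study <- simulate_study(cohort_spec(), seed = 11)
#' nrow(study$participants)  # 104
simulate_study <- function(spec, config = task_config(), seed = spec$seed,
                           return_sessions = FALSE) {
  stopifnot(inherits(spec, "dd_cohort_spec"))
  seeds <- derive_seeds(seed, 2)
  participants <- generate_cohort(spec, seed = seeds[1])

  if (spec$mode == "direct") {
    scores <- data.frame(participant_id = participants$participant_id,
                         k = exp(participants$ln_k),
                         ln_k = participants$ln_k,
                         catch_correct = NA_integer_,
                         catch_total = NA_integer_,
                         valid = TRUE)
    return(list(participants = participants, scores = scores,
                excluded = scores[0, , drop = FALSE]))
  }

  stopifnot(inherits(config, "dd_task_config"))
  n <- nrow(participants)
  session_seeds <- derive_seeds(seeds[2], n)
  sessions <- vector("list", n)
  scores <- vector("list", n)
  for (i in seq_len(n)) {
    agent <- if (is.finite(spec$inverse_temperature)) {
      dd_agent("logistic_hyperbolic", k_true = participants$k_true[i],
               inverse_temperature = spec$inverse_temperature,
               catch_error_rate = spec$catch_error_rate)
    } else {
      dd_agent("deterministic_hyperbolic", k_true = participants$k_true[i],
               catch_error_rate = spec$catch_error_rate)
    }
    sessions[[i]] <- run_session(agent, config, seed = session_seeds[i],
                                 participant_id = participants$participant_id[i])
    scores[[i]] <- score_session(sessions[[i]], config)
  }
  split <- apply_exclusions(scores_table(scores))
  out <- list(participants = participants,
              scores = split$retained, excluded = split$excluded)
  if (return_sessions) out$sessions <- sessions
  out
}
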