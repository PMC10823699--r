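#' ANCOVA of ln(k) on group with an age covariate
#'
#' Fits the linear model `ln_k ~ group + age` by ordinary least squares
#' and tests the group term with a Type II sum of squares (for this
#' one-factor-plus-covariate design Types II and III coincide under the
#' default treatment coding). Adjusted (estimated marginal) group means
#' are the model predictions at the grand mean age over all analyzed
#' participants.
#'
#' @param data Data frame with columns `ln_k`, `group`, `age`; at least
#'   two groups with two observations each and non-constant age.
#' @return An object of class `dd_ancova`: `F`, `df_num`, `df_den`,
#'   `p`, `eta_p2`, `adjusted_means` (with standard errors),
#'   `covariate_coefficient`, `residual_variance`, group sizes, the
#'   grand mean age, and the underlying `lm` fit.
#' @export
#' @examples
#' study <- simulate_study(cohort_spec(), seed = 3)
#' dat <- merge(study$scores, study$participants, by = "participant_id")
#' ancova_group_effect(dat)
ancova_group_effect <- function(data) {
  needed <- c("ln_k", "group", "age")
  if (!all(needed %in% names(data)))
    stop_domain("`data` must have columns ", paste(needed, collapse = ", "))
  data <- data.frame(ln_k = data$ln_k,
                     group = factor(data$group, levels = unique(data$group)),
                     age = data$age)
  if (nlevels(data$group) < 2 || any(table(data$group) < 2))
    stop_domain("need at least 2 groups with at least 2 observations each")
  if (stats::var(data$age) == 0)
    stop_domain("age is constant; the covariate cannot be estimated")

  fit <- stats::lm(ln_k ~ group + age, data = data)
  if (fit$rank < length(stats::coef(fit)))
    stop_domain("singular design: group and age are confounded")
  rss_full <- sum(stats::residuals(fit)^2)
  rss_age <- sum(stats::residuals(stats::lm(ln_k ~ age, data = data))^2)
  ss_group <- rss_age - rss_full
  df_num <- nlevels(data$group) - 1L
  df_den <- fit$df.residual
  F_stat <- (ss_group / df_num) / (rss_full / df_den)
  p <- stats::pf(F_stat, df_num, df_den, lower.tail = FALSE)

  grand_age <- mean(data$age)
  newdata <- data.frame(group = factor(levels(data$group),
                                       levels = levels(data$group)),
                        age = grand_age)
  pred <- stats::predict(fit, newdata = newdata, se.fit = TRUE)
  adjusted <- data.frame(group = levels(data$group),
                         adjusted_mean = as.numeric(pred$fit),
                         se = as.numeric(pred$se.fit),
                         n = as.integer(table(data$group)))

  structure(list(F = F_stat, df_num = df_num, df_den = df_den, p = p,
                 eta_p2 = ss_group / (ss_group + rss_full),
                 ss_group = ss_group, ss_resid = rss_full,
                 adjusted_means = adjusted,
                 covariate_coefficient = unname(stats::coef(fit)["age"]),
                 residual_variance = rss_full / df_den,
                 grand_mean_age = grand_age,
                 fit = fit, data = data),
            class = "dd_ancova")
}

#' @export
print.dd_ancova <- function(x, digits = 3, ...) {
  cat(sprintf("ANCOVA of ln(k) on group, age-covaried: F(%d, %d) = %.2f, p = %.3g, partial eta^2 = %.2f\n",
              x$df_num, x$df_den, x$F, x$p, x$eta_p2))
  cat("Age-adjusted group means of ln(k):\n")
  print(x$adjusted_means, row.names = FALSE, digits = digits)
  invisible(x)
}

#' Bar chart of age-adjusted group means
#'
#' @param x A `dd_ancova`.
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the bar midpoints.
#' @export
plot.dd_ancova <- function(x, ...) {
  am <- x$adjusted_means
  mids <- graphics::barplot(am$adjusted_mean, names.arg = am$group,
                            ylab = "age-adjusted mean ln(k)",
                            ylim = range(0, am$adjusted_mean - 2 * am$se,
                                         am$adjusted_mean + 2 * am$se), ...)
  graphics::arrows(mids, am$adjusted_mean - am$se,
                   mids, am$adjusted_mean + am$se,
                   angle = 90, code = 3, length = 0.06)
  invisible(mids)
}

#' Partial eta squared from an F statistic
#'
#' The sum-of-squares identity
#' `eta_p^2 = SS_effect / (SS_effect + SS_error)` expressed through the
#' F statistic: `F * df_num / (F * df_num + df_den)`.
#'
#' @param F F statistic (>= 0).
#' @param df_num,df_den Numerator and denominator degrees of freedom.
#' @return Effect-size proportion in `[0, 1)`; vectorized.
#' @export
#' @examples
#' partial_eta_squared(5.93, 2, 101)  # ~0.105
partial_eta_squared <- function(F, df_num, df_den) {
  if (any(F < 0) || any(df_num < 1) || any(df_den < 1))
    stop_domain("need F >= 0 and both dfs >= 1")
  (F * df_num) / (F * df_num + df_den)
}

#' Hedges' g standardized mean difference
#'
#' Cohen's d on the pooled standard deviation, multiplied by the
#' small-sample bias correction `J = 1 - 3 / (4 (n1 + n2) - 9)`.
#'
#' @param mean1,sd1,n1 Summary statistics of the first sample.
#' @param mean2,sd2,n2 Summary statistics of the second sample.
#' @return Hedges' g; positive when the first mean is larger.
#' @export
#' @examples
#' hedges_g(-6.10, 2.00, 57, -7.26, 1.73, 28)  # ~0.60
hedges_g <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (min(sd1, sd2) < 0 || min(n1, n2) < 2)
    stop_domain("need non-negative SDs and n >= 2 per sample")
  s_pooled <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  if (s_pooled == 0) stop_domain("degenerate pooled SD")
  j <- 1 - 3 / (4 * (n1 + n2) - 9)
  j * (mean1 - mean2) / s_pooled
}

#' Pairwise t-tests on age-adjusted means
#'
#' Planned pairwise contrasts between the groups of a fitted ANCOVA.
#' Each contrast is the difference of adjusted means, with a standard
#' error from the full model's coefficient covariance (single pooled
#' residual variance, not per-pair refits), a t-test on the model's
#' residual degrees of freedom, and Bonferroni correction multiplying
#' the raw p by the number of contrasts (capped at 1). Hedges' g is
#' attached per pair, by default from the raw group means and SDs of
#' `ln_k`; set `g_adjusted = TRUE` to standardize the adjusted-mean
#' difference by the raw pooled SD instead.
#'
#' @param result A `dd_ancova` from [ancova_group_effect()].
#' @param g_adjusted Use the adjusted-mean difference in the numerator
#'   of Hedges' g.
#' @return A data frame of class `dd_pairwise`, one row per contrast:
#'   `contrast`, `difference` (adjusted means), `se`, `t`, `df`,
#'   `p_raw`, `p_bonferroni`, `hedges_g`.
#' @export
pairwise_adjusted_contrasts <- function(result, g_adjusted = FALSE) {
  stopifnot(inherits(result, "dd_ancova"))
  fit <- result$fit
  data <- result$data
  lev <- levels(data$group)
  V <- stats::vcov(fit)
  coefs <- stats::coef(fit)
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  m <- length(pairs)

  rows <- lapply(pairs, function(pr) {
    cvec <- numeric(length(coefs))
    names(cvec) <- names(coefs)
    # treatment coding: adjusted mean of group g = intercept + coef(g) + b*age,
    # so differences reduce to group-coefficient differences
    for (g in pr[1]) if (g != lev[1]) cvec[paste0("group", g)] <- 1
    for (g in pr[2]) if (g != lev[1]) cvec[paste0("group", g)] <- -1
    diff <- sum(cvec * coefs)
    se <- sqrt(drop(t(cvec) %*% V %*% cvec))
    t_stat <- diff / se
    p_raw <- 2 * stats::pt(-abs(t_stat), fit$df.residual)

    g1 <- data$ln_k[data$group == pr[1]]
    g2 <- data$ln_k[data$group == pr[2]]
    g_val <- if (g_adjusted) {
      am <- result$adjusted_means
      s_pooled <- sqrt(((length(g1) - 1) * stats::var(g1) +
                          (length(g2) - 1) * stats::var(g2)) /
                         (length(g1) + length(g2) - 2))
      j <- 1 - 3 / (4 * (length(g1) + length(g2)) - 9)
      j * (am$adjusted_mean[am$group == pr[1]] -
             am$adjusted_mean[am$group == pr[2]]) / s_pooled
    } else {
      hedges_g(mean(g1), stats::sd(g1), length(g1),
               mean(g2), stats::sd(g2), length(g2))
    }
    data.frame(contrast = paste(pr[1], pr[2], sep = "-"),
               difference = diff, se = se, t = t_stat,
               df = fit$df.residual, p_raw = p_raw,
               p_bonferroni = min(1, m * p_raw),
               hedges_g = g_val)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("dd_pairwise", "data.frame")
  out
}

#' Regress ln(k) on ARFID presentation flags, controlling for age
#'
#' Ordinary least squares of `ln_k` on the three 0/1 presentation
#' indicators (sensory sensitivity, fear of aversive consequences,
#' lack of interest) plus age, with an intercept. Multiple regression
#' is used, rather than three separate tests, because the
#' presentations co-occur.
#'
#' @param arfid_data Data frame with columns `ln_k`, the three flag
#'   columns, and `age`; at least 6 rows and no constant flag.
#' @return An object of class `dd_regression`: `coefficients` (term,
#'   `B`, `se`, `t`, `p`), overall `F`, `p_overall`, `r2`,
#'   `adjusted_r2`, and the `lm` fit.
#' @export
regress_presentations <- function(arfid_data) {
  flags <- c("sensory_sensitivity", "fear_of_aversive_consequences",
             "lack_of_interest")
  needed <- c("ln_k", flags, "age")
  if (!all(needed %in% names(arfid_data)))
    stop_domain("`arfid_data` must have columns ",
                paste(needed, collapse = ", "))
  if (nrow(arfid_data) < 6)
    stop_domain("need at least 6 observations")
  constant <- flags[vapply(arfid_data[flags],
                           function(x) stats::var(x) == 0, logical(1))]
  if (length(constant))
    stop_domain("constant presentation flag(s): ",
                paste(constant, collapse = ", "))

  fml <- stats::reformulate(c(flags, "age"), response = "ln_k")
  fit <- stats::lm(fml, data = arfid_data)
  if (fit$rank < length(stats::coef(fit))) {
    dropped <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop_domain("rank-deficient design; collinear column(s): ",
                paste(dropped, collapse = ", "))
  }
  sm <- summary(fit)
  ct <- stats::coef(sm)
  fs <- sm$fstatistic
  structure(list(coefficients = data.frame(term = rownames(ct),
                                           B = ct[, 1], se = ct[, 2],
                                           t = ct[, 3], p = ct[, 4],
                                           row.names = NULL),
                 F = unname(fs[1]),
                 p_overall = stats::pf(fs[1], fs[2], fs[3],
                                       lower.tail = FALSE),
                 r2 = sm$r.squared,
                 adjusted_r2 = sm$adj.r.squared,
                 fit = fit),
            class = "dd_regression")
}

#' @export
print.dd_regression <- function(x, digits = 3, ...) {
  cat(sprintf("Regression of ln(k) on ARFID presentations + age: F = %.2f, p = %.3g, adj. R^2 = %.2f\n",
              x$F, x$p_overall, x$adjusted_r2))
  print(x$coefficients, row.names = FALSE, digits = digits)
  invisible(x)
}

#' Achieved power of the omnibus ANCOVA group test
#'
#' Post hoc power from the noncentral F distribution: the observed
#' partial eta squared is converted to Cohen's
#' `f^2 = eta_p2 / (1 - eta_p2)`, the noncentrality is
#' `lambda = f^2 * N`, and power is the probability that a noncentral
#' `F(groups - 1, N - groups - covariates, lambda)` variate exceeds the
#' central critical value at `alpha`.
#'
#' @param eta_p2 Observed partial eta squared, in `(0, 1)`.
#' @param N Total sample size.
#' @param groups Number of groups.
#' @param covariates Number of continuous covariates in the model.
#' @param alpha Type I error rate.
#' @return An object of class `dd_power`: `eta_p2_input`, `f2`,
#'   `lambda`, `df_num`, `df_den`, `critical_F`, `power`, `alpha`.
#' @export
#' @examples
#' achieved_power(0.11, 104, groups = 3, covariates = 1)
achieved_power <- function(eta_p2, N, groups = 3, covariates = 1,
                           alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop_domain("alpha must lie in (0, 1)")
  if (eta_p2 <= 0 || eta_p2 >= 1) stop_domain("eta_p2 must lie in (0, 1)")
  if (N <= groups + covariates)
    stop_domain("N must exceed groups + covariates")
  f2 <- eta_p2 / (1 - eta_p2)
  lambda <- f2 * N
  df_num <- groups - 1
  df_den <- N - groups - covariates
  crit <- stats::qf(1 - alpha, df_num, df_den)
  power <- stats::pf(crit, df_num, df_den, ncp = lambda, lower.tail = FALSE)
  structure(list(eta_p2_input = eta_p2, f2 = f2, lambda = lambda,
                 df_num = df_num, df_den = df_den,
                 critical_F = crit, power = power, alpha = alpha),
            class = "dd_power")
}

#' @export
print.dd_power <- function(x, ...) {
  cat(sprintf("Achieved power: eta_p^2 = %.3f -> f^2 = %.3f, lambda = %.2f, F crit(%d, %d) = %.2f, power = %.3f\n",
              x$eta_p2_input, x$f2, x$lambda, x$df_num, x$df_den,
              x$critical_F, x$power))
  invisible(x)
}

#' Run the full inference stack on a simulated or observed study
#'
#' Joins scores to participants, drops invalid participants, and runs
#' the ANCOVA with age covariate, the Bonferroni pairwise contrasts on
#' adjusted means with Hedges' g, the ARFID presentation regression,
#' and achieved power at the observed effect size.
#'
#' @param participants Participant table (see [generate_cohort()]).
#' @param scores Scores table with `participant_id`, `ln_k`, `valid`.
#' @param alpha Significance level for the power computation.
#' @param g_adjusted Passed to [pairwise_adjusted_contrasts()].
#' @return An object of class `dd_report` bundling the four result
#'   objects plus per-group raw summaries.
#' @export
#' @examples
#' study <- simulate_study(cohort_spec(), seed = 5)
#' analyze_study(study$participants, study$scores)
analyze_study <- function(participants, scores, alpha = 0.05,
                          g_adjusted = FALSE) {
  orphans <- setdiff(scores$participant_id, participants$participant_id)
  if (length(orphans))
    stop_domain("scores with no participant record: ",
                paste(orphans, collapse = ", "))
  part_cols <- setdiff(names(participants), c("ln_k", "k", "k_true", "valid"))
  dat <- merge(participants[, part_cols, drop = FALSE],
               scores[, c("participant_id", "ln_k", "valid")],
               by = "participant_id")
  dat <- dat[dat$valid, , drop = FALSE]
  dat$group <- factor(dat$group, levels = intersect(
    unique(participants$group), unique(dat$group)))

  anc <- ancova_group_effect(dat)
  pw <- pairwise_adjusted_contrasts(anc, g_adjusted = g_adjusted)
  arfid <- dat[dat$group == "ARFID", , drop = FALSE]
  reg <- if (nrow(arfid) >= 6 &&
               all(vapply(arfid[c("sensory_sensitivity",
                                  "fear_of_aversive_consequences",
                                  "lack_of_interest")],
                          function(x) stats::var(x) > 0, logical(1)))) {
    regress_presentations(arfid)
  } else NULL
  pow <- achieved_power(anc$eta_p2, N = nrow(dat),
                        groups = nlevels(dat$group), covariates = 1,
                        alpha = alpha)
  summaries <- do.call(rbind, lapply(split(dat, dat$group), function(d) {
    data.frame(group = d$group[1], n = nrow(d),
               ln_k_mean = mean(d$ln_k), ln_k_sd = stats::sd(d$ln_k),
               age_mean = mean(d$age), age_sd = stats::sd(d$age))
  }))
  rownames(summaries) <- NULL
  structure(list(ancova = anc, pairwise = pw, regression = reg,
                 power = pow, group_summaries = summaries,
                 n_analyzed = nrow(dat)),
            class = "dd_report")
}

#' @export
print.dd_report <- function(x, digits = 3, ...) {
  cat("=== Delay-discounting group analysis (N =", x$n_analyzed, ") ===\n\n")
  cat("Group summaries of ln(k) and age:\n")
  print(x$group_summaries, row.names = FALSE, digits = digits)
  cat("\n")
  print(x$ancova, digits = digits)
  cat("\nBonferroni-corrected pairwise contrasts on adjusted means:\n")
  print(as.data.frame(x$pairwise), row.names = FALSE, digits = digits)
  cat("\n")
  if (!is.null(x$regression)) print(x$regression, digits = digits)
  cat("\n")
  print(x$power)
  invisible(x)
}
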