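test_that("ANCOVA matches the explicit normal-equations oracle", {
  dat <- ancova_fixture()
  res <- ancova_group_effect(dat)

  g <- factor(dat$group, levels = unique(dat$group))
  X_full <- cbind(1, g == levels(g)[2], g == levels(g)[3], dat$age)
  X_red <- cbind(1, dat$age)
  full <- oracle_ols(X_full, dat$ln_k)
  red <- oracle_ols(X_red, dat$ln_k)
  ss_group <- red$rss - full$rss
  F_oracle <- (ss_group / 2) / (full$rss / (12 - 4))

  expect_equal(res$F, F_oracle, tolerance = 1e-10)
  expect_equal(res$df_num, 2L)
  expect_equal(res$df_den, 8L)
  expect_equal(res$eta_p2, ss_group / (ss_group + full$rss), tolerance = 1e-10)
  expect_equal(res$covariate_coefficient, full$beta[4], tolerance = 1e-10)
  # adjusted means at the grand mean age
  mu_age <- mean(dat$age)
  adj_oracle <- c(full$beta[1] + full$beta[4] * mu_age,
                  full$beta[1] + full$beta[2] + full$beta[4] * mu_age,
                  full$beta[1] + full$beta[3] + full$beta[4] * mu_age)
  expect_equal(res$adjusted_means$adjusted_mean, adj_oracle, tolerance = 1e-10)
})

test_that("ANCOVA group F agrees with the car Type II cross-check", {
  skip_if_not_installed("car")
  dat <- ancova_fixture()
  res <- ancova_group_effect(dat)
  fit <- stats::lm(ln_k ~ group + age, data = dat)
  tab <- car::Anova(fit, type = 2)
  expect_equal(res$F, tab["group", "F value"], tolerance = 1e-10)
  expect_equal(res$p, tab["group", "Pr(>F)"], tolerance = 1e-10)
})

test_that("with age orthogonal to group and no age effect, the group SS is the one-way between SS", {
  # residual pattern (1,-3,3,-1)/10 is orthogonal to both the intercept
  # and the centered age pattern, so the fitted age slope is exactly 0
  dat <- data.frame(group = rep(c("A", "B", "C"), each = 4),
                    age = rep(c(12, 16, 20, 24), times = 3),
                    ln_k = rep(c(-5, -7, -6), each = 4) +
                      rep(c(0.1, -0.3, 0.3, -0.1), times = 3))
  res <- ancova_group_effect(dat)
  expect_equal(res$covariate_coefficient, 0, tolerance = 1e-10)
  fit1 <- stats::aov(ln_k ~ group, data = dat)
  ss_between <- summary(fit1)[[1]]["group", "Sum Sq"]
  expect_equal(res$ss_group, ss_between, tolerance = 1e-10)
  # same SS and RSS, so the F ratios differ only through the residual df
  # the covariate consumes: F_ancova = F_oneway * df_den_ancova / df_den_anova
  F_oneway <- summary(fit1)[[1]]["group", "F value"]
  expect_equal(res$F, F_oneway * (12 - 4) / (12 - 3), tolerance = 1e-10)
})

test_that("ANCOVA rejects degenerate designs", {
  dat <- ancova_fixture()
  expect_error(ancova_group_effect(dat[, c("group", "age")]), "columns")
  dat$age <- 20
  expect_error(ancova_group_effect(dat), "constant")
  expect_error(ancova_group_effect(data.frame(group = c("A", "A", "B"),
                                              age = c(1, 2, 3),
                                              ln_k = c(0, 1, 2))),
               "at least 2")
})

test_that("partial eta squared follows the SS identity", {
  expect_equal(round(partial_eta_squared(5.93, 2, 101), 2), 0.11)
  expect_equal(partial_eta_squared(0, 2, 101), 0)
  expect_equal(partial_eta_squared(10, 1, 10), 0.5)
  # identity against a fitted model
  res <- ancova_group_effect(ancova_fixture())
  expect_equal(partial_eta_squared(res$F, res$df_num, res$df_den),
               res$eta_p2, tolerance = 1e-12)
})

test_that("pairwise contrasts match the coefficient-covariance oracle", {
  dat <- ancova_fixture()
  res <- ancova_group_effect(dat)
  pw <- pairwise_adjusted_contrasts(res)
  expect_equal(nrow(pw), 3)

  g <- factor(dat$group, levels = unique(dat$group))
  X <- cbind(1, g == levels(g)[2], g == levels(g)[3], dat$age)
  full <- oracle_ols(X, dat$ln_k)
  # ARFID - AN contrast is -beta2; ARFID - HC is -beta3; AN - HC is beta2-beta3
  cons <- list(c(0, -1, 0, 0), c(0, 0, -1, 0), c(0, 1, -1, 0))
  for (i in 1:3) {
    cv <- cons[[i]]
    diff_o <- sum(cv * full$beta)
    se_o <- sqrt(drop(t(cv) %*% full$vcov %*% cv))
    expect_equal(pw$difference[i], diff_o, tolerance = 1e-10)
    expect_equal(pw$se[i], se_o, tolerance = 1e-10)
    expect_equal(pw$t[i], diff_o / se_o, tolerance = 1e-10)
    expect_equal(pw$p_bonferroni[i], min(1, 3 * pw$p_raw[i]), tolerance = 1e-12)
  }
})

test_that("pairwise contrasts agree with the emmeans cross-check", {
  skip_if_not_installed("emmeans")
  dat <- ancova_fixture()
  res <- ancova_group_effect(dat)
  pw <- pairwise_adjusted_contrasts(res)
  dat$group <- factor(dat$group, levels = unique(dat$group))
  fit <- stats::lm(ln_k ~ group + age, data = dat)
  em <- emmeans::emmeans(fit, "group")
  ct <- as.data.frame(emmeans::contrast(em, "pairwise", adjust = "bonferroni"))
  expect_equal(pw$difference, ct$estimate, tolerance = 1e-8)
  expect_equal(pw$se, ct$SE, tolerance = 1e-8)
  expect_equal(pw$p_bonferroni, ct$p.value, tolerance = 1e-8)
  # adjusted means themselves
  expect_equal(res$adjusted_means$adjusted_mean,
               as.data.frame(em)$emmean, tolerance = 1e-8)
})

test_that("identical groups produce a zero contrast with p = 1", {
  dat <- data.frame(group = rep(c("A", "B", "C"), each = 4),
                    age = rep(c(12, 16, 20, 24), times = 3),
                    ln_k = rep(c(-0.3, 0.1, 0.4, -0.2), times = 3))
  pw <- pairwise_adjusted_contrasts(ancova_group_effect(dat))
  expect_equal(pw$difference, rep(0, 3), tolerance = 1e-12)
  expect_equal(pw$p_bonferroni, rep(1, 3))
})

test_that("Hedges' g follows the pooled-SD small-sample formula", {
  expect_equal(hedges_g(-6, 1, 20, -6, 2, 30), 0)
  g <- hedges_g(-6.10, 2.00, 57, -7.26, 1.73, 28)
  s_pool <- sqrt((56 * 4 + 27 * 1.73^2) / 83)
  expect_equal(g, (1 - 3 / (4 * 85 - 9)) * 1.16 / s_pool, tolerance = 1e-12)
  expect_equal(g, 0.600, tolerance = 5e-4)
  # antisymmetry
  expect_equal(hedges_g(-7.26, 1.73, 28, -6.10, 2.00, 57), -g)
  expect_error(hedges_g(1, 0, 5, 1, 0, 5), "degenerate")
  expect_error(hedges_g(1, 1, 1, 2, 1, 5), "n >= 2")
})

test_that("presentation regression matches the normal-equations oracle", {
  set.seed(21)
  dat <- data.frame(sensory_sensitivity = rep(c(0L, 1L), 6),
                    fear_of_aversive_consequences = rep(c(0L, 0L, 1L), 4),
                    lack_of_interest = rep(c(1L, 0L), each = 6),
                    age = c(12, 18, 25, 14, 19, 22, 16, 28, 11, 20, 23, 15))
  dat$ln_k <- -6 + 0.8 * dat$sensory_sensitivity - 0.5 * dat$age / 10 +
    rnorm(12, sd = 0.7)
  res <- regress_presentations(dat)
  X <- cbind(1, dat$sensory_sensitivity, dat$fear_of_aversive_consequences,
             dat$lack_of_interest, dat$age)
  full <- oracle_ols(X, dat$ln_k)
  expect_equal(unname(res$coefficients$B), unname(full$beta), tolerance = 1e-10)
  expect_equal(unname(res$coefficients$se), sqrt(diag(full$vcov)),
               tolerance = 1e-10)
  # overall F against the intercept-only reduction
  rss0 <- sum((dat$ln_k - mean(dat$ln_k))^2)
  F_o <- ((rss0 - full$rss) / 4) / (full$rss / 7)
  expect_equal(res$F, F_o, tolerance = 1e-10)
  r2 <- 1 - full$rss / rss0
  expect_equal(res$adjusted_r2, 1 - (1 - r2) * 11 / 7, tolerance = 1e-10)
})

test_that("an orthogonal flag's coefficient is the difference of flag-group means", {
  # 2^3 factorial columns are mutually orthogonal after centering; age
  # follows the x1*x2 interaction pattern, so every regressor is balanced
  s <- rep(c(0, 1), times = 4)
  f <- rep(c(0, 0, 1, 1), times = 2)
  l <- rep(c(0, 1), each = 4)
  age <- 15 + 5 * as.numeric(xor(s, f))
  set.seed(33)
  dat <- data.frame(sensory_sensitivity = s, fear_of_aversive_consequences = f,
                    lack_of_interest = l, age = age,
                    ln_k = rnorm(8, -6, 1))
  res <- regress_presentations(dat)
  b_s <- res$coefficients$B[res$coefficients$term == "sensory_sensitivity"]
  expect_equal(b_s, mean(dat$ln_k[s == 1]) - mean(dat$ln_k[s == 0]),
               tolerance = 1e-10)
})

test_that("presentation regression guards its preconditions", {
  dat <- data.frame(sensory_sensitivity = rep(c(0L, 1L), 6),
                    fear_of_aversive_consequences = 0L,
                    lack_of_interest = rep(c(1L, 0L), each = 6),
                    age = 11:22, ln_k = rnorm(12))
  expect_error(regress_presentations(dat), "constant presentation flag")
  expect_error(regress_presentations(dat[1:4, ]), "at least 6")
})

test_that("achieved power follows the noncentral F tail", {
  pow <- achieved_power(0.11, 104, groups = 3, covariates = 1, alpha = 0.05)
  expect_equal(pow$f2, 0.11 / 0.89, tolerance = 1e-12)
  expect_equal(pow$lambda, pow$f2 * 104, tolerance = 1e-12)
  expect_equal(pow$df_den, 100)
  # Monte-Carlo oracle for the noncentral F tail
  set.seed(77)
  draws <- (stats::rchisq(1e6, 2, ncp = pow$lambda) / 2) /
    (stats::rchisq(1e6, 100) / 100)
  expect_equal(pow$power, mean(draws > pow$critical_F), tolerance = 2e-3)
  # null limit and monotonicity in N
  expect_equal(achieved_power(1e-12, 104, 3, 1, 0.05)$power, 0.05,
               tolerance = 1e-6)
  powers <- vapply(c(30, 60, 120),
                   function(N) achieved_power(0.11, N, 3, 1, 0.05)$power,
                   numeric(1))
  expect_true(all(diff(powers) > 0))
  expect_error(achieved_power(0.11, 104, alpha = 1.2), "alpha")
  expect_error(achieved_power(1.1, 104), "eta_p2")
  expect_error(achieved_power(0.11, 4, groups = 3, covariates = 1), "exceed")
})

test_that("analyze_study assembles the full inference stack", {
  study <- simulate_study(cohort_spec(), seed = 5)
  rpt <- analyze_study(study$participants, study$scores)
  expect_s3_class(rpt$ancova, "dd_ancova")
  expect_equal(nrow(rpt$pairwise), 3)
  expect_s3_class(rpt$regression, "dd_regression")
  expect_equal(rpt$n_analyzed, 104)
  expect_equal(rpt$power$eta_p2_input, rpt$ancova$eta_p2)
  # orphan scores are reported by id
  bad <- study$scores
  bad$participant_id[1] <- "ZZZ"
  expect_error(analyze_study(study$participants, bad), "ZZZ")
})
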