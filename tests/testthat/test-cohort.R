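test_that("default cohort reproduces the study composition", {
  cohort <- generate_cohort(cohort_spec(), seed = 7)
  expect_equal(nrow(cohort), 104)
  expect_equal(as.integer(table(factor(cohort$group,
                                       c("ARFID", "AN", "HC")))),
               c(57L, 28L, 19L))
  arfid <- cohort[cohort$group == "ARFID", ]
  expect_equal(sum(arfid$sensory_sensitivity), 45)
  expect_equal(sum(arfid$fear_of_aversive_consequences), 18)
  expect_equal(sum(arfid$lack_of_interest), 24)
  # every ARFID participant carries at least one presentation; nobody else any
  flags <- c("sensory_sensitivity", "fear_of_aversive_consequences",
             "lack_of_interest")
  expect_true(all(rowSums(arfid[flags]) >= 1))
  expect_true(all(rowSums(cohort[cohort$group != "ARFID", flags]) == 0))
  expect_true(all(cohort$age >= 10 & cohort$age <= 30))
})

test_that("cohort generation is reproducible and seed-sensitive", {
  spec <- cohort_spec()
  expect_identical(generate_cohort(spec, seed = 11),
                   generate_cohort(spec, seed = 11))
  expect_false(identical(generate_cohort(spec, seed = 11),
                         generate_cohort(spec, seed = 12)))
  study <- simulate_study(spec, seed = 13)
  study2 <- simulate_study(spec, seed = 13)
  expect_identical(study, study2)
})

test_that("infeasible presentation marginals are rejected", {
  expect_error(cohort_spec(flag_marginals = c(sensory_sensitivity = 60L,
                                              fear_of_aversive_consequences = 18L,
                                              lack_of_interest = 24L)),
               "infeasible")
  expect_error(cohort_spec(flag_marginals = c(sensory_sensitivity = 20L,
                                              fear_of_aversive_consequences = 18L,
                                              lack_of_interest = 10L)),
               "infeasible")
})

test_that("flag allocation keeps exact marginals under co-occurrence stress", {
  # marginals sum well above n, forcing heavy co-occurrence
  spec <- cohort_spec(groups = data.frame(group = "ARFID", n = 20L,
                                          ln_k_mean = -6, ln_k_sd = 2,
                                          age_mean = 18, age_sd = 4),
                      flag_marginals = c(sensory_sensitivity = 19L,
                                         fear_of_aversive_consequences = 17L,
                                         lack_of_interest = 15L),
                      female_fraction = c(ARFID = 0.5))
  for (s in 1:10) {
    cohort <- generate_cohort(spec, seed = s)
    expect_equal(sum(cohort$sensory_sensitivity), 19)
    expect_equal(sum(cohort$fear_of_aversive_consequences), 17)
    expect_equal(sum(cohort$lack_of_interest), 15)
    expect_true(all(rowSums(cohort[, c("sensory_sensitivity",
                                       "fear_of_aversive_consequences",
                                       "lack_of_interest")]) >= 1))
  }
})

test_that("direct-mode ln(k) draws match the specified normal (KS at alpha = 0.01)", {
  spec <- cohort_spec(groups = data.frame(group = "HC", n = 10000L,
                                          ln_k_mean = -6.1, ln_k_sd = 2,
                                          age_mean = 18, age_sd = 4),
                      flag_marginals = integer(0),
                      female_fraction = c(HC = 0.5))
  cohort <- generate_cohort(spec, seed = 2024)
  ks <- suppressWarnings(stats::ks.test(cohort$ln_k, "pnorm", -6.1, 2))
  expect_gt(ks$p.value, 0.01)
})

test_that("noiseless behavioral pipeline equals the staircase oracle exactly", {
  spec <- cohort_spec(groups = data.frame(group = "HC",
                                          n = length(k_true_grid),
                                          ln_k_mean = -6, ln_k_sd = 2,
                                          age_mean = 18, age_sd = 4),
                      flag_marginals = integer(0),
                      female_fraction = c(HC = 0.5),
                      mode = "behavioral")
  study <- simulate_study(spec, seed = 99, return_sessions = TRUE)
  # overwrite the drawn rates with the test grid via direct agents
  cfg <- task_config()
  for (k in k_true_grid) {
    sc <- score_session(run_session(dd_agent("deterministic_hyperbolic",
                                             k_true = k), cfg, seed = 1), cfg)
    expect_equal(sc$ln_k, oracle_lnk(k), tolerance = 1e-12)
  }
  # and the behavioral study reproduces its own draws deterministically
  joined <- merge(study$participants, study$scores, by = "participant_id")
  expect_equal(joined$ln_k,
               vapply(joined$k_true, oracle_lnk, numeric(1)),
               tolerance = 1e-12)
})

test_that("total catch failure excludes every participant", {
  spec <- cohort_spec(groups = data.frame(group = "HC", n = 5L,
                                          ln_k_mean = -6, ln_k_sd = 2,
                                          age_mean = 18, age_sd = 4),
                      flag_marginals = integer(0),
                      female_fraction = c(HC = 0.5),
                      mode = "behavioral", catch_error_rate = 1)
  study <- simulate_study(spec, seed = 17)
  expect_equal(nrow(study$scores), 0)
  expect_equal(nrow(study$excluded), 5)
  expect_true(all(study$excluded$catch_correct == 0))
})

test_that("direct-mode group means concentrate on the specified values", {
  # mean of ARFID ln_k across cohorts has SE 2/sqrt(57)/sqrt(R)
  spec <- cohort_spec()
  means <- vapply(1:200, function(s) {
    cohort <- generate_cohort(spec, seed = 3000 + s)
    mean(cohort$ln_k[cohort$group == "ARFID"])
  }, numeric(1))
  se <- 2 / sqrt(57) / sqrt(200)
  expect_lt(abs(mean(means) - (-6.1)), 4 * se)
})
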