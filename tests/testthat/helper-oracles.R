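# Independent oracles used across the suite. These deliberately avoid
# the package's own staircase/scoring code paths: plain loops over the
# bisection arithmetic, explicit normal equations, and Monte-Carlo
# draws for the noncentral F tail.

# Binary-search oracle: final hypothetical offer of a 6-step halving
# staircase for a responder with fixed indifference value v (ties to
# the future option, i.e. "present" only when offer > v).
oracle_staircase <- function(v, initial = 500, steps = 6) {
  offer <- initial
  for (t in seq_len(steps)) {
    change <- initial / 2^t
    offer <- if (offer > v) offer - change else offer + change
  }
  offer
}

# Offer implied by an explicit choice sequence (TRUE = future).
oracle_offer_from_choices <- function(future, initial = 500) {
  s <- ifelse(future, 1, -1)
  initial + sum(s * initial / 2^seq_along(s))
}

# Full scoring oracle for a noiseless hyperbolic discounter.
oracle_lnk <- function(k_true, delays = c(14, 30, 182, 365, 1095, 1825, 3650),
                       future_amount = 1000) {
  ip <- vapply(delays, function(D) {
    oracle_staircase(future_amount / (1 + k_true * D))
  }, numeric(1))
  k_d <- (future_amount / ip - 1) / delays
  log(mean(k_d))
}

k_true_grid <- c(0.0005, 0.001, 0.005, 0.01, 0.05, 0.2)

# Least-squares oracle by explicit normal equations.
oracle_ols <- function(X, y) {
  beta <- solve(t(X) %*% X, t(X) %*% y)
  resid <- y - X %*% beta
  list(beta = drop(beta), rss = sum(resid^2),
       vcov = solve(t(X) %*% X) * sum(resid^2) / (nrow(X) - ncol(X)))
}

# Hand-built 12-row three-group fixture with an age covariate.
ancova_fixture <- function() {
  data.frame(
    group = rep(c("ARFID", "AN", "HC"), each = 4),
    age = c(12, 15, 19, 24, 18, 20, 22, 25, 14, 17, 21, 28),
    ln_k = c(-5.2, -6.8, -4.9, -6.1, -7.5, -8.0, -6.9, -7.2,
             -5.0, -5.9, -4.4, -6.3))
}

# Population partial eta squared implied by group means/SDs under the
# generator's model (between-group variance over between + pooled
# within), used to predict omnibus power.
oracle_population_eta_p2 <- function(n, means, sds) {
  N <- sum(n)
  mu <- sum(n * means) / N
  var_between <- sum(n * (means - mu)^2) / N
  var_within <- sum(n * sds^2) / N
  var_between / (var_between + var_within)
}
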