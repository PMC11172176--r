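test_that("KM estimator matches the naive product oracle", {
  # closed form: events at t=1,2 among n=2
  km <- km_estimate(c(1, 2), c(1, 1))
  expect_equal(km$surv, c(0.5, 0))
  # no events: survival identically 1
  km0 <- km_estimate(c(3, 5, 7), c(0, 0, 0))
  expect_true(all(km0$surv == 1))
  # random data vs explicit product over risk sets
  set.seed(51)
  for (i in 1:5) {
    t <- round(rexp(40, 0.1), 1) + 0.1
    e <- rbinom(40, 1, 0.6)
    if (sum(e) == 0) e[1] <- 1
    km <- km_estimate(t, e)
    orc <- km_oracle(t, e)
    at_events <- km[km$n_event > 0, ]
    expect_equal(at_events$surv,
                 orc$surv[match(at_events$time, orc$time)],
                 tolerance = 1e-12)
  }
  # invariant to input ordering
  perm <- sample(40)
  t <- round(rexp(40, 0.1), 1) + 0.1
  e <- rbinom(40, 1, 0.6)
  expect_equal(km_estimate(t, e), km_estimate(t[perm], e[perm]))
})

test_that("log-rank matches the risk-set enumeration oracle and its invariances", {
  # hand-checkable fixture: A = {(1,event),(4,event)}, B = {(2,event),(3,cens)}
  t <- c(1, 4, 2, 3)
  e <- c(1, 1, 1, 0)
  g <- c("A", "A", "B", "B")
  res <- logrank_test(t, e, g)
  expect_equal(res$statistic, logrank_oracle(t, e, g), tolerance = 1e-10)
  # duplicated groups: chi-square 0, p 1
  res0 <- logrank_test(c(t, t), c(e, e), rep(c("X", "Y"), each = 4))
  expect_equal(res0$statistic, 0, tolerance = 1e-12)
  expect_equal(res0$p, 1)
  # label permutation invariance
  set.seed(52)
  t <- rexp(60, 0.1)
  e <- rbinom(60, 1, 0.5)
  g <- sample(c("a", "b", "c"), 60, TRUE)
  relab <- c(a = "c", b = "a", c = "b")[g]
  expect_equal(logrank_test(t, e, g)$statistic,
               logrank_test(t, e, relab)$statistic, tolerance = 1e-12)
  expect_equal(logrank_test(t, e, g)$df, 2)
  expect_error(logrank_test(t, rep(0, 60), g), "no events")
  expect_error(logrank_test(t, e, rep("a", 60)), "at least 2")
})

test_that("cox fit matches the closed-form partial-likelihood solution", {
  # 3 subjects, no ties: direct maximization of the explicit partial
  # likelihood is the oracle
  t <- c(1, 2, 3)
  e <- c(1, 1, 1)
  x <- c(1, 0, 1)
  pl <- function(b) {
    log(exp(b) / (2 * exp(b) + 1)) + log(1 / (exp(b) + 1))
  }
  b_oracle <- optimize(pl, c(-5, 5), maximum = TRUE)$maximum
  fit <- cox_fit(data.frame(x = x), t, e)
  expect_equal(fit$coefficients$coef, b_oracle, tolerance = 1e-5)
  expect_equal(fit$coefficients$coef, -log(sqrt(2)), tolerance = 1e-8)
  expect_equal(fit$coefficients$hr, exp(fit$coefficients$coef))
})

test_that("cox estimates recover null and nonnull truths within 2 SE", {
  set.seed(53)
  n <- 1500
  x <- rbinom(n, 1, 0.5)
  t <- rexp(n, 0.02)
  cens <- runif(n, 20, 80)
  fit <- cox_fit(data.frame(x = x), pmin(t, cens), as.integer(t <= cens))
  expect_lt(abs(fit$coefficients$coef), 2 * fit$coefficients$se)
  # coefficient equivariance under covariate scaling
  xc <- rnorm(n)
  t2 <- rexp(n, 0.02 * exp(0.5 * xc))
  d2 <- data.frame(x = xc)
  f1 <- cox_fit(d2, pmin(t2, cens), as.integer(t2 <= cens))
  d3 <- data.frame(x = xc / 10)
  f2 <- cox_fit(d3, pmin(t2, cens), as.integer(t2 <= cens))
  expect_equal(f2$coefficients$coef, 10 * f1$coefficients$coef,
               tolerance = 1e-6)
  expect_error(cox_fit(data.frame(x = rep(1, n)), t, rep(1, n)), "constant")
  expect_error(cox_fit(data.frame(x = x), t, rep(0, n)), "no events")
})

test_that("complete separation is flagged as non-convergence", {
  t <- c(1, 2, 3, 4, 5, 6)
  e <- c(1, 1, 1, 0, 0, 0)
  x <- c(1, 1, 1, 0, 0, 0)  # events only in x = 1: monotone likelihood
  fit <- cox_fit(data.frame(x = x), t, e)
  expect_false(fit$converged)
})

test_that("backward stepwise retains the true predictor and obeys the threshold", {
  set.seed(54)
  keep <- 0
  for (rep in 1:25) {
    n <- 400
    x_true <- rbinom(n, 1, 0.5)
    noise <- matrix(rnorm(n * 4), n, dimnames = list(NULL, paste0("z", 1:4)))
    t <- rexp(n, 0.02 * exp(1.0 * x_true))
    cens <- runif(n, 20, 80)
    d <- data.frame(x_true = x_true, noise)
    fit <- backward_stepwise_wald(d, pmin(t, cens), as.integer(t <= cens),
                                  p_remove = 0.10)
    if ("x_true" %in% fit$retained) keep <- keep + 1
    # every removal happened above the threshold; every survivor is at or
    # below it (or is the last covariate standing)
    if (nrow(fit$trace) > 0)
      expect_true(all(fit$trace$p_at_removal > 0.10))
    if (length(fit$retained) > 1)
      expect_true(all(fit$term_wald$p <= 0.10))
    # the trace reconstructs the final model
    expect_setequal(c(fit$retained, fit$trace$removed), names(d))
  }
  expect_gte(keep, 24)  # >= 95% of replicates
})

test_that("a final-step covariate with p in (0.05, 0.10] is kept at 0.10 but dropped at 0.05", {
  # constructed fixture whose final-step Wald p lands between the two
  # conventional thresholds, mirroring a retained borderline ratio score
  set.seed(2)
  n <- 260
  x1 <- rbinom(n, 1, 0.5)
  x2 <- rnorm(n)
  t <- rexp(n, 0.03 * exp(0.28 * x1 + 0.35 * x2))
  cens <- runif(n, 10, 60)
  d <- data.frame(x1 = x1, x2 = x2)
  time <- pmin(t, cens)
  event <- as.integer(t <= cens)
  fit10 <- backward_stepwise_wald(d, time, event, p_remove = 0.10)
  p_x1 <- fit10$term_wald$p[fit10$term_wald$term == "x1"]
  expect_true(p_x1 > 0.05 && p_x1 <= 0.10)
  expect_true("x1" %in% fit10$retained)
  fit05 <- backward_stepwise_wald(d, time, event, p_remove = 0.05)
  expect_false("x1" %in% fit05$retained)
})

test_that("all-noise covariates are retained at roughly the removal rate", {
  # under the null each covariate should survive selection with probability
  # near p_remove; the only bias is the always-kept last covariate, diluted
  # here across 8 noise columns
  set.seed(55)
  retained <- 0
  total <- 0
  for (rep in 1:30) {
    n <- 250
    noise <- matrix(rnorm(n * 8), n, dimnames = list(NULL, paste0("z", 1:8)))
    t <- rexp(n, 0.03)
    cens <- runif(n, 10, 60)
    fit <- backward_stepwise_wald(as.data.frame(noise), pmin(t, cens),
                                  as.integer(t <= cens), p_remove = 0.10)
    retained <- retained + length(fit$retained)
    total <- total + 8
  }
  rate <- retained / total
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.30)
})
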