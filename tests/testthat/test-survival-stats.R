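test_that("Kaplan-Meier matches hand product-limit computations", {
  # three events, no censoring
  km <- km_curve(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))

  # censoring between events: S(1)=3/4, S(2)=3/4*(1-1/2)=1/2, flat after
  km2 <- km_curve(c(1, 2, 2, 4), c(1, 0, 1, 0))
  expect_equal(km2$event_times, c(1, 2))
  expect_equal(km2$survival, c(3 / 4, 1 / 2))

  # all censored -> survival identically 1
  km3 <- km_curve(c(5, 10, 20), c(0, 0, 0))
  expect_equal(survival_at(km3, c(0, 15, 100)), c(1, 1, 1))

  # survival at last event time equals independent product formula
  set.seed(11)
  tm <- sample(1:30, 40, replace = TRUE)
  ev <- rbinom(40, 1, 0.6)
  km4 <- km_curve(tm, ev)
  prod_formula <- prod(1 - km4$n_events / km4$at_risk)
  expect_equal(km4$survival[length(km4$survival)], prod_formula)
})

test_that("KM curve evaluation is a right-continuous step function", {
  km <- km_curve(c(1, 2, 2, 4), c(1, 0, 1, 0))
  expect_equal(survival_at(km, 0), 1)
  expect_equal(survival_at(km, 2), 1 / 2)      # post-drop value at event time
  expect_equal(survival_at(km, 1.99), 3 / 4)
  expect_equal(survival_at(km, 100), 1 / 2)    # extends beyond last time

  # three-year rate is the 36-month evaluation
  expect_equal(three_year_rate(c(12, 40, 50, 60), c(1, 0, 0, 0)), 0.75)
  expect_equal(three_year_rate(c(40, 50), c(0, 0)), 1)
  set.seed(3)
  tm <- rexp(50, 1 / 40) + 1; ev <- rbinom(50, 1, 0.5)
  expect_equal(three_year_rate(tm, ev), survival_at(km_curve(tm, ev), 36))
})

test_that("log-rank test matches the hand O/E/V oracle and is symmetric", {
  # fixed 8-subject two-group example with ties and censoring
  t1 <- c(2, 4, 4, 7); e1 <- c(1, 1, 0, 1)
  t2 <- c(3, 4, 9, 12); e2 <- c(0, 1, 1, 0)
  res <- logrank(t1, e1, t2, e2)
  expect_equal(res$chi_square, oracle_logrank_chisq(t1, e1, t2, e2),
               tolerance = 1e-10)
  expect_equal(res$df, 1L)

  # label invariance
  swapped <- logrank(t2, e2, t1, e1)
  expect_equal(res$chi_square, swapped$chi_square)

  # identical groups -> chi-square 0, p 1
  same <- logrank(t1, e1, t1, e1)
  expect_equal(same$chi_square, 0)
  expect_equal(same$p_value, 1)

  # zero events overall -> degenerate flagged result
  none <- logrank(c(1, 2), c(0, 0), c(3, 4), c(0, 0))
  expect_true(none$degenerate)
  expect_equal(none$chi_square, 0)
  expect_equal(none$p_value, 1)

  # chi-square equals the squared standardized (O-E) statistic
  expect_equal(res$chi_square,
               ((res$observed - res$expected) / sqrt(res$variance))^2)
})

test_that("log-rank agrees with survival::survdiff on random fixtures", {
  skip_if_not_installed("survival")
  set.seed(21)
  for (rep in 1:5) {
    n <- 60
    tm <- sample(1:25, n, replace = TRUE)
    ev <- rbinom(n, 1, 0.6)
    g <- rbinom(n, 1, 0.5)
    res <- logrank(tm[g == 0], ev[g == 0], tm[g == 1], ev[g == 1])
    ref <- survival::survdiff(survival::Surv(tm, ev) ~ g)
    expect_equal(res$chi_square, ref$chisq, tolerance = 1e-10)
  }
})

test_that("Cox coefficient matches brute-force partial likelihood on 6 subjects", {
  tm <- c(1, 2, 3, 4, 5, 6)
  ev <- c(1, 1, 0, 1, 0, 1)
  x <- c(1, 0, 1, 1, 0, 0)
  fit <- cox_fit(tm, ev, x)
  grid <- stats::optimize(function(b) oracle_cox_loglik(b, tm, ev, x),
                          interval = c(-10, 10), maximum = TRUE,
                          tol = 1e-10)
  expect_equal(unname(coef(fit)), grid$maximum, tolerance = 1e-6)
  expect_equal(fit$loglik[["final"]], grid$objective, tolerance = 1e-9)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$score)), 1e-9)
  expect_equal(unname(fit$hr), exp(unname(coef(fit))))
})

test_that("Cox fit agrees with survival::coxph under both tie corrections", {
  skip_if_not_installed("survival")
  set.seed(42)
  n <- 150
  x <- cbind(a = rbinom(n, 1, 0.4), b = rnorm(n), c = runif(n))
  tm <- ceiling(rexp(n, exp(0.6 * x[, 1] - 0.4 * x[, 2]) / 30))
  ev <- rbinom(n, 1, 0.7)
  for (ties in c("efron", "breslow")) {
    fit <- cox_fit(tm, ev, x, ties = ties)
    ref <- survival::coxph(survival::Surv(tm, ev) ~ x, ties = ties)
    expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-7)
    expect_equal(unname(fit$se), unname(sqrt(diag(stats::vcov(ref)))),
                 tolerance = 1e-7)
    expect_equal(fit$loglik[["final"]], ref$loglik[2], tolerance = 1e-8)
  }
})

test_that("Efron and Breslow agree exactly without tied event times", {
  set.seed(5)
  n <- 80
  tm <- rexp(n) + 0.01  # continuous, no ties
  ev <- rbinom(n, 1, 0.7)
  x <- rbinom(n, 1, 0.5)
  fe <- cox_fit(tm, ev, x, ties = "efron")
  fb <- cox_fit(tm, ev, x, ties = "breslow")
  expect_equal(coef(fe), coef(fb), tolerance = 1e-12)
  expect_equal(fe$loglik, fb$loglik, tolerance = 1e-12)
})

test_that("Cox estimates are well-behaved under null and alternative", {
  # independent covariate: HR near 1 at n = 1000
  set.seed(100)
  n <- 1000
  x <- rbinom(n, 1, 0.5)
  tm <- rexp(n, 1 / 50)
  ev <- as.integer(tm < 60)
  fit <- cox_fit(tm, ev, x)
  expect_gt(unname(fit$hr), 0.8)
  expect_lt(unname(fit$hr), 1.25)
  expect_true(fit$ci_low <= fit$hr && fit$hr <= fit$ci_high)

  # exponential two-group data with true HR 2 at n = 5000
  set.seed(101)
  n <- 5000
  z <- rbinom(n, 1, 0.5)
  tm2 <- rexp(n, rate = 0.02 * 2^z)
  ev2 <- as.integer(tm2 < 80)
  tm2 <- pmin(tm2, 80)
  fit2 <- cox_fit(tm2, ev2, z)
  expect_gt(unname(fit2$hr), 1.85)
  expect_lt(unname(fit2$hr), 2.15)
})

test_that("separation yields a flagged degenerate fit, not a silent lie", {
  # all events in one group: monotone likelihood
  tm <- c(1, 2, 3, 10, 11, 12)
  ev <- c(1, 1, 1, 0, 0, 0)
  x <- c(1, 1, 1, 0, 0, 0)
  fit <- cox_fit(tm, ev, x)
  expect_true(fit$degenerate)
  expect_false(fit$converged)
  expect_true(abs(unname(coef(fit))) >= 10)  # capped, clearly diverging
  expect_error(cox_fit(tm, ev, rep(1, 6)), "constant")
  expect_error(cox_fit(tm, rep(0, 6), x), "no events")
})

test_that("Harrell's C matches O(n^2) pair counting and its identities", {
  # perfectly anti-ordered scores, no censoring -> C = 1
  tm <- c(1, 2, 3, 4, 5)
  ev <- rep(1, 5)
  expect_equal(harrell_c(5:1, tm, ev, n_boot = 0)$c_index, 1)
  # all scores equal -> C = 0.5
  expect_equal(harrell_c(rep(2, 5), tm, ev, n_boot = 0)$c_index, 0.5)

  # fixed 10-subject example with censoring and score ties
  set.seed(8)
  tm2 <- c(3, 5, 5, 8, 10, 12, 15, 18, 20, 25)
  ev2 <- c(1, 0, 1, 1, 0, 1, 0, 1, 0, 0)
  sc <- c(4, 4, 3, 5, 2, 3, 1, 2, 1, 0)
  got <- harrell_c(sc, tm2, ev2, n_boot = 200, seed = 1)
  expect_equal(got$c_index, oracle_c_index(sc, tm2, ev2))
  expect_true(got$ci_low <= got$c_index && got$c_index <= got$ci_high)

  # reversal identity when there are no score ties
  sc2 <- seq(0.1, 1, by = 0.1)
  c_fwd <- harrell_c(sc2, tm2, ev2, n_boot = 0)$c_index
  c_rev <- harrell_c(-sc2, tm2, ev2, n_boot = 0)$c_index
  expect_equal(c_fwd, 1 - c_rev)

  expect_error(harrell_c(1:3, c(5, 6, 7), c(0, 0, 0), n_boot = 0),
               "no comparable pairs")
})

test_that("Harrell's C agrees with survival::concordance on tie-free data", {
  skip_if_not_installed("survival")
  set.seed(9)
  n <- 100
  tm <- rexp(n) + 0.001
  ev <- rbinom(n, 1, 0.6)
  sc <- rnorm(n)
  got <- harrell_c(sc, tm, ev, n_boot = 0)$c_index
  ref <- survival::concordance(survival::Surv(tm, ev) ~ sc,
                               reverse = TRUE)$concordance
  expect_equal(got, ref, tolerance = 1e-12)
})
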