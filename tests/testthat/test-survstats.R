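test_that("KM estimator matches empirical survival and hand oracles", {
  km <- km_estimate(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))
  expect_true(all(diff(km$surv) <= 0))
  expect_true(all(km$lower <= km$surv & km$surv <= km$upper))
  # all censored -> S = 1 throughout
  km2 <- km_estimate(c(2, 5, 7), c(0, 0, 0))
  expect_true(all(km2$surv == 1))
  # mixed 6-sample case vs hand product-limit computation
  t6 <- c(1, 2, 2, 3, 5, 8); e6 <- c(1, 0, 1, 1, 0, 1)
  km3 <- km_estimate(t6, e6)
  orc <- oracle_km(t6, e6)
  expect_equal(km3$surv, orc$surv)
  # no censoring: equals the empirical survival function (random draws)
  set.seed(5)
  for (i in 1:5) {
    tt <- sample(1:30, 25, replace = TRUE)
    km4 <- km_estimate(tt, rep(1, 25))
    emp <- vapply(km4$time, function(x) mean(tt > x), numeric(1))
    expect_equal(km4$surv, emp)
  }
})

test_that("log-rank: identical groups, hand tabulation, and time-rescaling invariance", {
  tt <- c(1, 2, 3, 4, 5, 6, 7, 8)
  ev <- rep(1, 8)
  gr <- rep(c("a", "b"), 4)
  same <- logrank_test(c(tt, tt), c(ev, ev), rep(c("a", "b"), each = 8))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # 8-sample worked case against the O-E/V oracle
  t8 <- c(2, 3, 5, 7, 8, 10, 12, 14)
  e8 <- c(1, 1, 0, 1, 1, 1, 0, 1)
  g8 <- c("a", "a", "a", "a", "b", "b", "b", "b")
  lr <- logrank_test(t8, e8, g8)
  expect_equal(lr$statistic, oracle_logrank(t8, e8, g8))
  # invariant under monotone time transforms
  lr2 <- logrank_test(exp(t8 / 3), e8, g8)
  expect_equal(lr2$statistic, lr$statistic, tolerance = 1e-12)
  expect_warning(z <- logrank_test(c(1, 2), c(0, 0), c("a", "b")), "events")
  expect_true(is.na(z$p_value))
})

test_that("log-rank has power against a planted hazard ratio", {
  # scaled down from 200 simulations to 60: planted HR 3 at n=75/75 is a
  # very high-power setting
  hits <- 0
  for (s in 1:60) {
    set.seed(1000 + s)
    t1 <- rexp(75, 1); t2 <- rexp(75, 3)
    cens <- rexp(150, 0.25)
    tt <- pmin(c(t1, t2), cens)
    ev <- as.integer(c(t1, t2) <= cens)
    p <- logrank_test(tt, ev, rep(c("a", "b"), each = 75))$p_value
    if (p < 0.001) hits <- hits + 1
  }
  expect_gte(hits / 60, 0.95)
})

test_that("Cox fit matches a partial-likelihood grid oracle and recovers beta", {
  t0 <- c(3, 5, 7, 10, 2, 4, 6, 9, 12, 15)
  e0 <- c(1, 1, 1, 0, 1, 1, 0, 1, 1, 1)
  x0 <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)
  fit <- cox_fit(t0, e0, x0)
  grid <- seq(-3, 3, by = 1e-3)
  ll <- vapply(grid, oracle_cox_loglik, numeric(1), time = t0, event = e0,
               x = x0)
  expect_equal(fit$beta, grid[which.max(ll)], tolerance = 0.01)
  # parameter recovery at n = 500
  set.seed(11)
  x <- rnorm(500)
  tt <- rexp(500, exp(0.7 * x))
  cens <- rexp(500, 0.15)
  fit2 <- cox_fit(pmin(tt, cens), as.integer(tt <= cens), x)
  expect_lt(abs(fit2$beta - 0.7), 0.15)
  expect_error(cox_fit(t0, e0, rep(1, 10)), "constant")
})

test_that("Cox Wald CI covers the null at roughly nominal rate", {
  cover <- 0
  nsim <- 150
  for (s in 1:nsim) {
    set.seed(3000 + s)
    x <- rnorm(80)
    tt <- rexp(80)
    fit <- suppressWarnings(cox_fit(tt, rep(1, 80), x))
    if (fit$hr_lower[1] <= 1 && 1 <= fit$hr_upper[1]) cover <- cover + 1
  }
  expect_gt(cover / nsim, 0.88)
  expect_lt(cover / nsim, 0.99)
})

test_that("concordance matches brute force, with ties and null calibration", {
  expect_equal(concordance_index(c(4, 3, 2, 1), 1:4, rep(1, 4)), 1)
  set.seed(21)
  for (i in 1:4) {
    n <- 60
    sc <- sample(1:10, n, replace = TRUE)       # force score ties
    tt <- sample(1:20, n, replace = TRUE)
    ev <- rbinom(n, 1, 0.7)
    expect_equal(concordance_index(sc, tt, ev), oracle_concordance(sc, tt, ev))
  }
  set.seed(22)
  nulls <- replicate(5, {
    tt <- rexp(500); ev <- rbinom(500, 1, 0.8)
    concordance_index(rnorm(500), tt, ev)
  })
  expect_lt(abs(mean(nulls) - 0.5), 0.03)
  expect_true(is.na(concordance_index(1, 5, 1)))
})

test_that("group tests: Mann-Whitney enumeration, Kruskal-Wallis, correlations", {
  gt <- group_tests(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(gt$test, "mann-whitney")
  expect_equal(gt$statistic, oracle_u(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(gt$statistic, 0)              # documented W convention
  kw <- group_tests(c(1, 2, 9, 10, 20, 21),
                    rep(c("a", "b", "c"), each = 2))
  expect_equal(kw$test, "kruskal-wallis")
  expect_error(group_tests(1:5, c("a", "a", "a", "a", "b")), "at least 2")
  # Spearman of any strictly monotone pairing is 1
  x <- sort(rnorm(20))
  at <- assoc_tests(x, exp(x))
  expect_equal(at$estimate[at$method == "spearman"], 1)
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)),
               p.adjust(c(0.01, 0.02, 0.03), "BH"))
})

test_that("Mann-Whitney null p-values are approximately uniform", {
  set.seed(31)
  ps <- replicate(400, {
    group_tests(rnorm(24), rep(c("a", "b"), each = 12))$p_value
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("bootstrap CIs: constant metric, CLT width, determinism, redraw cap", {
  b0 <- bootstrap_ci(rep(5, 50), mean, B = 200, seed = 1)
  expect_equal(b0$lower, b0$upper)
  set.seed(12)
  x <- rnorm(200)
  b1 <- bootstrap_ci(x, mean, B = 1000, seed = 3)
  width <- b1$upper - b1$lower
  expect_equal(width, 2 * 1.96 / sqrt(200), tolerance = 0.2)
  b2 <- bootstrap_ci(x, mean, B = 1000, seed = 3)
  expect_identical(b1, b2)
  expect_error(bootstrap_ci(x, mean, B = 50), "B must be")
  flaky <- function(v) if (length(unique(v)) < 199) NA_real_ else mean(v)
  expect_error(bootstrap_ci(x, flaky, B = 100, seed = 1, max_redraw = 5),
               "too many")
})
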