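test_that("quality path follows the measurements and drops to zero at follow-up", {
  tr <- qol_trajectory(0, 1.0, 4, 1)
  Q <- build_quality_path(tr)
  expect_equal(Q(c(0, 1, 3.999)), c(1, 1, 1))
  expect_equal(Q(c(4, 4.5)), c(0, 0))

  tr2 <- qol_trajectory(c(0, 4), c(1.0, 0.5), 4, 1)
  Q2 <- build_quality_path(tr2)
  expect_equal(Q2(2), 0.75)
  expect_equal(Q2(1), 0.875)
  expect_equal(Q2(4 + 1e-9), 0)

  expect_error(qol_trajectory(c(0, 3), c(1), 4, 1), "equal length")
  expect_error(qol_trajectory(c(0, 5), c(1, 1), 4, 1), "exceed follow-up")
})

test_that("adjust_time integrates the piecewise-linear path exactly", {
  tr <- qol_trajectory(0, 1.0, 4, 1)
  expect_equal(adjust_time(tr)$t_adj, 4)

  tr2 <- qol_trajectory(c(0, 4), c(1.0, 0.5), 4, 1)
  expect_equal(adjust_time(tr2)$t_adj, 3)   # int_0^4 (1 - t/8) dt

  # grid refinement leaves the total untouched (additivity of the integral)
  g1 <- time_grid(c(0, 4)); g4 <- time_grid(c(0, 1, 2, 3, 4))
  a1 <- adjust_time(tr2, g1); a4 <- adjust_time(tr2, g4)
  expect_equal(a1$t_adj, a4$t_adj)
  expect_equal(sum(a4$q), a4$t_adj)
  expect_equal(a4$q, c(15 / 16, 13 / 16, 11 / 16, 9 / 16))

  # truncation at the grid horizon
  g2 <- time_grid(c(0, 2))
  expect_equal(adjust_time(tr2, g2)$t_adj, 2 - 4 / 8 * 0.5)  # int_0^2
})

test_that("Kaplan-Meier estimate matches the hand product-limit computation", {
  km <- km_survival(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km$fn(c(0, 1, 2, 2.5, 3)), c(1, 2 / 3, 2 / 3, 2 / 3, 0))
  # no censoring: reverse-KM of the censoring distribution is identically 1
  G <- km_survival(c(1, 2, 3), c(1, 1, 1), flip = TRUE)
  expect_equal(G$fn(c(0.5, 1.5, 3)), c(1, 1, 1))
  # monotone nonincreasing on random censored data
  set.seed(4)
  tt <- rexp(60); ev <- rbinom(60, 1, 0.6)
  s <- km_survival(tt, ev)$fn(sort(runif(100, 0, max(tt))))
  expect_true(all(diff(s) <= 1e-12))
  expect_error(km_survival(numeric(0), integer(0)), "nonempty")
})

test_that("KM restricted moments reduce to sample moments without censoring", {
  x <- c(1, 2, 3)
  mo <- km_moments(x, c(1, 1, 1))
  expect_equal(mo$mean, 2)
  expect_equal(mo$var, 2 / 3)       # population divisor
  set.seed(8)
  y <- rnorm(400, 4, 0.75)
  mo2 <- km_moments(y, rep(1, 400))
  expect_equal(mo2$mean, mean(y), tolerance = 1e-10)
  expect_equal(mo2$var, var(y) * 399 / 400, tolerance = 1e-8)
})

test_that("partitioned QALY estimator matches hand bookkeeping", {
  # all alive and uncensored through one interval: the plain mean
  g1 <- time_grid(c(0, 2))
  expect_equal(qaly_mean_partitioned(cbind(c(1, 2, 3)), c(2, 2, 2), c(0, 0, 0), g1), 2)

  # four patients, two intervals [0,1), [1,2); patient 4 dies at t = 0.5
  # interval 1: all four at risk (the death is an observed event)
  #   qbar_1 = (0.9 + 0.8 + 1.0 + 0.4) / 4
  # interval 2: patients 1-3 at risk, S_hat(1-) = 3/4
  #   qbar_2 = (0.7 + 0.6 + 0.9) / 3
  g2 <- time_grid(c(0, 1, 2))
  q <- rbind(c(0.9, 0.7), c(0.8, 0.6), c(1.0, 0.9), c(0.4, 0))
  mu <- qaly_mean_partitioned(q, c(2, 2, 2, 0.5), c(0, 0, 0, 1), g2)
  expect_equal(mu, mean(c(0.9, 0.8, 1.0, 0.4)) + 0.75 * mean(c(0.7, 0.6, 0.9)))

  # linearity in q
  mu2 <- qaly_mean_partitioned(3 * q, c(2, 2, 2, 0.5), c(0, 0, 0, 1), g2)
  expect_equal(mu2, 3 * mu)
})

test_that("IPCW regression reduces to OLS without censoring and sums per interval", {
  g1 <- time_grid(c(0, 1))
  fit <- ipcw_regression(c(10, 20, 30), rep(1, 3), rep(1, 3), g1)
  expect_equal(unname(fit$coef), 20)

  # with a covariate and no censoring: the OLS solution
  set.seed(12)
  n <- 50
  z <- runif(n); yresp <- 5 + 3 * z + rnorm(n)
  Z <- cbind(1, z)
  fit2 <- ipcw_regression(yresp, rep(1, n), rep(1, n), g1, Z = Z)
  expect_equal(unname(fit2$coef), unname(coef(lm(yresp ~ z))), tolerance = 1e-10)

  # two intervals: the estimate is the sum of the per-interval solutions
  g2 <- time_grid(c(0, 1, 2))
  resp2 <- cbind(runif(n, 5, 10), runif(n, 1, 3))
  fu <- rep(2, n)
  f_all <- ipcw_regression(resp2, fu, rep(1, n), g2, Z = Z)
  expect_equal(f_all$coef, rowSums(f_all$per_interval))

  # hand-computed censored case: 4 patients, intercept-only, K = 1
  # followup (1, 2, 3, 4), events (1, 0, 1, 1), costs (10, 20, 30, 40)
  # censoring KM G: drop at t=2 (1 censored of 3 at risk) -> G = 2/3 after 2
  # delta* = (1, 0, 1, 1); G(X*-) = (1, 1, 2/3, 2/3)
  # alpha = sum(d*C/G) / sum(d*/G) = (10 + 45 + 60) / (1 + 1.5 + 1.5)
  g <- time_grid(c(0, 4))
  fit3 <- ipcw_regression(c(10, 20, 30, 40), c(1, 2, 3, 4), c(1, 0, 1, 1), g)
  expect_equal(unname(fit3$coef), 115 / 4)

  # collinear design errors out naming the columns
  expect_error(
    ipcw_regression(yresp, rep(1, n), rep(1, n), g1,
                    Z = cbind(a = rep(1, n), b = rep(2, n))),
    "singular")
})

test_that("Buckley-James variance uses event residuals only", {
  expect_equal(bj_variance(c(-10, 0, 10), c(1, 1, 1)), 200)
  expect_equal(bj_variance(rep(3, 5), rep(1, 5)), 0)
  # censored residuals drop out
  expect_equal(bj_variance(c(-10, 0, 10, 99), c(1, 1, 1, 0)), 200)
  # shift invariance
  expect_equal(bj_variance(c(-10, 0, 10) + 7, c(1, 1, 1)), 200)
  expect_error(bj_variance(c(1, 2), c(1, 1)), "more than 2 events")
})

test_that("both tau estimators agree exactly with pairwise enumeration", {
  expect_equal(kendall_tau_complete(1:3, 1:3), 1)
  expect_equal(kendall_tau_complete(c(1, 2, 3), c(3, 1, 2)), -1 / 3)
  # hand-worked censored case: only the (1,3) pair is orderable, discordant
  expect_equal(kendall_tau_censored(c(1, 2, 3), c(3, 1, 2), c(1, 0, 1)), -1)

  for (seed in 1:10) {
    d <- sim_small(40, seed, rate = 0.25)
    expect_equal(kendall_tau_censored(d$cost, d$time, d$event),
                 oracle_tau_censored(d$cost, d$time, d$event),
                 tolerance = 1e-12)
    expect_equal(kendall_tau_complete(d$cost, d$t_latent),
                 oracle_tau_complete(d$cost, d$t_latent),
                 tolerance = 1e-12)
    # symmetry of the complete-data statistic
    expect_equal(kendall_tau_complete(d$cost, d$t_latent),
                 kendall_tau_complete(d$t_latent, d$cost))
  }
  # with no censoring the censored estimator is the sample statistic
  for (seed in 1:5) {
    d <- sim_small(60, seed, rate = 0)
    expect_identical(kendall_tau_censored(d$cost, d$time, d$event),
                     kendall_tau_complete(d$cost, d$time))
  }
  expect_error(kendall_tau_complete(1, 1), ">= 2")
})

test_that("censored tau is close to the generating dependence at moderate n", {
  taus <- vapply(1:10, function(r) {
    d <- sim_small(1000, 500 + r, rate = 0.09)   # ~30% censoring
    kendall_tau_censored(d$cost, d$time, d$event)
  }, numeric(1))
  expect_equal(mean(taus), 0.6, tolerance = 0.02)
})
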