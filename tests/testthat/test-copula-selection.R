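test_that("censored likelihood reduces exactly to the plain copula likelihood", {
  d <- sim_small(300, 1, rate = 0)
  mod <- joint_model(margin_spec("normal", mean(d$cost), var(d$cost)),
                     margin_spec("normal", mean(d$time), var(d$time)),
                     copula_spec("clayton", theta = 3))
  ll <- censored_loglik(mod, d$cost, d$time, d$event)
  uT <- pnorm(d$time, mod$margin_qaly$mu, sqrt(mod$margin_qaly$sigma2))
  uC <- pnorm(d$cost, mod$margin_cost$mu, sqrt(mod$margin_cost$sigma2))
  direct <- sum(log(copula_pdf(mod$copula, uT, uC)) +
                  dnorm(d$time, mod$margin_qaly$mu, sqrt(mod$margin_qaly$sigma2), log = TRUE) +
                  dnorm(d$cost, mod$margin_cost$mu, sqrt(mod$margin_cost$sigma2), log = TRUE))
  expect_equal(as.numeric(ll), direct, tolerance = 1e-12)
  expect_identical(attr(ll, "n_bad"), 0L)
})

test_that("each likelihood factor matches term-by-term hand evaluation", {
  mc <- margin_spec("normal", 1500, 400^2)
  mt <- margin_spec("normal", 4, 0.75^2)
  cop <- copula_spec("clayton", theta = 3)
  link <- copula_spec("clayton", theta = 0.5)
  mod <- joint_model(mc, mt, cop, censor_rate = 0.09, censor_link = link)

  # one censored record: factor 2 (joint survival of T beyond y) and
  # factor 3 (censoring density with its cost link)
  y <- 3.2; x <- 1400
  ll_c <- censored_loglik(mod, x, y, 0L)
  uT <- pnorm(y, 4, 0.75); uC <- pnorm(x, 1500, 400); uH <- pexp(y, 0.09)
  by_hand <- log(1 - copula_cdf(cop, uT, uC)) +
    log(copula_pdf(link, uH, uC)) + dexp(y, 0.09, log = TRUE) +
    dnorm(x, 1500, 400, log = TRUE)
  expect_equal(as.numeric(ll_c), by_hand, tolerance = 1e-12)

  # one observed record: factor 1 (joint density) and factor 4
  ll_o <- censored_loglik(mod, x, y, 1L)
  by_hand_o <- log(copula_pdf(cop, uT, uC)) + dnorm(y, 4, 0.75, log = TRUE) +
    dnorm(x, 1500, 400, log = TRUE) + log(1 - copula_cdf(link, uH, uC))
  expect_equal(as.numeric(ll_o), by_hand_o, tolerance = 1e-12)

  # censored data without a censoring margin is refused
  mod0 <- joint_model(mc, mt, cop)
  expect_error(censored_loglik(mod0, x, y, 0L), "censoring margin")
})

test_that("likelihood peaks near the generating dependence parameter", {
  wins <- 0L
  for (seed in 1:8) {
    d <- sim_small(2000, 100 + seed, rate = 0.041)
    at <- function(th) {
      m <- joint_model(margin_spec("normal", 1500, 400^2),
                       margin_spec("normal", 4, 0.75^2),
                       copula_spec("clayton", theta = th),
                       censor_rate = 0.041)
      as.numeric(censored_loglik(m, d$cost, d$time, d$event))
    }
    if (at(3) >= max(at(2.7), at(3.3))) wins <- wins + 1L
  }
  expect_gte(wins, 7L)
})

test_that("posterior sampling is reproducible and concentrates near the truth", {
  d <- sim_small(2000, 77, rate = 0.041)
  ps <- posterior_sample("clayton", d$cost, d$time, d$event, n_draws = 600,
                         burnin = 400, seed = 11, cost_family = "normal",
                         qaly_family = "normal")
  expect_gt(ps$accept, 0.1)
  expect_lt(ps$accept, 0.6)
  expect_equal(mean(ps$draws[, "theta"]), 3, tolerance = 0.12)
  expect_equal(mean(ps$draws[, "mu_c"]), 1500, tolerance = 25)
  ps2 <- posterior_sample("clayton", d$cost, d$time, d$event, n_draws = 600,
                          burnin = 400, seed = 11, cost_family = "normal",
                          qaly_family = "normal")
  expect_identical(ps$draws, ps2$draws)
})

test_that("DIC equals the deviance for a degenerate parameter sample", {
  d <- sim_small(300, 5, rate = 0.09)
  fit <- fit_joint_model(d$cost, d$time, d$event, "clayton",
                         cost_family = "normal", qaly_family = "normal")
  phi <- t(replicate(5, c(mu_c = fit$margin_cost$mu, s2_c = fit$margin_cost$sigma2,
                          mu_t = fit$margin_qaly$mu, s2_t = fit$margin_qaly$sigma2,
                          theta = fit$copula$theta)))
  res <- dic("clayton", d$cost, d$time, d$event, draws = phi,
             cost_family = "normal", qaly_family = "normal")
  D <- -2 * as.numeric(censored_loglik(fit, d$cost, d$time, d$event))
  expect_equal(res$dic, D, tolerance = 1e-8)
  expect_equal(res$mean_deviance, res$dev_at_mean, tolerance = 1e-8)
})

test_that("plug-in DIC agrees with the MCMC DIC", {
  d <- sim_small(1000, 6, rate = 0.041)
  d1 <- dic("clayton", d$cost, d$time, d$event, mode = "mcmc", n_draws = 600,
            burnin = 300, seed = 2, cost_family = "normal", qaly_family = "normal")
  d2 <- dic("clayton", d$cost, d$time, d$event, mode = "plugin", B = 40,
            seed = 3, cost_family = "normal", qaly_family = "normal")
  expect_equal(d1$dic, d2$dic, tolerance = 0.05 * abs(d1$dic))
})

test_that("copula selection returns the full report and is seed-deterministic", {
  d <- sim_small(600, 14, rate = 0.041)
  one <- select_copula(d$cost, d$time, d$event, families = "clayton", seed = 4,
                       B = 15, qaly_family = "normal")
  expect_identical(one$chosen, "clayton")
  sel <- select_copula(d$cost, d$time, d$event,
                       families = c("gaussian", "clayton"), seed = 4, B = 15,
                       qaly_family = "normal")
  expect_identical(nrow(sel$table), 2L)
  expect_identical(sel$chosen, sel$table$family[which.min(sel$table$dic)])
  sel2 <- select_copula(d$cost, d$time, d$event,
                        families = c("gaussian", "clayton"), seed = 4, B = 15,
                        qaly_family = "normal")
  expect_identical(sel$table, sel2$table)
  expect_error(select_copula(d$cost, d$time, d$event, families = character(0)),
               "at least one")
})
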