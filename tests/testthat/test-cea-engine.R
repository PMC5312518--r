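ind_model <- function(mu_c = 1500, s2_c = 400^2, mu_t = 4, s2_t = 0.75^2,
                      cop = copula_spec("clayton", theta = 1e-7)) {
  joint_model(margin_spec("normal", mu_c, s2_c),
              margin_spec("normal", mu_t, s2_t), cop)
}

test_that("joint expectations marginalize correctly and match Monte Carlo", {
  m_ind <- ind_model()
  expect_equal(as.numeric(joint_expectation(m_ind, "cost")), 1500, tolerance = 1e-3)
  expect_equal(as.numeric(joint_expectation(m_ind, "qaly")), 4, tolerance = 1e-5)
  expect_equal(as.numeric(joint_expectation(m_ind, "product")), 6000, tolerance = 0.01)

  # the marginal means do not depend on the copula family (1e-3 relative)
  for (f in c("gaussian", "student", "clayton", "gumbel", "frank", "joe")) {
    m <- joint_model(margin_spec("gamma", 1500, 187500),
                     margin_spec("normal", 4, 0.75^2),
                     copula_spec(f, tau = 0.6))
    expect_equal(as.numeric(joint_expectation(m, "cost")) / 1500, 1,
                 tolerance = 1e-3, label = sprintf("%s E[C]", f))
    expect_equal(as.numeric(joint_expectation(m, "qaly")) / 4, 1,
                 tolerance = 1e-3, label = sprintf("%s E[T]", f))
  }

  # model covariance against a large Monte-Carlo draw
  mcl <- joint_model(margin_spec("normal", 1500, 400^2),
                     margin_spec("normal", 4, 0.75^2),
                     copula_spec("clayton", theta = 3))
  cov_quad <- as.numeric(joint_expectation(mcl, "product")) -
    as.numeric(joint_expectation(mcl, "cost")) *
    as.numeric(joint_expectation(mcl, "qaly"))
  uv <- sample_copula(mcl$copula, 2e5, seed = 31)
  cc <- qnorm(uv[, 2], 1500, 400); tt <- qnorm(uv[, 1], 4, 0.75)
  mc_cov <- cov(cc, tt)
  se <- sd((cc - mean(cc)) * (tt - mean(tt))) / sqrt(2e5)
  expect_lt(abs(cov_quad - mc_cov), 3 * se)
})

test_that("delta components behave at the trivial limits", {
  m <- ind_model(cop = copula_spec("clayton", theta = 3))
  comp <- delta_components(m, m, 100, 100)
  expect_equal(comp$delta_cost, 0, tolerance = 1e-9)
  expect_equal(comp$delta_qaly, 0, tolerance = 1e-9)
  expect_equal(comp$var_delta_cost, 2 * 400^2 / 100)

  comp_ind <- delta_components(ind_model(), ind_model(mu_c = 1700), 50, 50)
  expect_equal(comp_ind$cov_delta, 0, tolerance = 1e-4)
  expect_equal(comp_ind$delta_cost, 200, tolerance = 1e-2)
  expect_error(delta_components(m, m, 1, 100), ">= 2")
})

test_that("the ICER is the ratio of mean differences", {
  # Delta_C and Delta_T on the scale of a two-arm QALY trial
  comp <- cea_components(403.40 - 217.20, 0.7268 - 0.7083, 50, 1e-4, 0)
  expect_equal(icer(comp), 10064.86, tolerance = 1e-5)
  expect_equal(icer(cea_components(0, 0.02, 1, 1e-6)), 0)
  expect_lt(icer(cea_components(200, -0.02, 1, 1e-6)), 0)
  expect_error(icer(cea_components(200, 0, 1, 1e-6)), "undefined")
})

test_that("Fieller interval collapses, bounds, and goes typed when degenerate", {
  comp <- cea_components(200, 0.02, 1e-12, 1e-16, 0)
  ci <- fieller_ci(comp)
  expect_identical(ci$type, "bounded")
  expect_equal(ci$lower, 10000, tolerance = 1e-6)
  expect_equal(ci$upper, 10000, tolerance = 1e-6)

  # denominator not significantly nonzero: a typed, non-numeric outcome
  weak <- cea_components(200, 0.001, 20^2, 0.05^2, 0)
  expect_true(fieller_ci(weak)$type %in% c("exclusive", "unbounded"))

  # against a parametric-bootstrap oracle (2%)
  comp2 <- cea_components(200, 0.02, 20^2, 0.002^2, 0.5 * 20 * 0.002)
  ci2 <- fieller_ci(comp2, 0.05)
  set.seed(1)
  S <- matrix(c(400, 0.02, 0.02, 4e-6), 2)
  Z <- matrix(rnorm(2e5), ncol = 2) %*% chol(S)
  q <- unname(quantile((200 + Z[, 1]) / (0.02 + Z[, 2]), c(0.025, 0.975)))
  expect_equal(ci2$lower, q[1], tolerance = 0.02 * abs(q[1]))
  expect_equal(ci2$upper, q[2], tolerance = 0.02 * abs(q[2]))
})

test_that("Fieller interval attains nominal coverage over simulated trials", {
  m0 <- joint_model(margin_spec("normal", 1500, 400^2),
                    margin_spec("normal", 4, 0.75^2), copula_spec("clayton", theta = 3))
  m1 <- joint_model(margin_spec("normal", 1700, 400^2),
                    margin_spec("normal", 4.5, 0.75^2), copula_spec("clayton", theta = 3))
  truth <- 200 / 0.5
  set.seed(42)
  hits <- 0L
  for (i in 1:500) {
    s0 <- sample_copula(m0$copula, 500); s1 <- sample_copula(m1$copula, 500)
    c0 <- qnorm(s0[, 2], 1500, 400); t0 <- qnorm(s0[, 1], 4, 0.75)
    c1 <- qnorm(s1[, 2], 1700, 400); t1 <- qnorm(s1[, 1], 4.5, 0.75)
    cm <- cea_components(mean(c1) - mean(c0), mean(t1) - mean(t0),
                         var(c1) / 500 + var(c0) / 500,
                         var(t1) / 500 + var(t0) / 500,
                         cov(c1, t1) / 500 + cov(c0, t0) / 500)
    ci <- fieller_ci(cm, 0.05)
    if (ci$type == "bounded" && ci$lower <= truth && truth <= ci$upper)
      hits <- hits + 1L
  }
  expect_gte(hits / 500, 0.93)
  expect_lte(hits / 500, 0.97)
})

test_that("INB identities and the Fieller duality hold", {
  comp <- cea_components(200, 0.02, 20^2, 0.002^2, 0.5 * 20 * 0.002)
  at0 <- inb(comp, 0)
  expect_equal(at0$inb, -200)
  expect_equal(at0$variance, 400)

  expect_equal(inb(comp, icer(comp))$inb, 0, tolerance = 1e-10)

  nocov <- cea_components(200, 0.02, 3, 2, 0)
  expect_equal(inb(nocov, 1)$variance, 5)

  # z at the Fieller bounds equals +-z_{1-alpha/2} (within 1%)
  ci <- fieller_ci(comp, 0.05)
  zz <- inb(comp, c(ci$lower, ci$upper))$z
  expect_equal(abs(zz), rep(qnorm(0.975), 2), tolerance = 0.01)

  # affine in lambda with slope Delta_T
  grid <- inb(comp, c(0, 1000, 2000))
  expect_equal(diff(grid$inb), rep(1000 * 0.02, 2))
  expect_error(inb(cea_components(1, 1, 1e-6, 1e-6, 10), 1), "variance")
})

test_that("subgroup INB vanishes for exchangeable cells and adds up under independence", {
  cell <- list(mean_cost = 1500, mean_qaly = 4, var_cost = 400^2,
               var_qaly = 0.75^2, cov = 0, n = 200)
  cells <- list(`1,1` = cell, `1,0` = cell, `0,1` = cell, `0,0` = cell)
  res <- subgroup_inb(cells, lambda = 1000)
  expect_equal(res$inb, 0)
  expect_false(res$reject)
  expect_equal(res$variance,
               1000^2 * 4 * 0.75^2 / 200 + 4 * 400^2 / 200)
  expect_error(subgroup_inb(cells[1:3], 1000), "missing cell")
})

test_that("unbalanced-mode variance matches a cross-linked simulation", {
  # four cells of n = 200; within cells costs and QALY are independent, but
  # arm-1 QALY is linked to arm-0 cost (and vice versa) through a Gaussian
  # copula with correlation 0.7 within each subgroup level
  n <- 200; rho <- 0.7; lam <- 500
  cross_cov_true <- rho * 0.75 * 400     # bivariate-normal covariance
  gcop <- copula_spec("gaussian", theta = rho)
  set.seed(88)
  reps <- 1500
  vals <- numeric(reps)
  for (i in seq_len(reps)) {
    stat <- 0
    for (k in 0:1) {
      A <- sample_copula(gcop, n); B <- sample_copula(gcop, n)
      T1 <- qnorm(A[, 1], 4, 0.75); C0 <- qnorm(A[, 2], 1500, 400)
      T0 <- qnorm(B[, 1], 4, 0.75); C1 <- qnorm(B[, 2], 1500, 400)
      sgn <- if (k == 1) 1 else -1   # level contrast within each arm
      stat <- stat + sgn * (lam * (mean(T1) - mean(T0)) - (mean(C1) - mean(C0)))
    }
    vals[i] <- stat
  }
  cell <- list(mean_cost = 1500, mean_qaly = 4, var_cost = 400^2,
               var_qaly = 0.75^2, cov = 0, n = n)
  cells <- list(`1,1` = cell, `1,0` = cell, `0,1` = cell, `0,0` = cell)
  cross <- list(t1c0 = rep(cross_cov_true / n, 2),
                t0c1 = rep(cross_cov_true / n, 2))
  v_model <- subgroup_inb(cells, lam, mode = "unbalanced", cross_cov = cross)$variance
  expect_equal(var(vals), v_model, tolerance = 0.10 * v_model)
  # and the randomized mode (no crossed terms) is measurably wrong here
  v_rand <- subgroup_inb(cells, lam, mode = "randomized")$variance
  expect_gt(abs(var(vals) - v_rand), 0.15 * v_rand)
})

test_that("cea_summary assembles a coherent report", {
  m0 <- ind_model(); m1 <- ind_model(mu_c = 1700, mu_t = 4.5)
  res <- cea_summary(m0, m1, 400, 400, lambda = c(0, 400, 800))
  expect_equal(res$icer, 200 / 0.5, tolerance = 0.05)
  expect_identical(res$fieller$type, "bounded")
  expect_equal(nrow(res$inb_curve), 3L)
  expect_output(print(res), "Delta cost")
})
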