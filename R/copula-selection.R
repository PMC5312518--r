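#' Joint cost-QALY model for one trial arm
#'
#' Bundles the two fitted margins, the copula linking them, and an optional
#' exponential model for the (quality-adjusted) censoring times. The
#' censoring model is required to evaluate the censored likelihood on data
#' containing censored records; its own copula link with costs is held in
#' `censor_link`.
#'
#' @param margin_cost,margin_qaly [margin_spec()] objects for costs and
#'   quality-adjusted survival.
#' @param copula A [copula_spec()].
#' @param censor_rate Optional exponential rate for the censoring margin
#'   (`NULL` when the data are uncensored).
#' @param censor_link Copula linking the censoring time with costs in the
#'   likelihood's censoring factors: a [copula_spec()], or `NULL` for the
#'   independence copula. The dependence of this link is a separate quantity
#'   from the cost-QALY dependence and is estimated from the observed
#'   censoring times (see [fit_joint_model()]); forcing the cost-QALY theta
#'   onto it badly distorts model selection whenever censoring is in truth
#'   unrelated to costs.
#' @return An object of class `joint_model`.
#' @export
joint_model <- function(margin_cost, margin_qaly, copula, censor_rate = NULL,
                        censor_link = NULL) {
  stopifnot(inherits(margin_cost, "margin_spec"),
            inherits(margin_qaly, "margin_spec"),
            inherits(copula, "copula_spec"))
  if (!is.null(censor_rate) && (!is.finite(censor_rate) || censor_rate <= 0))
    .stopf("`censor_rate` must be positive")
  if (!is.null(censor_link)) stopifnot(inherits(censor_link, "copula_spec"))
  structure(list(margin_cost = margin_cost, margin_qaly = margin_qaly,
                 copula = copula, censor_rate = censor_rate,
                 censor_link = censor_link),
            class = "joint_model")
}

#' @export
print.joint_model <- function(x, ...) {
  cat("Joint cost-QALY model\n  cost:  ")
  print(x$margin_cost)
  cat("  QALY:  ")
  print(x$margin_qaly)
  cat("  link:  ")
  print(x$copula)
  if (!is.null(x$censor_rate))
    cat(sprintf("  censoring: exponential(rate = %.4g)\n", x$censor_rate))
  invisible(x)
}

# flatten the estimable parameters: cost moments, QALY moments, theta
.model_phi <- function(model) {
  c(mu_c = model$margin_cost$mu, s2_c = model$margin_cost$sigma2,
    mu_t = model$margin_qaly$mu, s2_t = model$margin_qaly$sigma2,
    theta = model$copula$theta)
}

.phi_model <- function(phi, template) {
  joint_model(
    suppressWarnings(margin_spec(template$margin_cost$family,
                                 phi[["mu_c"]], phi[["s2_c"]])),
    suppressWarnings(margin_spec(template$margin_qaly$family,
                                 phi[["mu_t"]], phi[["s2_t"]])),
    copula_spec(template$copula$family, theta = phi[["theta"]],
                df = if (is.null(template$copula$df)) 4 else template$copula$df),
    censor_rate = template$censor_rate, censor_link = template$censor_link)
}

#' Censored copula log-likelihood
#'
#' The four-factor likelihood for right-censored QALY with fully observed
#' costs. Uncensored records contribute the joint density
#' `c(F_T(y), F_C(x)) f_T(y) f_C(x)` and the factor
#' `1 - C(F_eta(y), F_C(x))` (the censoring time exceeding y); censored
#' records contribute `1 - C(F_T(y), F_C(x))` and the censoring-margin
#' density factor `c(F_eta(y), F_C(x)) f_eta(y) f_C(x)`. With no censored
#' records and no censoring margin this reduces exactly to the plain copula
#' log-likelihood. Impossible values (zero density) contribute `-Inf`, with
#' their count attached as attribute `n_bad`.
#'
#' @param model A [joint_model()]; `censor_rate` must be set when any record
#'   is censored.
#' @param cost Observed costs.
#' @param time Observed (possibly censored) quality-adjusted times.
#' @param event 0/1 event indicators.
#' @return The log-likelihood (scalar, possibly `-Inf`).
#' @export
censored_loglik <- function(model, cost, time, event) {
  stopifnot(inherits(model, "joint_model"))
  n <- length(cost)
  if (n == 0L || length(time) != n || length(event) != n)
    .stopf("`cost`, `time`, `event` must be nonempty and of equal length")
  d <- as.integer(event)
  if (any(d == 0L) && is.null(model$censor_rate))
    .stopf("data contain censored records but the model has no censoring margin")
  uT <- .clamp01(margin_cdf(model$margin_qaly, time))
  uC <- .clamp01(margin_cdf(model$margin_cost, cost))
  ll <- numeric(n)
  obs <- d == 1L
  if (any(obs)) {
    ll[obs] <- log(copula_pdf(model$copula, uT[obs], uC[obs])) +
      log(margin_pdf(model$margin_qaly, time[obs])) +
      log(margin_pdf(model$margin_cost, cost[obs]))
  }
  if (any(!obs)) {
    ll[!obs] <- log1p(-copula_cdf(model$copula, uT[!obs], uC[!obs]))
  }
  if (!is.null(model$censor_rate)) {
    uH <- .clamp01(stats::pexp(time, model$censor_rate))
    link <- model$censor_link
    link_pdf <- if (is.null(link)) function(u, v) rep(1, length(u)) else
      function(u, v) copula_pdf(link, u, v)
    link_cdf <- if (is.null(link)) function(u, v) u * v else
      function(u, v) copula_cdf(link, u, v)
    if (any(!obs)) {
      ll[!obs] <- ll[!obs] +
        log(link_pdf(uH[!obs], uC[!obs])) +
        stats::dexp(time[!obs], model$censor_rate, log = TRUE) +
        log(margin_pdf(model$margin_cost, cost[!obs]))
    }
    if (any(obs)) {
      ll[obs] <- ll[obs] + log1p(-link_cdf(uH[obs], uC[obs]))
    }
  }
  bad <- !is.finite(ll)
  out <- sum(ll)
  attr(out, "n_bad") <- sum(bad)
  out
}

#' Two-stage fit of a joint model
#'
#' The estimation flow used throughout: margins first (sample moments for the
#' always-observed costs, Kaplan-Meier restricted moments for censored QALY),
#' then the censoring-robust Kendall's tau inverted to the copula parameter
#' of the requested family. The censoring margin is an exponential fitted to
#' the censoring times by maximum likelihood
#' (`rate = #censored / sum(time)`).
#'
#' @param cost,time,event Patient-level data as in [censored_loglik()].
#' @param copula_family Copula family for the dependence link.
#' @param cost_family,qaly_family Margin families; when `NULL` the family is
#'   chosen by [select_margin()] (costs among normal/gamma/lognormal, QALY
#'   among normal/gamma).
#' @param df Student-t degrees of freedom.
#' @return A [joint_model()] with attribute `tau` (the estimated tau).
#' @export
fit_joint_model <- function(cost, time, event, copula_family,
                            cost_family = NULL, qaly_family = NULL, df = 4) {
  d <- as.integer(event)
  mc <- if (is.null(cost_family)) {
    select_margin(cost)$spec
  } else {
    suppressWarnings(margin_spec(cost_family, mean(cost), stats::var(cost)))
  }
  mt <- if (is.null(qaly_family)) {
    select_margin(time, d, families = c("normal", "gamma"))$spec
  } else {
    mo <- if (all(d == 1L)) list(mean = mean(time), var = stats::var(time)) else km_moments(time, d)
    suppressWarnings(margin_spec(qaly_family, mo$mean, mo$var))
  }
  tau <- if (all(d == 1L)) kendall_tau_complete(cost, time) else
    kendall_tau_censored(cost, time, d)
  cop <- copula_spec(copula_family, tau = tau, df = df)
  rate <- NULL
  link <- NULL
  if (any(d == 0L)) {
    rate <- sum(d == 0L) / sum(time)
    cens <- d == 0L
    if (sum(cens) >= 10L) {
      tau_h <- kendall_tau_complete(cost[cens], time[cens])
      link <- tryCatch(copula_spec(copula_family, tau = tau_h, df = df),
                       error = function(e) NULL)
    }
  }
  out <- joint_model(mc, mt, cop, censor_rate = rate, censor_link = link)
  attr(out, "tau") <- tau
  out
}

# parameter transforms for the sampler: unconstrained real scale
.phi_transform <- function(phi, template) {
  fam_c <- template$margin_cost$family
  th <- phi[["theta"]]
  cop <- template$copula$family
  c(if (fam_c == "normal") phi[["mu_c"]] else log(phi[["mu_c"]]),
    log(phi[["s2_c"]]),
    phi[["mu_t"]],           # QALY margin mean (normal or gamma, mean kept raw/log)
    log(phi[["s2_t"]]),
    switch(cop,
           gaussian = , student = atanh(th),
           clayton = log(th),
           gumbel = , joe = log(th - 1),
           frank = th))
}

.phi_untransform <- function(psi, template) {
  fam_c <- template$margin_cost$family
  cop <- template$copula$family
  c(mu_c = if (fam_c == "normal") psi[1] else exp(psi[1]),
    s2_c = exp(psi[2]),
    mu_t = psi[3],
    s2_t = exp(psi[4]),
    theta = switch(cop,
                   gaussian = , student = tanh(psi[5]),
                   clayton = exp(psi[5]),
                   gumbel = , joe = 1 + exp(psi[5]),
                   frank = psi[5]))
}

#' Posterior sample of the joint-model parameters
#'
#' Adaptive random-walk Metropolis on transformed parameters (log scale for
#' variances and positive means, Fisher-z or log for the copula parameter)
#' with flat priors on the transformed scale. The chain is initialized at the
#' two-stage estimate; the proposal scale adapts during burn-in towards an
#' acceptance fraction near 0.3.
#'
#' @param family Copula family to fit.
#' @param cost,time,event Data as in [censored_loglik()].
#' @param n_draws Retained draws (after burn-in).
#' @param burnin Burn-in iterations.
#' @param seed Optional seed.
#' @param df Student-t degrees of freedom.
#' @param cost_family,qaly_family Margin families (default: selected).
#' @return List with `draws` (an `n_draws x 5` matrix of natural-scale
#'   parameters), `accept` (post-adaptation acceptance fraction) and the
#'   two-stage `init` model.
#' @export
posterior_sample <- function(family, cost, time, event, n_draws = 1000,
                             burnin = 500, seed = NULL, df = 4,
                             cost_family = NULL, qaly_family = NULL) {
  if (n_draws < 1) .stopf("`n_draws` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  init <- fit_joint_model(cost, time, event, family,
                          cost_family = cost_family, qaly_family = qaly_family,
                          df = df)
  psi <- .phi_transform(.model_phi(init), init)
  ll <- function(psi) {
    phi <- .phi_untransform(psi, init)
    if (!is.finite(phi[["s2_c"]]) || !is.finite(phi[["s2_t"]])) return(-Inf)
    ok <- tryCatch({
      m <- .phi_model(phi, init)
      as.numeric(censored_loglik(m, cost, time, event))
    }, error = function(e) -Inf)
    if (!is.finite(ok)) -Inf else ok
  }
  cur_ll <- ll(psi)
  if (!is.finite(cur_ll))
    .stopf("log-likelihood not finite at the moment-based initialization; check the margins")
  p <- length(psi)
  sd0 <- rep(0.05, p)
  draws <- matrix(NA_real_, n_draws, p)
  acc_window <- 0L
  n_acc <- 0L; n_post <- 0L
  total <- burnin + n_draws
  for (it in seq_len(total)) {
    prop <- psi + stats::rnorm(p, 0, sd0)
    prop_ll <- ll(prop)
    if (is.finite(prop_ll) && log(stats::runif(1)) < prop_ll - cur_ll) {
      psi <- prop; cur_ll <- prop_ll
      acc_window <- acc_window + 1L
      if (it > burnin) n_acc <- n_acc + 1L
    }
    if (it <= burnin && it %% 50L == 0L) {
      rate <- acc_window / 50
      sd0 <- sd0 * exp(rate - 0.3)   # push acceptance towards ~0.3
      acc_window <- 0L
    }
    if (it > burnin) {
      n_post <- n_post + 1L
      draws[n_post, ] <- .phi_untransform(psi, init)
    }
  }
  colnames(draws) <- c("mu_c", "s2_c", "mu_t", "s2_t", "theta")
  list(draws = draws, accept = n_acc / n_draws, init = init)
}

#' Deviance information criterion for one copula family
#'
#' `DIC = 2 E[D(Phi)] - D(E[Phi])` with `D(Phi) = -2 loglik`, both
#' expectations approximated over a sample of parameter vectors. Two
#' samplers are available: `"mcmc"` draws from the posterior via
#' [posterior_sample()]; the default `"plugin"` mode approximates the
#' posterior with parametric-bootstrap replicates of the two-stage estimator
#' (refitting moments and tau on data simulated from the fitted model), which
#' is much cheaper and agrees closely on well-sized samples.
#'
#' @param family Copula family.
#' @param cost,time,event Data.
#' @param mode `"plugin"` or `"mcmc"`.
#' @param B Bootstrap replicates (plugin mode).
#' @param n_draws,burnin MCMC settings (mcmc mode).
#' @param seed Optional seed.
#' @param df Student-t degrees of freedom.
#' @param cost_family,qaly_family Margin families (default: selected once on
#'   the data and held fixed across draws).
#' @param draws Optional precomputed parameter draws (`matrix` with columns
#'   `mu_c, s2_c, mu_t, s2_t, theta`); overrides the sampler.
#' @return List with `dic`, `mean_deviance`, `dev_at_mean`, `family`.
#' @export
dic <- function(family, cost, time, event, mode = c("plugin", "mcmc"),
                B = 40, n_draws = 1000, burnin = 500, seed = NULL, df = 4,
                cost_family = NULL, qaly_family = NULL, draws = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  fit <- fit_joint_model(cost, time, event, family,
                         cost_family = cost_family, qaly_family = qaly_family,
                         df = df)
  if (is.null(draws)) {
    draws <- if (mode == "mcmc") {
      posterior_sample(family, cost, time, event, n_draws = n_draws,
                       burnin = burnin, df = df,
                       cost_family = fit$margin_cost$family,
                       qaly_family = fit$margin_qaly$family)$draws
    } else {
      .bootstrap_phi_draws(fit, length(cost), B, df = df)
    }
  }
  D <- apply(draws, 1, function(phi) {
    m <- tryCatch(.phi_model(phi, fit), error = function(e) NULL)
    if (is.null(m)) return(NA_real_)
    -2 * as.numeric(censored_loglik(m, cost, time, event))
  })
  D <- D[is.finite(D)]
  if (length(D) == 0L) .stopf("no finite deviance draws for the %s copula", family)
  phi_bar <- colMeans(draws[is.finite(draws[, 1]), , drop = FALSE])
  dev_at_mean <- -2 * as.numeric(censored_loglik(.phi_model(phi_bar, fit),
                                                 cost, time, event))
  list(dic = 2 * mean(D) - dev_at_mean, mean_deviance = mean(D),
       dev_at_mean = dev_at_mean, family = family, fit = fit)
}

# parametric-bootstrap draws of the two-stage estimator around `fit`
.bootstrap_phi_draws <- function(fit, n, B, df = 4) {
  draws <- matrix(NA_real_, B, 5)
  colnames(draws) <- c("mu_c", "s2_c", "mu_t", "s2_t", "theta")
  fam <- fit$copula$family
  for (b in seq_len(B)) {
    uv <- sample_copula(fit$copula, n)
    tt <- margin_quantile(fit$margin_qaly, uv[, 1])
    cc <- margin_quantile(fit$margin_cost, uv[, 2])
    if (!is.null(fit$censor_rate)) {
      eta <- stats::rexp(n, fit$censor_rate)
      tobs <- pmin(tt, eta)
      d <- as.integer(tt <= eta)
    } else {
      tobs <- tt
      d <- rep(1L, n)
    }
    mo <- if (all(d == 1L)) list(mean = mean(tobs), var = stats::var(tobs)) else
      km_moments(tobs, d)
    tau_b <- if (all(d == 1L)) kendall_tau_complete(cc, tobs) else
      kendall_tau_censored(cc, tobs, d)
    th <- tryCatch(tau_to_theta(fam, tau_b, df = df), error = function(e) NA_real_)
    draws[b, ] <- c(mean(cc), stats::var(cc), mo$mean, mo$var, th)
  }
  draws[stats::complete.cases(draws), , drop = FALSE]
}

#' Select a copula family by DIC
#'
#' Computes the DIC of every candidate family on the same data and returns
#' the full report; the chosen family is the one with the smallest DIC.
#'
#' @param cost,time,event Data.
#' @param families Candidate copula families.
#' @param mode,B,n_draws,burnin,seed,df Passed to [dic()].
#' @param cost_family,qaly_family Margin families (default: selected once on
#'   the data, shared by all candidates).
#' @return An object of class `copula_selection`: list with `table` (family,
#'   dic, mean_deviance, dev_at_mean), `chosen`, and the fitted model of the
#'   winner.
#' @export
select_copula <- function(cost, time, event,
                          families = c("gaussian", "clayton", "gumbel"),
                          mode = c("plugin", "mcmc"), B = 40, n_draws = 1000,
                          burnin = 500, seed = NULL, df = 4,
                          cost_family = NULL, qaly_family = NULL) {
  if (length(families) == 0L) .stopf("at least one candidate family is required")
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(cost_family)) cost_family <- select_margin(cost)$family
  if (is.null(qaly_family))
    qaly_family <- select_margin(time, event, families = c("normal", "gamma"))$family
  res <- vector("list", length(families))
  errs <- character(0)
  for (i in seq_along(families)) {
    res[[i]] <- tryCatch(
      dic(families[i], cost, time, event, mode = mode, B = B,
          n_draws = n_draws, burnin = burnin, df = df,
          cost_family = cost_family, qaly_family = qaly_family),
      error = function(e) {
        errs <<- c(errs, sprintf("%s: %s", families[i], conditionMessage(e)))
        NULL
      })
  }
  ok <- !vapply(res, is.null, logical(1))
  if (!any(ok))
    .stopf("all candidate families failed to fit:\n  %s",
           paste(errs, collapse = "\n  "))
  tab <- data.frame(
    family = families[ok],
    dic = vapply(res[ok], `[[`, numeric(1), "dic"),
    mean_deviance = vapply(res[ok], `[[`, numeric(1), "mean_deviance"),
    dev_at_mean = vapply(res[ok], `[[`, numeric(1), "dev_at_mean"),
    stringsAsFactors = FALSE)
  best <- which.min(tab$dic)
  structure(list(table = tab, chosen = tab$family[best],
                 model = res[ok][[best]]$fit, failed = errs),
            class = "copula_selection")
}

#' @export
print.copula_selection <- function(x, ...) {
  cat("Copula selection by DIC\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("chosen: %s\n", x$chosen))
  invisible(x)
}
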