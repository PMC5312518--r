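#' Quality-of-life trajectory for one patient
#'
#' Holds utility scores at their measurement times, the follow-up time
#' `X = min(survival, censoring)` and the event indicator (1 = death
#' observed). Times must be strictly increasing and no later than follow-up.
#'
#' @param times Measurement times, strictly increasing, all `<= followup`.
#' @param scores Utility values at those times, finite.
#' @param followup Follow-up time `X`.
#' @param event Event indicator in `{0, 1}`.
#' @return An object of class `qol_trajectory`.
#' @export
qol_trajectory <- function(times, scores, followup, event) {
  if (length(times) == 0L || length(times) != length(scores))
    .stopf("`times` and `scores` must be nonempty and of equal length")
  if (any(diff(times) <= 0)) .stopf("`times` must be strictly increasing")
  if (any(times > followup)) .stopf("measurement times must not exceed follow-up")
  if (!all(is.finite(scores))) .stopf("`scores` must be finite")
  if (!event %in% c(0, 1)) .stopf("`event` must be 0 or 1")
  structure(list(times = as.numeric(times), scores = as.numeric(scores),
                 followup = as.numeric(followup), event = as.integer(event)),
            class = "qol_trajectory")
}

#' Partition of the study horizon into intervals
#'
#' Boundaries `a_1 = 0 < a_2 < ... < a_{K+1} = tau_horizon` defining the K
#' half-open intervals `[a_k, a_{k+1})` used by the partitioned QALY and
#' IPCW estimators. Events falling exactly on a boundary belong to the
#' interval that starts there.
#'
#' @param boundaries Strictly increasing numeric vector starting at 0.
#' @return An object of class `time_grid`.
#' @export
time_grid <- function(boundaries) {
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) < 2L || boundaries[1] != 0 || any(diff(boundaries) <= 0))
    .stopf("`boundaries` must start at 0 and increase strictly")
  structure(list(boundaries = boundaries, K = length(boundaries) - 1L),
            class = "time_grid")
}

#' Piecewise quality-of-life path Q(t)
#'
#' Returns the utility path as a function of time: constant at the first
#' score before the first measurement, linearly interpolated between
#' consecutive measurements, constant at the last score up to follow-up, and
#' zero afterwards.
#'
#' @param traj A [qol_trajectory()].
#' @return A vectorized function `Q(t)`.
#' @export
build_quality_path <- function(traj) {
  stopifnot(inherits(traj, "qol_trajectory"))
  tms <- traj$times; sc <- traj$scores; X <- traj$followup
  function(t) {
    if (length(tms) == 1L) {
      q <- rep(sc, length(t))
    } else {
      q <- stats::approx(tms, sc,
                         xout = pmin(pmax(t, tms[1]), tms[length(tms)]),
                         rule = 2)$y
    }
    q[t >= X] <- 0
    q
  }
}

#' Quality-adjusted time from a trajectory
#'
#' Integrates the piecewise-linear utility path exactly (trapezoid areas on
#' each linear segment) from 0 to follow-up, optionally split per interval of
#' a [time_grid()]. The total is `H(X)`, the quality-adjusted follow-up.
#'
#' @param traj A [qol_trajectory()].
#' @param grid Optional [time_grid()]; integration is truncated at its
#'   horizon and reported per interval.
#' @return List with `q` (per-interval integrals; one element when no grid is
#'   given) and `t_adj` (their sum).
#' @export
adjust_time <- function(traj, grid = NULL) {
  stopifnot(inherits(traj, "qol_trajectory"))
  X <- traj$followup
  horizon <- if (is.null(grid)) X else min(X, max(grid$boundaries))
  # knots of the piecewise-linear path, restricted to [0, horizon]
  knots <- sort(unique(c(0, traj$times, horizon,
                         if (!is.null(grid)) grid$boundaries)))
  knots <- knots[knots <= horizon]
  Q <- build_quality_path(traj)
  # evaluate strictly inside each segment to dodge the jump at X
  lo <- knots[-length(knots)]; hi <- knots[-1]
  midv <- (Q(lo + (hi - lo) * 1e-9) + Q(hi - (hi - lo) * 1e-9)) / 2
  seg <- midv * (hi - lo)
  if (is.null(grid)) {
    t_adj <- sum(seg)
    return(list(q = t_adj, t_adj = t_adj))
  }
  b <- grid$boundaries
  idx <- findInterval(lo, b, rightmost.closed = FALSE)
  q <- vapply(seq_len(grid$K), function(k) sum(seg[idx == k]), numeric(1))
  list(q = q, t_adj = sum(q))
}

#' Kaplan-Meier survival (or censoring-distribution) estimate
#'
#' Product-limit estimator wrapped around [survival::survfit()]. With
#' `flip = TRUE` the event indicator is reversed so that the returned step
#' function estimates the censoring distribution G (the "reverse
#' Kaplan-Meier" used for IPCW weights).
#'
#' @param time Follow-up times.
#' @param event 0/1 event indicators.
#' @param flip Estimate the censoring distribution instead of survival.
#' @return An object of class `km_fit`: a list with the fitted step function
#'   `fn` (right-continuous, `S(0) = 1`), the left-limit evaluator `fn_left`,
#'   and the step `time`/`surv` vectors.
#' @export
km_survival <- function(time, event, flip = FALSE) {
  if (length(time) == 0L) .stopf("`time` must be nonempty")
  if (any(time < 0)) .stopf("`time` must be nonnegative")
  ev <- if (flip) 1L - as.integer(event) else as.integer(event)
  fit <- survival::survfit(survival::Surv(time, ev) ~ 1)
  tt <- fit$time; ss <- fit$surv
  fn <- stats::stepfun(tt, c(1, ss), right = FALSE)
  fn_left <- function(t) {
    # S(t-): value just before t
    idx <- findInterval(t, tt, left.open = TRUE)
    c(1, ss)[idx + 1L]
  }
  structure(list(fn = fn, fn_left = fn_left, time = tt, surv = ss,
                 flip = flip), class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf("Kaplan-Meier %s estimate with %d step(s)\n",
              if (x$flip) "censoring-distribution" else "survival",
              length(x$time)))
  invisible(x)
}

#' Kaplan-Meier restricted mean and variance
#'
#' Moments of the distribution implied by the product-limit estimator,
#' restricted to the observed time range: `E[T] = t_(1) + int S(t) dt` and
#' `E[T^2]` via `int 2 t S(t) dt` over the step function. With no censoring
#' these equal the sample moments (population-variance divisor).
#'
#' @param time Follow-up times.
#' @param event 0/1 event indicators.
#' @return List with `mean` and `var`.
#' @export
km_moments <- function(time, event) {
  if (length(time) < 2L) .stopf("need at least two observations")
  fit <- survival::survfit(survival::Surv(time - min(time, 0), event) ~ 1)
  shift <- min(time, 0)  # guard for (rare) negative adjusted times
  tt <- fit$time + shift; ss <- fit$surv
  t0 <- tt[1]
  dt1 <- diff(tt)
  s_left <- ss[-length(ss)]
  mu <- t0 + sum(s_left * dt1)
  m2 <- t0^2 + sum(s_left * (tt[-1]^2 - tt[-length(tt)]^2))
  list(mean = mu, var = max(m2 - mu^2, 0))
}

#' Partitioned estimator of mean QALY
#'
#' Implements `mu_hat = sum_k S_hat(a_k) qbar_k` where `qbar_k` averages the
#' per-interval quality-adjusted times over patients at risk in interval k
#' (alive at `a_k` and not censored during `[a_k, a_{k+1})`), and `S_hat` is
#' the Kaplan-Meier survival evaluated as the left limit at `a_k` (so
#' `S_hat(0) = 1`). Intervals with nobody at risk contribute zero with a
#' warning.
#'
#' @param q Matrix (`n x K`) of per-interval quality-adjusted times.
#' @param followup Follow-up times `X_i`.
#' @param event 0/1 event indicators.
#' @param grid A [time_grid()] with `K` intervals.
#' @return The estimated mean QALY (nonnegative for nonnegative scores).
#' @export
qaly_mean_partitioned <- function(q, followup, event, grid) {
  stopifnot(inherits(grid, "time_grid"))
  q <- as.matrix(q)
  n <- nrow(q)
  if (ncol(q) != grid$K) .stopf("`q` must have one column per grid interval")
  if (length(followup) != n || length(event) != n)
    .stopf("`followup` and `event` must match `q` rows")
  km <- km_survival(followup, event)
  a <- grid$boundaries
  mu <- 0
  for (k in seq_len(grid$K)) {
    at_risk <- followup >= a[k] & (followup >= a[k + 1] | event == 1L)
    Yk <- sum(at_risk)
    if (Yk == 0L) {
      warning(sprintf("no patients at risk in interval %d; it contributes 0", k),
              call. = FALSE)
      next
    }
    Sk <- if (a[k] == 0) 1 else km$fn_left(a[k])
    mu <- mu + Sk * sum(q[at_risk, k]) / Yk
  }
  mu
}

#' IPCW regression of costs (or QALY) on covariates
#'
#' Inverse-probability-of-censoring-weighted least squares, solved per grid
#' interval and summed: coefficient `alpha_k` solves the weighted normal
#' equations with weights `delta*_ki / G_hat(X*_ki)` where
#' `X*_ki = min(X_i, a_{k+1})`, `delta*_ki` indicates the patient is not
#' censored before `X*_ki`, and `G_hat` is the reverse Kaplan-Meier estimate
#' of the censoring distribution. The returned estimate is
#' `alpha = sum_k alpha_k`. With no censoring and a single interval this is
#' the ordinary least-squares solution. Rows whose weight denominator is zero
#' (beyond the last point where `G_hat > 0`) are excluded with a message.
#'
#' @param response Per-interval responses: an `n x K` matrix (or a vector for
#'   `K = 1` cumulative responses).
#' @param followup Follow-up times `X_i`.
#' @param event 0/1 event indicators.
#' @param grid A [time_grid()].
#' @param Z Design matrix (`n x p`); defaults to an intercept-only column.
#' @return List with `coef` (the summed coefficient vector), `per_interval`
#'   (a `p x K` matrix) and `n_dropped`.
#' @export
ipcw_regression <- function(response, followup, event, grid, Z = NULL) {
  stopifnot(inherits(grid, "time_grid"))
  response <- as.matrix(response)
  n <- nrow(response)
  if (ncol(response) != grid$K)
    .stopf("`response` must have one column per grid interval")
  if (is.null(Z)) Z <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  Z <- as.matrix(Z)
  a <- grid$boundaries
  G <- km_survival(followup, event, flip = TRUE)
  per <- matrix(NA_real_, ncol(Z), grid$K)
  rownames(per) <- colnames(Z)
  dropped <- 0L
  for (k in seq_len(grid$K)) {
    Xstar <- pmin(followup, a[k + 1])
    dstar <- as.integer(event == 1L | followup >= a[k + 1])
    Gx <- G$fn_left(Xstar)  # G(X*-): probability of remaining uncensored
    w <- numeric(n)
    usable <- Gx > 0
    dropped <- dropped + sum(!usable & dstar == 1L)
    w[usable] <- dstar[usable] / Gx[usable]
    ZtWZ <- crossprod(Z, Z * w)
    if (qr(ZtWZ)$rank < ncol(Z)) {
      .stopf("weighted design is singular in interval %d (columns: %s)",
             k, paste(colnames(Z), collapse = ", "))
    }
    per[, k] <- solve(ZtWZ, crossprod(Z, response[, k] * w))
  }
  if (dropped > 0L)
    message(sprintf("ipcw_regression: %d row-interval(s) beyond the support of G were dropped",
                    dropped))
  list(coef = rowSums(per), per_interval = per, n_dropped = dropped)
}

#' Buckley-James residual variance
#'
#' `sigma2_hat = 1/(sum(delta) - 2) * sum_i delta_i (e_i - ebar)^2` where
#' `ebar` is the event-weighted mean residual; censored residuals drop out.
#'
#' @param residuals Regression residuals.
#' @param events 0/1 event indicators.
#' @return The variance estimate (nonnegative).
#' @export
bj_variance <- function(residuals, events) {
  events <- as.integer(events)
  nd <- sum(events)
  if (nd <= 2L) .stopf("Buckley-James variance needs more than 2 events")
  e <- residuals[events == 1L]
  sum((e - mean(e))^2) / (nd - 2)
}

# ---- Kendall's tau --------------------------------------------------------

#' Sample Kendall's tau for fully observed pairs
#'
#' The sample concordance statistic: over all `n(n-1)/2` pairs, the number of
#' concordant minus discordant pairs divided by the number of pairs whose
#' ordering is defined in both coordinates (tied pairs contribute zero and
#' are removed from the denominator; with continuous data this equals the
#' classical `choose(n, 2)` version).
#'
#' @param x,y Numeric vectors of equal length `n >= 2`.
#' @return Kendall's tau in \[-1, 1\].
#' @export
kendall_tau_complete <- function(x, y) {
  n <- length(x)
  if (n < 2L || length(y) != n) .stopf("need two vectors of equal length >= 2")
  out <- .tau_complete_cpp(as.numeric(x), as.numeric(y))
  if (is.na(out)) .stopf("all pairs are tied")
  out
}

#' Censoring-robust Kendall's tau (renormalized Oakes estimator)
#'
#' For cost-QALY pairs where only the QALY coordinate is right-censored:
#' a pair is usable when the ordering of the two adjusted times is certain
#' under censoring - both observed, or the smaller observed value is an event
#' while the larger is censored above it. Because short-lived pairs are
#' over-represented among usable pairs, each usable pair is reweighted by the
#' inverse of its estimated orderability probability
#' `G_hat(t_min)^2` - the reverse Kaplan-Meier censoring survival at the
#' pair's smaller observed time (the renormalization that makes the Oakes
#' statistic consistent). The estimator is the weighted concordant minus
#' discordant sum over the weighted count of usable pairs; it reduces exactly
#' to [kendall_tau_complete()] when nothing is censored. Pairs beyond the
#' support of `G_hat` (weight denominator 0) are excluded.
#'
#' @param cost Fully observed costs.
#' @param t_adj Observed (possibly censored) quality-adjusted times.
#' @param event 0/1 event indicators for `t_adj` (1 = observed).
#' @return Kendall's tau in \[-1, 1\].
#' @export
kendall_tau_censored <- function(cost, t_adj, event) {
  n <- length(cost)
  if (n < 2L || length(t_adj) != n || length(event) != n)
    .stopf("need three vectors of equal length >= 2")
  d <- as.logical(event)
  if (all(d)) return(kendall_tau_complete(cost, t_adj))
  # per-subject weight: usable as the smaller member of a pair iff its time is
  # an event inside the support of G; weight 1/G(t)^2 then corrects for the
  # orderability probability
  G <- km_survival(t_adj, as.integer(d), flip = TRUE)
  g <- G$fn(t_adj)
  wsub <- ifelse(d & g > 0, 1 / pmax(g, 1e-300)^2, 0)
  out <- .tau_censored_cpp(as.numeric(cost), as.numeric(t_adj), wsub)
  if (is.na(out)) .stopf("no usable pairs under this censoring pattern")
  out
}
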