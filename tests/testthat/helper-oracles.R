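# Independent brute-force oracles used across the suite.

# plain pairwise enumeration of Kendall's tau (ties dropped from both sums)
oracle_tau_complete <- function(x, y) {
  n <- length(x)
  num <- 0; den <- 0
  for (r in seq_len(n - 1)) {
    for (s in (r + 1):n) {
      dx <- x[r] - x[s]; dy <- y[r] - y[s]
      if (dx == 0 || dy == 0) next
      num <- num + sign(dx) * sign(dy)
      den <- den + 1
    }
  }
  num / den
}

# pairwise enumeration of the renormalized censored statistic: a pair counts
# when the smaller observed time is an event, weighted by 1/G(t_small)^2 with
# G the reverse Kaplan-Meier of censoring
oracle_tau_censored <- function(cost, t_adj, event) {
  n <- length(cost)
  G <- survival::survfit(survival::Surv(t_adj, 1 - event) ~ 1)
  g_at <- function(t) {
    idx <- findInterval(t, G$time)
    c(1, G$surv)[idx + 1L]
  }
  num <- 0; den <- 0
  for (r in seq_len(n - 1)) {
    for (s in (r + 1):n) {
      dx <- cost[r] - cost[s]; dy <- t_adj[r] - t_adj[s]
      if (dx == 0 || dy == 0) next
      small <- if (dy < 0) r else s
      if (event[small] != 1) next
      g <- g_at(t_adj[small])
      if (g <= 0) next
      w <- 1 / g^2
      num <- num + sign(dx) * sign(dy) * w
      den <- den + w
    }
  }
  if (den == 0) return(NA_real_)
  num / den
}

# small censored bivariate sample for reuse in tests
sim_small <- function(n, seed, rate = 0.2, tau = 0.6, family = "clayton") {
  set.seed(seed)
  uv <- sample_copula(copula_spec(family, tau = tau), n)
  t_adj <- qnorm(uv[, 1], 4, 0.75)
  cost <- qnorm(uv[, 2], 1500, 400)
  eta <- if (rate > 0) rexp(n, rate) else rep(Inf, n)
  list(cost = cost, time = pmin(t_adj, eta),
       event = as.integer(t_adj <= eta), t_latent = t_adj, eta = eta)
}
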