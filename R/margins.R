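#' Moment-parameterized marginal distributions for costs and QALY
#'
#' A `margin_spec` is a parametric margin (normal, gamma or lognormal)
#' parameterized by its mean `mu` and variance `sigma2`. The natural
#' parameters are derived from the moment maps and stored alongside:
#' `meanlog`/`sdlog2` for the lognormal (mean and variance of the log values)
#' and `shape`/`scale` for the gamma. Gamma and lognormal margins require
#' `mu > 0`.
#'
#' A normal margin intended for quality-adjusted survival may put some mass
#' below zero; when more than 1% of the fitted distribution is negative a
#' warning is emitted (the fit is kept untruncated, the usual practice when
#' the QALY mean is large relative to its spread).
#'
#' @param family `"normal"`, `"gamma"` or `"lognormal"`.
#' @param mu Mean (monetary units or QALY); positive for gamma/lognormal.
#' @param sigma2 Variance, positive.
#' @return An object of class `margin_spec`.
#' @examples
#' margin_spec("gamma", mu = 1500, sigma2 = 12 * 125^2)  # shape 12, scale 125
#' @export
margin_spec <- function(family, mu, sigma2) {
  family <- match.arg(family, c("normal", "gamma", "lognormal"))
  if (!is.finite(mu) || !is.finite(sigma2) || sigma2 <= 0)
    .stopf("`mu` must be finite and `sigma2` positive")
  spec <- list(family = family, mu = mu, sigma2 = sigma2)
  if (family == "lognormal") {
    p <- lognormal_from_moments(mu, sigma2)
    spec$meanlog <- p[["meanlog"]]
    spec$sdlog2 <- p[["sdlog2"]]
  } else if (family == "gamma") {
    p <- gamma_from_moments(mu, sigma2)
    spec$shape <- p[["shape"]]
    spec$scale <- p[["scale"]]
  } else if (stats::pnorm(0, mu, sqrt(sigma2)) > 0.01) {
    warning(sprintf(
      "normal margin places %.1f%% of its mass below 0; interpret with care",
      100 * stats::pnorm(0, mu, sqrt(sigma2))), call. = FALSE)
  }
  structure(spec, class = "margin_spec")
}

#' @export
print.margin_spec <- function(x, ...) {
  extra <- switch(x$family,
    lognormal = sprintf(" (meanlog %.4f, varlog %.4f)", x$meanlog, x$sdlog2),
    gamma = sprintf(" (shape %.4f, scale %.4f)", x$shape, x$scale),
    "")
  cat(sprintf("%s margin: mean %.4g, variance %.4g%s\n",
              x$family, x$mu, x$sigma2, extra))
  invisible(x)
}

#' Lognormal natural parameters from mean and variance
#'
#' Implements the exact moment map `meanlog = 2 log(mu) - log(sigma2 + mu^2)/2`
#' and `varlog = log(sigma2 + mu^2) - 2 log(mu)`, so that a lognormal with
#' these log-scale parameters has mean `mu` and variance `sigma2`.
#'
#' @param mu,sigma2 Target mean and variance, both positive.
#' @return Named vector `c(meanlog, sdlog2)` (`sdlog2` is the log-scale
#'   variance).
#' @export
lognormal_from_moments <- function(mu, sigma2) {
  if (!is.finite(mu) || mu <= 0 || !is.finite(sigma2) || sigma2 <= 0)
    .stopf("lognormal moments require mu > 0 and sigma2 > 0")
  c(meanlog = 2 * log(mu) - 0.5 * log(sigma2 + mu^2),
    sdlog2 = log(sigma2 + mu^2) - 2 * log(mu))
}

#' Gamma shape and scale from mean and variance
#'
#' `shape = mu^2 / sigma2`, `scale = sigma2 / mu`, so the gamma has mean `mu`
#' and variance `sigma2`.
#'
#' @inheritParams lognormal_from_moments
#' @return Named vector `c(shape, scale)`.
#' @export
gamma_from_moments <- function(mu, sigma2) {
  if (!is.finite(mu) || mu <= 0 || !is.finite(sigma2) || sigma2 <= 0)
    .stopf("gamma moments require mu > 0 and sigma2 > 0")
  c(shape = mu^2 / sigma2, scale = sigma2 / mu)
}

#' Build a lognormal margin directly from log-scale parameters
#'
#' Convenience constructor used by the simulation harness, where generating
#' parameters are stated on the log scale.
#'
#' @param meanlog Mean of the log values.
#' @param sdlog Standard deviation of the log values.
#' @return A `margin_spec` whose `mu`/`sigma2` are the implied moments.
#' @export
lognormal_margin <- function(meanlog, sdlog) {
  mu <- exp(meanlog + sdlog^2 / 2)
  sigma2 <- expm1(sdlog^2) * exp(2 * meanlog + sdlog^2)
  margin_spec("lognormal", mu, sigma2)
}

# density / cdf / quantile dispatch ----------------------------------------

#' @rdname margin_spec
#' @param spec A `margin_spec`.
#' @param x,p Evaluation points / probabilities.
#' @export
margin_pdf <- function(spec, x) {
  stopifnot(inherits(spec, "margin_spec"))
  switch(spec$family,
    normal = stats::dnorm(x, spec$mu, sqrt(spec$sigma2)),
    gamma = stats::dgamma(x, shape = spec$shape, scale = spec$scale),
    lognormal = stats::dlnorm(x, spec$meanlog, sqrt(spec$sdlog2)))
}

#' @rdname margin_spec
#' @export
margin_cdf <- function(spec, x) {
  stopifnot(inherits(spec, "margin_spec"))
  switch(spec$family,
    normal = stats::pnorm(x, spec$mu, sqrt(spec$sigma2)),
    gamma = stats::pgamma(x, shape = spec$shape, scale = spec$scale),
    lognormal = stats::plnorm(x, spec$meanlog, sqrt(spec$sdlog2)))
}

#' @rdname margin_spec
#' @export
margin_quantile <- function(spec, p) {
  stopifnot(inherits(spec, "margin_spec"))
  switch(spec$family,
    normal = stats::qnorm(p, spec$mu, sqrt(spec$sigma2)),
    gamma = stats::qgamma(p, shape = spec$shape, scale = spec$scale),
    lognormal = stats::qlnorm(p, spec$meanlog, sqrt(spec$sdlog2)))
}

# ---- deviance and family selection ---------------------------------------

#' Deviance of a sample under a fitted margin
#'
#' Minus twice the log-likelihood. Censored entries (`event == 0`) contribute
#' the log survival probability at the censoring point instead of the log
#' density, consistent with the censored likelihood used for copula
#' selection. A gamma or lognormal margin evaluated at a nonpositive observed
#' value contributes `-Inf` log-likelihood; such observations are reported
#' via a warning, never silently dropped.
#'
#' @param x Observed values.
#' @param spec A [margin_spec()].
#' @param event 0/1 event indicators (1 = observed); defaults to all
#'   observed.
#' @return The deviance `-2 * loglik` (may be `Inf`).
#' @export
margin_deviance <- function(x, spec, event = NULL) {
  stopifnot(inherits(spec, "margin_spec"))
  if (length(x) == 0L) .stopf("`x` must be nonempty")
  if (is.null(event)) event <- rep(1L, length(x))
  event <- as.integer(event)
  if (length(event) != length(x)) .stopf("`event` must match `x` in length")
  ll <- numeric(length(x))
  obs <- event == 1L
  ll[obs] <- log(margin_pdf(spec, x[obs]))
  if (any(!obs)) {
    # survival term: S(x) = 1 - F(x)
    ll[!obs] <- log1p(-margin_cdf(spec, x[!obs]))
  }
  if (spec$family != "normal" && any(bad <- obs & x <= 0)) {
    warning(sprintf("%d nonpositive observation(s) have zero %s density",
                    sum(bad), spec$family), call. = FALSE)
    ll[bad] <- -Inf
  }
  -2 * sum(ll)
}

#' Select a marginal family by the deviance criterion
#'
#' Each candidate family is parameterized by moment matching to the supplied
#' (censoring-adjusted) mean and variance, its deviance `-2 loglik` is
#' evaluated on the sample, and the family with the smallest deviance is
#' returned. When `mu`/`sigma2` are not given they are estimated from the
#' data: the plain sample moments if nothing is censored, otherwise the
#' Kaplan-Meier restricted moments from [km_moments()].
#'
#' @param x Observed values.
#' @param event Optional 0/1 event indicators (default: all observed).
#' @param families Candidate families, a subset of
#'   `c("normal", "gamma", "lognormal")`.
#' @param mu,sigma2 Optional moment estimates to use for all candidates.
#' @return A list with the winning `spec`, the named `deviance` vector for
#'   all candidates, and the moments used.
#' @export
select_margin <- function(x, event = NULL,
                          families = c("normal", "gamma", "lognormal"),
                          mu = NULL, sigma2 = NULL) {
  if (length(families) == 0L) .stopf("at least one candidate family is required")
  families <- match.arg(families, c("normal", "gamma", "lognormal"),
                        several.ok = TRUE)
  if (is.null(event)) event <- rep(1L, length(x))
  if (is.null(mu) || is.null(sigma2)) {
    if (all(event == 1L)) {
      mu <- mean(x)
      sigma2 <- stats::var(x)
    } else {
      mo <- km_moments(x, event)
      mu <- mo$mean
      sigma2 <- mo$var
    }
  }
  dev <- vapply(families, function(f) {
    spec <- suppressWarnings(margin_spec(f, mu, sigma2))
    suppressWarnings(margin_deviance(x, spec, event))
  }, numeric(1))
  best <- families[which.min(dev)]
  list(spec = suppressWarnings(margin_spec(best, mu, sigma2)),
       family = best, deviance = dev, mu = mu, sigma2 = sigma2)
}
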