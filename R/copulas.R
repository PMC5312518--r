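#' Bivariate parametric copula families
#'
#' A `copula_spec` describes one of six exchangeable bivariate copula families
#' together with its dependence parameter `theta`. Dependence can be supplied
#' either directly as `theta` or through Kendall's tau, which every family maps
#' one-to-one onto its parameter (the route the estimation pipeline takes: tau
#' is estimated once, then inverted per candidate family).
#'
#' Parameter domains: Gaussian and Student-t have `theta` in (-1, 1) (the
#' correlation of the underlying elliptical distribution); Clayton has
#' `theta >= -1`, `theta != 0`; Gumbel and Joe have `theta >= 1`; Frank has any
#' nonzero real `theta`.
#'
#' @param family One of `"gaussian"`, `"student"`, `"clayton"`, `"gumbel"`,
#'   `"frank"`, `"joe"`.
#' @param theta Dependence parameter. Exactly one of `theta`, `tau` must be
#'   given.
#' @param tau Kendall's tau; converted through [tau_to_theta()].
#' @param df Degrees of freedom for the Student-t family (default 4; ignored
#'   otherwise).
#' @return An object of class `copula_spec` with fields `family`, `theta`,
#'   `df` (Student only) and the implied `tau`.
#' @examples
#' copula_spec("clayton", tau = 0.6)   # theta = 3
#' copula_spec("gaussian", theta = 0.809)
#' @export
copula_spec <- function(family, theta = NULL, tau = NULL, df = 4) {
  family <- match.arg(family, .copula_families)
  if (is.null(theta) && is.null(tau))
    .stopf("supply either `theta` or `tau` for the %s copula", family)
  if (!is.null(theta) && !is.null(tau))
    .stopf("supply only one of `theta` and `tau`")
  if (is.null(theta)) theta <- tau_to_theta(family, tau, df = df)
  .check_theta(family, theta)
  structure(
    list(family = family, theta = theta,
         df = if (family == "student") df else NULL,
         tau = theta_to_tau(family, theta, df = df)),
    class = "copula_spec")
}

.copula_families <- c("gaussian", "student", "clayton", "gumbel", "frank", "joe")

.check_theta <- function(family, theta) {
  if (length(theta) != 1L || !is.finite(theta))
    .stopf("`theta` must be a single finite number")
  ok <- switch(family,
    gaussian = ,
    student  = theta > -1 && theta < 1,
    clayton  = theta >= -1 && theta != 0,
    gumbel   = ,
    joe      = theta >= 1,
    frank    = theta != 0)
  if (!ok) .stopf("theta = %g outside the %s copula domain", theta, family)
  invisible(TRUE)
}

#' @export
print.copula_spec <- function(x, ...) {
  cat(sprintf("%s copula: theta = %.6g (Kendall's tau = %.4f)%s\n",
              x$family, x$theta, x$tau,
              if (!is.null(x$df)) sprintf(", df = %g", x$df) else ""))
  invisible(x)
}

# ---- Kendall's tau <-> theta --------------------------------------------

#' Map a copula parameter to Kendall's tau
#'
#' Closed forms are used where they exist: `theta/(theta+2)` for Clayton,
#' `1 - 1/theta` for Gumbel, `(2/pi) asin(theta)` for the elliptical families.
#' Frank uses the Debye-function relation and Joe the series
#' `1 - 4 * sum_k 1 / (k (theta k + 2)(theta (k-1) + 2))`, truncated once
#' terms fall below 1e-14.
#'
#' @param family Copula family name.
#' @param theta Dependence parameter, inside the family's domain.
#' @param df Degrees of freedom (Student only; tau does not depend on it).
#' @return Kendall's tau in \[-1, 1\].
#' @export
theta_to_tau <- function(family, theta, df = 4) {
  family <- match.arg(family, .copula_families)
  .check_theta(family, theta)
  switch(family,
    gaussian = ,
    student  = 2 / pi * asin(theta),
    clayton  = theta / (theta + 2),
    gumbel   = 1 - 1 / theta,
    frank    = .frank_tau(theta),
    joe      = .joe_tau(theta))
}

.frank_debye1 <- function(theta) {
  # D1(theta) = (1/theta) * int_0^theta t / (e^t - 1) dt, theta > 0
  stats::integrate(function(t) ifelse(t == 0, 1, t / expm1(t)),
                   0, theta, rel.tol = 1e-12)$value / theta
}

.frank_tau <- function(theta) {
  s <- sign(theta)
  th <- abs(theta)
  s * (1 + 4 * (.frank_debye1(th) - 1) / th)
}

.joe_tau <- function(theta) {
  if (theta == 1) return(0)
  total <- 0
  k0 <- 1
  repeat {
    k <- k0:(k0 + 49999)
    term <- 1 / (k * (theta * k + 2) * (theta * (k - 1) + 2))
    total <- total + sum(term)
    if (term[length(term)] < 1e-14 || k0 > 5e6) break
    k0 <- k0 + 50000
  }
  1 - 4 * total
}

#' Invert Kendall's tau to the copula parameter
#'
#' Closed-form inversions are used for Clayton (`2 tau / (1 - tau)`), Gumbel
#' (`1 / (1 - tau)`), and the elliptical families (`sin(pi tau / 2)`). Frank
#' and Joe are inverted numerically by bracketed root finding on
#' [theta_to_tau()] to a tolerance of 1e-10 on theta (1e-8 or better on tau).
#'
#' @param family Copula family name.
#' @param tau Kendall's tau inside the family's attainable range (positive for
#'   Clayton's positive branch, Gumbel and Joe).
#' @param df Degrees of freedom (Student only; unused in the map).
#' @return The family parameter theta.
#' @export
tau_to_theta <- function(family, tau, df = 4) {
  family <- match.arg(family, .copula_families)
  if (length(tau) != 1L || !is.finite(tau) || tau <= -1 || tau >= 1)
    .stopf("`tau` must be a single number in (-1, 1)")
  switch(family,
    gaussian = ,
    student  = sin(pi * tau / 2),
    clayton  = {
      if (tau <= 0) .stopf("Clayton's positive branch requires tau > 0 (got %g)", tau)
      2 * tau / (1 - tau)
    },
    gumbel = {
      if (tau < 0) .stopf("the Gumbel copula cannot attain tau < 0 (got %g)", tau)
      1 / (1 - tau)
    },
    frank = {
      if (tau == 0) return(0)  # independence limit
      s <- sign(tau); at <- abs(tau)
      up <- 1
      while (.frank_tau(up) < at) up <- up * 2
      s * stats::uniroot(function(th) .frank_tau(th) - at, c(1e-9, up),
                         tol = 1e-12)$root
    },
    joe = {
      if (tau < 0) .stopf("the Joe copula cannot attain tau < 0 (got %g)", tau)
      if (tau == 0) return(1)
      up <- 2
      while (.joe_tau(up) < tau) up <- up * 2
      stats::uniroot(function(th) .joe_tau(th) - tau, c(1 + 1e-12, up),
                     tol = 1e-12)$root
    })
}

# ---- CDF ------------------------------------------------------------------

#' Copula cumulative distribution function
#'
#' Archimedean families use their closed forms. The Gaussian and Student-t
#' CDFs are computed by Gauss-Legendre quadrature of the exact conditional
#' representation `C(u, v) = int_{-inf}^{q(u)} f(z) F_cond(q(v) | z) dz` on
#' the elliptical scale (absolute accuracy around 1e-9 for the Gaussian,
#' 1e-7 for the t).
#'
#' @param spec A [copula_spec()].
#' @param u,v Numeric vectors in \[0, 1\] (recycled to a common length).
#' @return `C(u, v)`, in \[0, 1\], with the uniform-margin boundary behaviour
#'   `C(u, 1) = u`, `C(1, v) = v`, `C(u, 0) = C(0, v) = 0`.
#' @export
copula_cdf <- function(spec, u, v) {
  stopifnot(inherits(spec, "copula_spec"))
  if (!.is_prob(u) || !.is_prob(v)) .stopf("`u` and `v` must lie in [0, 1]")
  n <- max(length(u), length(v))
  u <- rep_len(u, n); v <- rep_len(v, n)
  out <- numeric(n)
  edge0 <- u == 0 | v == 0
  eu1 <- !edge0 & u == 1
  ev1 <- !edge0 & v == 1 & !eu1
  out[eu1] <- v[eu1]
  out[ev1] <- u[ev1]
  inner <- !(edge0 | eu1 | ev1)
  if (any(inner)) {
    ui <- u[inner]; vi <- v[inner]; th <- spec$theta
    out[inner] <- switch(spec$family,
      gaussian = .biv_norm_cdf(ui, vi, th),
      student  = .biv_t_cdf(ui, vi, th, spec$df),
      clayton  = pmax(ui^(-th) + vi^(-th) - 1, 0)^(-1 / th),
      gumbel   = exp(-((-log(ui))^th + (-log(vi))^th)^(1 / th)),
      frank    = -log1p((expm1(-th * ui) * expm1(-th * vi)) / expm1(-th)) / th,
      joe      = {
        x <- (1 - ui)^th; y <- (1 - vi)^th
        1 - (x + y - x * y)^(1 / th)
      })
  }
  pmin(pmax(out, 0), 1)
}

# vectorized bivariate normal CDF via the conditional decomposition
.biv_norm_cdf <- function(u, v, rho, nodes = 64L) {
  x <- stats::qnorm(u)
  yv <- stats::qnorm(v)
  s <- sqrt(1 - rho^2)
  a <- pmin(x, -8.5)  # below here the mass is < 1e-17
  rule <- .gl_rule(nodes)
  half <- (x - a) / 2
  mid <- (x + a) / 2
  Z <- outer(half, rule$x) + mid               # n x nodes
  G <- stats::dnorm(Z) * stats::pnorm((yv - rho * Z) / s)
  as.vector((G %*% rule$w) * half)
}

# vectorized bivariate t CDF: conditional t_{df+1} representation, integrated
# piecewise in z with an analytic-limit tail correction below z_lo
.biv_t_cdf <- function(u, v, rho, df, nodes = 48L) {
  x <- stats::qt(u, df)
  yv <- stats::qt(v, df)
  s2 <- 1 - rho^2
  cond <- function(z, y) stats::pt((y - rho * z) * sqrt((df + 1) / ((df + z^2) * s2)), df + 1)
  z_lo <- stats::qt(1e-10, df)
  rule <- .gl_rule(nodes)
  breaks <- c(z_lo, stats::qt(c(1e-6, 1e-3), df), -6, 0, 6)
  n <- length(x)
  out <- stats::pt(z_lo, df) * cond(z_lo, yv)  # tail: conditional ~ constant
  lo <- rep(z_lo, n)
  for (b in c(breaks[-1], Inf)) {
    hi <- pmin(x, if (is.finite(b)) b else x)
    live <- hi > lo
    if (any(live)) {
      half <- (hi[live] - lo[live]) / 2
      mid <- (hi[live] + lo[live]) / 2
      Z <- outer(half, rule$x) + mid
      G <- stats::dt(Z, df) * cond(Z, yv[live])
      out[live] <- out[live] + as.vector((G %*% rule$w) * half)
    }
    lo <- pmax(lo, hi)
  }
  out
}

# ---- density --------------------------------------------------------------

#' Copula density
#'
#' Closed-form densities for all six families. Values exactly on the boundary
#' of the unit square are evaluated in the limit from inside; where the
#' density diverges (e.g. the Clayton lower corner) the result is `Inf`,
#' never `NaN`.
#'
#' @inheritParams copula_cdf
#' @return The density `c(u, v) >= 0`.
#' @export
copula_pdf <- function(spec, u, v) {
  stopifnot(inherits(spec, "copula_spec"))
  if (!.is_prob(u) || !.is_prob(v)) .stopf("`u` and `v` must lie in [0, 1]")
  n <- max(length(u), length(v))
  u <- .clamp01(rep_len(u, n)); v <- .clamp01(rep_len(v, n))
  th <- spec$theta
  switch(spec$family,
    gaussian = {
      x <- stats::qnorm(u); y <- stats::qnorm(v); s2 <- 1 - th^2
      exp(-(th^2 * (x^2 + y^2) - 2 * th * x * y) / (2 * s2)) / sqrt(s2)
    },
    student = {
      df <- spec$df
      x <- stats::qt(u, df); y <- stats::qt(v, df); s2 <- 1 - th^2
      lc <- lgamma((df + 2) / 2) + lgamma(df / 2) - 2 * lgamma((df + 1) / 2) -
        0.5 * log(s2) -
        (df + 2) / 2 * log1p((x^2 + y^2 - 2 * th * x * y) / (df * s2)) +
        (df + 1) / 2 * (log1p(x^2 / df) + log1p(y^2 / df))
      exp(lc)
    },
    clayton = {
      if (th > 0) {
        exp(log1p(th) - (th + 1) * (log(u) + log(v)) -
              (2 + 1 / th) * log(u^(-th) + v^(-th) - 1))
      } else {
        s <- pmax(u^(-th) + v^(-th) - 1, 0)
        ifelse(s > 0,
               (1 + th) * (u * v)^(-th - 1) * s^(-(2 + 1 / th)), 0)
      }
    },
    gumbel = {
      x <- -log(u); y <- -log(v)
      S <- x^th + y^th
      A <- S^(1 / th)
      exp(-A) / (u * v) * (x * y)^(th - 1) * S^(1 / th - 2) * (A + th - 1)
    },
    frank = {
      E <- expm1(-th)
      num <- th * (-E) * exp(-th * (u + v))
      den <- (-E - expm1(-th * u) * expm1(-th * v))^2
      num / den
    },
    joe = {
      x <- (1 - u)^th; y <- (1 - v)^th
      S <- x + y - x * y
      S^(1 / th - 2) * (1 - u)^(th - 1) * (1 - v)^(th - 1) * (th - 1 + S)
    })
}

# ---- sampling -------------------------------------------------------------

#' Draw from a bivariate copula
#'
#' Elliptical families use the correlation transform (a scale-mixture of
#' normals for the Student-t). Clayton and Frank invert their closed-form
#' conditional distributions; Gumbel uses its positive-stable frailty
#' (Marshall-Olkin construction); Joe inverts its conditional distribution by
#' vectorized bisection. Margins are uniform on (0, 1) by construction.
#'
#' @param spec A [copula_spec()].
#' @param n Number of pairs to draw.
#' @param seed Optional integer seed (`set.seed` is called when supplied).
#' @return An `n x 2` matrix of (u, v) pairs in (0, 1).
#' @export
sample_copula <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "copula_spec"))
  if (!is.numeric(n) || length(n) != 1L || n < 1) .stopf("`n` must be >= 1")
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  th <- spec$theta
  uv <- switch(spec$family,
    gaussian = {
      z1 <- stats::rnorm(n); z2 <- th * z1 + sqrt(1 - th^2) * stats::rnorm(n)
      cbind(stats::pnorm(z1), stats::pnorm(z2))
    },
    student = {
      df <- spec$df
      z1 <- stats::rnorm(n); z2 <- th * z1 + sqrt(1 - th^2) * stats::rnorm(n)
      w <- sqrt(stats::rchisq(n, df) / df)
      cbind(stats::pt(z1 / w, df), stats::pt(z2 / w, df))
    },
    clayton = {
      u <- stats::runif(n); w <- stats::runif(n)
      if (th > 0) {
        v <- (u^(-th) * (w^(-th / (1 + th)) - 1) + 1)^(-1 / th)
        cbind(u, v)
      } else {
        cbind(u, .cond_bisect(spec, u, w))
      }
    },
    frank = {
      u <- stats::runif(n); w <- stats::runif(n)
      E <- w * expm1(-th) / (exp(-th * u) * (1 - w) + w)
      cbind(u, -log1p(E) / th)
    },
    gumbel = {
      if (th == 1) {
        cbind(stats::runif(n), stats::runif(n))
      } else {
        alpha <- 1 / th
        V <- .rpostable(n, alpha)
        e1 <- stats::rexp(n); e2 <- stats::rexp(n)
        cbind(exp(-(e1 / V)^alpha), exp(-(e2 / V)^alpha))
      }
    },
    joe = {
      u <- stats::runif(n); w <- stats::runif(n)
      cbind(u, .cond_bisect(spec, u, w))
    })
  uv[] <- .clamp01(uv)
  dimnames(uv) <- list(NULL, c("u", "v"))
  uv
}

# positive stable S(alpha, 1) via Chambers-Mallows-Stuck
.rpostable <- function(n, alpha) {
  U <- stats::runif(n, 0, pi)
  E <- stats::rexp(n)
  (sin(alpha * U) / sin(U)^(1 / alpha)) *
    (sin((1 - alpha) * U) / E)^((1 - alpha) / alpha)
}

# conditional CDF h(v | u) = dC/du, used by the bisection sampler
.cond_cdf <- function(spec, u, v) {
  th <- spec$theta
  switch(spec$family,
    clayton = u^(-th - 1) * pmax(u^(-th) + v^(-th) - 1, 0)^(-1 / th - 1),
    joe = {
      x <- (1 - u)^th; y <- (1 - v)^th
      (x + y - x * y)^(1 / th - 1) * (1 - y) * (1 - u)^(th - 1)
    },
    .stopf("no conditional form registered for the %s copula", spec$family))
}

.cond_bisect <- function(spec, u, w, iter = 60L) {
  lo <- rep(1e-14, length(u)); hi <- rep(1 - 1e-14, length(u))
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    below <- .cond_cdf(spec, u, mid) < w
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  (lo + hi) / 2
}
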