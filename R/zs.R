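#' Log Bayes factor of a g-prior model against the null
#'
#' For a Gaussian linear model with p_gamma centered predictors under
#' Zellner's g-prior on the coefficients and reference priors on
#' intercept and scale, the Bayes factor against the intercept-only null
#' has the closed form
#' \deqn{\frac{n-1-p_\gamma}{2}\log(1+g)-\frac{n-1}{2}\log\{1+g(1-R^2)\}.}
#'
#' @param n number of rows.
#' @param p_gamma number of included predictors (0 gives exactly 0).
#' @param r_squared coefficient of determination of the model, in `[0, 1)`.
#' @param g prior scale, > 0.
#' @return log Bayes factor versus the null model (dimensionless).
#' @export
log_bf_given_g <- function(n, p_gamma, r_squared, g) {
  stopifnot(g > 0, n > p_gamma + 1, r_squared >= 0)
  if (r_squared >= 1) stop("saturated fit (R^2 = 1): marginal likelihood diverges",
                           call. = FALSE)
  if (p_gamma == 0) return(0)
  ((n - 1 - p_gamma) / 2) * log1p(g) -
    ((n - 1) / 2) * log1p(g * (1 - r_squared))
}

# log density of the Zellner-Siow mixing distribution
# g ~ Inverse-Gamma(1/2, n*alpha/2), i.e. the Cauchy prior on coefficients
zs_log_prior <- function(g, n, alpha) {
  s <- n * alpha / 2
  0.5 * log(s) - lgamma(0.5) - 1.5 * log(g) - s / g
}

# log integrand on the t = log(g) scale (prior x BF x Jacobian);
# vectorized and safe at the tails where exp(t) under/overflows
zs_log_integrand_t <- function(t, n, p_gamma, r_squared, alpha) {
  g <- exp(t)
  s <- n * alpha / 2
  bf <- ((n - 1 - p_gamma) / 2) * log1p(g) -
    ((n - 1) / 2) * log1p(g * (1 - r_squared))
  lp <- 0.5 * log(s) - lgamma(0.5) - 1.5 * t - s * exp(-t)
  out <- bf + lp + t
  out[!is.finite(out)] <- -Inf
  out
}

# derivatives (orders 1-4) of the log integrand in t, all analytic;
# the log integrand is a*log(1+g) - b*log(1+c*g) - t/2 - s/g + const
zs_dlogf <- function(t, n, p_gamma, r_squared, alpha) {
  g <- exp(unname(t))
  a <- (n - 1 - p_gamma) / 2
  b <- (n - 1) / 2
  cc <- 1 - r_squared
  s <- n * alpha / 2
  sig <- g / (1 + g)
  sic <- cc * g / (1 + cc * g)
  se <- s / g
  d1 <- a * sig - b * sic - 0.5 + se
  d2 <- a * sig * (1 - sig) - b * sic * (1 - sic) - se
  d3 <- a * sig * (1 - sig) * (1 - 2 * sig) -
    b * sic * (1 - sic) * (1 - 2 * sic) + se
  d4 <- a * sig * (1 - sig) * (1 - 6 * sig + 6 * sig^2) -
    b * sic * (1 - sic) * (1 - 6 * sic + 6 * sic^2) - se
  c(d1 = d1, d2 = d2, d3 = d3, d4 = d4)
}

# allocation-free scalar Laplace evaluator for the model-scoring hot
# loops; falls back to the public evaluator when Newton misbehaves
zs_laplace_fast <- function(n, p_gamma, r_squared, alpha = 1) {
  if (p_gamma == 0) return(0)
  a <- (n - 1 - p_gamma) / 2
  b <- (n - 1) / 2
  cc <- 1 - r_squared
  s <- n * alpha / 2
  t0 <- log(n)
  ok <- FALSE
  for (i in 1:30) {
    g <- exp(t0)
    sig <- g / (1 + g)
    sic <- cc * g / (1 + cc * g)
    se <- s / g
    d1 <- a * sig - b * sic - 0.5 + se
    d2 <- a * sig * (1 - sig) - b * sic * (1 - sic) - se
    if (!is.finite(d1) || d2 >= 0) break
    t1 <- t0 - d1 / d2
    if (!is.finite(t1) || abs(t1) > 60) break
    if (abs(t1 - t0) < 1e-10) { t0 <- t1; ok <- TRUE; break }
    t0 <- t1
  }
  if (!ok) return(log_marginal_zs(n, p_gamma, r_squared, alpha))
  g <- exp(t0)
  sig <- g / (1 + g)
  sic <- cc * g / (1 + cc * g)
  se <- s / g
  d2 <- a * sig * (1 - sig) - b * sic * (1 - sic) - se
  d3 <- a * sig * (1 - sig) * (1 - 2 * sig) -
    b * sic * (1 - sic) * (1 - 2 * sic) + se
  d4 <- a * sig * (1 - sig) * (1 - 6 * sig + 6 * sig^2) -
    b * sic * (1 - sic) * (1 - 6 * sic + 6 * sic^2) - se
  h <- -d2
  if (!is.finite(h) || h <= 0) return(log_marginal_zs(n, p_gamma, r_squared, alpha))
  fmode <- a * log1p(g) - b * log1p(cc * g) +
    0.5 * log(s) - lgamma(0.5) - 0.5 * t0 - se
  corr <- 1 + d4 / (8 * h^2) + 5 * d3^2 / (24 * h^3)
  fmode + 0.5 * log(2 * pi) - 0.5 * log(h) + if (is.finite(corr) && corr > 0) log(corr) else 0
}

#' Zellner-Siow null-based log marginal likelihood (log Bayes factor)
#'
#' Integrates the conditional g-prior Bayes factor [log_bf_given_g()]
#' over the Zellner-Siow mixing density g ~ Inverse-Gamma(1/2,
#' n alpha / 2), giving the "ZS-null" log Bayes factor of the model
#' against the intercept-only null. The default evaluator is a Laplace
#' approximation on the log-g scale: the integrand's mode is located by
#' safeguarded Newton iteration on the analytic score (falling back to
#' golden-section search if Newton leaves the bracket), and the curvature
#' comes from the analytic second derivative. A slow adaptive-quadrature
#' evaluator (`method = "quadrature"`) serves as the independent
#' reference.
#'
#' @inheritParams log_bf_given_g
#' @param alpha prior scale multiplier (default 1, the conventional
#'   Zellner-Siow calibration).
#' @param method `"laplace"` (default) or `"quadrature"`.
#' @return log Bayes factor versus the null; the null model (p_gamma = 0)
#'   short-circuits to exactly 0.
#' @export
log_marginal_zs <- function(n, p_gamma, r_squared, alpha = 1,
                            method = c("laplace", "quadrature")) {
  method <- match.arg(method)
  stopifnot(alpha > 0, n > p_gamma + 1, r_squared >= 0)
  if (p_gamma == 0) return(0)
  if (r_squared >= 1) stop("saturated fit (R^2 = 1): marginal likelihood diverges",
                           call. = FALSE)

  f <- function(t) zs_log_integrand_t(t, n, p_gamma, r_squared, alpha)

  # mode of the log integrand in t = log g
  t_star <- NA_real_
  t0 <- log(n)
  for (i in 1:50) {
    d <- zs_dlogf(t0, n, p_gamma, r_squared, alpha)
    if (!is.finite(d[[1]]) || d[[2]] >= 0) break
    t1 <- t0 - d[[1]] / d[[2]]
    if (!is.finite(t1) || abs(t1) > 60) break
    if (abs(t1 - t0) < 1e-10) { t_star <- t1; break }
    t0 <- t1
  }
  if (is.na(t_star)) {
    opt <- stats::optimize(f, interval = c(-40, 60), maximum = TRUE, tol = 1e-10)
    t_star <- opt$maximum
    if (min(abs(t_star - c(-40, 60))) < 1e-3) {
      warning("mode search did not converge; using quadrature")
      method <- "quadrature"
    }
  }

  if (method == "laplace") {
    d <- zs_dlogf(t_star, n, p_gamma, r_squared, alpha)
    h <- -d[["d2"]]
    if (!is.finite(h) || h <= 0) {
      warning("non-positive curvature at mode; using quadrature")
      method <- "quadrature"
    } else {
      # second-order (skew/kurtosis) refinement of the Gaussian Laplace
      # term; the integrand in log g is markedly skewed when few
      # predictors are included, where the leading-order term alone is
      # off by ~0.1 log units
      corr <- 1 + d[["d4"]] / (8 * h^2) + 5 * d[["d3"]]^2 / (24 * h^3)
      add <- if (is.finite(corr) && corr > 0) log(corr) else 0
      return(f(t_star) + 0.5 * log(2 * pi) - 0.5 * log(h) + add)
    }
  }

  shift <- f(t_star)
  val <- stats::integrate(function(t) exp(f(t) - shift),
                          lower = -Inf, upper = Inf,
                          rel.tol = 1e-10, subdivisions = 500L)
  shift + log(val$value)
}
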