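#' @title Moment-matched trait distributions
#' @description
#' Internal samplers used by the synthetic herd generator. Each trait is
#' described only by a printed mean and SD, so every family here is
#' parameterised by moment matching:
#'
#' * `truncated_normal`: a normal truncated below at `lower` whose *realized*
#'   (post-truncation) mean and SD equal the targets. The parent `(mu, sigma)`
#'   are solved numerically from the closed-form truncated moments.
#' * `lognormal_moment_matched`: `sigma^2 = log(1 + CV^2)`,
#'   `mu = log(mean) - sigma^2/2`.
#' * `negbinom_moment_matched`: `size = mean^2 / (var - mean)`; requires
#'   `var > mean`, otherwise the caller falls back to `poisson`.
#'
#' A zero-truncated normal cannot reach a coefficient of variation of 1 or
#' more; traits whose printed CV exceeds [cv_truncnorm_max()] are resolved to
#' the lognormal family instead.
#' @name distributions
#' @keywords internal
NULL

# Largest CV a zero-truncated normal is asked to match before the generator
# falls back to a lognormal (the theoretical supremum is 1).
cv_truncnorm_max <- function() 0.95

#' Mean and SD of a normal truncated below
#'
#' Closed-form moments of `N(mu, sigma^2)` conditioned on exceeding `lower`.
#'
#' @param mu,sigma parent normal parameters (`sigma > 0`).
#' @param lower truncation point.
#' @return list with `mean` and `sd` of the truncated variable.
#' @keywords internal
truncnorm_moments <- function(mu, sigma, lower = 0) {
  a <- (lower - mu) / sigma
  lam <- exp(stats::dnorm(a, log = TRUE) - stats::pnorm(a, lower.tail = FALSE, log.p = TRUE))
  m <- mu + sigma * lam
  v <- sigma^2 * (1 + a * lam - lam^2)
  list(mean = m, sd = sqrt(pmax(v, 0)))
}

# Solve parent (mu, sigma) so the truncated moments hit (mean, sd).
# Returns NULL when the target CV is not achievable.
solve_truncnorm <- function(mean, sd, lower = 0) {
  stopifnot(sd > 0, mean > lower)
  if ((sd / (mean - lower)) >= cv_truncnorm_max()) return(NULL)
  obj <- function(p) {
    mo <- truncnorm_moments(p[1], exp(p[2]), lower)
    ((mo$mean - mean)^2 + (mo$sd - sd)^2) / sd^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  mo <- truncnorm_moments(fit$par[1], exp(fit$par[2]), lower)
  if (abs(mo$mean - mean) > 1e-4 * sd || abs(mo$sd - sd) > 1e-4 * sd) return(NULL)
  list(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# Quantile function of the lower-truncated normal (used by the copula path).
qtruncnorm <- function(p, mu, sigma, lower = 0) {
  pa <- stats::pnorm((lower - mu) / sigma)
  mu + sigma * stats::qnorm(pa + p * (1 - pa))
}

lognormal_params <- function(mean, sd) {
  stopifnot(mean > 0, sd > 0)
  s2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

negbinom_params <- function(mean, sd) {
  stopifnot(mean > 0)
  if (sd^2 <= mean) return(NULL)           # caller falls back to poisson
  list(mu = mean, size = mean^2 / (sd^2 - mean))
}

# Cache of solved truncated-normal parameters, keyed on (mean, sd, lower).
.truncnorm_cache <- new.env(parent = emptyenv())

#' Resolve a trait distribution to a concrete sampler
#'
#' Takes a declared family plus target moments and returns the family that
#' will actually be used (after fallbacks) together with its parameters.
#'
#' @param family one of `"truncated_normal"`, `"lognormal_moment_matched"`,
#'   `"negbinom_moment_matched"`, `"poisson"`.
#' @param mean,sd target moments (trait units).
#' @param lower lower bound for the truncated normal (default 0).
#' @return list with elements `family` and `params`.
#' @keywords internal
resolve_distribution <- function(family, mean, sd, lower = 0) {
  if (!is.finite(mean) || !is.finite(sd) || sd <= 0)
    stop("trait distribution needs finite mean and sd > 0 (got mean=", mean,
         ", sd=", sd, ")", call. = FALSE)
  switch(family,
    truncated_normal = {
      key <- sprintf("%.10g|%.10g|%.10g", mean, sd, lower)
      par <- .truncnorm_cache[[key]]
      if (is.null(par)) {
        par <- solve_truncnorm(mean, sd, lower)
        if (!is.null(par)) assign(key, par, envir = .truncnorm_cache)
      }
      if (is.null(par))   # CV too large for a zero-truncated normal
        resolve_distribution("lognormal_moment_matched", mean, sd)
      else
        list(family = "truncated_normal", params = c(par, lower = lower))
    },
    lognormal_moment_matched =
      list(family = "lognormal_moment_matched", params = lognormal_params(mean, sd)),
    negbinom_moment_matched = {
      par <- negbinom_params(mean, sd)
      if (is.null(par)) list(family = "poisson", params = list(lambda = mean))
      else list(family = "negbinom_moment_matched", params = par)
    },
    poisson = list(family = "poisson", params = list(lambda = mean)),
    stop("unknown distribution family: ", family, call. = FALSE)
  )
}

# Transform U(0,1) draws through a resolved distribution's quantile function.
quantile_transform <- function(u, dist) {
  p <- dist$params
  switch(dist$family,
    truncated_normal         = qtruncnorm(u, p$mu, p$sigma, p$lower),
    lognormal_moment_matched = stats::qlnorm(u, p$meanlog, p$sdlog),
    negbinom_moment_matched  = stats::qnbinom(u, mu = p$mu, size = p$size),
    poisson                  = stats::qpois(u, p$lambda),
    stop("unknown resolved family: ", dist$family, call. = FALSE)
  )
}

#' Draw trait values from a moment-matched distribution
#'
#' @param n number of draws.
#' @param family declared family (see [resolve_distribution()]).
#' @param mean,sd target mean and SD in trait units.
#' @param lower truncation bound (truncated normal only).
#' @return numeric vector of length `n`.
#' @keywords internal
draw_trait <- function(n, family, mean, sd, lower = 0) {
  quantile_transform(stats::runif(n), resolve_distribution(family, mean, sd, lower))
}
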