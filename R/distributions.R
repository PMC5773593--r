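#' Negative binomial log-probability mass function
#'
#' Log PMF of the negative binomial distribution parameterized by its mean
#' `mu` and inverse dispersion `theta` (variance `mu + mu^2/theta`; the
#' dispersion is `phi = 1/theta` and `theta = Inf` recovers the Poisson).
#' Computed through log-gamma identities so that very large or very small
#' `theta` stay finite.
#'
#' @param y vector of non-negative integer counts.
#' @param mu vector of positive means.
#' @param theta vector of positive inverse dispersions.
#' @return vector of log-probabilities, with the usual recycling rules.
#' @examples
#' nbLogPmf(0, 1, 1)  # log(1/2)
#' @export
nbLogPmf <- function(y, mu, theta) {
  .checkZinbArgs(y, mu, theta, pi = NULL)
  lgamma(y + theta) - lgamma(y + 1) - lgamma(theta) +
    theta * (log(theta) - log(theta + mu)) +
    y * (log(mu) - log(mu + theta))
}

#' Zero-inflated negative binomial log-probability mass function
#'
#' Log PMF of the mixture `pi * delta_0(y) + (1 - pi) * NB(y; mu, theta)`.
#' The `y = 0` branch is evaluated with a log-sum-exp on the logit scale so
#' that extreme dropout probabilities and dispersions do not overflow;
#' `pi = 1` with `y > 0` returns `-Inf`.
#'
#' @inheritParams nbLogPmf
#' @param pi vector of zero-inflation (dropout) probabilities in `[0, 1]`.
#' @return vector of log-probabilities.
#' @examples
#' zinbLogPmf(0, mu = 2, theta = 1, pi = 0.3)  # log(8/15)
#' @export
zinbLogPmf <- function(y, mu, theta, pi) {
  .checkZinbArgs(y, mu, theta, pi)
  n <- max(length(y), length(mu), length(theta), length(pi))
  y <- rep_len(y, n); mu <- rep_len(mu, n)
  theta <- rep_len(theta, n); pi <- rep_len(pi, n)
  nb <- nbLogPmf(y, mu, theta)
  out <- log1p(-pi) + nb
  i0 <- which(y == 0)
  if (length(i0)) {
    out[i0] <- .logsumexp2(log(pi[i0]), log1p(-pi[i0]) + nb[i0])
  }
  out[pi == 1 & y > 0] <- -Inf
  out[pi == 1 & y == 0] <- 0
  out
}

#' Moments and zero probability of the ZINB distribution
#'
#' @inheritParams zinbLogPmf
#' @return list with elements `mean` (`(1 - pi) * mu`), `zero_prob`
#'   (`pi + (1 - pi) * (theta / (theta + mu))^theta`) and `nb_variance`
#'   (`mu + mu^2 / theta`, the variance of the count component).
#' @export
zinbMoments <- function(mu, theta, pi = 0) {
  .checkZinbArgs(0, mu, theta, pi)
  lp0 <- theta * (log(theta) - log(theta + mu))
  list(mean = (1 - pi) * mu,
       zero_prob = pi + (1 - pi) * exp(lp0),
       nb_variance = mu + mu^2 / theta)
}

#' Analytic score of the ZINB log-PMF in the mean and dropout probability
#'
#' Derivatives of `zinbLogPmf` with respect to `mu` and `pi`, using the
#' two-branch closed forms (for `y > 0`: `y/mu - (y + theta)/(mu + theta)`
#' and `-1/(1 - pi)`; for `y = 0` the ratio expressions involving
#' `(theta/(mu + theta))^theta`, evaluated in log space). At the boundary
#' `pi = 1` with `y > 0` the `pi`-derivative is `-Inf` by contract.
#'
#' @inheritParams zinbLogPmf
#' @return list with vectors `d_mu` and `d_pi`.
#' @export
zinbGradMuPi <- function(y, mu, theta, pi) {
  .checkZinbArgs(y, mu, theta, pi)
  n <- max(length(y), length(mu), length(theta), length(pi))
  y <- rep_len(y, n); mu <- rep_len(mu, n)
  theta <- rep_len(theta, n); pi <- rep_len(pi, n)
  d_mu <- y / mu - (y + theta) / (mu + theta)
  d_pi <- -1 / (1 - pi)
  i0 <- which(y == 0)
  if (length(i0)) {
    lp0 <- theta[i0] * (log(theta[i0]) - log(theta[i0] + mu[i0]))
    # log of denominator pi + (1 - pi) p0
    lden <- .logsumexp2(log(pi[i0]), log1p(-pi[i0]) + lp0)
    d_mu[i0] <- -exp(log1p(-pi[i0]) + lp0 - lden) * theta[i0] / (mu[i0] + theta[i0])
    p0 <- exp(lp0)
    d_pi[i0] <- (1 - p0) / exp(lden)
  }
  list(d_mu = d_mu, d_pi = d_pi)
}

#' Analytic score of the ZINB log-PMF in the inverse dispersion
#'
#' Derivative of `zinbLogPmf` with respect to `theta`. For `y > 0` this is
#' `digamma(y + theta) - digamma(theta) + log(theta) + 1 - log(mu + theta) -
#' (y + theta)/(mu + theta)`; for `y = 0` the same numerator (at `y = 0`) is
#' damped by `1 + pi (mu + theta)^theta / ((1 - pi) theta^theta)`, with the
#' ratio computed in log space.
#'
#' @inheritParams zinbLogPmf
#' @return vector of derivatives.
#' @export
zinbGradTheta <- function(y, mu, theta, pi = 0) {
  .checkZinbArgs(y, mu, theta, pi)
  n <- max(length(y), length(mu), length(theta), length(pi))
  y <- rep_len(y, n); mu <- rep_len(mu, n)
  theta <- rep_len(theta, n); pi <- rep_len(pi, n)
  out <- digamma(y + theta) - digamma(theta) +
    log(theta) + 1 - log(mu + theta) - (y + theta) / (mu + theta)
  i0 <- which(y == 0)
  if (length(i0)) {
    lp0 <- theta[i0] * (log(theta[i0]) - log(theta[i0] + mu[i0]))
    num <- log(theta[i0]) + 1 - log(mu[i0] + theta[i0]) -
      theta[i0] / (mu[i0] + theta[i0])
    # damping 1 / (1 + exp(logit(pi) - log p0)), stable for pi at the boundary
    lrat <- log(pi[i0]) - log1p(-pi[i0]) - lp0
    out[i0] <- num * exp(-.log1pexp(lrat))
  }
  out
}

.checkZinbArgs <- function(y, mu, theta, pi) {
  if (any(!is.finite(mu)) || any(mu <= 0))
    stop("mu must be positive and finite", call. = FALSE)
  if (any(is.na(theta)) || any(theta <= 0))
    stop("theta must be positive", call. = FALSE)
  if (any(y < 0) || any(y != floor(y)))
    stop("y must be a non-negative integer", call. = FALSE)
  if (!is.null(pi) && (any(pi < 0) || any(pi > 1)))
    stop("pi must lie in [0, 1]", call. = FALSE)
  invisible(TRUE)
}

# ---- internal vectorized kernel on the (log mu, logit pi, log theta) scale ---
# No argument checking; used by the likelihood and the optimizers. All inputs
# are recycled to a common length by the caller.

.zinbLL <- function(y, lmu, eta, ltheta) {
  mu <- exp(lmu)
  theta <- exp(ltheta)
  nb <- stats::dnbinom(y, size = theta, mu = mu, log = TRUE)
  out <- -.log1pexp(eta) + nb
  i0 <- which(y == 0)
  if (length(i0)) {
    out[i0] <- .logsumexp2(eta[i0], nb[i0]) - .log1pexp(eta[i0])
  }
  out
}

# G = mu * d/dmu, H = pi (1 - pi) * d/dpi of the ZINB log-PMF
.zinbGH <- function(y, lmu, eta, ltheta) {
  mu <- exp(lmu)
  theta <- exp(ltheta)
  pi_ <- stats::plogis(eta)
  G <- y - mu * (y + theta) / (mu + theta)
  H <- -pi_
  i0 <- which(y == 0)
  if (length(i0)) {
    lp0 <- theta[i0] * (ltheta[i0] - log(mu[i0] + theta[i0]))
    p0 <- exp(lp0)
    # w0 = (1 - pi) p0 / (pi + (1 - pi) p0) computed as p0 / (e^eta + p0)
    w0 <- exp(lp0 - .logsumexp2(eta[i0], lp0))
    G[i0] <- -mu[i0] * theta[i0] / (mu[i0] + theta[i0]) * w0
    H[i0] <- pi_[i0] * (1 - p0) * exp(-.logsumexp2(eta[i0], lp0))
  }
  list(G = G, H = H)
}

# d/dtheta of the ZINB log-PMF on the same internal scale
.zinbDTheta <- function(y, lmu, eta, ltheta) {
  mu <- exp(lmu)
  theta <- exp(ltheta)
  out <- digamma(y + theta) - digamma(theta) +
    ltheta + 1 - log(mu + theta) - (y + theta) / (mu + theta)
  i0 <- which(y == 0)
  if (length(i0)) {
    lp0 <- theta[i0] * (ltheta[i0] - log(mu[i0] + theta[i0]))
    num <- ltheta[i0] + 1 - log(mu[i0] + theta[i0]) -
      theta[i0] / (mu[i0] + theta[i0])
    out[i0] <- num * exp(-.log1pexp(eta[i0] - lp0))
  }
  out
}
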