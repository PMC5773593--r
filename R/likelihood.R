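#' Log-likelihood, penalty, and information criteria
#'
#' `zinbLogLik` evaluates the ZINB log-likelihood of a count matrix under a
#' model; `zinbPenalty` the ridge penalty
#' \deqn{\frac{\epsilon_\beta}{2}\|\beta^0\|^2 +
#'       \frac{\epsilon_\gamma}{2}\|\gamma^0\|^2 +
#'       \frac{\epsilon_W}{2}\|W\|^2 +
#'       \frac{\epsilon_\alpha}{2}\|\alpha\|^2 +
#'       \frac{\epsilon_\zeta}{2}\mathrm{Var}(\zeta)}
#' (Frobenius norms; `beta^0`, `gamma^0` exclude unpenalized intercept rows;
#' `alpha` covers the mean and dropout loadings jointly; `Var` is the
#' unbiased sample variance); `zinbPenalizedLogLik` their difference.
#'
#' @param model a [ZinbModel-class].
#' @param Y `n x J` matrix of non-negative integer counts (samples in rows).
#' @return a scalar.
#' @export
zinbLogLik <- function(model, Y) {
  .checkCounts(Y)
  n <- nSamples(model); J <- nFeatures(model)
  if (!all(dim(Y) == c(n, J)))
    stop("Y must be ", n, " x ", J, call. = FALSE)
  lmu <- getLogMu(model)
  eta <- getLogitPi(model)
  ltheta <- matrix(model@zeta, n, J, byrow = TRUE)
  sum(.zinbLL(as.vector(Y), as.vector(lmu), as.vector(eta), as.vector(ltheta)))
}

#' @rdname zinbLogLik
#' @export
zinbPenalty <- function(model) {
  eps <- .epsilons(model)
  msk <- .penaltyMasks(model)
  J <- nFeatures(model)
  vz <- if (J > 1) stats::var(model@zeta) else 0
  eps$beta / 2 * (sum(model@beta_mu[msk$beta_mu, ]^2) +
                  sum(model@beta_pi[msk$beta_pi, ]^2)) +
    eps$gamma / 2 * (sum(model@gamma_mu[msk$gamma_mu, ]^2) +
                     sum(model@gamma_pi[msk$gamma_pi, ]^2)) +
    eps$W / 2 * sum(model@W^2) +
    eps$alpha / 2 * (sum(model@alpha_mu^2) + sum(model@alpha_pi^2)) +
    eps$zeta / 2 * vz
}

#' @rdname zinbLogLik
#' @export
zinbPenalizedLogLik <- function(model, Y) {
  zinbLogLik(model, Y) - zinbPenalty(model)
}

#' Information criteria for a fitted ZINB factor model
#'
#' `numberParams` counts the estimated parameters,
#' `N = J (M_mu + M_pi) + n (L_mu + L_pi) + 2 K J + n K + J` for genewise
#' dispersion (the trailing `J` becomes `1` for common dispersion).
#' `zinbAIC` returns `2 N - 2 l` and `zinbBIC` returns `ln(n) N - 2 l`,
#' where `l` is the unpenalized log-likelihood at the estimate.
#'
#' @inheritParams zinbLogLik
#' @return `numberParams`: an integer; `zinbAIC` / `zinbBIC`: a scalar.
#' @export
numberParams <- function(model) {
  n <- nSamples(model); J <- nFeatures(model); K <- nFactors(model)
  M_mu <- length(model@which_X_mu); M_pi <- length(model@which_X_pi)
  L_mu <- length(model@which_V_mu); L_pi <- length(model@which_V_pi)
  J * (M_mu + M_pi) + n * (L_mu + L_pi) + 2 * K * J + n * K +
    if (model@commonDispersion) 1L else J
}

#' @rdname numberParams
#' @export
zinbAIC <- function(model, Y) {
  2 * numberParams(model) - 2 * zinbLogLik(model, Y)
}

#' @rdname numberParams
#' @export
zinbBIC <- function(model, Y) {
  log(nSamples(model)) * numberParams(model) - 2 * zinbLogLik(model, Y)
}
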