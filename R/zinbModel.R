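#' Construct a ZINB factor model
#'
#' Builds a [ZinbModel-class] object from its design and (optionally) its
#' parameters. Unspecified designs default to intercept-only (`X` a column of
#' ones accounting for gene-specific baselines, `V` a column of ones whose
#' coefficient `gamma` acts as a sample-specific scaling factor); unspecified
#' parameters default to zero.
#'
#' @param n,J number of samples (cells) and features (genes). Inferred from
#'   `X`/`V` when those are given.
#' @param K number of latent factors (columns of `W`).
#' @param X sample-level covariate matrix (`n x M`).
#' @param V gene-level covariate matrix (`J x L`).
#' @param O_mu,O_pi offset matrices (`n x J`), default zero.
#' @param which_X_mu,which_X_pi,which_V_mu,which_V_pi integer vectors of
#'   column indices of `X` / `V` used in the mean and dropout regressions
#'   (defaults: all columns in both).
#' @param W,beta_mu,beta_pi,gamma_mu,gamma_pi,alpha_mu,alpha_pi,zeta optional
#'   parameter values (see [ZinbModel-class] for dimensions).
#' @param commonDispersion logical; single dispersion shared across genes.
#' @param epsilon ridge penalty scale; defaults to `J`, so that the
#'   block-level weights `epsilon/J`, `epsilon/n`, ... balance the penalties
#'   across parameter blocks of different sizes.
#' @return a [ZinbModel-class] object.
#' @examples
#' m <- zinbModel(n = 10, J = 5, K = 2)
#' nSamples(m); nFeatures(m); nFactors(m)
#' @export
zinbModel <- function(n = NULL, J = NULL, K = 0,
                      X = NULL, V = NULL, O_mu = NULL, O_pi = NULL,
                      which_X_mu = NULL, which_X_pi = NULL,
                      which_V_mu = NULL, which_V_pi = NULL,
                      W = NULL, beta_mu = NULL, beta_pi = NULL,
                      gamma_mu = NULL, gamma_pi = NULL,
                      alpha_mu = NULL, alpha_pi = NULL, zeta = NULL,
                      commonDispersion = FALSE, epsilon = NULL) {
  if (is.null(n)) n <- if (!is.null(X)) nrow(X) else stop("provide n or X")
  if (is.null(J)) J <- if (!is.null(V)) nrow(V) else stop("provide J or V")
  if (is.null(X)) X <- matrix(1, n, 1)
  if (is.null(V)) V <- matrix(1, J, 1)
  if (!is.matrix(X)) X <- as.matrix(X)
  if (!is.matrix(V)) V <- as.matrix(V)
  if (nrow(X) != n) stop("X must have n rows")
  if (nrow(V) != J) stop("V must have J rows")
  if (is.null(O_mu)) O_mu <- matrix(0, n, J)
  if (is.null(O_pi)) O_pi <- matrix(0, n, J)
  if (is.null(which_X_mu)) which_X_mu <- seq_len(ncol(X))
  if (is.null(which_X_pi)) which_X_pi <- seq_len(ncol(X))
  if (is.null(which_V_mu)) which_V_mu <- seq_len(ncol(V))
  if (is.null(which_V_pi)) which_V_pi <- seq_len(ncol(V))
  M_mu <- length(which_X_mu); M_pi <- length(which_X_pi)
  L_mu <- length(which_V_mu); L_pi <- length(which_V_pi)
  if (is.null(W)) W <- matrix(0, n, K)
  if (is.null(beta_mu)) beta_mu <- matrix(0, M_mu, J)
  if (is.null(beta_pi)) beta_pi <- matrix(0, M_pi, J)
  if (is.null(gamma_mu)) gamma_mu <- matrix(0, L_mu, n)
  if (is.null(gamma_pi)) gamma_pi <- matrix(0, L_pi, n)
  if (is.null(alpha_mu)) alpha_mu <- matrix(0, ncol(W), J)
  if (is.null(alpha_pi)) alpha_pi <- matrix(0, ncol(W), J)
  if (is.null(zeta)) zeta <- numeric(J)
  if (length(zeta) == 1L) zeta <- rep(zeta, J)
  if (is.null(epsilon)) epsilon <- J
  methods::new("ZinbModel",
    X = X, V = V, O_mu = O_mu, O_pi = O_pi,
    which_X_mu = as.integer(which_X_mu), which_X_pi = as.integer(which_X_pi),
    which_V_mu = as.integer(which_V_mu), which_V_pi = as.integer(which_V_pi),
    W = W, beta_mu = beta_mu, beta_pi = beta_pi,
    gamma_mu = gamma_mu, gamma_pi = gamma_pi,
    alpha_mu = alpha_mu, alpha_pi = alpha_pi,
    zeta = as.numeric(zeta),
    commonDispersion = isTRUE(commonDispersion),
    epsilon = as.numeric(epsilon))
}

# ---- accessors ---------------------------------------------------------------

#' Model dimensions and parameter accessors
#'
#' Accessor generics for [ZinbModel-class] objects: number of samples,
#' features and latent factors, design sub-matrices, parameter blocks, and
#' the derived `n x J` matrices of means, dropout probabilities and
#' dispersions.
#'
#' @param object,model a [ZinbModel-class].
#' @param type `"mu"` or `"pi"`, selecting the regression component.
#' @name zinb-accessors
NULL

#' @rdname zinb-accessors
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))
#' @rdname zinb-accessors
#' @export
setGeneric("nFeatures", function(object) standardGeneric("nFeatures"))
#' @rdname zinb-accessors
#' @export
setGeneric("nFactors", function(object) standardGeneric("nFactors"))

#' @rdname zinb-accessors
#' @export
setMethod("nSamples", "ZinbModel", function(object) nrow(object@X))
#' @rdname zinb-accessors
#' @export
setMethod("nFeatures", "ZinbModel", function(object) nrow(object@V))
#' @rdname zinb-accessors
#' @export
setMethod("nFactors", "ZinbModel", function(object) ncol(object@W))

#' @rdname zinb-accessors
#' @export
getX <- function(model, type = c("mu", "pi")) {
  type <- match.arg(type)
  idx <- if (type == "mu") model@which_X_mu else model@which_X_pi
  model@X[, idx, drop = FALSE]
}

#' @rdname zinb-accessors
#' @export
getV <- function(model, type = c("mu", "pi")) {
  type <- match.arg(type)
  idx <- if (type == "mu") model@which_V_mu else model@which_V_pi
  model@V[, idx, drop = FALSE]
}

#' @rdname zinb-accessors
#' @export
getW <- function(model) model@W

#' @rdname zinb-accessors
#' @export
getBeta <- function(model, type = c("mu", "pi")) {
  if (match.arg(type) == "mu") model@beta_mu else model@beta_pi
}

#' @rdname zinb-accessors
#' @export
getGamma <- function(model, type = c("mu", "pi")) {
  if (match.arg(type) == "mu") model@gamma_mu else model@gamma_pi
}

#' @rdname zinb-accessors
#' @export
getAlpha <- function(model, type = c("mu", "pi")) {
  if (match.arg(type) == "mu") model@alpha_mu else model@alpha_pi
}

#' @rdname zinb-accessors
#' @export
getZeta <- function(model) model@zeta

#' Linear predictors and distribution parameters of a model
#'
#' `getLogMu` / `getLogitPi` return the `n x J` linear predictors
#' `X beta + (V gamma)^T + W alpha + O`; `getMu`, `getPi` and `getTheta`
#' return the corresponding NB means, dropout probabilities and inverse
#' dispersions (`getTheta` is the length-`J` vector `exp(zeta)`).
#'
#' @param model a [ZinbModel-class].
#' @return a matrix (`getLogMu`, `getLogitPi`, `getMu`, `getPi`) or a vector
#'   (`getTheta`).
#' @name zinb-predictors
NULL

#' @rdname zinb-predictors
#' @export
getLogMu <- function(model) {
  .linearPredictor(model, "mu")
}

#' @rdname zinb-predictors
#' @export
getLogitPi <- function(model) {
  .linearPredictor(model, "pi")
}

#' @rdname zinb-predictors
#' @export
getMu <- function(model) exp(getLogMu(model))

#' @rdname zinb-predictors
#' @export
getPi <- function(model) stats::plogis(getLogitPi(model))

#' @rdname zinb-predictors
#' @export
getTheta <- function(model) exp(model@zeta)

.linearPredictor <- function(model, type) {
  X <- getX(model, type); V <- getV(model, type)
  beta <- getBeta(model, type); gamma <- getGamma(model, type)
  alpha <- getAlpha(model, type)
  O <- if (type == "mu") model@O_mu else model@O_pi
  n <- nSamples(model); J <- nFeatures(model)
  out <- O
  if (ncol(X) > 0) {
    if (ncol(beta) != J || nrow(beta) != ncol(X))
      stop("dimension mismatch in beta_", type, call. = FALSE)
    out <- out + X %*% beta
  }
  if (ncol(V) > 0) {
    if (ncol(gamma) != n || nrow(gamma) != ncol(V))
      stop("dimension mismatch in gamma_", type, call. = FALSE)
    out <- out + t(V %*% gamma)
  }
  if (ncol(model@W) > 0) {
    out <- out + model@W %*% alpha
  }
  out
}

# per-block penalty weights derived from the scalar epsilon
.epsilons <- function(model) {
  n <- nSamples(model); J <- nFeatures(model)
  list(beta = model@epsilon / J, gamma = model@epsilon / n,
       W = model@epsilon / n, alpha = model@epsilon / J,
       zeta = model@epsilon)
}

# logical masks marking the penalized (non-intercept) rows of beta and gamma
.penaltyMasks <- function(model) {
  list(beta_mu = !.interceptCols(getX(model, "mu")),
       beta_pi = !.interceptCols(getX(model, "pi")),
       gamma_mu = !.interceptCols(getV(model, "mu")),
       gamma_pi = !.interceptCols(getV(model, "pi")))
}

setMethod("show", "ZinbModel", function(object) {
  cat("Object of class", class(object), "\n")
  cat(sprintf("%d samples; %d genes; %d latent factor(s)\n",
              nSamples(object), nFeatures(object), nFactors(object)))
  cat(sprintf("X: %d column(s) (mu: %d, pi: %d); V: %d column(s) (mu: %d, pi: %d)\n",
              ncol(object@X), length(object@which_X_mu), length(object@which_X_pi),
              ncol(object@V), length(object@which_V_mu), length(object@which_V_pi)))
  cat(sprintf("dispersion: %s; epsilon = %g\n",
              if (object@commonDispersion) "common" else "genewise",
              object@epsilon))
})

setMethod("show", "ZinbFit", function(object) {
  methods::callNextMethod()
  cat(sprintf("converged: %s after %d outer iteration(s); penalized loglik %.4f\n",
              object@converged, object@iterations,
              object@trace[length(object@trace)]))
})
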