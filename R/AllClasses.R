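#' ZINB factor model
#'
#' S4 class holding the design and the parameters of a zero-inflated negative
#' binomial factor model for an `n x J` count matrix (samples in rows, genes
#' in columns). The NB mean and the dropout probability are modeled as
#'
#' \deqn{\ln\mu = X\beta_\mu + (V\gamma_\mu)^\top + W\alpha_\mu + O_\mu,}
#' \deqn{logit(\pi) = X\beta_\pi + (V\gamma_\pi)^\top + W\alpha_\pi + O_\pi,}
#' \deqn{\ln\theta_{ij} = \zeta_j,}
#'
#' where `X` (`n x M`) holds known sample-level covariates, `V` (`J x L`)
#' known gene-level covariates, `W` (`n x K`) unobserved sample-level factors
#' with loadings `alpha` (`K x J`), and `zeta` the log inverse dispersions.
#' `X` and `V` may enter the two regressions through different column subsets
#' (`which_X_mu`, `which_X_pi`, `which_V_mu`, `which_V_pi`).
#'
#' @slot X sample-level covariate matrix (`n x M`).
#' @slot V gene-level covariate matrix (`J x L`).
#' @slot O_mu,O_pi offset matrices (`n x J`).
#' @slot which_X_mu,which_X_pi,which_V_mu,which_V_pi integer column indices
#'   selecting the covariates used in the mean and dropout regressions.
#' @slot W latent factor matrix (`n x K`).
#' @slot beta_mu,beta_pi regression coefficients of `X` (`M_mu x J`, `M_pi x J`).
#' @slot gamma_mu,gamma_pi regression coefficients of `V` (`L_mu x n`, `L_pi x n`).
#' @slot alpha_mu,alpha_pi factor loadings (`K x J`).
#' @slot zeta log inverse dispersions (length `J`).
#' @slot commonDispersion logical; if `TRUE` a single dispersion is shared by
#'   all genes (`zeta` constant).
#' @slot epsilon non-negative scalar controlling the ridge penalty; the
#'   block-specific weights are `epsilon/J` for `beta` and `alpha`,
#'   `epsilon/n` for `gamma` and `W`, and `epsilon` for `zeta`.
#'
#' @aliases ZinbModel-class
#' @seealso [zinbModel()], [zinbFit()]
#' @export
setClass("ZinbModel",
  representation(
    X = "matrix", V = "matrix",
    O_mu = "matrix", O_pi = "matrix",
    which_X_mu = "integer", which_X_pi = "integer",
    which_V_mu = "integer", which_V_pi = "integer",
    W = "matrix",
    beta_mu = "matrix", beta_pi = "matrix",
    gamma_mu = "matrix", gamma_pi = "matrix",
    alpha_mu = "matrix", alpha_pi = "matrix",
    zeta = "numeric",
    commonDispersion = "logical",
    epsilon = "numeric"
  )
)

setValidity("ZinbModel", function(object) {
  n <- nrow(object@X)
  J <- nrow(object@V)
  K <- ncol(object@W)
  msg <- NULL
  chk <- function(cond, what) if (!cond) msg <<- c(msg, what)
  chk(nrow(object@W) == n, "W must have n rows")
  chk(all(dim(object@O_mu) == c(n, J)), "O_mu must be n x J")
  chk(all(dim(object@O_pi) == c(n, J)), "O_pi must be n x J")
  chk(all(object@which_X_mu %in% seq_len(ncol(object@X))), "which_X_mu out of range")
  chk(all(object@which_X_pi %in% seq_len(ncol(object@X))), "which_X_pi out of range")
  chk(all(object@which_V_mu %in% seq_len(ncol(object@V))), "which_V_mu out of range")
  chk(all(object@which_V_pi %in% seq_len(ncol(object@V))), "which_V_pi out of range")
  chk(all(dim(object@beta_mu) == c(length(object@which_X_mu), J)), "beta_mu dimensions")
  chk(all(dim(object@beta_pi) == c(length(object@which_X_pi), J)), "beta_pi dimensions")
  chk(all(dim(object@gamma_mu) == c(length(object@which_V_mu), n)), "gamma_mu dimensions")
  chk(all(dim(object@gamma_pi) == c(length(object@which_V_pi), n)), "gamma_pi dimensions")
  chk(all(dim(object@alpha_mu) == c(K, J)), "alpha_mu dimensions")
  chk(all(dim(object@alpha_pi) == c(K, J)), "alpha_pi dimensions")
  chk(length(object@zeta) == J, "zeta must have length J")
  chk(length(object@epsilon) == 1L && object@epsilon >= 0, "epsilon must be a non-negative scalar")
  chk(all(is.finite(object@X)) && all(is.finite(object@V)), "designs must be finite")
  chk(all(is.finite(object@zeta)), "zeta must be finite")
  if (isTRUE(object@commonDispersion) && J > 1)
    chk(max(object@zeta) - min(object@zeta) < 1e-10,
        "zeta must be constant when commonDispersion = TRUE")
  if (is.null(msg)) TRUE else msg
})

#' Fitted ZINB factor model
#'
#' Extends [ZinbModel-class] with diagnostics from the fitting procedure.
#'
#' @slot trace penalized log-likelihood after initialization and after each
#'   outer iteration.
#' @slot traceDetail data.frame with the objective after every block update
#'   (dispersion, cell, gene, orthogonalize) of every outer iteration.
#' @slot converged logical convergence flag.
#' @slot iterations number of outer iterations performed.
#'
#' @aliases ZinbFit-class
#' @export
setClass("ZinbFit",
  contains = "ZinbModel",
  representation(
    trace = "numeric",
    traceDetail = "data.frame",
    converged = "logical",
    iterations = "integer"
  )
)
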