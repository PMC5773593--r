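#' Fit a ZINB factor model by penalized maximum likelihood
#'
#' Estimates all parameters of a [ZinbModel-class] from a count matrix by
#' block-coordinate ascent on the penalized log-likelihood: after a
#' log-normal/logistic initialization ([zinbInitialize()]), the procedure
#' iterates (1) dispersion optimization (a common dispersion found by
#' bounded 1-D search on `[-50, 50]`, then genewise quasi-Newton refinement
#' from the constant solution), (2) cell-block updates of `(gamma, W)` — one
#' penalized ZINB regression per cell ([solveZinbRegression()]), (3)
#' gene-block updates of `(beta, alpha)` — one regression per gene, and (4)
#' SVD rebalancing of `(W, alpha)` ([orthogonalizeFactors()]), until the
#' relative change of the objective drops below `tol` or `maxIter` outer
#' iterations are reached. Every step can only increase the objective, so
#' the recorded trace is non-decreasing (up to numerical tolerance).
#'
#' @param Y count matrix with samples (cells) in rows and features (genes)
#'   in columns; no all-zero row or column may be present.
#' @param X,V,O_mu,O_pi,which_X_mu,which_X_pi,which_V_mu,which_V_pi design;
#'   see [zinbModel()].
#' @param K number of latent factors.
#' @param commonDispersion logical; share one dispersion across genes.
#' @param epsilon ridge penalty scale (default: number of genes).
#' @param maxIter maximum outer iterations.
#' @param tol relative-change stopping tolerance for the objective.
#' @param initAlternations alternation rounds inside [zinbInitialize()].
#' @param innerControl control list passed to the BFGS sub-solver of every
#'   cell- and gene-block regression (see [stats::optim()]).
#' @param stopOnDecrease if `TRUE`, a decrease of the objective beyond
#'   numerical tolerance aborts with an error instead of a warning.
#' @param verbose print the objective after each outer iteration.
#' @return a [ZinbFit-class] object.
#' @examples
#' m0 <- zinbModel(n = 30, J = 15, K = 1,
#'                 beta_mu = matrix(1, 1, 15), zeta = rep(1, 15))
#' Y <- zinbSim(m0, seed = 1)$counts
#' fit <- zinbFit(Y, K = 1, maxIter = 3)
#' @export
zinbFit <- function(Y, X = NULL, V = NULL, K = 0,
                    O_mu = NULL, O_pi = NULL,
                    which_X_mu = NULL, which_X_pi = NULL,
                    which_V_mu = NULL, which_V_pi = NULL,
                    commonDispersion = FALSE, epsilon = NULL,
                    maxIter = 25, tol = 1e-4, initAlternations = 2,
                    innerControl = list(maxit = 100),
                    stopOnDecrease = FALSE, verbose = FALSE) {
  .checkCounts(Y)
  n <- nrow(Y); J <- ncol(Y)
  model <- zinbModel(n = n, J = J, K = K, X = X, V = V,
                     O_mu = O_mu, O_pi = O_pi,
                     which_X_mu = which_X_mu, which_X_pi = which_X_pi,
                     which_V_mu = which_V_mu, which_V_pi = which_V_pi,
                     commonDispersion = commonDispersion, epsilon = epsilon)
  model <- zinbInitialize(Y, model, alternations = initAlternations)
  obj <- zinbPenalizedLogLik(model, Y)
  trace <- obj
  detail <- data.frame(iteration = 0L, step = "initialize", objective = obj,
                       stringsAsFactors = FALSE)
  converged <- FALSE
  it <- 0L
  record <- function(step, value) {
    detail <<- rbind(detail,
                     data.frame(iteration = it, step = step,
                                objective = value, stringsAsFactors = FALSE))
    drop <- obj - value
    if (drop > 1e-6 * (abs(obj) + 1)) {
      msg <- sprintf("objective decreased by %.3g during %s (iteration %d)",
                     drop, step, it)
      if (stopOnDecrease) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
    }
    obj <<- value
  }
  for (it in seq_len(maxIter)) {
    prev <- obj
    model <- .optimizeDispersion(model, Y)
    record("dispersion", zinbPenalizedLogLik(model, Y))
    model <- .updateCellParams(model, Y, control = innerControl)
    record("cell", zinbPenalizedLogLik(model, Y))
    model <- .updateGeneParams(model, Y, control = innerControl)
    record("gene", zinbPenalizedLogLik(model, Y))
    if (nFactors(model) > 0) {
      model <- .orthogonalizeModel(model)
      record("orthogonalize", zinbPenalizedLogLik(model, Y))
    }
    trace <- c(trace, obj)
    if (verbose)
      message(sprintf("iteration %d: penalized loglik %.6f", it, obj))
    if (abs(obj - prev) <= tol * (abs(prev) + 1)) {
      converged <- TRUE
      break
    }
  }
  methods::new("ZinbFit", model,
               trace = trace, traceDetail = detail,
               converged = converged, iterations = it)
}

# ---- dispersion --------------------------------------------------------------

.optimizeDispersion <- function(model, Y) {
  n <- nSamples(model); J <- nFeatures(model)
  eps <- .epsilons(model)
  lmu <- as.vector(getLogMu(model))
  eta <- as.vector(getLogitPi(model))
  y <- as.vector(Y)
  colIdx <- rep(seq_len(J), each = n)
  llCommon <- function(z) {
    sum(.zinbLL(y, lmu, eta, rep(z, n * J)))
  }
  opt <- stats::optimize(llCommon, interval = c(-50, 50), maximum = TRUE)
  zetaC <- rep(opt$maximum, J)
  if (model@commonDispersion || J == 1L) {
    # a single gene has Var(zeta) = 0; the common solution is genewise too
    if (J == 1L && !model@commonDispersion) {
      gw <- .genewiseZeta(zetaC, y, lmu, eta, colIdx, n, J, eps$zeta)
      model@zeta <- gw
    } else {
      model@zeta <- zetaC
    }
    return(model)
  }
  model@zeta <- .genewiseZeta(zetaC, y, lmu, eta, colIdx, n, J, eps$zeta)
  model
}

# genewise quasi-Newton refinement from the constant solution, within the
# same [-50, 50] box; falls back to the start if no improvement is found
.genewiseZeta <- function(zeta0, y, lmu, eta, colIdx, n, J, epsZeta) {
  penVar <- function(z) if (J > 1) epsZeta / 2 * stats::var(z) else 0
  fn <- function(z) {
    lt <- z[colIdx]
    -(sum(.zinbLL(y, lmu, eta, lt)) - penVar(z))
  }
  gr <- function(z) {
    lt <- z[colIdx]
    d <- .zinbDTheta(y, lmu, eta, lt) * exp(lt)
    g <- rowsum(d, colIdx)[, 1]
    if (J > 1) g <- g - epsZeta / (J - 1) * (z - mean(z))
    -g
  }
  res <- tryCatch(
    stats::optim(zeta0, fn, gr, method = "L-BFGS-B",
                 lower = -50, upper = 50, control = list(maxit = 100)),
    error = function(e) list(par = zeta0, value = fn(zeta0)))
  if (res$value <= fn(zeta0)) res$par else zeta0
}

# ---- cell and gene block updates --------------------------------------------

.updateCellParams <- function(model, Y, control = list(maxit = 100)) {
  n <- nSamples(model); K <- nFactors(model)
  eps <- .epsilons(model)
  msk <- .penaltyMasks(model)
  V_mu <- getV(model, "mu"); V_pi <- getV(model, "pi")
  L_mu <- ncol(V_mu); L_pi <- ncol(V_pi)
  if (L_mu + L_pi + K == 0L) return(model)
  B_mu <- t(model@alpha_mu); B_pi <- t(model@alpha_pi)
  C_mu <- getX(model, "mu") %*% model@beta_mu + model@O_mu
  C_pi <- getX(model, "pi") %*% model@beta_pi + model@O_pi
  w_g_mu <- eps$gamma * as.numeric(msk$gamma_mu)
  w_g_pi <- eps$gamma * as.numeric(msk$gamma_pi)
  zeta <- model@zeta
  for (i in seq_len(n)) {
    res <- solveZinbRegression(
      y = Y[i, ],
      A_mu = V_mu, B_mu = B_mu, C_mu = C_mu[i, ],
      A_pi = V_pi, B_pi = B_pi, C_pi = C_pi[i, ],
      C_theta = zeta,
      w_a_mu = w_g_mu, w_a_pi = w_g_pi, w_b = eps$W,
      start = list(a_mu = model@gamma_mu[, i], a_pi = model@gamma_pi[, i],
                   b = model@W[i, ]),
      control = control)
    if (L_mu) model@gamma_mu[, i] <- res$a_mu
    if (L_pi) model@gamma_pi[, i] <- res$a_pi
    if (K) model@W[i, ] <- res$b
  }
  model
}

.updateGeneParams <- function(model, Y, control = list(maxit = 100)) {
  J <- nFeatures(model); n <- nSamples(model); K <- nFactors(model)
  eps <- .epsilons(model)
  msk <- .penaltyMasks(model)
  X_mu <- getX(model, "mu"); X_pi <- getX(model, "pi")
  M_mu <- ncol(X_mu); M_pi <- ncol(X_pi)
  if (M_mu + M_pi + K == 0L) return(model)
  A_mu <- cbind(X_mu, model@W)
  A_pi <- cbind(X_pi, model@W)
  V_mu <- getV(model, "mu"); V_pi <- getV(model, "pi")
  C_mu <- (if (ncol(V_mu)) t(V_mu %*% model@gamma_mu) else matrix(0, n, J)) +
    model@O_mu
  C_pi <- (if (ncol(V_pi)) t(V_pi %*% model@gamma_pi) else matrix(0, n, J)) +
    model@O_pi
  w_mu <- c(eps$beta * as.numeric(msk$beta_mu), rep(eps$alpha, K))
  w_pi <- c(eps$beta * as.numeric(msk$beta_pi), rep(eps$alpha, K))
  for (j in seq_len(J)) {
    res <- solveZinbRegression(
      y = Y[, j],
      A_mu = A_mu, C_mu = C_mu[, j],
      A_pi = A_pi, C_pi = C_pi[, j],
      C_theta = rep(model@zeta[j], n),
      w_a_mu = w_mu, w_a_pi = w_pi,
      start = list(a_mu = c(model@beta_mu[, j], model@alpha_mu[, j]),
                   a_pi = c(model@beta_pi[, j], model@alpha_pi[, j]),
                   b = numeric(0)),
      control = control)
    if (M_mu) model@beta_mu[, j] <- res$a_mu[seq_len(M_mu)]
    if (K) model@alpha_mu[, j] <- res$a_mu[M_mu + seq_len(K)]
    if (M_pi) model@beta_pi[, j] <- res$a_pi[seq_len(M_pi)]
    if (K) model@alpha_pi[, j] <- res$a_pi[M_pi + seq_len(K)]
  }
  model
}

.orthogonalizeModel <- function(model) {
  eps <- .epsilons(model)
  o <- orthogonalizeFactors(model@W, model@alpha_mu, model@alpha_pi,
                            epsilon_W = eps$W, epsilon_alpha = eps$alpha)
  model@W <- o$W
  model@alpha_mu <- o$alpha_mu
  model@alpha_pi <- o$alpha_pi
  model
}
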