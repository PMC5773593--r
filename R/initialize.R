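#' Initialize the parameters of a ZINB factor model
#'
#' Produces starting values for [zinbFit()] by approximating the non-zero
#' counts with a log-normal distribution and treating the zeros as binary
#' dropout outcomes:
#'
#' 1. On the positive entries `P`, set `L = ln(Y) - O_mu` and estimate
#'    `beta_mu`, `gamma_mu` by alternating closed-form ridge regressions
#'    (per-cell, then per-gene; intercepts unpenalized).
#' 2. Complete the residual `D = L - X beta - (V gamma)^T` with
#'    [softImputeLowRank()] at `lambda = sqrt(eps_W eps_alpha)` and split the
#'    result into `W` and `alpha_mu` via its SVD.
#' 3. Fit a ridge logistic regression of the zero indicator on
#'    `(X, V-intercepts, W)` with `W` fixed, alternating the per-cell
#'    `gamma_pi` update and the per-gene `(beta_pi, alpha_pi)` update.
#' 4. Set `zeta = 0`.
#'
#' @param Y `n x J` count matrix; every gene and every cell must have at
#'   least one positive count (filter first, see [filterGenes()]).
#' @param model a [ZinbModel-class] providing the design.
#' @param alternations rounds of the alternating ridge updates.
#' @param verbose print progress.
#' @return the model with initialized parameter slots.
#' @export
zinbInitialize <- function(Y, model, alternations = 2, verbose = FALSE) {
  .checkCounts(Y)
  n <- nSamples(model); J <- nFeatures(model); K <- nFactors(model)
  if (any(rowSums(Y) == 0))
    stop("some cells have all-zero counts; remove them before fitting",
         call. = FALSE)
  if (any(colSums(Y) == 0))
    stop("some genes have all-zero counts; filter them out before fitting ",
         "(see filterGenes)", call. = FALSE)
  eps <- .epsilons(model)
  msk <- .penaltyMasks(model)

  P <- Y > 0
  L <- matrix(NA_real_, n, J)
  L[P] <- log(Y[P]) - model@O_mu[P]

  X_mu <- getX(model, "mu"); V_mu <- getV(model, "mu")
  M_mu <- ncol(X_mu); L_mu <- ncol(V_mu)
  beta_mu <- matrix(0, M_mu, J)
  gamma_mu <- matrix(0, L_mu, n)
  dG <- diag(as.numeric(msk$gamma_mu), L_mu)
  dB <- diag(as.numeric(msk$beta_mu), M_mu)
  for (round in seq_len(alternations)) {
    # per-cell ridge in gamma_mu given beta_mu
    if (L_mu > 0) {
      Xb <- X_mu %*% beta_mu
      for (i in seq_len(n)) {
        jj <- which(P[i, ])
        Vi <- V_mu[jj, , drop = FALSE]
        ri <- L[i, jj] - Xb[i, jj]
        gamma_mu[, i] <- solve(crossprod(Vi) + eps$gamma / 2 * dG,
                               crossprod(Vi, ri))
      }
    }
    # per-gene ridge in beta_mu given gamma_mu
    if (M_mu > 0) {
      Vg <- if (L_mu > 0) t(V_mu %*% gamma_mu) else matrix(0, n, J)
      for (j in seq_len(J)) {
        ii <- which(P[, j])
        Xj <- X_mu[ii, , drop = FALSE]
        rj <- L[ii, j] - Vg[ii, j]
        beta_mu[, j] <- solve(crossprod(Xj) + eps$beta / 2 * dB,
                              crossprod(Xj, rj))
      }
    }
  }
  model@beta_mu <- beta_mu
  model@gamma_mu <- gamma_mu

  # low-rank completion of the log-scale residual
  if (K > 0) {
    D <- L - X_mu %*% beta_mu -
      (if (L_mu > 0) t(V_mu %*% gamma_mu) else 0)
    si <- softImputeLowRank(D, lambda = sqrt(eps$W * eps$alpha), K = K)
    cc <- (eps$alpha / eps$W)^(1/4)
    sq <- sqrt(si$d)
    model@W <- cc * si$u * rep(sq, each = n)
    model@alpha_mu <- (1 / cc) * (sq * t(si$v))
  }

  # ridge logistic regression of the zero indicator
  Z <- matrix(as.numeric(Y == 0), n, J)
  model <- .initLogistic(model, Z, alternations, verbose)
  model@zeta <- rep(0, J)
  model
}

# Alternating ridge logistic fit for (gamma_pi) vs (beta_pi, alpha_pi); all
# blocks fully penalized here, matching the convex initialization problem.
.initLogistic <- function(model, Z, alternations, verbose = FALSE) {
  n <- nSamples(model); J <- nFeatures(model); K <- nFactors(model)
  eps <- .epsilons(model)
  X_pi <- getX(model, "pi"); V_pi <- getV(model, "pi")
  M_pi <- ncol(X_pi); L_pi <- ncol(V_pi)
  W <- model@W
  beta_pi <- matrix(0, M_pi, J)
  gamma_pi <- matrix(0, L_pi, n)
  alpha_pi <- matrix(0, K, J)
  interceptOnlyV <- L_pi == 1 && all(V_pi == 1)
  for (round in seq_len(alternations)) {
    # per-cell gamma_pi
    if (L_pi > 0) {
      fixed <- X_pi %*% beta_pi + W %*% alpha_pi + model@O_pi
      if (interceptOnlyV && all(beta_pi == 0) && all(alpha_pi == 0) &&
          all(model@O_pi == 0)) {
        # logit of the per-cell zero proportion, clamped to the +/-50 box
        gamma_pi[1, ] <- .logitClamped(rowMeans(Z))
      } else {
        for (i in seq_len(n)) {
          gamma_pi[, i] <- .ridgeLogistic(Z[i, ], V_pi, fixed[i, ],
                                          eps$gamma, gamma_pi[, i])
        }
      }
    }
    # per-gene (beta_pi, alpha_pi)
    if (M_pi + K > 0) {
      A <- cbind(X_pi, W)
      off <- (if (L_pi > 0) t(V_pi %*% gamma_pi) else matrix(0, n, J)) +
        model@O_pi
      wts <- c(rep(eps$beta, M_pi), rep(eps$alpha, K))
      for (j in seq_len(J)) {
        cf <- .ridgeLogistic(Z[, j], A, off[, j], wts,
                             c(beta_pi[, j], alpha_pi[, j]))
        if (M_pi) beta_pi[, j] <- cf[seq_len(M_pi)]
        if (K) alpha_pi[, j] <- cf[M_pi + seq_len(K)]
      }
    }
  }
  model@beta_pi <- beta_pi
  model@gamma_pi <- gamma_pi
  model@alpha_pi <- alpha_pi
  model
}

# small dense ridge-penalized logistic regression with offset, by BFGS
.ridgeLogistic <- function(z, A, offset, weights, start) {
  p <- ncol(A)
  weights <- rep_len(weights, p)
  fn <- function(b) {
    eta <- offset + A %*% b
    sum(-z * eta + .log1pexp(eta)) + sum(weights * b^2) / 2
  }
  gr <- function(b) {
    eta <- as.vector(offset + A %*% b)
    as.vector(crossprod(A, stats::plogis(eta) - z)) + weights * b
  }
  res <- stats::optim(start, fn, gr, method = "BFGS",
                      control = list(maxit = 100))
  if (res$value > fn(start)) start else res$par
}
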