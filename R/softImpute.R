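#' Rank-constrained nuclear-norm matrix completion
#'
#' Approximately minimizes \eqn{\|D - R\|_P^2 + \lambda \|R\|_*} subject to
#' `rank(R) <= K`, where the squared error runs over the observed entries `P`
#' only, by iterating impute / soft-threshold-SVD: fill the unobserved
#' entries with the current `R`, take an SVD, shrink the singular values by
#' `lambda / 2`, truncate to rank `K`, and repeat until the relative change
#' of `R` falls below `tol`. For a fully observed `D` this converges in one
#' step to the nuclear-norm prox (singular values `max(s - lambda/2, 0)`).
#'
#' @param D numeric matrix with `NA` at the unobserved entries.
#' @param lambda non-negative nuclear-norm weight.
#' @param K rank cap (`K >= 1`).
#' @param tol relative convergence tolerance.
#' @param maxIter maximum number of impute/SVD sweeps.
#' @return list with the completed low-rank matrix `R` and its thresholded
#'   SVD factors `u`, `d`, `v` (`K` columns; trailing entries of `d` may be
#'   zero when the solution has lower rank).
#' @export
softImputeLowRank <- function(D, lambda, K, tol = 1e-5, maxIter = 100) {
  if (lambda < 0) stop("lambda must be non-negative")
  if (K < 1) stop("K must be at least 1")
  obs <- !is.na(D)
  if (!any(obs)) stop("no observed entries in D")
  K <- min(K, dim(D))
  R <- matrix(0, nrow(D), ncol(D))
  Dfill <- D
  Dfill[!obs] <- 0
  prevNorm <- 0
  for (it in seq_len(maxIter)) {
    s <- svd(Dfill)
    d <- pmax(s$d - lambda / 2, 0)
    keep <- seq_len(K)
    Rnew <- s$u[, keep, drop = FALSE] %*%
      (d[keep] * t(s$v[, keep, drop = FALSE]))
    delta <- sqrt(sum((Rnew - R)^2))
    R <- Rnew
    Dfill[!obs] <- R[!obs]
    nrm <- sqrt(sum(R^2))
    if (delta <= tol * max(nrm, 1)) break
    prevNorm <- nrm
  }
  list(R = R,
       u = s$u[, keep, drop = FALSE],
       d = d[keep],
       v = s$v[, keep, drop = FALSE])
}

#' Rebalance latent factors and loadings by SVD
#'
#' Given `W` (`n x K`) and the stacked loadings `alpha = [alpha_mu alpha_pi]`
#' (`K x 2J`), replaces them by the penalty-minimizing factorization of the
#' product `R = W alpha`: if `R = R_L R_S R_R` is an SVD, then
#' `W = (eps_alpha/eps_W)^(1/4) R_L R_S^(1/2)` and
#' `alpha = (eps_W/eps_alpha)^(1/4) R_S^(1/2) R_R`. The products
#' `W alpha_mu`, `W alpha_pi` are unchanged, the columns of `W` become
#' orthogonal, and the ridge penalty on `(W, alpha)` attains its lower bound
#' `sqrt(eps_W eps_alpha) ||R||_*`.
#'
#' @param W latent factors (`n x K`).
#' @param alpha_mu,alpha_pi loadings (`K x J` each).
#' @param epsilon_W,epsilon_alpha the penalty weights on `W` and `alpha`.
#' @return list with rebalanced `W`, `alpha_mu`, `alpha_pi`.
#' @export
orthogonalizeFactors <- function(W, alpha_mu, alpha_pi,
                                 epsilon_W, epsilon_alpha) {
  K <- ncol(W)
  if (K < 1) stop("K must be at least 1")
  alpha <- cbind(alpha_mu, alpha_pi)
  # compact SVD of W %*% alpha through a K x K core
  sw <- svd(W, nu = K, nv = K)
  sa <- svd(t(alpha), nu = K, nv = K)
  core <- (sw$d[seq_len(K)] * t(sw$v)) %*% sa$v %*% diag(sa$d[seq_len(K)], K)
  s <- svd(core)
  U <- sw$u %*% s$u
  Vv <- sa$u %*% s$v
  cc <- (epsilon_alpha / epsilon_W)^(1/4)
  sq <- sqrt(s$d)
  Wn <- cc * U * rep(sq, each = nrow(U))
  an <- (1 / cc) * (sq * t(Vv))
  J <- ncol(alpha_mu)
  list(W = Wn,
       alpha_mu = an[, seq_len(J), drop = FALSE],
       alpha_pi = an[, J + seq_len(J), drop = FALSE])
}
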