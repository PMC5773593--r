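#' Penalized ZINB regression sub-solver
#'
#' Maximizes the ridge-penalized ZINB log-likelihood of a count vector `y`
#' under the parameterization
#' \deqn{\ln\mu = A_\mu a_\mu + B_\mu b + C_\mu,\quad
#'       logit(\pi) = A_\pi a_\pi + B_\pi b + C_\pi,\quad
#'       \ln\theta = C_\theta,}
#' over `(a_mu, a_pi, b)`, using BFGS with the analytic gradients
#' \eqn{\nabla_{a_\mu} = A_\mu^\top G}, \eqn{\nabla_{a_\pi} = A_\pi^\top H},
#' \eqn{\nabla_b = B_\mu^\top G + B_\pi^\top H} (where
#' \eqn{G_i = \mu_i \partial\ln f/\partial\mu} and
#' \eqn{H_i = \pi_i(1-\pi_i)\partial\ln f/\partial\pi}), minus the ridge
#' terms. Internally the negative penalized log-likelihood is minimized; the
#' returned point is never worse than the starting point.
#'
#' @param y length-`N` vector of non-negative integer counts.
#' @param A_mu,B_mu `N x p` and `N x r` design blocks for the mean; may have
#'   zero columns.
#' @param C_mu length-`N` offset for the mean.
#' @param A_pi,B_pi,C_pi analogous blocks for the dropout probability.
#' @param C_theta length-`N` vector of log inverse dispersions.
#' @param w_a_mu,w_a_pi,w_b ridge weights, recycled to lengths `p`, `q`, `r`
#'   (a zero weight leaves the corresponding coefficient unpenalized).
#' @param start list with starting values `a_mu`, `a_pi`, `b`.
#' @param control passed to [stats::optim()] (BFGS); defaults to
#'   `maxit = 100`.
#' @return list with `a_mu`, `a_pi`, `b`, the achieved penalized
#'   log-likelihood `value`, and `convergence` (the BFGS code; `1` flags an
#'   iteration-limit stop, in which case the best iterate is returned).
#' @export
solveZinbRegression <- function(y, A_mu = NULL, B_mu = NULL, C_mu = 0,
                                A_pi = NULL, B_pi = NULL, C_pi = 0,
                                C_theta = 0,
                                w_a_mu = 0, w_a_pi = 0, w_b = 0,
                                start = NULL,
                                control = list(maxit = 100)) {
  N <- length(y)
  blk <- function(A) {
    if (is.null(A)) matrix(0, N, 0) else if (!is.matrix(A)) matrix(A, N) else A
  }
  A_mu <- blk(A_mu); B_mu <- blk(B_mu); A_pi <- blk(A_pi); B_pi <- blk(B_pi)
  p <- ncol(A_mu); q <- ncol(A_pi); r <- ncol(B_mu)
  if (ncol(B_pi) != r) stop("B_mu and B_pi must have the same number of columns")
  C_mu <- rep_len(C_mu, N); C_pi <- rep_len(C_pi, N)
  C_theta <- rep_len(C_theta, N)
  w_a_mu <- rep_len(w_a_mu, p); w_a_pi <- rep_len(w_a_pi, q)
  w_b <- rep_len(w_b, r)
  if (is.null(start)) start <- list(a_mu = numeric(p), a_pi = numeric(q),
                                    b = numeric(r))
  par0 <- c(start$a_mu, start$a_pi, start$b)
  npar <- p + q + r
  if (npar == 0L) {
    val <- sum(.zinbLL(y, C_mu, C_pi, C_theta))
    return(list(a_mu = numeric(0), a_pi = numeric(0), b = numeric(0),
                value = val, convergence = 0L))
  }
  wAll <- c(w_a_mu, w_a_pi, w_b)
  iA <- seq_len(p); iQ <- p + seq_len(q); iB <- p + q + seq_len(r)

  predict <- function(par) {
    a <- par[iA]; ap <- par[iQ]; b <- par[iB]
    lmu <- C_mu
    if (p) lmu <- lmu + A_mu %*% a
    if (r) lmu <- lmu + B_mu %*% b
    eta <- C_pi
    if (q) eta <- eta + A_pi %*% ap
    if (r) eta <- eta + B_pi %*% b
    list(lmu = as.vector(lmu), eta = as.vector(eta))
  }
  fn <- function(par) {
    pr <- predict(par)
    ll <- sum(.zinbLL(y, pr$lmu, pr$eta, C_theta))
    if (!is.finite(ll)) return(1e12)
    -ll + sum(wAll * par^2) / 2
  }
  gr <- function(par) {
    pr <- predict(par)
    gh <- .zinbGH(y, pr$lmu, pr$eta, C_theta)
    g <- numeric(npar)
    if (p) g[iA] <- crossprod(A_mu, gh$G)
    if (q) g[iQ] <- crossprod(A_pi, gh$H)
    if (r) g[iB] <- crossprod(B_mu, gh$G) + crossprod(B_pi, gh$H)
    -g + wAll * par
  }
  if (any(!is.finite(par0))) stop("non-finite objective at the starting point")
  pr0 <- predict(par0)
  ll0 <- sum(.zinbLL(y, pr0$lmu, pr0$eta, C_theta))
  if (is.na(ll0)) stop("non-finite objective at the starting point")
  f0 <- fn(par0)
  ctl <- utils::modifyList(list(maxit = 100), control)
  res <- tryCatch(
    stats::optim(par0, fn, gr, method = "BFGS", control = ctl),
    error = function(e) list(par = par0, value = f0, convergence = 52L))
  if (!is.finite(res$value) || res$value > f0) {
    res$par <- par0
    res$value <- f0
  }
  list(a_mu = res$par[iA], a_pi = res$par[iQ], b = res$par[iB],
       value = -res$value,
       convergence = res$convergence)
}
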