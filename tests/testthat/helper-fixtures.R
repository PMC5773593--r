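# Shared fixture builders: random parameterized models and count matrices,
# all generated in code under explicit seeds.

randomModel <- function(n, J, K = 2, seed = 1, commonDispersion = FALSE,
                        epsilon = J) {
  set.seed(seed)
  zeta <- if (commonDispersion) rep(rnorm(1, 0.5, 0.2), J) else
    rnorm(J, 0.5, 0.3)
  zinbModel(
    n = n, J = J, K = K,
    W = matrix(rnorm(n * K, 0, 0.8), n, K),
    beta_mu = matrix(rnorm(J, 1.5, 0.8), 1, J),
    beta_pi = matrix(rnorm(J, -1, 0.8), 1, J),
    gamma_mu = matrix(rnorm(n, 0, 0.3), 1, n),
    gamma_pi = matrix(rnorm(n, 0, 0.5), 1, n),
    alpha_mu = matrix(rnorm(K * J, 0, 0.5), K, J),
    alpha_pi = matrix(rnorm(K * J, 0, 0.5), K, J),
    zeta = zeta,
    commonDispersion = commonDispersion,
    epsilon = epsilon)
}

simCounts <- function(n, J, K = 2, seed = 1, ...) {
  m <- randomModel(n, J, K = K, seed = seed, ...)
  sim <- zinbSim(m, seed = seed + 1000)
  list(model = m, Y = sim$counts, mu = sim$mu, pi = sim$pi)
}

# counts guaranteed free of all-zero rows/columns for fitting tests
fittableCounts <- function(n, J, K = 2, seed = 1, ...) {
  s <- simCounts(n, J, K = K, seed = seed, ...)
  Y <- s$Y
  zr <- which(rowSums(Y) == 0)
  if (length(zr)) Y[cbind(zr, 1)] <- 1L
  zc <- which(colSums(Y) == 0)
  if (length(zc)) Y[cbind(1, zc)] <- 1L
  s$Y <- Y
  s
}

# central finite difference of a scalar function
finiteDiff <- function(f, x, h = 1e-6) {
  (f(x + h) - f(x - h)) / (2 * h)
}

# a tiny fixed mixture so scenario tests need no mclust fit
fixedMixture <- function(K = 2, C = 3, sep = 1.5) {
  ang <- seq(0, 2 * pi, length.out = C + 1)[seq_len(C)]
  means <- matrix(0, C, K)
  means[, 1] <- sep * cos(ang)
  if (K >= 2) means[, 2] <- sep * sin(ang)
  list(means = means,
       covariances = rep(list(diag(0.25, K)), C),
       weights = rep(1 / C, C))
}
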