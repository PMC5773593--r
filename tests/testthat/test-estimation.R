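# Initialization, dispersion optimization, block updates, and full fits.

test_that("initialization on strictly positive counts matches closed-form ridge", {
  # with X = 1_n, V = 1_J, K = 0 and no zeros, the alternating ridge on
  # ln(Y) has exact closed-form per-cell / per-gene updates (intercepts are
  # unpenalized, so these are plain means given the other block)
  set.seed(71)
  n <- 12; J <- 9
  Y <- matrix(rpois(n * J, 20) + 1L, n, J)
  m <- zinbModel(n = n, J = J, K = 0)
  init <- zinbInitialize(Y, m, alternations = 2)
  L <- log(Y)
  g <- rep(0, n); b <- rep(0, J)
  for (round in 1:2) {
    g <- rowMeans(L - matrix(b, n, J, byrow = TRUE))
    b <- colMeans(L - matrix(g, n, J))
  }
  expect_equal(as.numeric(init@gamma_mu), g, tolerance = 1e-10)
  expect_equal(as.numeric(init@beta_mu), b, tolerance = 1e-10)
  expect_equal(init@zeta, rep(0, J))
})

test_that("dropout intercepts initialize at the logit of the per-cell zero fraction", {
  s <- fittableCounts(15, 12, K = 0, seed = 72)
  m <- zinbModel(n = 15, J = 12, K = 0)
  init <- zinbInitialize(s$Y, m, alternations = 1)
  expected <- qlogis(rowMeans(s$Y == 0))
  expected <- pmin(pmax(expected, -50), 50)
  expect_equal(as.numeric(init@gamma_pi), expected)
})

test_that("all-zero genes or cells are rejected with an actionable message", {
  s <- fittableCounts(10, 8, seed = 73)
  Y <- s$Y
  Y[, 3] <- 0L
  expect_error(zinbInitialize(Y, zinbModel(n = 10, J = 8)), "filter")
  Y <- s$Y
  Y[4, ] <- 0L
  expect_error(zinbInitialize(Y, zinbModel(n = 10, J = 8)), "cells")
})

test_that("initialized W and loadings reproduce the soft-impute split", {
  s <- fittableCounts(20, 15, K = 2, seed = 74)
  m <- zinbModel(n = 20, J = 15, K = 2)
  init <- zinbInitialize(s$Y, m)
  # scaled column/row norms of W and alpha_mu balance as in the SVD split
  eps <- zinbfactor:::.epsilons(m)
  for (k in 1:2) {
    nw <- eps$W * sum(init@W[, k]^2)
    na <- eps$alpha * sum(init@alpha_mu[k, ]^2)
    if (nw + na > 1e-12) expect_equal(nw, na, tolerance = 1e-6)
  }
})

test_that("dispersion optimization matches a dense grid for a single gene", {
  set.seed(75)
  n <- 80
  m <- zinbModel(n = n, J = 1, K = 0,
                 beta_mu = matrix(1.4, 1, 1), beta_pi = matrix(-1, 1, 1))
  Y <- zinbSim(m, seed = 76)$counts
  mOpt <- zinbfactor:::.optimizeDispersion(m, Y)
  grid <- seq(-6, 6, by = 2e-4)
  lmu <- rep(getLogMu(m)[, 1], 1)
  eta <- rep(getLogitPi(m)[, 1], 1)
  gll <- vapply(grid, function(z)
    sum(zinbfactor:::.zinbLL(Y[, 1], lmu, eta, rep(z, n))), numeric(1))
  expect_lt(abs(mOpt@zeta - grid[which.max(gll)]), 1e-3)
})

test_that("quasi-Poisson data push the common dispersion to the upper bound", {
  set.seed(77)
  n <- 60; J <- 10
  Y <- matrix(rpois(n * J, 8), n, J)
  Y[Y == 0] <- 1L
  m <- zinbModel(n = n, J = J, K = 0, commonDispersion = TRUE, epsilon = 0,
                 beta_mu = matrix(log(8), 1, J),
                 beta_pi = matrix(-10, 1, J))
  mOpt <- zinbfactor:::.optimizeDispersion(m, Y)
  # the likelihood is essentially flat beyond theta ~ e^20, so "near the
  # boundary" means an effectively infinite dispersion (Poisson regime)
  expect_gt(mOpt@zeta[1], 20)
})

test_that("an overwhelming variance penalty collapses genewise to common dispersion", {
  s <- fittableCounts(40, 8, K = 0, seed = 78)
  m <- s$model
  m@epsilon <- 1e9
  mBig <- zinbfactor:::.optimizeDispersion(m, s$Y)
  expect_lt(max(mBig@zeta) - min(mBig@zeta), 1e-3)
  m@epsilon <- 0
  mFree <- zinbfactor:::.optimizeDispersion(m, s$Y)
  expect_gt(max(mFree@zeta) - min(mFree@zeta), 1e-3)
})

test_that("block updates never decrease the penalized objective", {
  for (seed in 79:82) {
    s <- fittableCounts(25, 20, K = 2, seed = seed)
    m <- zinbInitialize(s$Y, zinbModel(n = 25, J = 20, K = 2))
    obj <- zinbPenalizedLogLik(m, s$Y)
    m <- zinbfactor:::.optimizeDispersion(m, s$Y)
    o1 <- zinbPenalizedLogLik(m, s$Y)
    expect_gte(o1, obj - 1e-6 * abs(obj))
    m <- zinbfactor:::.updateCellParams(m, s$Y)
    o2 <- zinbPenalizedLogLik(m, s$Y)
    expect_gte(o2, o1 - 1e-6 * abs(o1))
    m <- zinbfactor:::.updateGeneParams(m, s$Y)
    o3 <- zinbPenalizedLogLik(m, s$Y)
    expect_gte(o3, o2 - 1e-6 * abs(o2))
    m <- zinbfactor:::.orthogonalizeModel(m)
    o4 <- zinbPenalizedLogLik(m, s$Y)
    expect_gte(o4, o3 - 1e-6 * abs(o3))
  }
})

test_that("identical cells receive identical cell-block updates", {
  s <- fittableCounts(10, 15, K = 1, seed = 83)
  Y <- s$Y
  Y[2, ] <- Y[1, ]                      # duplicate rows
  m <- zinbInitialize(Y, zinbModel(n = 10, J = 15, K = 1))
  # force identical starting parameters for the twin cells
  m@gamma_mu[, 2] <- m@gamma_mu[, 1]
  m@gamma_pi[, 2] <- m@gamma_pi[, 1]
  m@W[2, ] <- m@W[1, ]
  up <- zinbfactor:::.updateCellParams(m, Y)
  expect_equal(up@gamma_mu[, 2], up@gamma_mu[, 1])
  expect_equal(up@gamma_pi[, 2], up@gamma_pi[, 1])
  expect_equal(up@W[2, ], up@W[1, ])
})

test_that("identical genes receive identical gene-block updates", {
  s <- fittableCounts(20, 8, K = 1, seed = 84)
  Y <- s$Y
  Y[, 2] <- Y[, 1]
  m <- zinbInitialize(Y, zinbModel(n = 20, J = 8, K = 1))
  m@beta_mu[, 2] <- m@beta_mu[, 1]
  m@beta_pi[, 2] <- m@beta_pi[, 1]
  m@alpha_mu[, 2] <- m@alpha_mu[, 1]
  m@alpha_pi[, 2] <- m@alpha_pi[, 1]
  m@zeta[2] <- m@zeta[1]
  up <- zinbfactor:::.updateGeneParams(m, Y)
  expect_equal(up@beta_mu[, 2], up@beta_mu[, 1])
  expect_equal(up@alpha_mu[, 2], up@alpha_mu[, 1])
  expect_equal(up@beta_pi[, 2], up@beta_pi[, 1])
})

test_that("a K = 0 single-covariate fit matches the grid-search ZINB MLE", {
  # X = 1_n only, no gene covariate, epsilon = 0: the genes decouple into
  # independent 3-parameter (ln mu, logit pi, zeta) ZINB likelihoods
  set.seed(85)
  n <- 150; J <- 6
  truth <- list(lmu = runif(J, 1, 2.5), lpi = runif(J, -1.5, 0),
                zeta = runif(J, 0, 1))
  repeat {
    Y <- sapply(seq_len(J), function(j) {
      drop <- rbinom(n, 1, plogis(truth$lpi[j]))
      ifelse(drop == 1, 0L,
             rnbinom(n, size = exp(truth$zeta[j]), mu = exp(truth$lmu[j])))
    })
    if (all(rowSums(Y) > 0) && all(colSums(Y) > 0)) break
  }
  fit <- zinbFit(Y, V = matrix(numeric(0), J, 0), K = 0, epsilon = 0,
                 maxIter = 60, tol = 1e-12,
                 innerControl = list(maxit = 300, reltol = 1e-13))
  for (j in seq_len(J)) {
    # dense grid + Nelder-Mead polish as the independent oracle
    gr <- expand.grid(lmu = seq(0.5, 3, length.out = 26),
                      lpi = seq(-4, 2, length.out = 25),
                      z = seq(-1.5, 2.5, length.out = 21))
    ll <- function(p) sum(zinbfactor:::.zinbLL(Y[, j], rep(p[1], n),
                                               rep(p[2], n), rep(p[3], n)))
    gll <- apply(gr, 1, ll)
    p0 <- as.numeric(gr[which.max(gll), ])
    oracle <- optim(p0, function(p) -ll(p), method = "Nelder-Mead",
                    control = list(maxit = 2000, reltol = 1e-14))$par
    expect_lt(abs(fit@beta_mu[1, j] - oracle[1]), 1e-3)
    expect_lt(abs(fit@zeta[j] - oracle[3]), 1e-3)
    if (abs(oracle[2]) <= 5) {
      expect_lt(abs(fit@beta_pi[1, j] - oracle[2]), 1e-3)
    } else {
      # dropout MLE at the boundary: the logit is unidentified (flat
      # likelihood); both solutions must agree on the probability scale
      expect_true(sign(fit@beta_pi[1, j]) == sign(oracle[2]) &&
                    abs(fit@beta_pi[1, j]) > 5)
      expect_lt(abs(plogis(fit@beta_pi[1, j]) - plogis(oracle[2])), 1e-3)
    }
  }
})

test_that("the fit trace is non-decreasing and reordering samples/genes commutes", {
  s <- fittableCounts(30, 25, K = 2, seed = 86)
  fit <- zinbFit(s$Y, K = 2, maxIter = 3)
  d <- fit@traceDetail$objective
  expect_true(all(diff(d) > -1e-6 * (abs(d[-length(d)]) + 1)))
  # permuting rows and columns of Y permutes the parameter blocks
  pr <- sample(30); pc <- sample(25)
  fitP <- zinbFit(s$Y[pr, pc], K = 2, maxIter = 3)
  expect_equal(fitP@beta_mu[, order(pc), drop = FALSE], fit@beta_mu,
               tolerance = 1e-6)
  expect_equal(fitP@gamma_mu[, order(pr), drop = FALSE], fit@gamma_mu,
               tolerance = 1e-6)
  expect_equal(fitP@zeta[order(pc)], fit@zeta, tolerance = 1e-6)
  expect_equal(abs(fitP@W[order(pr), ]), abs(fit@W), tolerance = 1e-5)
  expect_equal(zinbPenalizedLogLik(fitP, s$Y[pr, pc]),
               zinbPenalizedLogLik(fit, s$Y), tolerance = 1e-8)
})

test_that("factors recovered from model-simulated data correlate with the truth", {
  tpl <- syntheticTemplate(J = 80, n = 120, seed = 87)
  sc <- simulateScenario(tpl, n = 120, J = 80, targetZeroFraction = 0.45,
                         b2 = 1, C = 3, seed = 88, wMixture = fixedMixture())
  Y <- sc$counts
  Y[cbind(which(rowSums(Y) == 0), 1)] <- 1L
  Y <- Y[, colSums(Y) > 0]
  fit <- zinbFit(Y, K = 2, maxIter = 10)
  expect_gt(distanceCorrelation(sc$W, getW(fit))$average, 0.8)
  # initialization lies below the final objective
  expect_gt(fit@trace[length(fit@trace)], fit@trace[1])
})
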