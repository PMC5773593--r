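# Model parameterization, likelihood, penalty, information criteria.

test_that("linear predictors assemble the regression blocks correctly", {
  # all parameters zero: mu = 1 everywhere
  m <- zinbModel(n = 4, J = 3, K = 2)
  expect_equal(getLogMu(m), matrix(0, 4, 3))
  expect_equal(getMu(m), matrix(1, 4, 3))
  # K = 0: no W alpha term
  m0 <- zinbModel(n = 3, J = 2, K = 0,
                  beta_mu = matrix(1:2, 1, 2),
                  gamma_mu = matrix(c(0.1, 0.2, 0.3), 1, 3))
  expect_equal(getLogMu(m0),
               matrix(1:2, 3, 2, byrow = TRUE) +
                 matrix(c(0.1, 0.2, 0.3), 3, 2))
  # random small instance against an explicit elementwise sum
  set.seed(5)
  n <- 3; J <- 2
  X <- cbind(1, rnorm(n)); V <- cbind(1, rnorm(J))
  m <- zinbModel(n = n, J = J, K = 1, X = X, V = V,
                 O_mu = matrix(rnorm(n * J), n, J),
                 W = matrix(rnorm(n), n, 1),
                 beta_mu = matrix(rnorm(2 * J), 2, J),
                 gamma_mu = matrix(rnorm(2 * n), 2, n),
                 alpha_mu = matrix(rnorm(J), 1, J))
  expected <- matrix(0, n, J)
  for (i in 1:n) for (j in 1:J) {
    expected[i, j] <- sum(X[i, ] * m@beta_mu[, j]) +
      sum(V[j, ] * m@gamma_mu[, i]) +
      sum(m@W[i, ] * m@alpha_mu[, j]) + m@O_mu[i, j]
  }
  expect_equal(getLogMu(m), expected)
})

test_that("restricting covariates per component works through column masks", {
  set.seed(6)
  n <- 5; J <- 4
  X <- cbind(1, rnorm(n))
  m <- zinbModel(n = n, J = J, K = 0, X = X,
                 which_X_mu = 1:2, which_X_pi = 1L,
                 beta_mu = matrix(rnorm(2 * J), 2, J),
                 beta_pi = matrix(rnorm(J), 1, J))
  expect_equal(getLogMu(m), X %*% m@beta_mu, ignore_attr = TRUE)
  expect_equal(dim(getBeta(m, "pi")), c(1L, J))
  expect_equal(getLogitPi(m), X[, 1, drop = FALSE] %*% m@beta_pi,
               ignore_attr = TRUE)
})

test_that("log-likelihood is the sum of entrywise ZINB log-PMFs", {
  # n = J = 1 equals a single PMF call
  m <- zinbModel(n = 1, J = 1, beta_mu = matrix(1), beta_pi = matrix(-0.5),
                 zeta = 0.3)
  Y <- matrix(3L, 1, 1)
  expect_equal(zinbLogLik(m, Y),
               zinbLogPmf(3, exp(1 + m@gamma_mu[1]), exp(0.3),
                          plogis(-0.5 + m@gamma_pi[1])))
  # brute-force double loop on a 4 x 3 instance
  s <- simCounts(4, 3, K = 1, seed = 9)
  mu <- getMu(s$model); pi <- getPi(s$model); th <- getTheta(s$model)
  ll <- 0
  for (i in 1:4) for (j in 1:3)
    ll <- ll + zinbLogPmf(s$Y[i, j], mu[i, j], th[j], pi[i, j])
  expect_equal(zinbLogLik(s$model, s$Y), ll)
})

test_that("duplicating a sample row doubles its likelihood contribution", {
  s <- simCounts(1, 5, K = 0, seed = 10)
  m2 <- zinbModel(n = 2, J = 5, K = 0,
                  beta_mu = s$model@beta_mu, beta_pi = s$model@beta_pi,
                  gamma_mu = cbind(s$model@gamma_mu, s$model@gamma_mu),
                  gamma_pi = cbind(s$model@gamma_pi, s$model@gamma_pi),
                  zeta = s$model@zeta)
  Y2 <- rbind(s$Y, s$Y)
  expect_equal(zinbLogLik(m2, Y2), 2 * zinbLogLik(s$model, s$Y))
})

test_that("penalty matches its term-by-term definition", {
  m <- zinbModel(n = 4, J = 3, K = 1)
  expect_equal(zinbPenalty(m), 0)          # all parameters zero
  # constant zeta contributes nothing
  m@zeta <- rep(2, 3)
  expect_equal(zinbPenalty(m), 0)
  # random parameters, epsilon = 1, intercept rows excluded by hand
  set.seed(12)
  n <- 2; J <- 2
  X <- cbind(1, rnorm(n)); V <- cbind(1, rnorm(J))
  m <- zinbModel(n = n, J = J, K = 1, X = X, V = V, epsilon = 1,
                 W = matrix(rnorm(n), n, 1),
                 beta_mu = matrix(rnorm(2 * J), 2, J),
                 beta_pi = matrix(rnorm(2 * J), 2, J),
                 gamma_mu = matrix(rnorm(2 * n), 2, n),
                 gamma_pi = matrix(rnorm(2 * n), 2, n),
                 alpha_mu = matrix(rnorm(J), 1, J),
                 alpha_pi = matrix(rnorm(J), 1, J),
                 zeta = rnorm(J))
  byHand <- 1 / J / 2 * (sum(m@beta_mu[2, ]^2) + sum(m@beta_pi[2, ]^2)) +
    1 / n / 2 * (sum(m@gamma_mu[2, ]^2) + sum(m@gamma_pi[2, ]^2)) +
    1 / n / 2 * sum(m@W^2) +
    1 / J / 2 * (sum(m@alpha_mu^2) + sum(m@alpha_pi^2)) +
    1 / 2 * var(m@zeta)
  expect_equal(zinbPenalty(m), byHand)
})

test_that("penalized log-likelihood is loglik minus penalty and responds to scale", {
  s <- fittableCounts(6, 5, K = 1, seed = 13)
  m <- s$model
  expect_equal(zinbPenalizedLogLik(m, s$Y),
               zinbLogLik(m, s$Y) - zinbPenalty(m))
  # with epsilon = 0 the penalty vanishes
  m0 <- m; m0@epsilon <- 0
  expect_equal(zinbPenalizedLogLik(m0, s$Y), zinbLogLik(m0, s$Y))
  # growing W with a compensating zero alpha leaves loglik fixed but
  # strictly lowers the objective
  mBig <- m
  mBig@W <- cbind(m@W, 1)
  mBig@alpha_mu <- rbind(m@alpha_mu, 0)
  mBig@alpha_pi <- rbind(m@alpha_pi, 0)
  expect_equal(zinbLogLik(mBig, s$Y), zinbLogLik(m, s$Y))
  expect_lt(zinbPenalizedLogLik(mBig, s$Y), zinbPenalizedLogLik(m, s$Y))
})

test_that("likelihood is invariant under invertible reparameterization of (W, alpha)", {
  s <- simCounts(6, 5, K = 2, seed = 14)
  m <- s$model
  ll <- zinbLogLik(m, s$Y)
  set.seed(15)
  # any invertible K x K change of basis leaves W alpha unchanged
  A <- matrix(rnorm(4), 2, 2) + diag(2)
  m2 <- m
  m2@W <- m@W %*% A
  m2@alpha_mu <- solve(A) %*% m@alpha_mu
  m2@alpha_pi <- solve(A) %*% m@alpha_pi
  expect_equal(zinbLogLik(m2, s$Y), ll, tolerance = 1e-10)
  # an orthogonal rotation additionally preserves the penalized objective
  th <- 0.7
  Q <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  m3 <- m
  m3@W <- m@W %*% Q
  m3@alpha_mu <- t(Q) %*% m@alpha_mu
  m3@alpha_pi <- t(Q) %*% m@alpha_pi
  expect_equal(zinbPenalizedLogLik(m3, s$Y), zinbPenalizedLogLik(m, s$Y),
               tolerance = 1e-10)
})

test_that("information criteria count parameters per the closed form", {
  m <- zinbModel(n = 100, J = 50, K = 2)
  expect_equal(numberParams(m), 100 + 200 + 200 + 200 + 50)  # 750
  mc <- zinbModel(n = 100, J = 50, K = 2, commonDispersion = TRUE)
  expect_equal(numberParams(mc), 701)
  # BIC - AIC = (ln n - 2) N for any fit
  s <- simCounts(8, 6, K = 1, seed = 16)
  expect_equal(zinbBIC(s$model, s$Y) - zinbAIC(s$model, s$Y),
               (log(8) - 2) * numberParams(s$model))
  # criteria use the unpenalized log-likelihood
  expect_equal(zinbAIC(s$model, s$Y),
               2 * numberParams(s$model) - 2 * zinbLogLik(s$model, s$Y))
})

test_that("dimension mismatches raise structured errors", {
  m <- zinbModel(n = 4, J = 3)
  expect_error(zinbLogLik(m, matrix(0L, 3, 3)), "4 x 3")
  expect_error(zinbLogLik(m, matrix(-1L, 4, 3)), "negative")
  expect_error(zinbLogLik(m, matrix(0.5, 4, 3)), "integer")
})

test_that("models serialize to text and back without loss", {
  s <- simCounts(5, 4, K = 2, seed = 17)
  d <- file.path(tempdir(), "zinb-model-bundle")
  writeZinbModel(s$model, d)
  m2 <- readZinbModel(d)
  expect_equal(m2@beta_mu, s$model@beta_mu, ignore_attr = TRUE)
  expect_equal(m2@W, s$model@W, ignore_attr = TRUE)
  expect_equal(m2@zeta, s$model@zeta)
  expect_equal(zinbLogLik(m2, s$Y), zinbLogLik(s$model, s$Y))
  unlink(d, recursive = TRUE)
})
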