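#' Simulate counts from a ZINB factor model
#'
#' Draws each entry from the model's ZINB distribution: a Bernoulli dropout
#' indicator with probability `pi_ij` and, when not dropped, a negative
#' binomial count with mean `mu_ij` and size `theta_j`.
#'
#' @param model a [ZinbModel-class] with parameters set.
#' @param seed integer seed for reproducibility.
#' @return list with the count matrix `counts`, the dropout indicator matrix
#'   `dropout`, and the `mu` and `pi` matrices used.
#' @export
zinbSim <- function(model, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nSamples(model); J <- nFeatures(model)
  mu <- getMu(model)
  pi <- getPi(model)
  theta <- matrix(getTheta(model), n, J, byrow = TRUE)
  drop <- matrix(stats::rbinom(n * J, 1, as.vector(pi)), n, J)
  nb <- matrix(stats::rnbinom(n * J, size = as.vector(theta),
                              mu = as.vector(mu)), n, J)
  counts <- ifelse(drop == 1, 0, nb)
  list(counts = counts, dropout = drop, mu = mu, pi = pi)
}

#' Rescale the cluster separation of a factor matrix
#'
#' Applies, per column of `W`, the affine transform
#' `W* = (1 - a) Wbar + a (1 - b) Wbar_c + a b W` with
#' `a = sqrt(TSS / (b^2 WSS + BSS))`, which scales the ratio of
#' within-cluster to between-cluster sums of squares by `b2 = b^2` while
#' keeping the overall mean and total sum of squares of each column
#' unchanged. `b2 = 1` is the identity; large `b2` blurs the clusters.
#'
#' @param W numeric matrix (`n x K`).
#' @param labels cluster assignment of the `n` rows.
#' @param b2 positive scaling of the within/between sum-of-squares ratio.
#' @return transformed matrix of the same dimensions.
#' @export
clusterStrengthTransform <- function(W, labels, b2) {
  W <- as.matrix(W)
  labels <- as.factor(labels)
  if (any(table(labels) == 0)) stop("empty cluster")
  if (b2 <= 0) stop("b2 must be positive")
  if (b2 == 1) return(W)          # a = b = 1: identity transform
  b <- sqrt(b2)
  out <- W
  for (k in seq_len(ncol(W))) {
    w <- W[, k]
    wbar <- mean(w)
    means <- tapply(w, labels, mean)
    wc <- means[as.character(labels)]
    WSS <- sum((w - wc)^2)
    BSS <- sum((wc - wbar)^2)
    if (BSS <= 0)
      stop("between-cluster sum of squares is zero; ratio undefined")
    a <- sqrt((WSS + BSS) / (b2 * WSS + BSS))
    out[, k] <- (1 - a) * wbar + a * (1 - b) * wc + a * b * w
  }
  out
}

#' Expected zero fraction of a model
#'
#' Mean over all entries of `pi + (1 - pi) (theta / (theta + mu))^theta`,
#' the marginal probability of observing a zero.
#'
#' @param model a [ZinbModel-class].
#' @param delta optional additive shift applied to the dropout linear
#'   predictor before evaluating.
#' @return scalar in `(0, 1)`.
#' @export
expectedZeroFraction <- function(model, delta = 0) {
  n <- nSamples(model); J <- nFeatures(model)
  mu <- getMu(model)
  eta <- getLogitPi(model) + delta
  pi <- stats::plogis(eta)
  theta <- matrix(getTheta(model), n, J, byrow = TRUE)
  lp0 <- theta * (log(theta) - log(theta + mu))
  mean(pi + (1 - pi) * exp(lp0))
}

#' Calibrate the dropout intercept to a target zero fraction
#'
#' Finds the additive shift `delta` on the dropout linear predictor
#' (equivalently, on the intercept row of `gamma_pi`) such that the expected
#' zero fraction of the model equals `target`. The expected zero fraction is
#' monotone increasing in `delta`, so the shift is found by bisection. The
#' shift changes the dropout rate only, not the underlying mean expression.
#'
#' @param model a [ZinbModel-class].
#' @param target desired zero fraction, strictly between the model's
#'   NB-only floor (all dropout off) and 1.
#' @param tol tolerance on the achieved expected zero fraction.
#' @return the scalar shift `delta`.
#' @export
calibrateZeroFraction <- function(model, target, tol = 1e-4) {
  if (target <= 0 || target >= 1) stop("target must be in (0, 1)")
  lo <- -100; hi <- 100
  flo <- expectedZeroFraction(model, lo)
  fhi <- expectedZeroFraction(model, hi)
  if (target < flo || target > fhi)
    stop(sprintf(
      "target %.3f outside the achievable range [%.4f, %.4f]",
      target, flo, fhi))
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    fm <- expectedZeroFraction(model, mid)
    if (abs(fm - target) < tol || (hi - lo) < 1e-10) return(mid)
    if (fm < target) lo <- mid else hi <- mid
  }
  mid
}

#' Synthetic template models for simulation studies
#'
#' Builds a fully parameterized intercept-only [ZinbModel-class] (with
#' `K = 2` latent factors and `C = 3` clusters by default) whose parameter
#' distributions imitate fits to real single-cell data sets, to serve as the
#' template of [simulateScenario()]. Two profiles are provided: `"deep"`
#' imitates plate-based read-count data (higher means, moderate dropout) and
#' `"shallow"` imitates sparser UMI data (lower means, more dropout). These
#' templates are synthetic stand-ins generated from documented parametric
#' choices; no real data are involved.
#'
#' @param J number of genes.
#' @param n number of template cells (used only to carry the `W` and
#'   `gamma` values that the scenario generator resamples from).
#' @param K number of latent factors.
#' @param C number of clusters built into the template `W`.
#' @param profile `"deep"` or `"shallow"`.
#' @param seed integer seed.
#' @return a [ZinbModel-class] with all parameters set and cluster labels in
#'   `attr(, "labels")`.
#' @export
syntheticTemplate <- function(J = 200, n = 300, K = 2, C = 3,
                              profile = c("deep", "shallow"), seed = 1) {
  profile <- match.arg(profile)
  set.seed(seed)
  prm <- switch(profile,
    deep = list(beta_mu_mean = 2.5, beta_mu_sd = 1.2,
                beta_pi_mean = -1.8, beta_pi_sd = 1.0,
                zeta_mean = log(2), zeta_sd = 0.4,
                alpha_sd = 0.6, gamma_sd = c(0.35, 0.8), gamma_cor = -0.4),
    shallow = list(beta_mu_mean = 1.2, beta_mu_sd = 1.4,
                   beta_pi_mean = -0.8, beta_pi_sd = 1.0,
                   zeta_mean = log(1), zeta_sd = 0.5,
                   alpha_sd = 0.6, gamma_sd = c(0.45, 0.9), gamma_cor = -0.4))
  labels <- rep(seq_len(C), length.out = n)
  centers <- matrix(stats::rnorm(C * K, 0, 1.2), C, K)
  W <- centers[labels, , drop = FALSE] +
    matrix(stats::rnorm(n * K, 0, 0.5), n, K)
  # correlated cell intercepts: library-size-like gamma_mu, dropout gamma_pi
  Sg <- diag(prm$gamma_sd) %*%
    matrix(c(1, prm$gamma_cor, prm$gamma_cor, 1), 2) %*% diag(prm$gamma_sd)
  G <- MASS::mvrnorm(n, mu = c(0, 0), Sigma = Sg)
  zinbModel(
    n = n, J = J, K = K,
    W = W,
    beta_mu = matrix(stats::rnorm(J, prm$beta_mu_mean, prm$beta_mu_sd), 1, J),
    beta_pi = matrix(stats::rnorm(J, prm$beta_pi_mean, prm$beta_pi_sd), 1, J),
    gamma_mu = matrix(G[, 1], 1, n),
    gamma_pi = matrix(G[, 2], 1, n),
    alpha_mu = matrix(stats::rnorm(K * J, 0, prm$alpha_sd), K, J),
    alpha_pi = matrix(stats::rnorm(K * J, 0, prm$alpha_sd), K, J),
    zeta = stats::rnorm(J, prm$zeta_mean, prm$zeta_sd)) -> model
  attr(model, "labels") <- labels
  model
}

#' Generate a simulation scenario from a template model
#'
#' Reproduces the model-based simulation design: (1) fit a `C`-component
#' full-covariance Gaussian mixture to the template's `W` (or accept mixture
#' parameters through `wMixture`), sample `n` new factor rows cluster by
#' cluster, and rescale the cluster separation with
#' [clusterStrengthTransform()]; (2) fit a single bivariate Gaussian to the
#' template's cell intercepts `(gamma_mu, gamma_pi)`, sample `n` new pairs,
#' and shift the dropout intercept with [calibrateZeroFraction()] so the
#' expected zero fraction matches `targetZeroFraction`; (3) keep the
#' template's `beta`, `alpha` and `zeta` (subsampled to `J` genes); (4) draw
#' counts with [zinbSim()].
#'
#' @param template a parameterized [ZinbModel-class], e.g. from
#'   [syntheticTemplate()] or a previous [zinbFit()].
#' @param n number of cells to simulate.
#' @param J number of genes (at most the template's; genes are subsampled).
#' @param targetZeroFraction desired expected zero fraction.
#' @param b2 within/between cluster sum-of-squares scaling (1 = as fitted).
#' @param C number of clusters.
#' @param seed integer seed.
#' @param wMixture optional list with `means` (`C x K`), `covariances`
#'   (list of `K x K`), `weights`; when supplied the mixture fit is skipped.
#' @return list with `counts`, `W` (true factors), `labels`, `mu`, `pi`,
#'   `model` (the generating [ZinbModel-class]), and scenario metadata.
#' @export
simulateScenario <- function(template, n, J = nFeatures(template),
                             targetZeroFraction = 0.5, b2 = 1, C = 3,
                             seed = 1, wMixture = NULL) {
  set.seed(seed)
  K <- nFactors(template)
  if (J > nFeatures(template)) stop("J exceeds the template's gene count")
  genes <- sort(sample.int(nFeatures(template), J))
  if (is.null(wMixture)) {
    mc <- mclust::Mclust(template@W, G = C, modelNames = "VVV",
                         verbose = FALSE)
    if (is.null(mc)) stop("Gaussian mixture fit on the template W failed")
    wMixture <- list(
      means = t(mc$parameters$mean),
      covariances = lapply(seq_len(C), function(c)
        mc$parameters$variance$sigma[, , c]),
      weights = mc$parameters$pro)
  }
  labels <- sample(seq_len(C), n, replace = TRUE, prob = wMixture$weights)
  # ensure no empty cluster so the separation transform is defined
  for (c in seq_len(C)) if (!any(labels == c)) labels[sample.int(n, 1)] <- c
  W <- matrix(0, n, K)
  for (c in seq_len(C)) {
    idx <- which(labels == c)
    W[idx, ] <- MASS::mvrnorm(length(idx), mu = wMixture$means[c, ],
                              Sigma = wMixture$covariances[[c]])
  }
  W <- clusterStrengthTransform(W, labels, b2)
  # bivariate Gaussian for the correlated cell intercepts
  Gt <- cbind(template@gamma_mu[1, ], template@gamma_pi[1, ])
  mu_g <- colMeans(Gt)
  Sigma_g <- stats::cov(Gt)
  Gn <- MASS::mvrnorm(n, mu = mu_g, Sigma = Sigma_g)
  model <- zinbModel(
    n = n, J = J, K = K,
    W = W,
    beta_mu = template@beta_mu[, genes, drop = FALSE],
    beta_pi = template@beta_pi[, genes, drop = FALSE],
    gamma_mu = matrix(Gn[, 1], 1, n),
    gamma_pi = matrix(Gn[, 2], 1, n),
    alpha_mu = template@alpha_mu[, genes, drop = FALSE],
    alpha_pi = template@alpha_pi[, genes, drop = FALSE],
    zeta = template@zeta[genes])
  delta <- calibrateZeroFraction(model, targetZeroFraction)
  model@gamma_pi[1, ] <- model@gamma_pi[1, ] + delta
  sim <- zinbSim(model, seed = seed + 1L)
  list(counts = sim$counts, W = W, labels = labels,
       mu = sim$mu, pi = sim$pi, model = model,
       scenario = list(n = n, J = J,
                       targetZeroFraction = targetZeroFraction,
                       b2 = b2, C = C, seed = seed, deltaPi = delta))
}

#' Genewise ZINB simulator with multiplicative technical effects
#'
#' Simulates counts gene by gene from a ZINB whose NB mean is the product of
#' a gene-level expression level, a log-normal gene-specific technical
#' effect, and a log-normal cell-specific (library-size-like) effect; the
#' zero-inflation probability is constant across cells within a gene, plus
#' an additive shift (clipped to `[0, 1]`) that raises the zero fraction.
#' `C` equal-size clusters are induced by multiplicative fold-changes on a
#' random subset of genes per cluster. The default hyperparameters give a
#' baseline zero fraction of about 0.4; shifts of 0.3 and 0.6 raise it to
#' roughly 0.6 and 0.8.
#'
#' @param n,J numbers of cells and genes.
#' @param C number of equal-size clusters.
#' @param zfracShift additive shift on the per-gene dropout probability.
#' @param seed integer seed.
#' @param hyperparams list overriding any of: `exprMeanLog`, `exprSdLog`
#'   (log-normal expression levels), `geneEffectSdLog`, `cellEffectSdLog`
#'   (technical effects), `thetaMeanLog`, `thetaSdLog` (genewise inverse
#'   dispersions), `piRange` (uniform range of per-gene dropout
#'   probabilities), `deFraction` (fraction of genes perturbed per cluster),
#'   `log2FoldChange` (magnitude of the cluster fold-changes).
#' @return list with `counts`, `labels`, `mu`, `pi`, `theta`, and the
#'   hyperparameters used.
#' @export
simulateGenewiseZinb <- function(n, J, C = 3, zfracShift = 0, seed = 1,
                                 hyperparams = list()) {
  # defaults solve E[pi] = 0.1 and E[(theta/(theta+mu))^theta] = 1/3, so the
  # expected zero fraction is 0.40 at shift 0, 0.60 at 0.3, 0.80 at 0.6
  hp <- utils::modifyList(list(
    exprMeanLog = 0.7, exprSdLog = 1.4,
    geneEffectSdLog = 0.4, cellEffectSdLog = 0.4,
    thetaMeanLog = log(2), thetaSdLog = 0.5,
    piRange = c(0.02, 0.18),
    deFraction = 0.1, log2FoldChange = 2), hyperparams)
  if (zfracShift < 0 || zfracShift > 1) stop("zfracShift must be in [0, 1]")
  if (any(hp$piRange < 0) || any(hp$piRange > 1) || hp$deFraction < 0 ||
      hp$deFraction > 1)
    stop("invalid hyperparameters")
  set.seed(seed)
  labels <- rep(seq_len(C), length.out = n)
  expr <- exp(stats::rnorm(J, hp$exprMeanLog, hp$exprSdLog))
  geneEffect <- exp(stats::rnorm(J, 0, hp$geneEffectSdLog))
  cellEffect <- exp(stats::rnorm(n, 0, hp$cellEffectSdLog))
  theta <- exp(stats::rnorm(J, hp$thetaMeanLog, hp$thetaSdLog))
  pi0 <- stats::runif(J, hp$piRange[1], hp$piRange[2])
  pi0 <- pmin(pmax(pi0 + zfracShift, 0), 1)
  # cluster structure: per cluster, a random gene subset gets a fold-change
  lfc <- matrix(0, C, J)
  nDE <- round(hp$deFraction * J)
  for (c in seq_len(C)) {
    de <- sample.int(J, nDE)
    lfc[c, de] <- sample(c(-1, 1), nDE, replace = TRUE) * hp$log2FoldChange
  }
  foldChange <- 2^lfc[labels, , drop = FALSE]
  mu <- outer(cellEffect, expr * geneEffect) * foldChange
  piMat <- matrix(pi0, n, J, byrow = TRUE)
  thetaMat <- matrix(theta, n, J, byrow = TRUE)
  drop <- matrix(stats::rbinom(n * J, 1, as.vector(piMat)), n, J)
  nb <- matrix(stats::rnbinom(n * J, size = as.vector(thetaMat),
                              mu = as.vector(mu)), n, J)
  counts <- ifelse(drop == 1, 0, nb)
  list(counts = counts, labels = labels, mu = mu, pi = piMat,
       theta = theta, hyperparams = hp, zfracShift = zfracShift)
}

#' Simulation design grids
#'
#' `zinbDesignGrid()` enumerates the model-based simulation design — 2
#' template profiles x 3 sample sizes (100, 1000, 10000) x 3 zero fractions
#' (0.25, 0.50, 0.75) x 3 cluster-separation levels (`b2` in 1, 5, 10) — 54
#' scenarios, each with `B = 10` replicate data sets. `genewiseDesignGrid()`
#' enumerates the genewise design — 3 sample sizes x 3 dropout shifts (0,
#' 0.3, 0.6) — 9 scenarios with 10 replicates each.
#'
#' @param B number of replicate data sets per scenario.
#' @return data.frame with one row per replicate data set and the scenario
#'   settings as columns.
#' @export
zinbDesignGrid <- function(B = 10) {
  g <- expand.grid(template = c("deep", "shallow"),
                   n = c(100, 1000, 10000),
                   zeroFraction = c(0.25, 0.50, 0.75),
                   b2 = c(1, 5, 10),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$scenario <- seq_len(nrow(g))
  out <- merge(g, data.frame(replicate = seq_len(B)))
  out[order(out$scenario, out$replicate), ]
}

#' @rdname zinbDesignGrid
#' @export
genewiseDesignGrid <- function(B = 10) {
  g <- expand.grid(n = c(100, 1000, 10000),
                   zfracShift = c(0, 0.3, 0.6),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$scenario <- seq_len(nrow(g))
  out <- merge(g, data.frame(replicate = seq_len(B)))
  out[order(out$scenario, out$replicate), ]
}
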