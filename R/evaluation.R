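#' Silhouette widths of a clustering
#'
#' For each sample `i`, `s_i = (b_i - a_i) / max(a_i, b_i)`, where `a_i` is
#' the mean distance from `i` to the other members of its own cluster and
#' `b_i` the smallest mean distance to any other cluster. Samples in
#' singleton clusters get `s_i = 0`.
#'
#' @param D symmetric `n x n` distance matrix (or a [stats::dist] object)
#'   with zero diagonal.
#' @param labels cluster assignment of length `n`; at least two clusters.
#' @return list with per-sample `widths`, the `average`, and the
#'   `clusterAverage` per cluster.
#' @export
silhouetteWidths <- function(D, labels) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  n <- nrow(D)
  if (length(labels) != n) stop("labels must match the distance matrix")
  labels <- as.factor(labels)
  if (nlevels(labels) < 2) stop("at least two clusters are required")
  idx <- split(seq_len(n), labels)
  sizes <- lengths(idx)
  # mean distance from every sample to every cluster
  md <- vapply(idx, function(ii) rowSums(D[, ii, drop = FALSE]) / length(ii),
               numeric(n))
  own <- as.integer(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    ci <- own[i]
    if (sizes[ci] == 1L) { s[i] <- 0; next }
    a <- md[i, ci] * sizes[ci] / (sizes[ci] - 1)  # exclude self (D[i,i] = 0)
    b <- min(md[i, -ci])
    s[i] <- (b - a) / max(a, b)
  }
  list(widths = s, average = mean(s),
       clusterAverage = tapply(s, labels, mean))
}

#' Pair-counting precision and recall between two clusterings
#'
#' Counts, over all `choose(n, 2)` pairs of samples, how many are clustered
#' together in both partitions (`YY`), only in the estimate (`NY`), only in
#' the reference (`YN`), or in neither (`NN`). Precision is
#' `YY / (YY + NY)` and recall `YY / (YY + YN)`, with the first partition as
#' the reference. When the estimate has no co-clustered pair (`YY + NY = 0`)
#' the precision is reported as 0 with `precisionDefined = FALSE`.
#'
#' @param ref,est two label vectors of equal length (`n >= 2`).
#' @return list with `precision`, `recall`, the pair `counts`, and
#'   `precisionDefined`.
#' @export
precisionRecall <- function(ref, est) {
  n <- length(ref)
  if (length(est) != n) stop("ref and est must have the same length")
  if (n < 2) stop("at least two samples are required")
  # pair counts via the contingency table (equivalent to enumerating pairs)
  tab <- table(ref, est)
  pairs <- function(x) sum(choose(x, 2))
  YY <- pairs(tab)
  refTogether <- pairs(rowSums(tab))
  estTogether <- pairs(colSums(tab))
  YN <- refTogether - YY
  NY <- estTogether - YY
  NN <- choose(n, 2) - YY - YN - NY
  precDefined <- (YY + NY) > 0
  list(precision = if (precDefined) YY / (YY + NY) else 0,
       recall = if (refTogether > 0) YY / (YY + YN) else 0,
       counts = c(YY = YY, NY = NY, YN = YN, NN = NN),
       precisionDefined = precDefined)
}

#' Correlation of pairwise distances between two embeddings
#'
#' Computes Euclidean distance matrices in the true and estimated
#' low-dimensional spaces and, for every sample, the correlation between its
#' two vectors of distances to all other samples. Samples whose distance
#' vector is constant in either space are excluded and flagged.
#'
#' @param W_true `n x K` true embedding.
#' @param W_est `n x K'` estimated embedding (same `n`; `K'` may differ).
#' @param method correlation type, `"pearson"` (default) or `"spearman"`.
#' @return list with per-sample `correlations` (NA for excluded samples),
#'   the `average` over defined samples, and `nExcluded`.
#' @export
distanceCorrelation <- function(W_true, W_est,
                                method = c("pearson", "spearman")) {
  method <- match.arg(method)
  n <- nrow(as.matrix(W_true))
  if (nrow(as.matrix(W_est)) != n) stop("embeddings must have the same rows")
  if (n < 3) stop("at least three samples are required")
  Dt <- as.matrix(stats::dist(W_true))
  De <- as.matrix(stats::dist(W_est))
  cors <- vapply(seq_len(n), function(i) {
    x <- Dt[i, -i]; y <- De[i, -i]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y, method = method)
  }, numeric(1))
  list(correlations = cors,
       average = mean(cors, na.rm = TRUE),
       nExcluded = sum(is.na(cors)))
}

#' Bias and mean squared error over simulation replicates
#'
#' For a true parameter (scalar, vector, or matrix) and `B` replicate
#' estimates, computes the per-element bias `mean(est_b - true)` and MSE
#' `mean((est_b - true)^2)`, plus their averages over all elements.
#'
#' @param true the true parameter value.
#' @param estimates list of `B` estimates with the same shape as `true`.
#' @return list with elementwise `bias` and `mse` and the flattened
#'   averages `biasMean` and `mseMean`.
#' @export
biasMSE <- function(true, estimates) {
  if (!is.list(estimates)) estimates <- list(estimates)
  B <- length(estimates)
  if (B < 1) stop("at least one replicate is required")
  for (e in estimates) {
    if (length(e) != length(true) || !identical(dim(e), dim(true)))
      stop("estimate shape does not match the true value")
  }
  devs <- lapply(estimates, function(e) e - true)
  bias <- Reduce(`+`, devs) / B
  mse <- Reduce(`+`, lapply(devs, function(d) d^2)) / B
  list(bias = bias, mse = mse,
       biasMean = mean(bias), mseMean = mean(mse))
}
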