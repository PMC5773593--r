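# Internal numerical helpers. Everything works on the log / logit scale so
# that dispersions spanning exp(+/-50) and extreme dropout logits stay finite.

# log(1 + exp(x)), stable for large |x|
.log1pexp <- function(x) {
  out <- x
  small <- x <= 18
  out[small] <- log1p(exp(x[small]))
  mid <- x > 18 & x <= 33.3
  out[mid] <- x[mid] + exp(-x[mid])
  out
}

# log(exp(a) + exp(b)), elementwise; tolerates -Inf in either argument
.logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  d <- -abs(a - b)
  out <- m + log1p(exp(d))
  inf <- is.infinite(m) & m < 0
  out[inf] <- -Inf
  out
}

.clamp <- function(x, lo = -50, hi = 50) pmin(pmax(x, lo), hi)

# logit with the +/-50 box used throughout for boundary probabilities
.logitClamped <- function(p, box = 50) {
  eta <- stats::qlogis(p)
  .clamp(eta, -box, box)
}

# columns of a design matrix that are unpenalized intercepts (constant, non-zero)
.interceptCols <- function(A) {
  if (is.null(A) || ncol(A) == 0L) return(logical(0))
  apply(A, 2L, function(x) {
    length(unique(x)) == 1L && x[1] != 0
  })
}

.checkCounts <- function(Y, arg = "Y") {
  if (!is.matrix(Y)) stop(arg, " must be a matrix", call. = FALSE)
  if (any(!is.finite(Y))) stop(arg, " contains non-finite entries", call. = FALSE)
  if (any(Y < 0)) stop(arg, " contains negative entries", call. = FALSE)
  if (any(Y != floor(Y))) stop(arg, " contains non-integer entries", call. = FALSE)
  invisible(TRUE)
}
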