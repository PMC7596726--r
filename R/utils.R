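#' Numerically stable inverse logit
#'
#' `expit(x) = 1 / (1 + exp(-x))`, evaluated so that arguments of very large
#' magnitude neither overflow nor return `NaN`.
#'
#' @param x Numeric vector.
#' @return Probabilities in `[0, 1]`.
#' @export
#' @examples
#' expit(c(-800, 0, 800))
expit <- function(x) {
  # plogis is overflow-safe in both tails
  stats::plogis(x)
}

# log(1 + exp(x)) without overflow; used by the logistic losses
log1pexp <- function(x) {
  out <- x
  lo <- x <= 18
  out[lo] <- log1p(exp(x[lo]))
  hi <- x > 18 & x <= 33.3
  out[hi] <- x[hi] + exp(-x[hi])
  out
}

#' Inverse-gamma random draws
#'
#' Shape/scale parameterization with density proportional to
#' `x^(-shape-1) exp(-scale/x)`, so `IG(1/2, 1/2)` is the prior that yields
#' the conjugate posterior `IG((N_c+1)/2, (SSE+1)/2)` in the Bayesian linear
#' imputation model.
#'
#' @param n Number of draws.
#' @param shape,scale Positive parameters.
#' @return Numeric vector of positive draws.
#' @export
rinvgamma <- function(n, shape, scale) {
  stopifnot(shape > 0, scale > 0)
  1 / stats::rgamma(n, shape = shape, rate = scale)
}

# One multivariate normal draw mean + chol(Sigma)' z; tolerates PSD Sigma
# (including the all-zero matrix used in degenerate tests) via an eigen
# fallback when the Cholesky factorization fails.
rmvnorm1 <- function(mean, sigma) {
  d <- length(mean)
  if (all(sigma == 0)) return(as.numeric(mean))
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (!is.null(ch)) {
    return(as.numeric(mean + drop(crossprod(ch, stats::rnorm(d)))))
  }
  eg <- eigen(sigma, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  as.numeric(mean + eg$vectors %*% (sqrt(lam) * stats::rnorm(d)))
}

# Symmetric positive-definite solve; returns the inverse of a + lambda*I
# style matrices that are SPD by construction.
spd_inv <- function(a) {
  chol2inv(chol(a))
}

#' Derive a reproducible child seed from a master seed and counters
#'
#' Counter-based stream derivation: simulation replicates, methods, and
#' imputation indices get independent, order-insensitive seeds from one
#' master seed, so methods can be compared on identical generated data
#' without coupling their imputation noise. The result is always a valid
#' 32-bit seed in `[1, 2^31 - 2]`.
#'
#' @param seed Master seed (integer).
#' @param ... Integer counters (replicate index, method code, ...).
#' @return Integer seed.
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483629 # largest prime < 2^31
  h <- as.double(seed %% m)
  for (x in c(...)) {
    h <- (h * 1000003 + as.double(x) + 12345) %% m
  }
  as.integer(h %% (m - 2) + 1)
}
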