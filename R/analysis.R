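#' Fit the analysis model on one completed dataset
#'
#' Ordinary least squares for the linear analysis model
#' `y = theta_0 + theta_1 x_1 + ... + theta_p x_p + eps` on the data
#' pooled across sites. Because the least-squares solution depends on the
#' data only through `X'X` and `X'y`, fitting on pooled rows and
#' aggregating per-site sufficient statistics give the identical estimate;
#' the analysis model is always fitted this way, the distributed question
#' concerns only the imputation step.
#'
#' @param completed A completed [partitioned_dataset] (no missing cells),
#'   or a list with pooled `x` and `y`.
#' @return Object of class `analysis_fit`: `theta_hat` (length `p + 1`),
#'   `theta_cov` (`sigma2_hat * (X'X)^{-1}`), and `sigma2_hat`
#'   (`RSS / (N - p - 1)`).
#' @export
fit_analysis <- function(completed) {
  if (inherits(completed, "partitioned_dataset")) {
    X <- do.call(rbind, lapply(completed$sites, `[[`, "X"))
    y <- unlist(lapply(completed$sites, `[[`, "y"), use.names = FALSE)
  } else {
    X <- cbind(1, as.matrix(completed$x), deparse.level = 0)
    y <- completed$y
  }
  if (anyNA(X)) stop("the completed dataset still has missing cells")
  n <- nrow(X)
  d <- ncol(X)
  if (qr(X)$rank < d) stop("singular analysis design")
  xtx_inv <- tryCatch(spd_inv(crossprod(X)),
                      error = function(e) stop("singular analysis design"))
  theta <- drop(xtx_inv %*% crossprod(X, y))
  rss <- sum((y - drop(X %*% theta))^2)
  sigma2 <- rss / (n - d)
  structure(
    list(theta_hat = theta, theta_cov = sigma2 * xtx_inv,
         sigma2_hat = sigma2, n = n),
    class = "analysis_fit"
  )
}

#' Combine per-imputation fits by Rubin's rule
#'
#' Point estimate: `theta_hat = (1/M) sum_m theta_hat_m`. Variance, as
#' printed in the source formulas:
#' `Var = (1/M) sum_m Var_m + (1/(M-1)) sum_m (theta_m - theta)(theta_m -
#' theta)'`. The classical Rubin variance inflates the between-imputation
#' component by `(1 + 1/M)`; set `classical = TRUE` for that form.
#'
#' @param fits List of [analysis_fit] objects, one per imputed dataset.
#' @param classical Use the `(1 + 1/M)` between-variance inflation.
#' @return Object of class `pooled_result`: `theta_hat`, `theta_cov`, `M`,
#'   plus the `within` and `between` components. With `M = 1` the between
#'   term is undefined; the within-variance is returned and flagged.
#' @export
rubin_pool <- function(fits, classical = FALSE) {
  M <- length(fits)
  stopifnot(M >= 1L)
  d <- length(fits[[1L]]$theta_hat)
  thetas <- vapply(fits, `[[`, numeric(d), "theta_hat")
  thetas <- matrix(thetas, nrow = d)
  theta <- rowMeans(thetas)
  within <- Reduce(`+`, lapply(fits, `[[`, "theta_cov")) / M
  if (M == 1L) {
    warning("M = 1: between-imputation variance unavailable; returning within-variance only")
    between <- matrix(0, d, d)
  } else {
    dev <- thetas - theta
    between <- tcrossprod(dev) / (M - 1)
  }
  cov <- within + if (classical) (1 + 1 / M) * between else between
  structure(
    list(theta_hat = theta, theta_cov = cov, M = M,
         within = within, between = between, classical = classical),
    class = "pooled_result"
  )
}

#' Coefficient table with normal-approximation intervals
#'
#' @param pooled A [pooled_result].
#' @param level Confidence level (default 0.95).
#' @return `data.frame` with columns `term`, `estimate`, `variance`,
#'   `ci_low`, `ci_high` — the forest-plot input format.
#' @export
coef_table <- function(pooled, level = 0.95) {
  est <- pooled$theta_hat
  v <- diag(pooled$theta_cov)
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(
    term = c("(Intercept)", paste0("x", seq_len(length(est) - 1L))),
    estimate = est,
    variance = v,
    ci_low = est - z * sqrt(v),
    ci_high = est + z * sqrt(v)
  )
}

#' @export
print.pooled_result <- function(x, ...) {
  cat(sprintf("Rubin-pooled estimate over M = %d imputations%s\n", x$M,
              if (x$classical) " (classical variance)" else ""))
  print(coef_table(x), row.names = FALSE, digits = 4)
  invisible(x)
}
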