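#' Define one imputation task
#'
#' An imputation task names the incomplete covariate `X_j` to impute, the
#' imputation-model family, and the ridge penalty. The imputation model
#' regresses `X_j` on the outcome and the remaining covariates, with the
#' fixed predictor ordering `Z = [1, y, x_1, ..., x_p excluding x_j]`
#' (ascending covariate index), so parameter vectors are unambiguous across
#' sites and back-ends.
#'
#' For a continuous target the model is Bayesian linear regression with
#' priors `tau^2 ~ IG(1/2, 1/2)` and `alpha | tau^2 ~ N(0, tau^2 I /
#' lambda)`. For a binary target it is Bayesian logistic regression with
#' prior `alpha ~ N(0, I / lambda)`, fitted by MAP with a Gaussian
#' approximation to the posterior. `lambda` is kept small so the
#' regularization bias is negligible; it mainly guards against singular
#' designs and separation at small sites.
#'
#' @param target Covariate index `j` in `1..p`.
#' @param family `"gaussian"` (continuous `X_j`) or `"binomial"` (binary).
#' @param lambda Ridge penalty, `> 0`. Default `1e-4`.
#' @return Object of class `imputation_task`.
#' @export
imputation_task <- function(target, family = c("gaussian", "binomial"),
                            lambda = 1e-4) {
  family <- match.arg(family)
  stopifnot(target >= 1L, lambda > 0)
  structure(list(j = as.integer(target), family = family, lambda = lambda),
            class = "imputation_task")
}

#' Build the imputation design for one site and task
#'
#' Splits a site's rows by the missingness of the target variable and
#' assembles the predictor matrix `Z = [1, y, other covariates]`. Rows with
#' the target observed form the fitting set (`Z_c`, `target_c`); rows with
#' the target missing form the imputation set (`Z_miss`). Within chained
#' equations the other covariates hold their current imputed values and are
#' treated as observed, which is why only the target's missingness matters
#' here; in the univariate missing-data pattern the predictors are fully
#' observed by construction.
#'
#' @param site A [site_data] (its `X` must have no `NA` outside the target
#'   column).
#' @param task An [imputation_task].
#' @return List with `Z_c`, `target_c`, `Z_miss`, `idx_miss` (row indices
#'   of the missing target cells), and `n_c` (fitting-set size). Either
#'   part may be empty.
#' @export
build_task_design <- function(site, task) {
  j <- task$j
  miss <- site$mask[, j]
  Z <- cbind(site$X[, 1L, drop = FALSE], site$y,
             site$X[, -c(1L, j + 1L), drop = FALSE], deparse.level = 0)
  dimnames(Z) <- NULL
  if (anyNA(Z)) {
    stop("predictors for target ", j, " contain missing values; ",
         "fill them first (chained equations) or use a univariate pattern")
  }
  list(
    Z_c = Z[!miss, , drop = FALSE],
    target_c = site$X[!miss, j + 1L],
    Z_miss = Z[miss, , drop = FALSE],
    idx_miss = which(miss),
    n_c = sum(!miss)
  )
}

#' Local ridge / Bayesian linear fit
#'
#' Solves the penalized normal equations
#' `alpha_hat = (Z_c' Z_c + lambda I)^{-1} Z_c' target_c` and returns the
#' pieces every distributed back-end consumes: the point estimate, the
#' inverted precision `(Z_c' Z_c + lambda I)^{-1}`, the residual sum of
#' squares `sse = ||target_c - Z_c alpha_hat||^2`, and the raw sufficient
#' statistics (`gram = Z_c'Z_c`, `moment = Z_c'target_c`,
#' `target_ss = target_c'target_c`) that the sufficient-information
#' back-end gathers.
#'
#' @param Z_c Predictor matrix for rows with the target observed.
#' @param target_c Observed target values.
#' @param lambda Ridge penalty (`> 0`, or `0` with a nonsingular design).
#' @return Object of class `local_fit`.
#' @export
local_linear_fit <- function(Z_c, target_c, lambda) {
  d <- ncol(Z_c)
  gram <- crossprod(Z_c)
  moment <- drop(crossprod(Z_c, target_c))
  a <- gram + diag(lambda, d)
  precision_inv <- tryCatch(spd_inv(a), error = function(e) {
    stop("singular local system; increase lambda (", conditionMessage(e), ")")
  })
  alpha_hat <- drop(precision_inv %*% moment)
  resid <- target_c - drop(Z_c %*% alpha_hat)
  structure(
    list(
      alpha_hat = alpha_hat,
      precision_inv = precision_inv,
      sse = sum(resid^2),
      n_c_local = nrow(Z_c),
      gram = gram,
      moment = moment,
      target_ss = sum(target_c^2),
      family = "gaussian",
      converged = TRUE
    ),
    class = "local_fit"
  )
}

# Penalized Bernoulli negative log-likelihood, gradient, Hessian
logistic_obj <- function(alpha, Z, x, lambda) {
  eta <- drop(Z %*% alpha)
  sum(log1pexp(eta)) - sum(x * eta) + lambda / 2 * sum(alpha^2)
}
logistic_grad <- function(alpha, Z, x, lambda) {
  eta <- drop(Z %*% alpha)
  drop(crossprod(Z, expit(eta) - x)) + lambda * alpha
}
logistic_hess <- function(alpha, Z, lambda) {
  eta <- drop(Z %*% alpha)
  w <- expit(eta) * (1 - expit(eta))
  crossprod(Z, Z * w) + diag(lambda, ncol(Z))
}

#' Local penalized logistic MAP fit
#'
#' Maximizes the Bernoulli log-likelihood penalized by
#' `-(lambda/2)||alpha||^2` with damped Newton iterations (unit step,
#' halved until the objective does not increase). Convergence is declared
#' when `max|gradient| < tol` or the relative parameter change drops below
#' `1e-10`. The returned `precision_inv` is the Gaussian posterior
#' covariance approximation `(Z_c' W_c Z_c + lambda I)^{-1}` with
#' `w_ii = expit(z_i'alpha)(1 - expit(z_i'alpha))` at the MAP.
#'
#' @inheritParams local_linear_fit
#' @param tol Gradient sup-norm tolerance (default `1e-8`).
#' @param maxit Maximum Newton iterations (default 50).
#' @return Object of class `local_fit` (field `sse` is `NA` for this
#'   family). Non-convergence raises an error carrying diagnostics.
#' @export
local_logistic_map <- function(Z_c, target_c, lambda, tol = 1e-8, maxit = 50L) {
  if (!all(target_c %in% c(0, 1))) stop("binomial target must be 0/1")
  d <- ncol(Z_c)
  alpha <- numeric(d)
  f <- logistic_obj(alpha, Z_c, target_c, lambda)
  converged <- FALSE
  iter <- 0L
  while (iter < maxit) {
    iter <- iter + 1L
    g <- logistic_grad(alpha, Z_c, target_c, lambda)
    if (max(abs(g)) < tol) {
      converged <- TRUE
      break
    }
    h <- logistic_hess(alpha, Z_c, lambda)
    dir <- -drop(solve(h, g))
    s <- 1
    repeat {
      cand <- alpha + s * dir
      fc <- logistic_obj(cand, Z_c, target_c, lambda)
      if (fc < f || s < 1e-10) break
      s <- s / 2
    }
    rel <- sqrt(sum((s * dir)^2)) / max(sqrt(sum(alpha^2)), 1e-12)
    alpha <- cand
    f <- fc
    if (rel < 1e-10) {
      converged <- max(abs(logistic_grad(alpha, Z_c, target_c, lambda))) < sqrt(tol)
      break
    }
  }
  if (!converged) {
    g <- logistic_grad(alpha, Z_c, target_c, lambda)
    if (max(abs(g)) < tol) converged <- TRUE
  }
  if (!converged) {
    stop(sprintf(
      "logistic MAP did not converge in %d iterations (|grad|_inf = %.3e, n_c = %d)",
      maxit, max(abs(logistic_grad(alpha, Z_c, target_c, lambda))), nrow(Z_c)
    ))
  }
  structure(
    list(
      alpha_hat = alpha,
      precision_inv = spd_inv(logistic_hess(alpha, Z_c, lambda)),
      sse = NA_real_,
      n_c_local = nrow(Z_c),
      gram = NULL, moment = NULL, target_ss = NULL,
      family = "binomial",
      converged = TRUE,
      iterations = iter
    ),
    class = "local_fit"
  )
}

#' Global imputation posterior
#'
#' Container for the fitted imputation-model parameters produced by any
#' back-end. For the gaussian family the sampling law is
#' `tau^2 ~ IG(tau2_shape, tau2_scale)` followed by
#' `alpha ~ N(alpha_hat, tau^2 * alpha_cov_base)`; for the binomial family
#' `alpha ~ N(alpha_hat, alpha_cov_base)` with no dispersion parameter.
#'
#' @param family `"gaussian"` or `"binomial"`.
#' @param alpha_hat Point estimate, length `p + 1`.
#' @param alpha_cov_base Symmetric PSD matrix (per-`tau^2` covariance for
#'   gaussian, covariance for binomial).
#' @param tau2_shape,tau2_scale Inverse-gamma parameters (gaussian only).
#' @param n_c_total Pooled complete-case count behind the fit.
#' @return Object of class `global_posterior`.
#' @export
global_posterior <- function(family, alpha_hat, alpha_cov_base,
                             tau2_shape = NA_real_, tau2_scale = NA_real_,
                             n_c_total = NA_integer_) {
  if (family == "gaussian") stopifnot(tau2_shape > 0, tau2_scale > 0)
  structure(
    list(family = family, alpha_hat = alpha_hat,
         alpha_cov_base = alpha_cov_base,
         tau2_shape = tau2_shape, tau2_scale = tau2_scale,
         n_c_total = n_c_total),
    class = "global_posterior"
  )
}

#' Draw imputation-model parameters from a fitted posterior
#'
#' Gaussian family: for each `m`, `tau^2_m ~ IG(shape, scale)` then
#' `alpha_m ~ N(alpha_hat, tau^2_m * alpha_cov_base)`. Binomial family:
#' `alpha_m ~ N(alpha_hat, alpha_cov_base)`. Draws are independent across
#' `m` and consume the current RNG stream in the order
#' `(tau^2_1, alpha_1, tau^2_2, alpha_2, ...)`.
#'
#' @param post A [global_posterior].
#' @param M Number of draws, `>= 1`.
#' @return List of `M` draws, each a list `(m, tau2, alpha)` (`tau2` is
#'   `NA` for binomial).
#' @export
sample_posterior <- function(post, M) {
  stopifnot(M >= 1L)
  lapply(seq_len(M), function(m) {
    if (post$family == "gaussian") {
      tau2 <- rinvgamma(1L, post$tau2_shape, post$tau2_scale)
      alpha <- rmvnorm1(post$alpha_hat, tau2 * post$alpha_cov_base)
    } else {
      tau2 <- NA_real_
      alpha <- rmvnorm1(post$alpha_hat, post$alpha_cov_base)
    }
    list(m = m, tau2 = tau2, alpha = alpha)
  })
}

#' Impute one site's missing target cells from one parameter draw
#'
#' Gaussian: missing `x_ij <- z_i'alpha + N(0, tau^2)` noise. Binomial:
#' missing `x_ij ~ Bernoulli(expit(z_i'alpha))`. Observed cells are never
#' touched; the returned copy has no missing values left in the target
#' column (its `mask` is retained as the record of which cells were
#' imputed).
#'
#' @param site A [site_data].
#' @param task An [imputation_task].
#' @param draw One element of [sample_posterior()]'s result.
#' @return A completed copy of `site`.
#' @export
impute_with_draw <- function(site, task, draw) {
  des <- build_task_design(site, task)
  if (length(des$idx_miss) == 0L) return(site)
  eta <- drop(des$Z_miss %*% draw$alpha)
  vals <- if (task$family == "gaussian") {
    eta + stats::rnorm(length(eta), 0, sqrt(draw$tau2))
  } else {
    stats::rbinom(length(eta), 1L, expit(eta))
  }
  site$X[des$idx_miss, task$j + 1L] <- vals
  site
}
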