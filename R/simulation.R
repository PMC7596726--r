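#' Generative scenario specifications
#'
#' The three benchmark scenarios share the linear analysis model
#' `Y = theta_0 + sum_j theta_j X_j + eps`, `eps ~ N(0, 1)`, with every
#' `theta_j = 1`:
#'
#' * **Scenario 1** (`p = 2`, continuous target): `X2 ~ U(-3, 3)`,
#'   `X1 | X2 ~ N(0.2 - 0.5 X2, 1)`; `X1` is missing with probability
#'   `expit(0.3 - 0.2 Y + 0.1 X2)`, about 50% marginally.
#' * **Scenario 2** (`p = 2`, binary target): as scenario 1 except
#'   `X1 | X2 ~ Bernoulli(expit(0.2 - 0.5 X2))`.
#' * **Scenario 3** (`p = 5`, general pattern): `X4, X5` iid `N(0, 1)`;
#'   `(X1, X2, X3) | X4, X5 ~ N(mu 1, Sigma)` with
#'   `mu = 0.3 - 0.3 X4 - 0.1 X5`, unit variances and 0.5 covariances;
#'   `X1`–`X3` go missing via three logistic models in `(Y, X4, X5)`,
#'   about 20% each.
#'
#' @param id Scenario number, 1–3.
#' @param sigma2 Error variance of the outcome model. All scenarios state
#'   `sigma2 = 1`; exposed as an override for sensitivity analyses (see
#'   the methods vignette for why one might set `sigma2 = 4` in
#'   scenario 2).
#' @return Object of class `scenario_spec` with fields `id`, `p`,
#'   `theta0` (all-ones, length `p + 1`), `sigma2`, and `family` of the
#'   incomplete variable(s).
#' @export
scenario_spec <- function(id, sigma2 = 1) {
  id <- as.integer(id)
  stopifnot(id %in% 1:3, sigma2 >= 0)
  p <- if (id == 3L) 5L else 2L
  structure(
    list(id = id, p = p, theta0 = rep(1, p + 1L), sigma2 = sigma2,
         family = if (id == 2L) "binomial" else "gaussian",
         targets = if (id == 3L) 1:3 else 1L),
    class = "scenario_spec"
  )
}

#' Generate complete data from a scenario
#'
#' Draws `N` rows from the scenario's covariate law and the linear outcome
#' model, before any missingness is applied.
#'
#' @param spec A [scenario_spec].
#' @param N Number of rows.
#' @return List with covariate matrix `x` (`N x p`) and outcome `y`.
#' @export
gen_scenario <- function(spec, N) {
  stopifnot(N >= 1L)
  if (spec$id %in% c(1L, 2L)) {
    x2 <- stats::runif(N, -3, 3)
    x1 <- if (spec$id == 1L) {
      stats::rnorm(N, 0.2 - 0.5 * x2, 1)
    } else {
      stats::rbinom(N, 1L, expit(0.2 - 0.5 * x2))
    }
    x <- cbind(x1, x2, deparse.level = 0)
  } else {
    x4 <- stats::rnorm(N)
    x5 <- stats::rnorm(N)
    mu <- 0.3 - 0.3 * x4 - 0.1 * x5
    sig <- matrix(0.5, 3, 3)
    diag(sig) <- 1
    x123 <- matrix(stats::rnorm(3L * N), N, 3L) %*% chol(sig) + mu
    x <- cbind(x123, x4, x5, deparse.level = 0)
  }
  colnames(x) <- NULL
  y <- 1 + rowSums(x) + stats::rnorm(N, 0, sqrt(spec$sigma2))
  list(x = x, y = y)
}

#' Apply the scenario's missing-at-random mechanism
#'
#' Independent Bernoulli missingness per row and incomplete variable, with
#' the scenario's logistic models. The linear predictors involve only `Y`
#' and fully observed covariates, so the mechanism is MAR.
#'
#' @param spec A [scenario_spec].
#' @param x,y Complete data from [gen_scenario()].
#' @return Logical `N x p` mask, `TRUE` = missing.
#' @export
apply_missingness <- function(spec, x, y) {
  N <- length(y)
  mask <- matrix(FALSE, N, spec$p)
  if (spec$id %in% c(1L, 2L)) {
    pr <- expit(0.3 - 0.2 * y + 0.1 * x[, 2L])
    mask[, 1L] <- stats::rbinom(N, 1L, pr) == 1L
  } else {
    lp <- cbind(
      -1.0 - 0.4 * y - 0.1 * x[, 4L] - 0.2 * x[, 5L],
      -0.8 - 0.6 * y + 0.2 * x[, 4L] + 0.4 * x[, 5L],
      -0.8 - 1.0 * y + 0.4 * x[, 4L] + 0.3 * x[, 5L]
    )
    for (j in 1:3) {
      mask[, j] <- stats::rbinom(N, 1L, expit(lp[, j])) == 1L
    }
  }
  mask
}

# bare OLS coefficient vector, used by the CD and CC reference analyses
ols_theta <- function(x, y) {
  fit <- stats::lm.fit(cbind(1, x, deparse.level = 0), y)
  if (any(is.na(fit$coefficients))) stop("singular analysis design")
  unname(fit$coefficients)
}

sim_methods <- c("CD", "CC", "iMI", "avgmMI", "cslMI", "siMI",
                 "iMICE", "avgmMICE", "cslMICE", "siMICE")

#' Run a Monte-Carlo simulation study
#'
#' For each replicate: generate complete data from the scenario, draw the
#' missingness mask, allocate rows to sites per the `(type, K, N)`
#' allocation, run the requested method, and record the estimated analysis
#' coefficients and the communication count. `"CD"` fits on the complete
#' data before masking; `"CC"` fits on the pooled complete cases; the MI
#' and MICE methods impute, fit each completed dataset, and pool by
#' Rubin's rule.
#'
#' Reported metrics over replicates, with `theta_0` the truth and
#' Euclidean norms over the full coefficient vector (intercept included):
#' `Bias = ||E theta - theta_0||`, `SD = sqrt(E ||theta - E theta||^2)`,
#' `rMSE = sqrt(E ||theta - theta_0||^2)`, so `rMSE^2 = Bias^2 + SD^2`.
#'
#' Reproducibility: replicate `r` draws its data from a seed derived from
#' `(seed, r)` — identical across methods so methods are compared on the
#' same datasets — and its imputation noise from `(seed, r, method)`, so
#' no draws are coupled between methods. Replicates in which the method
#' fails (e.g. surrogate-likelihood instability at small sites) are
#' counted and excluded from the summaries with a warning.
#'
#' @param scenario Scenario id 1–3 or a [scenario_spec].
#' @param type Allocation type `"U"` or `"E"`.
#' @param K Number of sites.
#' @param N Total sample size.
#' @param method One of `"CD"`, `"CC"`, `"iMI"`, `"avgmMI"`, `"cslMI"`,
#'   `"siMI"`, `"iMICE"`, `"avgmMICE"`, `"cslMICE"`, `"siMICE"`.
#' @param M Imputations per replicate (default 20).
#' @param R Monte-Carlo replicates (default 1000).
#' @param seed Master seed.
#' @param lambda Ridge penalty for the imputation models.
#' @param central Central-site rule for the surrogate-likelihood methods.
#' @param schedule [mice_schedule] for the MICE methods (default
#'   `mice_schedule(M)`).
#' @return Object of class `study_result` with `bias`, `sd`, `rmse`, `com`
#'   (mean over replicates), `failures`, and the per-replicate coefficient
#'   archive `theta` (`R x (p+1)`, `NA` rows for failures).
#' @export
run_study <- function(scenario, type = "E", K = 1L, N = 250L,
                      method = "siMI", M = 20L, R = 1000L, seed = 1L,
                      lambda = 1e-4, central = "largest", schedule = NULL) {
  spec <- if (inherits(scenario, "scenario_spec")) scenario else scenario_spec(scenario)
  method <- match.arg(method, sim_methods)
  mcode <- match(method, sim_methods)
  is_mice <- grepl("MICE$", method)
  if (is_mice && is.null(schedule)) schedule <- mice_schedule(M = M)
  alloc <- site_allocation(type, K, N)

  d <- spec$p + 1L
  thetas <- matrix(NA_real_, R, d)
  coms <- rep(NA_real_, R)
  failures <- 0L

  for (r in seq_len(R)) {
    set.seed(derive_seed(seed, r))
    dat <- gen_scenario(spec, N)
    mask <- apply_missingness(spec, dat$x, dat$y)
    res <- tryCatch({
      if (method == "CD") {
        list(theta = ols_theta(dat$x, dat$y), com = 0)
      } else if (method == "CC") {
        keep <- rowSums(mask) == 0L
        list(theta = ols_theta(dat$x[keep, , drop = FALSE], dat$y[keep]),
             com = 0)
      } else {
        set.seed(derive_seed(seed, r, 100L + mcode))
        fed <- fed_partition(dat$x, dat$y, mask, alloc)
        run <- if (is_mice) {
          tasks <- lapply(spec$targets, imputation_task,
                          family = spec$family, lambda = lambda)
          run_mice(fed, tasks, method = method, schedule = schedule,
                   central = central)
        } else {
          task <- imputation_task(spec$targets[[1L]], spec$family, lambda)
          run_mi(fed, task, method = method, M = M, central = central)
        }
        fits <- lapply(run$completed, fit_analysis)
        list(theta = rubin_pool(fits)$theta_hat, com = run$ledger$com)
      }
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- failures + 1L
    } else {
      thetas[r, ] <- res$theta
      coms[r] <- res$com
    }
  }

  ok <- which(!is.na(thetas[, 1L]))
  if (failures > 0L) {
    warning(sprintf("%s: %d of %d replicates failed and were excluded",
                    method, failures, R))
  }
  if (length(ok) == 0L) stop("all replicates failed")
  th <- thetas[ok, , drop = FALSE]
  center <- colMeans(th)
  bias <- sqrt(sum((center - spec$theta0)^2))
  sdv <- sqrt(mean(rowSums((th - rep(center, each = nrow(th)))^2)))
  rmse <- sqrt(mean(rowSums((th - rep(spec$theta0, each = nrow(th)))^2)))

  structure(
    list(scenario = spec$id, type = type, K = K, N = N, method = method,
         M = M, R = R, bias = bias, sd = sdv, rmse = rmse,
         com = mean(coms[ok]), failures = failures, theta = thetas,
         seed = seed),
    class = "study_result"
  )
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf(
    "scenario %d | type %s, K = %d, N = %d | %s (R = %d)\n",
    x$scenario, x$type, x$K, x$N, x$method, x$R
  ))
  cat(sprintf("  Bias = %.3f  SD = %.3f  rMSE = %.3f  Com = %.1f  failures = %d\n",
              x$bias, x$sd, x$rmse, x$com, x$failures))
  invisible(x)
}

#' Metrics from a coefficient archive
#'
#' Recomputes Bias/SD/rMSE from a replicate-by-coefficient matrix, used to
#' check the identity `rMSE^2 = Bias^2 + SD^2`.
#'
#' @param theta Numeric matrix, one replicate per row (`NA` rows dropped).
#' @param theta0 True coefficient vector.
#' @return Named numeric vector `(bias, sd, rmse)`.
#' @export
study_metrics <- function(theta, theta0) {
  theta <- theta[stats::complete.cases(theta), , drop = FALSE]
  center <- colMeans(theta)
  c(bias = sqrt(sum((center - theta0)^2)),
    sd = sqrt(mean(rowSums((theta - rep(center, each = nrow(theta)))^2))),
    rmse = sqrt(mean(rowSums((theta - rep(theta0, each = nrow(theta)))^2))))
}
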