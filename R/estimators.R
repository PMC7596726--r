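#' @title Distributed back-ends for fitting the imputation model
#' @name distributed-backends
#' @description
#' Four back-ends turn per-site information into a [global_posterior]:
#'
#' * [fit_independent()] — every site fits on its own complete cases; no
#'   communication (the iMI back-end).
#' * [fit_si()] — sufficient-information aggregation; reproduces the
#'   pooled-data fit exactly. One gather for a linear model; `2T` rounds
#'   for a logistic model fitted by `T` distributed Newton iterations.
#' * [fit_avgm()] — complete-case-weighted average of per-site estimates;
#'   one gather.
#' * [fit_csl()] — surrogate-likelihood estimator using the central site's
#'   curvature and one pooled-gradient round; one broadcast + one gather.
#'
#' All losses follow one convention: `L` is the average negative penalized
#' log-likelihood over the pooled complete cases, `L_k` the per-site
#' average, and the ridge penalty enters every site's local loss as
#' `(lambda / 2 N_c) ||alpha||^2`, so per-site average gradients aggregate
#' as complete-case-weighted means and the pooled and surrogate objectives
#' agree across back-ends.
NULL

# Per-site task designs, pooled complete-case count, and a guard list of
# sites where the target is missing for every row.
task_designs <- function(fed, task) {
  des <- lapply(fed$sites, build_task_design, task = task)
  list(des = des,
       n_c = vapply(des, `[[`, integer(1), "n_c"),
       N_c = sum(vapply(des, `[[`, integer(1), "n_c")))
}

#' Independent per-site fits (iMI back-end)
#'
#' Each site fits the imputation model using only its own rows with the
#' target observed; nothing is communicated. A site where the target is
#' missing for all rows cannot fit and is flagged non-imputable — the
#' caller decides whether to exclude it (this is the iMI limitation that
#' motivates the communicating back-ends).
#'
#' @param fed A [partitioned_dataset].
#' @param task An [imputation_task].
#' @return List of length `K`: a [global_posterior] per site, or `NULL`
#'   for non-imputable sites. The attribute `"excluded"` holds their ids.
#' @export
fit_independent <- function(fed, task) {
  td <- task_designs(fed, task)
  posts <- vector("list", fed$K)
  excluded <- integer(0)
  for (k in seq_len(fed$K)) {
    d <- td$des[[k]]
    if (d$n_c == 0L) {
      excluded <- c(excluded, fed$sites[[k]]$site_id)
      next
    }
    posts[[k]] <- if (task$family == "gaussian") {
      lf <- local_linear_fit(d$Z_c, d$target_c, task$lambda)
      # conjugate posterior SSE: x'x - x'Z alpha_hat
      sse <- lf$target_ss - sum(lf$moment * lf$alpha_hat)
      global_posterior("gaussian", lf$alpha_hat, lf$precision_inv,
                       tau2_shape = (d$n_c + 1) / 2,
                       tau2_scale = (sse + 1) / 2,
                       n_c_total = d$n_c)
    } else {
      lf <- local_logistic_map(d$Z_c, d$target_c, task$lambda)
      global_posterior("binomial", lf$alpha_hat, lf$precision_inv,
                       n_c_total = d$n_c)
    }
  }
  attr(posts, "excluded") <- excluded
  posts
}

#' Sufficient-information fit (siMI back-end)
#'
#' Gaussian family: one gather of per-site sufficient statistics
#' `(Z_c'Z_c, Z_c'x, x'x, n_c)` and the global ridge solution is computed
#' at the central node — identical, to floating-point tolerance, to
#' fitting on the concatenated complete cases. The error-variance law is
#' the conjugate posterior `tau^2 ~ IG((N_c+1)/2, (SSE+1)/2)` with the
#' pooled `SSE = x'x - x'Z alpha_hat`.
#'
#' Binomial family: distributed Newton. Each iteration broadcasts the
#' current coefficient vector and gathers `(Z'WZ, Z'(x - pi))` from every
#' site (2 ledger rounds per iteration, including the final round that
#' certifies convergence), converging to the pooled penalized logistic
#' MAP.
#'
#' Sites where the target is missing for every row contribute empty
#' statistics and are no obstacle — the advantage of this back-end.
#'
#' @inheritParams fit_independent
#' @param ledger A [comm_ledger]; rounds are appended in place.
#' @param tol,maxit Newton controls (binomial only).
#' @return A [global_posterior].
#' @export
fit_si <- function(fed, task, ledger = comm_ledger(), tol = 1e-8, maxit = 50L) {
  td <- task_designs(fed, task)
  if (td$N_c == 0L) stop("no site has the target observed")
  d <- fed$p + 1L
  if (task$family == "gaussian") {
    gram <- Reduce(`+`, lapply(td$des, function(x) crossprod(x$Z_c)))
    moment <- Reduce(`+`, lapply(td$des, function(x)
      drop(crossprod(x$Z_c, x$target_c))))
    target_ss <- sum(vapply(td$des, function(x) sum(x$target_c^2), numeric(1)))
    record_round(ledger, "sites->central", "gram+moment+ss",
                 fed$K * (d * d + d + 2))
    a <- gram + diag(task$lambda, d)
    base <- spd_inv(a)
    alpha <- drop(base %*% moment)
    sse <- target_ss - sum(moment * alpha)
    global_posterior("gaussian", alpha, base,
                     tau2_shape = (td$N_c + 1) / 2,
                     tau2_scale = (sse + 1) / 2,
                     n_c_total = td$N_c)
  } else {
    theta <- numeric(d)
    iter <- 0L
    repeat {
      iter <- iter + 1L
      if (iter > maxit) stop("distributed Newton did not converge in ",
                             maxit, " iterations")
      record_round(ledger, "central->sites", "theta", d)
      hess <- matrix(0, d, d)
      score <- numeric(d)
      for (x in td$des) {
        if (x$n_c == 0L) next
        eta <- drop(x$Z_c %*% theta)
        pi_k <- expit(eta)
        w <- pi_k * (1 - pi_k)
        hess <- hess + crossprod(x$Z_c, x$Z_c * w)
        score <- score + drop(crossprod(x$Z_c, x$target_c - pi_k))
      }
      record_round(ledger, "sites->central", "hessian+score",
                   fed$K * (d * d + d))
      pen_grad <- score - task$lambda * theta
      a <- hess + diag(task$lambda, d)
      if (max(abs(pen_grad)) < tol) break
      theta <- theta + drop(solve(a, pen_grad))
    }
    post <- global_posterior("binomial", theta, spd_inv(a),
                             n_c_total = td$N_c)
    attr(post, "newton_iterations") <- iter
    post
  }
}

#' Average-mixture fit (avgmMI back-end)
#'
#' Every site fits locally, then the central node combines with
#' complete-case weights: `alpha_hat = sum_k (n_c^(k)/N_c) alpha_hat^(k)`
#' and `Cov = (1/N_c^2) sum_k n_c^(k)^2 Cov(alpha_hat^(k))`. For the
#' gaussian family the error variance is drawn from
#' `tau^2 ~ IG(N_c/2, SSE/2)` with `SSE = sum_k SSE^(k)`, the per-site
#' residual sums of squares, and the conditional coefficient covariance is
#' `(tau^2/N_c^2) sum_k n_c^(k)^2 (Z_c^(k)'Z_c^(k) + lambda I)^{-1}`.
#' One gather of `{alpha_hat^(k), SSE^(k), local matrix}` is recorded.
#'
#' @inheritParams fit_si
#' @return A [global_posterior].
#' @export
fit_avgm <- function(fed, task, ledger = comm_ledger()) {
  td <- task_designs(fed, task)
  empty <- which(td$n_c == 0L)
  if (length(empty) > 0L) {
    stop("avgm requires a local fit at every site; target missing for all rows at site(s) ",
         paste(empty, collapse = ", "))
  }
  d <- fed$p + 1L
  fits <- lapply(td$des, function(x) {
    if (task$family == "gaussian") {
      local_linear_fit(x$Z_c, x$target_c, task$lambda)
    } else {
      local_logistic_map(x$Z_c, x$target_c, task$lambda)
    }
  })
  record_round(ledger, "sites->central", "alpha+sse+cov",
               fed$K * (d + 1 + d * d))
  w <- td$n_c / td$N_c
  alpha <- drop(Reduce(`+`, Map(function(wk, f) wk * f$alpha_hat, w, fits)))
  base <- Reduce(`+`, Map(function(nk, f) nk^2 * f$precision_inv, td$n_c, fits)) /
    td$N_c^2
  if (task$family == "gaussian") {
    sse <- sum(vapply(fits, `[[`, numeric(1), "sse"))
    global_posterior("gaussian", alpha, base,
                     tau2_shape = td$N_c / 2, tau2_scale = sse / 2,
                     n_c_total = td$N_c)
  } else {
    global_posterior("binomial", alpha, base, n_c_total = td$N_c)
  }
}

#' Surrogate-likelihood fit (cslMI back-end)
#'
#' The central site supplies the initial estimate `alpha_bar` (its local
#' fit) and all curvature; one broadcast of `alpha_bar` and one gather of
#' per-site average gradients give the pooled gradient, and the surrogate
#' loss `L~(alpha) = L_1(alpha) - <grad L_1(alpha_bar) -
#' grad L(alpha_bar), alpha>` is minimized at the central site (a single
#' linear solve for the gaussian family, damped Newton for the binomial).
#' The coefficient covariance is `(1/N_c) [hessian of L_1]^{-1}` at the
#' solution; for the gaussian family this is the conditional form
#' `(tau^2 n_c^(1) / N_c)(Z_c^(1)'Z_c^(1) + lambda I)^{-1}` with
#' `tau^2 ~ IG(N_c/2, SSE/2)` and the asymptotic
#' `SSE = N_c ||x_c^(1) - Z_c^(1) alpha_hat||^2 / n_c^(1)`, which needs no
#' further communication.
#'
#' @inheritParams fit_si
#' @param central Index of the central site in `fed$sites`.
#' @return A [global_posterior]; attribute `"csl_state"` carries
#'   `alpha_bar`, the pooled and central gradients, and the central
#'   Hessian.
#' @export
fit_csl <- function(fed, task, central = 1L, ledger = comm_ledger(),
                    tol = 1e-8, maxit = 50L) {
  td <- task_designs(fed, task)
  c1 <- td$des[[central]]
  if (c1$n_c == 0L) stop("central site ", central, " has no observed target values")
  d <- fed$p + 1L
  N_c <- td$N_c
  lam <- task$lambda

  # initial estimate: the central site's own penalized fit
  bar <- if (task$family == "gaussian") {
    local_linear_fit(c1$Z_c, c1$target_c, lam)$alpha_hat
  } else {
    local_logistic_map(c1$Z_c, c1$target_c, lam)$alpha_hat
  }
  record_round(ledger, "central->sites", "alpha_bar", d)

  # per-site unpenalized score sums at alpha_bar, gathered in one round
  score_sum <- function(x, alpha) {
    if (x$n_c == 0L) return(numeric(d))
    eta <- drop(x$Z_c %*% alpha)
    if (task$family == "gaussian") {
      drop(crossprod(x$Z_c, eta - x$target_c))
    } else {
      drop(crossprod(x$Z_c, expit(eta) - x$target_c))
    }
  }
  pooled_grad <- (Reduce(`+`, lapply(td$des, score_sum, alpha = bar)) +
                    lam * bar) / N_c
  record_round(ledger, "sites->central", "avg gradients", fed$K * d)
  central_grad <- score_sum(c1, bar) / c1$n_c + lam / N_c * bar
  shift <- central_grad - pooled_grad

  if (task$family == "gaussian") {
    gram1 <- crossprod(c1$Z_c)
    moment1 <- drop(crossprod(c1$Z_c, c1$target_c))
    a <- gram1 / c1$n_c + diag(lam / N_c, d)
    alpha <- unname(drop(solve(a, moment1 / c1$n_c + shift)))
    resid1 <- c1$target_c - drop(c1$Z_c %*% alpha)
    sse <- N_c * sum(resid1^2) / c1$n_c
    base <- c1$n_c / N_c * spd_inv(gram1 + diag(lam, d))
    post <- global_posterior("gaussian", alpha, base,
                             tau2_shape = N_c / 2, tau2_scale = sse / 2,
                             n_c_total = N_c)
    hess1 <- a
  } else {
    # surrogate objective and derivatives live on the central data only
    sobj <- function(alpha) {
      logistic_obj(alpha, c1$Z_c, c1$target_c, 0) / c1$n_c +
        lam / (2 * N_c) * sum(alpha^2) - sum(shift * alpha)
    }
    sgrad <- function(alpha) {
      score_sum(c1, alpha) / c1$n_c + lam / N_c * alpha - shift
    }
    shess <- function(alpha) {
      eta <- drop(c1$Z_c %*% alpha)
      w <- expit(eta) * (1 - expit(eta))
      crossprod(c1$Z_c, c1$Z_c * w) / c1$n_c + diag(lam / N_c, d)
    }
    alpha <- bar
    f <- sobj(alpha)
    iter <- 0L
    repeat {
      g <- sgrad(alpha)
      if (max(abs(g)) < tol) break
      iter <- iter + 1L
      if (iter > maxit) {
        stop(sprintf("csl surrogate optimizer did not converge (|grad|_inf = %.3e)",
                     max(abs(g))))
      }
      dir <- -drop(solve(shess(alpha), g))
      s <- 1
      repeat {
        cand <- alpha + s * dir
        fc <- sobj(cand)
        if (fc < f || s < 1e-10) break
        s <- s / 2
      }
      alpha <- cand
      f <- fc
    }
    hess1 <- shess(alpha)
    post <- global_posterior("binomial", alpha, spd_inv(hess1) / N_c,
                             n_c_total = N_c)
  }
  attr(post, "csl_state") <- list(
    central_site = fed$sites[[central]]$site_id,
    alpha_bar = bar,
    pooled_gradient = pooled_grad,
    central_gradient = central_grad,
    central_hessian = hess1
  )
  post
}

#' Resolve the central-site rule
#'
#' @param fed A [partitioned_dataset].
#' @param rule `"largest"` (most rows; the default, matching a central
#'   site chosen as the biggest hospital), `"median"` (site at the median
#'   sample size), or an explicit site index.
#' @return Integer index into `fed$sites`.
#' @export
resolve_central <- function(fed, rule = "largest") {
  if (is.numeric(rule)) {
    rule <- as.integer(rule)
    stopifnot(rule >= 1L, rule <= fed$K)
    return(rule)
  }
  rule <- match.arg(rule, c("largest", "median"))
  sizes <- vapply(fed$sites, `[[`, integer(1), "n")
  if (rule == "largest") {
    which.max(sizes)
  } else {
    ord <- order(sizes, seq_along(sizes))
    ord[ceiling(fed$K / 2)]
  }
}
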