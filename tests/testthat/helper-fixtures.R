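# Small federations built in code; scenario-1-like unless stated otherwise.

toy_fed <- function(N = 60, sizes = NULL, family = "gaussian",
                    miss = 0.3, seed = 1) {
  set.seed(seed)
  x2 <- runif(N, -3, 3)
  x1 <- if (family == "gaussian") {
    rnorm(N, 0.2 - 0.5 * x2, 1)
  } else {
    rbinom(N, 1L, plogis(0.2 - 0.5 * x2))
  }
  y <- 1 + x1 + x2 + rnorm(N)
  mask <- cbind(runif(N) < miss, rep(FALSE, N))
  if (is.null(sizes)) sizes <- c(ceiling(N / 2), floor(N / 2))
  fed_partition(cbind(x1, x2), y, mask, sizes)
}

# pooled fitting design (target x1) for oracle comparisons
pooled_design <- function(fed) {
  conc <- fed_concat(fed)
  obs <- !conc$mask[, 1L]
  list(Z = cbind(1, conc$y, conc$x[, -1L, drop = FALSE])[obs, , drop = FALSE],
       x = conc$x[obs, 1L], obs = obs, conc = conc)
}

logistic_grad_test <- function(a, Z, x, lambda) {
  drop(crossprod(Z, plogis(drop(Z %*% a)) - x)) + lambda * a
}

# independent penalized-logistic oracle: quasi-Newton on the exact objective
logistic_oracle <- function(Z, x, lambda) {
  fn <- function(a) {
    eta <- drop(Z %*% a)
    sum(log1p(exp(-abs(eta))) + pmax(eta, 0)) - sum(x * eta) +
      lambda / 2 * sum(a^2)
  }
  gr <- function(a) {
    eta <- drop(Z %*% a)
    drop(crossprod(Z, plogis(eta) - x)) + lambda * a
  }
  optim(numeric(ncol(Z)), fn, gr, method = "BFGS",
        control = list(maxit = 2000, reltol = 1e-15))$par
}
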