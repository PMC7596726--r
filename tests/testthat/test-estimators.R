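test_that("independent back-end fits each site alone and flags all-missing sites", {
  fed <- toy_fed(N = 50, sizes = c(30L, 20L), seed = 6)
  task <- imputation_task(1)
  posts <- fit_independent(fed, task)
  expect_length(posts, 2L)
  for (k in 1:2) {
    d <- build_task_design(fed$sites[[k]], task)
    lf <- local_linear_fit(d$Z_c, d$target_c, task$lambda)
    expect_equal(posts[[k]]$alpha_hat, lf$alpha_hat)
    expect_equal(posts[[k]]$tau2_shape, (d$n_c + 1) / 2)
  }
  expect_length(attr(posts, "excluded"), 0L)
  # a site with the target all-missing is flagged non-imputable
  x2 <- cbind(rep(NA_real_, 10), rnorm(10))
  bad <- site_data(2, x2, rnorm(10))
  fed2 <- partitioned_dataset(list(fed$sites[[1]], bad))
  posts2 <- fit_independent(fed2, task)
  expect_null(posts2[[2]])
  expect_equal(attr(posts2, "excluded"), 2L)
})

test_that("sufficient-information fit equals the pooled fit (gaussian)", {
  # exact 2-point line split over two sites
  fed <- fed_partition(matrix(c(0, 1), 2, 1), c(2, 4), alloc = c(1L, 1L))
  post <- fit_si(fed, imputation_task(1, lambda = 1e-12))
  # imputation model regresses x1 on (1, y): x1 = -1 + 0.5 y
  expect_equal(post$alpha_hat, c(-1, 0.5), tolerance = 1e-6)

  # random instances, K varying: pooled-fit oracle at 1e-10 relative
  for (seed in 1:3) {
    fed <- toy_fed(N = 90, sizes = c(40L, 30L, 20L), seed = seed)
    lg <- comm_ledger()
    post <- fit_si(fed, imputation_task(1), lg)
    pd <- pooled_design(fed)
    lf <- local_linear_fit(pd$Z, pd$x, 1e-4)
    expect_equal(post$alpha_hat, lf$alpha_hat, tolerance = 1e-10)
    expect_equal(post$alpha_cov_base, lf$precision_inv, tolerance = 1e-10)
    expect_equal(lg$com, 1L) # one gather for the linear model
  }
})

test_that("sufficient-information fit equals the pooled MAP (binomial)", {
  fed <- toy_fed(N = 60, sizes = c(35L, 25L), family = "binomial", seed = 8)
  lg <- comm_ledger()
  post <- fit_si(fed, imputation_task(1, "binomial"), lg)
  pd <- pooled_design(fed)
  pooled <- local_logistic_map(pd$Z, pd$x, 1e-4)
  expect_equal(post$alpha_hat, pooled$alpha_hat, tolerance = 1e-6)
  expect_equal(post$alpha_cov_base, pooled$precision_inv, tolerance = 1e-6)
  # 2 rounds per Newton iteration
  expect_equal(lg$com, 2L * attr(post, "newton_iterations"))
  # sites with the target all-missing are usable under si
  gone <- site_data(3, cbind(rep(NA_real_, 8), rnorm(8)), rnorm(8))
  fed3 <- partitioned_dataset(c(fed$sites, list(gone)))
  post3 <- fit_si(fed3, imputation_task(1, "binomial"))
  expect_equal(post3$alpha_hat, post$alpha_hat, tolerance = 1e-8)
})

test_that("average-mixture combination uses complete-case weights", {
  # hand-checkable weighted mean via two single-column sites
  f1 <- list(alpha_hat = c(1, 0), precision_inv = diag(2), sse = 1, n_c_local = 10)
  f2 <- list(alpha_hat = c(3, 0), precision_inv = diag(2), sse = 2, n_c_local = 30)
  w <- c(10, 30) / 40
  expect_equal(drop(w[1] * f1$alpha_hat + w[2] * f2$alpha_hat), c(2.5, 0))

  fed <- toy_fed(N = 80, sizes = c(50L, 30L), seed = 10)
  task <- imputation_task(1)
  lg <- comm_ledger()
  post <- fit_avgm(fed, task, lg)
  expect_equal(lg$com, 1L)
  fits <- lapply(fed$sites, function(s) {
    d <- build_task_design(s, task)
    local_linear_fit(d$Z_c, d$target_c, task$lambda)
  })
  nc <- vapply(fits, `[[`, numeric(1), "n_c_local")
  expect_equal(sum(nc / sum(nc)), 1)
  manual <- (nc[1] * fits[[1]]$alpha_hat + nc[2] * fits[[2]]$alpha_hat) / sum(nc)
  expect_equal(post$alpha_hat, manual)
  expect_equal(post$tau2_scale, (fits[[1]]$sse + fits[[2]]$sse) / 2)
  expect_equal(post$alpha_cov_base,
               (nc[1]^2 * fits[[1]]$precision_inv +
                  nc[2]^2 * fits[[2]]$precision_inv) / sum(nc)^2)
  # identical local fits at all sites: combined equals the common fit
  s <- fed$sites[[1]]
  twin <- partitioned_dataset(list(s, site_data(2, s$X[, -1], s$y, s$mask)))
  post_twin <- fit_avgm(twin, task)
  d1 <- build_task_design(s, task)
  expect_equal(post_twin$alpha_hat,
               local_linear_fit(d1$Z_c, d1$target_c, task$lambda)$alpha_hat)
  # all-missing site is an error naming the site
  gone <- site_data(2, cbind(rep(NA_real_, 8), rnorm(8)), rnorm(8))
  expect_error(fit_avgm(partitioned_dataset(list(s, gone)), task), "site\\(s\\) 2")
})

test_that("surrogate-likelihood solution is stationary and matches the quadratic oracle", {
  fed <- toy_fed(N = 100, sizes = c(60L, 40L), seed = 12)
  task <- imputation_task(1)
  lg <- comm_ledger()
  post <- fit_csl(fed, task, central = 1L, ledger = lg)
  expect_equal(lg$com, 2L) # broadcast alpha_bar + gather gradients
  st <- attr(post, "csl_state")

  # closed-form oracle for the quadratic loss: rebuild the stationarity
  # system from raw data and solve it directly
  d1 <- build_task_design(fed$sites[[1]], task)
  pd <- pooled_design(fed)
  N_c <- nrow(pd$Z)
  lam <- task$lambda
  shift <- st$central_gradient - st$pooled_gradient
  a <- crossprod(d1$Z_c) / d1$n_c + diag(lam / N_c, 3)
  oracle <- solve(a, crossprod(d1$Z_c, d1$target_c) / d1$n_c + shift)
  expect_equal(post$alpha_hat, drop(oracle), tolerance = 1e-10)

  # gradient of the surrogate at the solution is zero
  g1 <- drop(crossprod(d1$Z_c, d1$Z_c %*% post$alpha_hat - d1$target_c)) / d1$n_c +
    lam / N_c * post$alpha_hat
  expect_lt(max(abs(g1 - shift)), 1e-9)

  # binomial: stationarity of the surrogate on a random logistic instance
  fedb <- toy_fed(N = 90, sizes = c(60L, 30L), family = "binomial", seed = 13)
  taskb <- imputation_task(1, "binomial")
  postb <- fit_csl(fedb, taskb, central = 1L)
  stb <- attr(postb, "csl_state")
  db <- build_task_design(fedb$sites[[1]], taskb)
  Ncb <- sum(!fed_concat(fedb)$mask[, 1])
  gb <- logistic_grad_test(postb$alpha_hat, db$Z_c, db$target_c, 0) / db$n_c +
    taskb$lambda / Ncb * postb$alpha_hat -
    (stb$central_gradient - stb$pooled_gradient)
  expect_lt(max(abs(gb)), 1e-7)
})

test_that("all four back-ends coincide at K = 1", {
  for (family in c("gaussian", "binomial")) {
    fed <- toy_fed(N = 70, sizes = 70L, family = family, seed = 14)
    task <- imputation_task(1, family)
    p_i <- fit_independent(fed, task)[[1]]
    p_si <- fit_si(fed, task)
    p_av <- fit_avgm(fed, task)
    p_cs <- fit_csl(fed, task, central = 1L)
    tol <- if (family == "gaussian") 1e-10 else 1e-6
    for (p in list(p_si, p_av, p_cs)) {
      expect_equal(p$alpha_hat, p_i$alpha_hat, tolerance = tol)
      expect_equal(p$alpha_cov_base, p_i$alpha_cov_base, tolerance = tol)
    }
    # with one site the pooled and central gradients agree
    st <- attr(p_cs, "csl_state")
    expect_equal(st$pooled_gradient, st$central_gradient, tolerance = 1e-10)
  }
})

test_that("central-site rules resolve as documented", {
  fed <- fed_partition(matrix(rnorm(60), 60, 1), rnorm(60),
                       alloc = c(10L, 30L, 20L))
  expect_equal(resolve_central(fed, "largest"), 2L)
  expect_equal(resolve_central(fed, "median"), 3L)
  expect_equal(resolve_central(fed, 1L), 1L)
})
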