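# a small scenario-3-like federation with missing cells in x1..x3
mice_fed <- function(N = 120, sizes = c(70L, 50L), seed = 40, miss = 0.2) {
  set.seed(seed)
  x45 <- matrix(rnorm(2 * N), N, 2)
  mu <- 0.3 - 0.3 * x45[, 1] - 0.1 * x45[, 2]
  sig <- matrix(0.5, 3, 3); diag(sig) <- 1
  x123 <- matrix(rnorm(3 * N), N, 3) %*% chol(sig) + mu
  x <- cbind(x123, x45)
  y <- 1 + rowSums(x) + rnorm(N)
  mask <- matrix(FALSE, N, 5)
  mask[, 1:3] <- matrix(runif(3 * N) < miss, N, 3)
  fed_partition(x, y, mask, sizes)
}

test_that("initial fill samples from observed values and touches nothing else", {
  fed <- mice_fed(seed = 41)
  tasks <- lapply(1:3, imputation_task, family = "gaussian")
  before <- fed_concat(fed)
  set.seed(5)
  filled <- fed_concat(initial_impute(fed, tasks))
  expect_false(anyNA(filled$x))
  for (j in 1:3) {
    obs <- !before$mask[, j]
    expect_identical(filled$x[obs, j], before$x[obs, j])
    expect_true(all(filled$x[!obs, j] %in% before$x[obs, j]))
  }
  # single observed value: every fill equals it
  s <- site_data(1, cbind(c(7, NA, NA, NA), 1:4), 1:4)
  one <- initial_impute(partitioned_dataset(list(s)),
                        list(imputation_task(1)))
  expect_equal(one$sites[[1]]$X[, 2], rep(7, 4))
  # no missing cells: identity
  full <- toy_fed(N = 20, sizes = 20L, miss = 0, seed = 42)
  expect_identical(fed_concat(initial_impute(full, list(imputation_task(1)))),
                   fed_concat(full))
  # fill distribution tracks the observed distribution (moment check, n = 1e4)
  set.seed(6)
  pool_x <- c(rnorm(4000, 5, 2), rep(NA_real_, 6000))
  sf <- fed_partition(cbind(pool_x, rnorm(10000)), rnorm(10000),
                      alloc = c(10000L))
  ff <- fed_concat(initial_impute(sf, list(imputation_task(1))))
  fills <- ff$x[is.na(pool_x), 1]
  obs <- pool_x[!is.na(pool_x)]
  expect_equal(mean(fills), mean(obs), tolerance = 0.05)
  expect_equal(sd(fills), sd(obs), tolerance = 0.05)
})

test_that("chained-equation communication accounting is exact", {
  fed <- mice_fed(seed = 43)
  tasks <- lapply(1:3, imputation_task, family = "gaussian")
  sch <- mice_schedule(M = 2, burn_in = 2, thin = 1)
  sweeps <- sch$total_sweeps
  expect_equal(sweeps, 3L)
  set.seed(1)
  expect_equal(run_mice(fed, tasks, "iMICE", sch)$ledger$com, 0L)
  set.seed(1)
  com_avgm <- run_mice(fed, tasks, "avgmMICE", sch)$ledger$com
  set.seed(1)
  com_csl <- run_mice(fed, tasks, "cslMICE", sch)$ledger$com
  set.seed(1)
  com_si <- run_mice(fed, tasks, "siMICE", sch)$ledger$com
  expect_equal(com_avgm, 2L * 3L * sweeps)
  expect_equal(com_si, 2L * 3L * sweeps)
  expect_equal(com_csl, 3L * 3L * sweeps)
  expect_equal(com_csl / com_avgm, 3 / 2)
  # the 3/2 ratio holds for any gaussian schedule
  sch2 <- mice_schedule(M = 3, burn_in = 1, thin = 2)
  set.seed(2)
  c_a <- run_mice(fed, tasks, "avgmMICE", sch2)$ledger$com
  set.seed(2)
  c_c <- run_mice(fed, tasks, "cslMICE", sch2)$ledger$com
  expect_equal(c_c / c_a, 3 / 2)
})

test_that("observed cells survive every sweep and emitted sets are complete", {
  fed <- mice_fed(seed = 44)
  tasks <- lapply(1:3, imputation_task, family = "gaussian")
  before <- fed_concat(fed)
  for (method in c("iMICE", "avgmMICE", "cslMICE", "siMICE")) {
    set.seed(9)
    run <- run_mice(fed, tasks, method, mice_schedule(M = 3, burn_in = 2, thin = 1))
    expect_length(run$completed, 3L)
    for (comp in run$completed) {
      after <- fed_concat(comp)
      expect_false(anyNA(after$x))
      for (j in 1:5) {
        obs <- !before$mask[, j]
        expect_identical(after$x[obs, j], before$x[obs, j])
      }
    }
    # consecutive emissions differ at imputed cells (the chain is moving)
    expect_false(identical(fed_concat(run$completed[[1]])$x,
                           fed_concat(run$completed[[2]])$x))
  }
})

test_that("siMICE reproduces single-machine chained equations on pooled data", {
  # missingness confined to site 1 so both layouts consume the RNG stream
  # identically; the K = 1 run is the standard pooled MICE benchmark
  set.seed(45)
  N <- 80
  x <- cbind(rnorm(N), rnorm(N), rnorm(N))
  y <- 1 + rowSums(x) + rnorm(N)
  mask <- matrix(FALSE, N, 3)
  mask[1:40, 1:2] <- matrix(runif(80) < 0.3, 40, 2)
  tasks <- lapply(1:2, imputation_task, family = "gaussian")
  sch <- mice_schedule(M = 2, burn_in = 2, thin = 1)
  fedK <- fed_partition(x, y, mask, c(40L, 25L, 15L))
  fed1 <- fed_partition(x, y, mask, c(80L))
  set.seed(321)
  a <- run_mice(fedK, tasks, "siMICE", sch)
  set.seed(321)
  b <- run_mice(fed1, tasks, "siMICE", sch)
  for (m in 1:2) {
    expect_equal(fed_concat(a$completed[[m]])$x,
                 fed_concat(b$completed[[m]])$x, tolerance = 1e-8)
  }
})

test_that("q = 1 chained equations degenerate to univariate MI", {
  fed <- toy_fed(N = 60, sizes = c(35L, 25L), seed = 46)
  task <- imputation_task(1)
  set.seed(11)
  run <- run_mice(fed, list(task), "siMICE",
                  mice_schedule(M = 2, burn_in = 1, thin = 1))
  expect_length(run$completed, 2L)
  for (comp in run$completed) expect_false(anyNA(fed_concat(comp)$x))
  # per-fit com is still 2 for the gaussian back-end
  expect_equal(run$ledger$com, 2L * run$schedule$total_sweeps)
})

test_that("iMICE drops sites with an all-missing target and runs without communication", {
  fed <- mice_fed(seed = 47)
  gone <- site_data(3, cbind(rep(NA_real_, 10), matrix(rnorm(40), 10, 4)),
                    rnorm(10))
  fed3 <- partitioned_dataset(c(fed$sites, list(gone)))
  tasks <- lapply(1:3, imputation_task, family = "gaussian")
  set.seed(3)
  run <- run_mice(fed3, tasks, "iMICE", mice_schedule(M = 2, burn_in = 1, thin = 1))
  expect_equal(run$excluded_sites, 3L)
  expect_equal(run$ledger$com, 0L)
  for (comp in run$completed) expect_equal(comp$K, 2L)
})
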