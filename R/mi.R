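#' Run multiple imputation for a univariate missing-data pattern
#'
#' Drives one full imputation run for a single incomplete variable: fit the
#' imputation model with the chosen back-end, draw `M` parameter sets at
#' the central node, broadcast them (one ledger round for the
#' communicating methods), and impute at every site, yielding `M`
#' completed datasets ready for [fit_analysis()] and [rubin_pool()].
#'
#' Total communication rounds recorded: `iMI` 0; `avgmMI` 2 (one gather +
#' the draw broadcast); `cslMI` 3; `siMI` 2 for a gaussian target and
#' `2T + 1` for a binomial target fitted in `T` distributed Newton
#' iterations. These counts do not depend on `K`.
#'
#' A site where the target is missing for every row is excluded under
#' `iMI` (recorded in `excluded_sites`; it appears in no completed
#' dataset) and is an error under `avgmMI`/`cslMI`, whose local fits are
#' undefined there. `siMI` uses such sites without difficulty.
#'
#' @param fed A [partitioned_dataset].
#' @param task An [imputation_task].
#' @param method One of `"iMI"`, `"avgmMI"`, `"cslMI"`, `"siMI"`
#'   (case-insensitive).
#' @param M Number of imputed datasets (default 20).
#' @param central Central-site rule for `cslMI`; see [resolve_central()].
#' @param ledger Optional [comm_ledger] to append to.
#' @return Object of class `mi_run`: list with `method`, `M`, `completed`
#'   (list of `M` completed [partitioned_dataset]s), `ledger`,
#'   `excluded_sites`, `posterior`, and `task`.
#' @export
run_mi <- function(fed, task, method = c("iMI", "avgmMI", "cslMI", "siMI"),
                   M = 20L, central = "largest", ledger = comm_ledger()) {
  canon <- c(imi = "iMI", avgmmi = "avgmMI", cslmi = "cslMI", simi = "siMI")
  if (length(method) > 1L) method <- method[[1L]]
  method <- canon[[match.arg(tolower(method), names(canon))]]
  stopifnot(M >= 1L)
  excluded <- integer(0)

  if (method == "iMI") {
    posts <- fit_independent(fed, task)
    excluded <- attr(posts, "excluded")
    keep <- which(!vapply(posts, is.null, logical(1)))
    if (length(keep) == 0L) stop("no site can impute the target under iMI")
    draws <- vector("list", fed$K)
    for (k in keep) draws[[k]] <- sample_posterior(posts[[k]], M)
    completed <- lapply(seq_len(M), function(m) {
      partitioned_dataset(lapply(keep, function(k) {
        impute_with_draw(fed$sites[[k]], task, draws[[k]][[m]])
      }))
    })
    posterior <- posts
  } else {
    all_missing <- which(vapply(seq_len(fed$K), function(k) {
      all(fed$sites[[k]]$mask[, task$j])
    }, logical(1)))
    if (method %in% c("avgmMI", "cslMI") && length(all_missing) > 0L) {
      stop(method, " cannot be used: target missing for all rows at site(s) ",
           paste(all_missing, collapse = ", "))
    }
    posterior <- switch(method,
      avgmMI = fit_avgm(fed, task, ledger),
      cslMI = fit_csl(fed, task, resolve_central(fed, central), ledger),
      siMI = fit_si(fed, task, ledger)
    )
    draws <- sample_posterior(posterior, M)
    record_round(ledger, "central->sites", "parameter draws",
                 M * (fed$p + 1L + (task$family == "gaussian")))
    completed <- lapply(seq_len(M), function(m) {
      partitioned_dataset(lapply(fed$sites, impute_with_draw,
                                 task = task, draw = draws[[m]]))
    })
  }

  structure(
    list(method = method, M = M, completed = completed, ledger = ledger,
         excluded_sites = excluded, posterior = posterior, task = task),
    class = "mi_run"
  )
}

#' @export
print.mi_run <- function(x, ...) {
  cat(sprintf("%s run: M = %d imputed datasets, com = %d\n",
              x$method, x$M, x$ledger$com))
  if (length(x$excluded_sites) > 0L) {
    cat("excluded sites:", paste(x$excluded_sites, collapse = ", "), "\n")
  }
  invisible(x)
}
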