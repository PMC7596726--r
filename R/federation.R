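#' Data held at one site of a horizontally partitioned study
#'
#' Builds the per-site container used throughout the package. Each of the
#' `K` sites holds the same variables (outcome `y` plus `p` covariates) for
#' a disjoint set of subjects. The design matrix is materialized with an
#' intercept column of ones in column 1; the missingness indicators live in
#' `mask`, which indexes the covariates only (the outcome and the intercept
#' are always observed).
#'
#' @param site_id Integer site identifier, `>= 1`.
#' @param x Numeric covariate matrix `n x p` (no intercept column). `NA`
#'   entries mark missing cells.
#' @param y Numeric outcome vector of length `n`, fully observed.
#' @param mask Optional logical `n x p` matrix, `TRUE` = missing. Defaults
#'   to `is.na(x)`. When supplied it must flag at least every `NA` in `x`.
#' @return An object of class `site_data`: list with elements `site_id`,
#'   `X` (`n x (p+1)` design including intercept, `NA` where missing), `y`,
#'   `mask`, `n`, and `n_c` (complete-case count).
#' @export
site_data <- function(site_id, x, y, mask = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  y <- as.numeric(y)
  n <- nrow(x)
  p <- ncol(x)
  if (n < 1L) stop("site ", site_id, ": sites with zero rows are not allowed")
  if (length(y) != n) stop("length(y) must equal nrow(x)")
  if (anyNA(y)) stop("the outcome y must be fully observed")
  if (is.null(mask)) mask <- is.na(x)
  mask <- matrix(as.logical(mask), n, p)
  if (any(is.na(x) & !mask)) stop("x has NA entries not flagged in mask")
  x[mask] <- NA_real_
  structure(
    list(
      site_id = as.integer(site_id),
      X = cbind(1, x, deparse.level = 0),
      y = y,
      mask = mask,
      n = n,
      n_c = sum(rowSums(mask) == 0L)
    ),
    class = "site_data"
  )
}

#' Horizontally partitioned dataset
#'
#' Assembles an ordered collection of [site_data] blocks into one federated
#' study. All sites must share the same number of covariates.
#'
#' @param sites List of `site_data` objects.
#' @return An object of class `partitioned_dataset` with elements `sites`,
#'   `K`, `p`, `N` (total rows), and `N_c` (total complete cases).
#' @export
partitioned_dataset <- function(sites) {
  stopifnot(length(sites) >= 1L)
  ps <- vapply(sites, function(s) ncol(s$X) - 1L, integer(1))
  if (length(unique(ps)) != 1L) stop("all sites must share the same covariates")
  structure(
    list(
      sites = sites,
      K = length(sites),
      p = ps[[1L]],
      N = sum(vapply(sites, `[[`, integer(1), "n")),
      N_c = sum(vapply(sites, `[[`, integer(1), "n_c"))
    ),
    class = "partitioned_dataset"
  )
}

#' @export
print.partitioned_dataset <- function(x, ...) {
  cat(sprintf(
    "Horizontally partitioned dataset: K = %d sites, p = %d covariates, N = %d (N_c = %d complete cases)\n",
    x$K, x$p, x$N, x$N_c
  ))
  sizes <- vapply(x$sites, `[[`, integer(1), "n")
  cat("site sizes:", paste(sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Sample allocations across sites
#'
#' The simulation study distributes `N` subjects over `K` sites in two ways.
#' Under type `"U"` (uneven) every site except the first holds exactly 15
#' subjects and site 1 holds the remainder `N - 15(K-1)`; under type `"E"`
#' (even) every site holds `N/K`. `K = 1` is the pooled single-site setting.
#'
#' @param type `"U"` or `"E"` (ignored when `K = 1`).
#' @param K Number of sites.
#' @param N Total number of subjects.
#' @return Object of class `site_allocation`: list with `type`, `K`, `N`,
#'   and integer `sizes` of length `K` summing to `N`.
#' @export
#' @examples
#' site_allocation("U", 5, 250)$sizes  # 190 15 15 15 15
#' site_allocation("E", 10, 1000)$sizes
site_allocation <- function(type, K, N) {
  type <- match.arg(type, c("U", "E"))
  K <- as.integer(K)
  N <- as.integer(N)
  stopifnot(K >= 1L, N >= 1L)
  if (K == 1L) {
    sizes <- N
  } else if (type == "E") {
    if (N %% K != 0L) stop("type E requires K to divide N evenly")
    sizes <- rep.int(N %/% K, K)
  } else {
    first <- N - 15L * (K - 1L)
    if (first < 15L) stop("type U requires N - 15(K-1) >= 15")
    sizes <- c(first, rep.int(15L, K - 1L))
  }
  structure(list(type = type, K = K, N = N, sizes = sizes),
            class = "site_allocation")
}

#' Partition pooled data into a federated dataset
#'
#' Splits pooled `(x, y, mask)` by rows, in order, according to an
#' allocation. Concatenating the sites back together (see [fed_concat])
#' reproduces the inputs exactly.
#'
#' @param x Pooled covariate matrix `N x p` (no intercept).
#' @param y Pooled outcome vector of length `N`.
#' @param mask Logical `N x p` missingness matrix; defaults to `is.na(x)`.
#' @param alloc A [site_allocation], or an integer vector of site sizes.
#' @return A [partitioned_dataset].
#' @export
fed_partition <- function(x, y, mask = NULL, alloc) {
  x <- as.matrix(x)
  if (is.null(mask)) mask <- is.na(x)
  sizes <- if (inherits(alloc, "site_allocation")) alloc$sizes else as.integer(alloc)
  if (any(sizes < 1L)) stop("empty sites are not allowed")
  if (sum(sizes) != nrow(x)) stop("allocation sizes must sum to nrow(x)")
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  sites <- lapply(seq_along(sizes), function(k) {
    idx <- starts[k]:ends[k]
    site_data(k, x[idx, , drop = FALSE], y[idx],
              mask[idx, , drop = FALSE])
  })
  partitioned_dataset(sites)
}

#' Concatenate a federated dataset back into pooled form
#'
#' Inverse of [fed_partition]: stacks the per-site blocks in site order.
#'
#' @param fed A [partitioned_dataset].
#' @return List with pooled `x` (covariates, `NA` at missing cells), `y`,
#'   and `mask`.
#' @export
fed_concat <- function(fed) {
  x <- do.call(rbind, lapply(fed$sites, function(s) s$X[, -1L, drop = FALSE]))
  list(
    x = x,
    y = unlist(lapply(fed$sites, `[[`, "y"), use.names = FALSE),
    mask = do.call(rbind, lapply(fed$sites, `[[`, "mask"))
  )
}

#' Communication ledger
#'
#' Append-only log of one-way communication rounds between the sites and
#' the central node. One *round* is one synchronized one-way communication
#' in which all participating sites take part at once: a gather of per-site
#' summaries counts 1 and a broadcast from the central node counts 1,
#' regardless of `K`. The total `com` is the "number of communications"
#' statistic reported for each imputation method.
#'
#' Implemented as an environment so that fitting back-ends can append to a
#' shared ledger in place.
#'
#' @return Object of class `comm_ledger` with fields `entries` (list) and
#'   `com` (integer round count).
#' @seealso [record_round()]
#' @export
comm_ledger <- function() {
  lg <- new.env(parent = emptyenv())
  lg$entries <- list()
  lg$com <- 0L
  class(lg) <- "comm_ledger"
  lg
}

#' Record one one-way communication round
#'
#' Appends one entry and increments the round count by exactly 1, whether
#' the round is a gather from all sites or a broadcast to all sites.
#'
#' @param ledger A [comm_ledger]; modified in place.
#' @param direction `"sites->central"` or `"central->sites"`.
#' @param payload_kind Character tag describing what was transferred.
#' @param scalar_count Optional number of scalars in the payload.
#' @return The ledger, invisibly.
#' @export
record_round <- function(ledger, direction, payload_kind, scalar_count = NA_real_) {
  stopifnot(inherits(ledger, "comm_ledger"))
  direction <- match.arg(direction, c("sites->central", "central->sites"))
  ledger$entries[[length(ledger$entries) + 1L]] <- list(
    round_index = ledger$com + 1L,
    direction = direction,
    payload_kind = payload_kind,
    payload_scalar_count = scalar_count
  )
  ledger$com <- ledger$com + 1L
  invisible(ledger)
}

#' @export
print.comm_ledger <- function(x, ...) {
  cat(sprintf("Communication ledger: %d one-way round(s)\n", x$com))
  for (e in x$entries) {
    cat(sprintf("  %2d. %-15s %s\n", e$round_index, e$direction, e$payload_kind))
  }
  invisible(x)
}

#' Write a federated dataset as per-site CSV files
#'
#' One file per site named `site_<k>.csv` with header `y,x1,...,xp`;
#' missing cells are written empty. The intercept is never serialized.
#'
#' @param fed A [partitioned_dataset].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_sites <- function(fed, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (s in fed$sites) {
    df <- data.frame(y = s$y, s$X[, -1L, drop = FALSE])
    names(df) <- c("y", paste0("x", seq_len(ncol(df) - 1L)))
    utils::write.csv(df, file.path(dir, sprintf("site_%d.csv", s$site_id)),
                     row.names = FALSE, na = "")
  }
  invisible(dir)
}

#' Read a federated dataset from per-site CSV files
#'
#' @param dir Directory holding `site_<k>.csv` files as written by
#'   [write_sites()].
#' @return A [partitioned_dataset]; empty cells become missing entries.
#' @export
read_sites <- function(dir) {
  files <- list.files(dir, pattern = "^site_[0-9]+\\.csv$", full.names = TRUE)
  if (length(files) == 0L) stop("no site_<k>.csv files in ", dir)
  ks <- as.integer(sub("^site_([0-9]+)\\.csv$", "\\1", basename(files)))
  files <- files[order(ks)]
  sites <- lapply(seq_along(files), function(k) {
    df <- utils::read.csv(files[k])
    site_data(k, as.matrix(df[, -1L, drop = FALSE]), df$y)
  })
  partitioned_dataset(sites)
}
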