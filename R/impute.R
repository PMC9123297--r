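#' Initial single fill of missing cells
#'
#' Starting point of a chained-equations run: every missing cell is filled
#' with a uniform random draw from the observed values of its own column.
#'
#' @param data A data frame with (possibly) missing values.
#' @param seed Optional integer seed.
#' @return A complete tibble; observed cells are untouched.
#' @export
initial_fill <- function(data, seed = NULL) {
  check_numeric_df(data, "initial_fill")
  set_seed_if(seed)
  out <- as_tibble(data)
  for (j in seq_along(out)) {
    miss <- is.na(out[[j]])
    if (!any(miss)) next
    obs <- out[[j]][!miss]
    if (length(obs) == 0) {
      abort(sprintf("Column `%s` has no observed values to draw from.", names(out)[j]))
    }
    out[[j]][miss] <- sample(obs, sum(miss), replace = TRUE)
  }
  out
}

# Bayesian draw from the posterior of a normal linear model (coefficients
# and residual variance), used for type-1 predictive mean matching. Falls
# back to a ridge-regularized fit when the design is singular.
norm_draw <- function(X, y) {
  n <- nrow(X)
  p <- ncol(X)
  qrX <- qr(X)
  ridge_used <- FALSE
  if (qrX$rank < p) {
    warn("Singular design in PMM regression; using a ridge-regularized fit.")
    ridge_used <- TRUE
    xtx <- crossprod(X)
    diag(xtx) <- diag(xtx) + 1e-5 * (mean(diag(xtx)) + 1)
    V <- chol2inv(chol(xtx))
    beta_hat <- drop(V %*% crossprod(X, y))
  } else {
    beta_hat <- qr.coef(qrX, y)
    R <- qr.R(qrX)
    V <- chol2inv(R)
  }
  res <- y - drop(X %*% beta_hat)
  df <- max(n - p, 1)
  sigma2_star <- sum(res^2) / rchisq(1, df)
  pert <- drop(crossprod(chol(V), rnorm(p))) * sqrt(sigma2_star)
  list(beta_hat = beta_hat, beta_star = beta_hat + pert, ridge = ridge_used)
}

# lean PMM engine: X is the full design matrix (with intercept column),
# y the target column with true observed values on !miss rows
pmm_fill <- function(X, y, miss, donors) {
  n_obs <- sum(!miss)
  if (n_obs < donors) {
    abort(sprintf("Only %d observed rows; at least `donors` = %d required.",
                  n_obs, donors))
  }
  yo <- y[!miss]
  dr <- norm_draw(X[!miss, , drop = FALSE], yo)
  eta_obs <- drop(X[!miss, , drop = FALSE] %*% dr$beta_hat)
  eta_mis <- drop(X[miss, , drop = FALSE] %*% dr$beta_star)
  ord <- order(eta_obs)
  eo <- eta_obs[ord]
  yo_sorted <- yo[ord]
  picks <- sample.int(donors, length(eta_mis), replace = TRUE)
  out <- numeric(length(eta_mis))
  pos <- findInterval(eta_mis, eo)
  for (i in seq_along(eta_mis)) {
    # distances to e are V-shaped in the sorted eo, so the j-th nearest
    # donor is found by a two-pointer merge outward from the insertion point
    e <- eta_mis[i]
    l <- pos[i]
    r <- pos[i] + 1L
    take <- 0L
    for (step in seq_len(picks[i])) {
      if (l >= 1L && (r > n_obs || e - eo[l] <= eo[r] - e)) {
        take <- l
        l <- l - 1L
      } else {
        take <- r
        r <- r + 1L
      }
    }
    out[i] <- yo_sorted[take]
  }
  out
}

#' Predictive-mean-matching column imputation
#'
#' Type-1 PMM: a linear regression of the target column on all other
#' columns is fit to the observed rows; predictions for the observed rows
#' use the least-squares coefficients while predictions for the missing
#' rows use a stochastic draw of the coefficients from their sampling
#' distribution. Each missing row then receives the observed value of one
#' donor drawn uniformly from the `donors` observed rows with the closest
#' predictions, so imputed values always lie on the observed support.
#'
#' @param data A data frame whose non-target columns are complete (a
#'   working dataset mid-chain).
#' @param target Name of the column to impute.
#' @param miss Logical vector marking the rows whose target value is
#'   missing. Defaults to `is.na(data[[target]])`.
#' @param donors Size of the donor pool (default 5).
#' @return A numeric vector of imputed values, one per missing row.
#' @export
impute_pmm_column <- function(data, target, miss = is.na(data[[target]]), donors = 5) {
  check_numeric_df(data, "impute_pmm_column")
  if (!target %in% names(data)) abort(sprintf("No column `%s` in `data`.", target))
  if (donors < 1) abort("`donors` must be a positive integer.")
  n_obs <- sum(!miss)
  if (n_obs < donors) {
    abort(sprintf("Column `%s` has %d observed rows; at least `donors` = %d required.",
                  target, n_obs, donors))
  }
  if (!any(miss)) return(numeric(0))
  X <- cbind(1, as.matrix(data[setdiff(names(data), target)]))
  if (anyNA(X)) abort("Predictor columns must be complete.")
  pmm_fill(X, data[[target]], miss, donors)
}

#' Random-forest column imputation
#'
#' Grows a bootstrap forest of `n_trees` trees for the target column on the
#' observed rows (regression trees for a numeric target, classification
#' trees when the observed values are binary 0/1). Each missing row is
#' dropped down every tree; the observed values sitting in the terminal
#' nodes it reaches (one node per tree) are pooled and one is drawn
#' uniformly at random, so imputed values always lie on the observed
#' support.
#'
#' @inheritParams impute_pmm_column
#' @param n_trees Number of trees (default 10).
#' @return A numeric vector of imputed values, one per missing row.
#' @export
impute_rf_column <- function(data, target, miss = is.na(data[[target]]), n_trees = 10) {
  check_numeric_df(data, "impute_rf_column")
  if (!target %in% names(data)) abort(sprintf("No column `%s` in `data`.", target))
  if (n_trees < 1) abort("`n_trees` must be a positive integer.")
  if (!any(miss)) return(numeric(0))
  preds <- as.data.frame(data[setdiff(names(data), target)])
  if (anyNA(preds)) abort("Predictor columns must be complete.")
  rf_fill(preds, data[[target]], miss, n_trees, label = target)
}

rf_fill <- function(preds, y, miss, n_trees, label = "target") {
  yo <- y[!miss]
  if (length(unique(yo)) == 1) {
    warn(sprintf("Column `%s` is constant among observed rows; imputing that constant.", label))
    return(rep(yo[1], sum(miss)))
  }
  is_bin <- all(yo %in% c(0, 1))
  yfit <- if (is_bin) factor(yo, levels = c(0, 1)) else yo
  fit <- ranger::ranger(
    x = preds[!miss, , drop = FALSE], y = yfit,
    num.trees = n_trees,
    mtry = max(1L, floor(sqrt(ncol(preds)))),
    min.node.size = 5,
    num.threads = 1,
    seed = sample.int(2147483646L, 1)
  )
  tn <- predict(fit, data = preds, type = "terminalNodes",
                num.threads = 1)$predictions
  tn_obs <- tn[!miss, , drop = FALSE]
  tn_mis <- tn[miss, , drop = FALSE]
  vapply(seq_len(nrow(tn_mis)), function(i) {
    pool <- unlist(lapply(seq_len(ncol(tn_obs)), function(t) {
      yo[tn_obs[, t] == tn_mis[i, t]]
    }))
    if (length(pool) == 0) pool <- yo # unreachable nodes: fall back to all observed
    pool[sample.int(length(pool), 1)]
  }, numeric(1))
}

#' Multiple imputation by chained equations
#'
#' Produces `m` completed copies of an incomplete dataset. Each chain runs
#' independently: an initial random fill ([initial_fill()]) is followed by
#' `n_cycles` sweeps over the columns with missingness (visited left to
#' right), each sweep re-imputing a column conditional on the current
#' values of all other columns with the chosen column imputer
#' ([impute_pmm_column()] or [impute_rf_column()]). Observed cells are
#' never touched.
#'
#' @param data An incomplete data frame, e.g. from [ampute_data()].
#' @param method `"pmm"` (predictive mean matching, the default) or `"rf"`
#'   (random forest).
#' @param m Number of imputed datasets (default 25).
#' @param n_cycles Chained-equation sweeps per chain (default 5).
#' @param donors PMM donor-pool size (default 5).
#' @param n_trees RF forest size (default 10).
#' @param seed Optional integer seed; chains receive independent substream
#'   seeds derived from it.
#' @return An object of class `imputed_stack`: a list with elements
#'   `completed` (list of `m` complete tibbles), the configuration, and the
#'   original incomplete data (`amputed`).
#' @examples
#' d <- simulate_friedman(200, seed = 1)
#' a <- ampute_data(d, "MCAR", seed = 2)
#' st <- impute_chained(a, method = "pmm", m = 3, seed = 3)
#' st
#' @export
impute_chained <- function(data,
                           method = c("pmm", "rf"),
                           m = 25,
                           n_cycles = 5,
                           donors = 5,
                           n_trees = 10,
                           seed = NULL) {
  method <- match.arg(method)
  check_numeric_df(data, "impute_chained")
  if (m < 1 || m != round(m)) abort("`m` must be a positive integer.")
  if (n_cycles < 1) abort("`n_cycles` must be a positive integer.")
  miss_mat <- is.na(as.matrix(data))
  cols_missing <- names(data)[colSums(miss_mat) > 0]
  for (cl in cols_missing) {
    if (all(miss_mat[, cl])) abort(sprintf("Column `%s` is entirely missing.", cl))
  }
  col_idx <- match(cols_missing, names(data))
  completed <- vector("list", m)
  for (chain in seq_len(m)) {
    if (!is.null(seed)) set.seed(child_seed(seed, chain))
    work <- as.matrix(initial_fill(data))
    for (cycle in seq_len(n_cycles)) {
      for (ci in seq_along(cols_missing)) {
        cl <- cols_missing[ci]
        j <- col_idx[ci]
        miss <- miss_mat[, cl]
        vals <- tryCatch(
          switch(method,
            pmm = pmm_fill(cbind(1, work[, -j, drop = FALSE]), work[, j],
                           miss, donors = donors),
            rf  = rf_fill(as.data.frame(work[, -j, drop = FALSE]), work[, j],
                          miss, n_trees = n_trees, label = cl)
          ),
          error = function(e) {
            abort(sprintf("Imputation failed (chain %d, cycle %d, column `%s`): %s",
                          chain, cycle, cl, conditionMessage(e)))
          }
        )
        work[miss, j] <- vals
      }
    }
    completed[[chain]] <- as_tibble(as.data.frame(work))
  }
  structure(
    list(
      completed = completed,
      method = method, m = m, n_cycles = n_cycles,
      donors = donors, n_trees = n_trees, seed = seed,
      amputed = as_tibble(data)
    ),
    class = "imputed_stack"
  )
}

#' @export
print.imputed_stack <- function(x, ...) {
  cat(sprintf(
    "<imputed_stack> %d imputations by %s (%d cycles), %d x %d data, %.1f%% incomplete rows\n",
    x$m, toupper(x$method), x$n_cycles,
    nrow(x$amputed), ncol(x$amputed),
    100 * incomplete_fraction(x$amputed)
  ))
  invisible(x)
}

#' Completed datasets from an imputed stack
#'
#' @param stack An [impute_chained()] result.
#' @param i Optional chain index; if given, that single completed tibble is
#'   returned, otherwise the full list.
#' @export
complete_datasets <- function(stack, i = NULL) {
  stopifnot(inherits(stack, "imputed_stack"))
  if (is.null(i)) stack$completed else stack$completed[[i]]
}

#' Long-format view of an imputed stack
#'
#' @param stack An [impute_chained()] result.
#' @return All `m` completed datasets row-bound into one tibble with a
#'   leading `.imp` chain index column.
#' @export
bind_imputations <- function(stack) {
  stopifnot(inherits(stack, "imputed_stack"))
  dplyr::bind_rows(stack$completed, .id = ".imp") |>
    dplyr::mutate(.imp = as.integer(.data$.imp))
}
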