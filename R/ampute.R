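#' Impose multivariate missingness on a complete dataset
#'
#' Masks cells of a complete rectangular dataset so that a target proportion
#' of rows ends up incomplete, following the multivariate amputation
#' approach: every row is first assigned to one candidate missingness
#' pattern (a subset of columns to be masked together), then rows are
#' selected for amputation within each pattern group. Under MCAR the
#' selection is uniform; under MAR or MNAR it is a logistic function of a
#' weighted sum score computed on standardized columns, right-tailed by
#' default (rows with high scores are more likely to lose values). MAR
#' weights load only on columns that stay observed in the pattern; MNAR
#' weights load on the columns being amputed, so missingness depends on the
#' unobserved values themselves.
#'
#' The logistic selection probabilities are shifted (on the linear scale) so
#' that the expected incomplete-row fraction equals `prop` exactly; the
#' realised fraction then varies with binomial noise only.
#'
#' @param data A complete numeric data frame.
#' @param mechanism `"MCAR"`, `"MAR"` or `"MNAR"`.
#' @param prop Target proportion of incomplete rows in `[0, 1)`; default
#'   0.35.
#' @param patterns Logical matrix, one row per pattern, one column per data
#'   column (`TRUE` = masked in that pattern). Default: one pattern per
#'   column, each masking that single column.
#' @param freqs Pattern assignment probabilities (summing to 1). Default
#'   equal.
#' @param weights Numeric matrix, same shape as `patterns`, of weighted
#'   sum-score loadings. Default: under MAR, weight 1 on every observed
#'   column of the pattern; under MNAR, weight 1 on every amputed column.
#'   Ignored under MCAR.
#' @param seed Optional integer seed.
#' @return A tibble of the same shape as `data` with masked cells set to
#'   `NA`; the complete source and the logical mask are attached as
#'   attributes and recoverable with [amputed_source()] and
#'   [amputed_mask()].
#' @examples
#' d <- simulate_friedman(500, seed = 1)
#' a <- ampute_data(d, "MCAR", seed = 2)
#' incomplete_fraction(a)
#' @export
ampute_data <- function(data,
                        mechanism = c("MCAR", "MAR", "MNAR"),
                        prop = 0.35,
                        patterns = NULL,
                        freqs = NULL,
                        weights = NULL,
                        seed = NULL) {
  mechanism <- match.arg(mechanism)
  check_numeric_df(data, "ampute_data")
  if (anyNA(data)) abort("`data` must be complete before amputation.")
  if (length(prop) != 1 || is.na(prop) || prop < 0 || prop >= 1) {
    abort("`prop` must lie in [0, 1).")
  }
  n <- nrow(data)
  p <- ncol(data)
  if (is.null(patterns)) {
    patterns <- diag(p) == 1
  }
  patterns <- as.matrix(patterns)
  storage.mode(patterns) <- "logical"
  if (nrow(patterns) < 1) abort("`patterns` must contain at least one pattern.")
  if (ncol(patterns) != p) abort("`patterns` must have one column per data column.")
  if (any(rowSums(patterns) == 0)) abort("Every pattern must ampute at least one column.")
  K <- nrow(patterns)
  freqs <- freqs %||% rep(1 / K, K)
  if (length(freqs) != K || any(freqs < 0) || abs(sum(freqs) - 1) > 1e-8) {
    abort("`freqs` must be nonnegative and sum to 1 over the patterns.")
  }
  if (is.null(weights)) {
    weights <- if (mechanism == "MNAR") patterns * 1 else (!patterns) * 1
  }
  weights <- as.matrix(weights)
  if (!all(dim(weights) == dim(patterns))) {
    abort("`weights` must have the same shape as `patterns`.")
  }
  if (mechanism == "MAR" && any(weights[patterns] != 0)) {
    abort("Under MAR, weights on amputed columns must be zero.")
  }

  set_seed_if(seed)
  pat_id <- sample.int(K, n, replace = TRUE, prob = freqs)
  miss <- logical(n)
  if (prop > 0) {
    if (mechanism == "MCAR") {
      miss <- runif(n) < prop
    } else {
      # weighted sum scores on standardized columns, scale-free weights
      z <- vapply(seq_len(p), function(j) {
        col <- data[[j]]
        s <- sd(col)
        if (s == 0) rep(0, n) else (col - mean(col)) / s
      }, numeric(n))
      for (k in seq_len(K)) {
        rows <- which(pat_id == k)
        if (length(rows) == 0) next
        wss <- drop(z[rows, , drop = FALSE] %*% weights[k, ])
        s <- sd(wss)
        if (length(rows) == 1 || is.na(s) || s == 0) {
          pr <- rep(prop, length(rows))
        } else {
          wz <- (wss - mean(wss)) / s
          shift <- uniroot(
            function(a) mean(plogis(wz + a)) - prop,
            lower = -50, upper = 50, tol = 1e-10
          )$root
          pr <- plogis(wz + shift)
        }
        miss[rows] <- runif(length(rows)) < pr
      }
    }
  }

  mask <- matrix(FALSE, n, p, dimnames = list(NULL, names(data)))
  if (any(miss)) {
    mask[miss, ] <- patterns[pat_id[miss], , drop = FALSE]
  }
  out <- as_tibble(data)
  for (j in seq_len(p)) out[[j]][mask[, j]] <- NA
  attr(out, "amputed_source") <- as_tibble(data)
  attr(out, "amputed_mask") <- mask
  class(out) <- c("amputed_df", class(out))
  out
}

#' @rdname ampute_data
#' @param x An amputed dataset produced by [ampute_data()].
#' @export
amputed_source <- function(x) attr(x, "amputed_source")

#' @rdname ampute_data
#' @export
amputed_mask <- function(x) {
  m <- attr(x, "amputed_mask")
  m %||% is.na(as.matrix(x))
}

#' Fraction of incomplete rows
#'
#' @param data A data frame, typically the output of [ampute_data()]. A row
#'   is incomplete if any of its cells is missing.
#' @return The proportion of rows with at least one missing value.
#' @export
incomplete_fraction <- function(data) {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  mean(!complete.cases(data))
}

#' Listwise deletion (complete-case reduction)
#'
#' @param data A data frame with (possibly) missing values.
#' @return A tibble containing only the fully observed rows, in their
#'   original order. Errors if no complete row remains, since a
#'   complete-case analysis is then impossible.
#' @export
listwise_delete <- function(data) {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  keep <- complete.cases(data)
  if (!any(keep)) abort("No complete rows remain after listwise deletion.")
  out <- as_tibble(as.data.frame(data)[keep, , drop = FALSE])
  out
}
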