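#' Pooling rules for per-imputation significance tests
#'
#' Combine the `m` p-values (and, for the D2 rules, test statistics and
#' parameter counts) obtained by running the same significance test on each
#' of `m` multiply imputed datasets into a single pooled p-value:
#'
#' * `pool_mpv()` — the median p-value rule: the sample median of the `m`
#'   p-values (for even `m`, the mean of the two central order statistics).
#' * `pool_mean()` — the arithmetic mean of the p-values.
#' * `pool_cauchy()` — the Cauchy combination test: the statistic
#'   \eqn{t_0 = \sum_i \tan\{(0.5 - p_i)\pi\}} is referred to a standard
#'   Cauchy distribution, \eqn{p = 1/2 - \arctan(t_0)/\pi}. Heavy Cauchy
#'   tails make the combination insensitive to the strong dependence
#'   between tests on imputed copies of the same data. P-values of exactly
#'   0 or 1 are clamped to `1e-15` / `1 - 1e-15` (with a warning) to avoid
#'   infinite tangents.
#' * `pool_d2()` — statistic pooling: with per-imputation statistics
#'   \eqn{d_i} and parameter counts \eqn{k_i}, the centre is
#'   \eqn{\bar d / \bar k} (mean statistic over mean parameter count), the
#'   between-imputation variance is \eqn{r_2 = (1 + 1/m)\,
#'   \mathrm{Var}(\sqrt{d_i})}, and
#'   \eqn{D_2 = \{\bar d/\bar k - \frac{m+1}{m-1} r_2\}/(1 + r_2)}
#'   (floored at 0) is referred to an \eqn{F(\bar k, \nu_2)} distribution
#'   with \eqn{\nu_2 = \bar k^{-3/m} (m - 1)(1 + 1/r_2)^2}. When all
#'   \eqn{d_i} are identical (\eqn{r_2 = 0}) the limit \eqn{\nu_2 \to
#'   \infty} is used.
#' * `pool_d2_alt()` — as `pool_d2()` but centred at the mean of the
#'   per-imputation quotients, \eqn{\mathrm{mean}(d_i / k_i)}, for use when
#'   the parameter count varies across imputations (as effective degrees of
#'   freedom do); the reference numerator df remains \eqn{\bar k}.
#' * `pool_single()` — no pooling: the first imputation's p-value.
#'
#' For penalized GAM smooth tests, `d` is the per-imputation approximate F
#' (or chi-square) statistic and `k` the smooth's effective degrees of
#' freedom; for B-spline likelihood ratio tests, `d` is the LRT deviance
#' and `k` the basis degrees of freedom.
#'
#' @param p Numeric vector of `m` per-imputation p-values in `[0, 1]`.
#' @param d Numeric vector of `m` nonnegative per-imputation test
#'   statistics.
#' @param k Numeric vector of `m` positive per-imputation parameter counts.
#' @return A one-row tibble with columns `method`, `statistic` (the pooled
#'   statistic where one exists, otherwise `NA`), `df1`, `df2` (reference
#'   degrees of freedom where applicable) and `p.value`.
#' @examples
#' pool_mpv(c(0.01, 0.04, 0.20))
#' pool_cauchy(c(0.01, 0.04, 0.20))
#' pool_d2(d = c(2, 3, 4), k = c(2, 2, 2))
#' @name pooling
NULL

check_p <- function(p, min_m = 1) {
  if (length(p) < min_m) {
    abort(sprintf("At least %d p-value%s required.", min_m, if (min_m > 1) "s are" else " is"))
  }
  if (anyNA(p) || any(p < 0) || any(p > 1)) abort("p-values must lie in [0, 1].")
  invisible(p)
}

pooled_row <- function(method, statistic = NA_real_, df1 = NA_real_,
                       df2 = NA_real_, p) {
  tibble(method = method, statistic = statistic, df1 = df1, df2 = df2,
         p.value = min(max(p, 0), 1))
}

#' @rdname pooling
#' @export
pool_mpv <- function(p) {
  check_p(p)
  pooled_row("mpv", p = median(p))
}

#' @rdname pooling
#' @export
pool_mean <- function(p) {
  check_p(p)
  pooled_row("mean", p = mean(p))
}

#' @rdname pooling
#' @export
pool_cauchy <- function(p) {
  check_p(p)
  eps <- 1e-15
  if (any(p < eps | p > 1 - eps)) {
    warn("Boundary p-values clamped to [1e-15, 1 - 1e-15] for the Cauchy combination.")
    p <- pmin(pmax(p, eps), 1 - eps)
  }
  t0 <- sum(tan((0.5 - p) * pi))
  # the arctan transform, evaluated on the stable branch: for |t0| > 1,
  # 1/2 - atan(t0)/pi = atan(1/t0)/pi (t0 > 0), avoiding cancellation in
  # the far tail
  pp <- if (t0 > 1) {
    atan(1 / t0) / pi
  } else if (t0 < -1) {
    1 - atan(-1 / t0) / pi
  } else {
    0.5 - atan(t0) / pi
  }
  pooled_row("cauchy", statistic = t0, p = pp)
}

#' @rdname pooling
#' @export
pool_single <- function(p) {
  check_p(p)
  pooled_row("single", p = p[1])
}

d2_core <- function(d, k, center, method) {
  m <- length(d)
  if (m < 2) {
    abort("D2 pooling needs m >= 2 imputations (use pool_single() for m = 1).")
  }
  if (length(k) != m) abort("`d` and `k` must have equal length.")
  if (anyNA(d) || any(d < 0)) abort("Statistics `d` must be nonnegative.")
  if (anyNA(k) || any(k <= 0)) abort("Parameter counts `k` must be positive.")
  kbar <- mean(k)
  r2 <- (1 + 1 / m) * var(sqrt(d))
  if (r2 == 0) {
    warn("All pooled statistics identical (r2 = 0); using the infinite-df limit.")
    D2 <- max(center, 0)
    nu2 <- Inf
  } else {
    D2 <- max((center - ((m + 1) / (m - 1)) * r2) / (1 + r2), 0)
    nu2 <- kbar^(-3 / m) * (m - 1) * (1 + 1 / r2)^2
  }
  pooled_row(method, statistic = D2, df1 = kbar, df2 = nu2,
             p = pf(D2, kbar, nu2, lower.tail = FALSE))
}

#' @rdname pooling
#' @export
pool_d2 <- function(d, k) {
  d2_core(d, k, center = mean(d) / mean(k), method = "d2")
}

#' @rdname pooling
#' @export
pool_d2_alt <- function(d, k) {
  if (length(k) != length(d)) abort("`d` and `k` must have equal length.")
  d2_core(d, k, center = mean(d / k), method = "d2_alt")
}

#' Pool per-imputation smooth tests for every covariate at once
#'
#' Data-frame-first wrapper around the pooling rules: takes the stacked
#' per-imputation test results (one row per imputation x covariate, as
#' produced by running [smooth_tests()] on each completed dataset) and
#' returns the pooled p-value of every requested rule for every covariate.
#'
#' @param tests A data frame with columns `term`, `statistic`, `df` and
#'   `p.value` (extra columns such as `.imp` are allowed and ignored).
#' @param methods Character vector of rules to apply, a subset of
#'   `c("mpv", "mean", "cauchy", "d2", "d2_alt", "single")`.
#' @return A tibble with one row per covariate x method: `term`, `method`,
#'   `statistic`, `df1`, `df2`, `p.value`.
#' @examples
#' d <- simulate_friedman(200, seed = 1)
#' a <- ampute_data(d, "MAR", seed = 2)
#' st <- impute_chained(a, m = 5, seed = 3)
#' tests <- purrr::map_dfr(complete_datasets(st), smooth_tests,
#'                         model = "bspline", .id = ".imp")
#' pool_tests(tests)
#' @export
pool_tests <- function(tests,
                       methods = c("mpv", "mean", "cauchy", "d2", "d2_alt", "single")) {
  if (!is.data.frame(tests)) abort("`tests` must be a data frame.")
  need <- c("term", "statistic", "df", "p.value")
  if (!all(need %in% names(tests))) {
    abort("`tests` must have columns term, statistic, df, p.value.")
  }
  methods <- match.arg(methods, several.ok = TRUE)
  tests |>
    dplyr::group_by(.data$term) |>
    dplyr::group_modify(function(g, key) {
      purrr::map_dfr(methods, function(mt) {
        switch(mt,
          mpv    = pool_mpv(g$p.value),
          mean   = pool_mean(g$p.value),
          cauchy = pool_cauchy(g$p.value),
          single = pool_single(g$p.value),
          d2     = pool_d2(g$statistic, g$df),
          d2_alt = pool_d2_alt(g$statistic, g$df)
        )
      })
    }) |>
    dplyr::ungroup()
}
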