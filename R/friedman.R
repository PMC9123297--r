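#' Friedman benchmark mean function
#'
#' Deterministic mean surface of the Friedman-type benchmark model
#' \deqn{f(x) = 10\,\sin(\pi x_1 x_2) + 20 (x_3 - 0.5)^2 + 10 x_4 + 5 x_5 + 0\,x_6,}
#' defined on the unit hypercube. The sixth covariate has exactly zero
#' contribution, so tests of its effect estimate the type-I error rate of a
#' testing procedure while `x1`--`x5` carry signal of varying shape
#' (trigonometric, U-shaped quadratic, strong linear, weak linear).
#'
#' @param x A numeric vector of length 6, or a matrix / data frame with
#'   columns `x1`...`x6`, all entries in `[0, 1]`.
#' @return A numeric vector of mean values, one per row.
#' @examples
#' friedman_mean(c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5))
#' @export
friedman_mean <- function(x) {
  if (is.vector(x) && is.numeric(x)) {
    x <- matrix(x, nrow = 1)
  } else if (is.data.frame(x)) {
    x <- as.matrix(x[paste0("x", 1:6)])
  }
  if (!is.matrix(x) || ncol(x) != 6) {
    abort("`x` must be a length-6 vector or a matrix/data frame with columns x1...x6.")
  }
  if (anyNA(x) || any(x < 0) || any(x > 1)) {
    abort("All covariate values must lie in [0, 1].")
  }
  10 * sin(x[, 1] * x[, 2] * pi) + 20 * (x[, 3] - 0.5)^2 +
    10 * x[, 4] + 5 * x[, 5] + 0 * x[, 6]
}

#' Which covariates carry true signal
#'
#' @return A tibble with columns `term` (`x1`...`x6`) and `truth`
#'   (`"signal"` for `x1`--`x5`, `"null"` for `x6`). Rejections of the null
#'   for signal terms measure power; rejections for `x6` measure type-I
#'   error. This labelling is consumed only when summarising simulation
#'   results, never by any fitting code.
#' @export
friedman_truth <- function() {
  tibble(
    term = paste0("x", 1:6),
    truth = c(rep("signal", 5), "null")
  )
}

#' Simulate a benchmark dataset from the Friedman model
#'
#' Draws six independent uniform(0, 1) covariates and an outcome from the
#' Friedman benchmark surface ([friedman_mean()]). For a normal outcome,
#' \eqn{y = f(x) + \varepsilon} with \eqn{\varepsilon \sim N(0, \sigma^2)}
#' (default variance 9). For a binary outcome the linear signal (including
#' the noise term by default, see `include_noise`) is standardized across
#' the dataset to a unit-variance score, mapped through the inverse logit to
#' a success probability, and a Bernoulli outcome is drawn; the average
#' event rate is therefore close to 1/2 and the log-odds follow the same
#' functional form in each covariate.
#'
#' Covariates are drawn column by column (`x1` first), then the noise, so a
#' dataset is bit-reproducible for a given `seed`.
#'
#' @param n Number of rows (positive integer).
#' @param outcome `"normal"` or `"binary"`.
#' @param noise_sd Standard deviation of the additive noise (default 3,
#'   i.e. variance 9). Must be nonnegative.
#' @param include_noise Binary outcomes only: whether the additive noise
#'   enters the score before standardization (default `TRUE`).
#' @param seed Optional integer seed; same seed, same dataset.
#' @return A tibble with columns `x1`...`x6` and `y`.
#' @examples
#' d <- simulate_friedman(100, seed = 1)
#' head(d)
#' @export
simulate_friedman <- function(n,
                              outcome = c("normal", "binary"),
                              noise_sd = 3,
                              include_noise = TRUE,
                              seed = NULL) {
  outcome <- match.arg(outcome)
  if (length(n) != 1 || is.na(n) || n < 1 || n != round(n)) {
    abort("`n` must be a positive integer.")
  }
  if (length(noise_sd) != 1 || is.na(noise_sd) || noise_sd < 0) {
    abort("`noise_sd` must be a nonnegative number.")
  }
  set_seed_if(seed)
  x <- vapply(1:6, function(j) runif(n), numeric(n))
  if (n == 1) x <- matrix(x, nrow = 1)
  colnames(x) <- paste0("x", 1:6)
  f <- friedman_mean(x)
  eps <- rnorm(n, 0, noise_sd)
  if (outcome == "normal") {
    y <- f + eps
  } else {
    s <- if (include_noise) f + eps else f
    if (n < 2 || sd(s) == 0) {
      abort("Binary outcome requires a non-degenerate signal (n >= 2 with non-constant score).")
    }
    z <- (s - mean(s)) / sd(s)
    y <- rbinom(n, 1, plogis(z))
  }
  out <- as_tibble(x)
  out$y <- y
  out
}
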