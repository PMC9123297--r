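test_that("the median p-value rule matches direct order statistics", {
  expect_equal(pool_mpv(c(0.2, 0.5, 0.9))$p.value, 0.5)
  expect_equal(pool_mpv(0.03)$p.value, 0.03)
  # even m: mean of the two central order statistics
  expect_equal(pool_mpv(c(0.01, 0.04, 0.06, 0.90))$p.value, 0.05)
  expect_error(pool_mpv(numeric(0)), "At least")
  expect_error(pool_mpv(c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("the mean p-value rule is the arithmetic mean", {
  expect_equal(pool_mean(c(0.2, 0.5, 0.9))$p.value, mean(c(0.2, 0.5, 0.9)))
  expect_equal(pool_mean(rep(0.37, 8))$p.value, 0.37)
  expect_equal(pool_mean(0.11)$p.value, 0.11)
})

test_that("the Cauchy combination follows the arctan transform", {
  # symmetry point
  expect_equal(pool_cauchy(c(0.5, 0.5, 0.5))$p.value, 0.5)
  # m = 1 identity: the transform inverts itself
  for (p in c(0.01, 0.2, 0.77)) {
    expect_equal(pool_cauchy(p)$p.value, p, tolerance = 1e-12)
  }
  # direct evaluation of the printed transform (frozen)
  r <- pool_cauchy(c(0.01, 0.04, 0.10))
  expect_equal(r$statistic, tan(0.49 * pi) + tan(0.46 * pi) + tan(0.40 * pi),
               tolerance = 1e-12)
  expect_equal(r$p.value, 0.00743336088567492, tolerance = 1e-10)
})

test_that("Cauchy combination equals the standard-Cauchy survival function", {
  set.seed(1)
  for (i in 1:1000) {
    p <- runif(sample(1:30, 1))
    r <- pool_cauchy(p)
    expect_equal(r$p.value, pcauchy(r$statistic, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("boundary p-values are clamped for the Cauchy combination", {
  expect_warning(r <- pool_cauchy(c(0, 0.5)), "clamped")
  expect_lt(r$p.value, 1e-14)
  expect_warning(r1 <- pool_cauchy(c(1, 1)), "clamped")
  expect_gt(r1$p.value, 1 - 1e-10)
})

test_that("D2 agrees with hand-computed values on a small fixture", {
  # d = (2, 3, 4), k = (2, 2, 2), m = 3, evaluated step by step:
  # r2 = (4/3) * var(sqrt(d)) = 0.1146584...; centre = 3/2;
  # D2 = (1.5 - 2 * r2) / (1 + r2) = 1.1399752...;
  # nu2 = 2^(-1) * 2 * (1 + 1/r2)^2 = 94.50863...
  r <- pool_d2(c(2, 3, 4), c(2, 2, 2))
  expect_equal(r$statistic, 1.1399752931093, tolerance = 1e-10)
  expect_equal(r$df1, 2)
  expect_equal(r$df2, 94.5086321906475, tolerance = 1e-8)
  expect_equal(r$p.value, 0.324184660322503, tolerance = 1e-9)
})

test_that("D2 zero-variance limit reduces to a scaled chi-square", {
  expect_warning(r <- pool_d2(c(3, 3, 3), c(2, 2, 2)), "identical")
  expect_equal(r$statistic, 1.5)
  expect_equal(r$p.value, pchisq(3, 2, lower.tail = FALSE), tolerance = 1e-12)
  # enormous statistics give a vanishing pooled p
  quiet({
    expect_lt(pool_d2(c(1e4, 1e4 + 1, 1e4 - 1), c(2, 2, 2))$p.value, 1e-10)
  })
})

test_that("the alternative D2 centres on the mean quotient", {
  # equal parameter counts: both centres coincide, results identical
  r1 <- pool_d2(c(2, 3, 4), c(3, 3, 3))
  r2 <- pool_d2_alt(c(2, 3, 4), c(3, 3, 3))
  expect_equal(r1[c("statistic", "df1", "df2", "p.value")],
               r2[c("statistic", "df1", "df2", "p.value")])
  # unequal k: centres diverge, mean(d/k) = 1.5 vs mean(d)/mean(k) = 4/3
  a <- quiet(pool_d2_alt(c(4, 4), c(2, 4))) # d identical: r2 = 0 limit
  b <- quiet(pool_d2(c(4, 4), c(2, 4)))
  expect_false(isTRUE(all.equal(a$p.value, b$p.value)))
  expect_lt(a$p.value, b$p.value) # larger centre, smaller tail probability
})

test_that("D2 variants demand at least two imputations and valid input", {
  expect_error(pool_d2(2, 2), "m >= 2")
  expect_error(pool_d2_alt(2, 2), "m >= 2")
  expect_error(pool_d2(c(-1, 2), c(2, 2)), "nonnegative")
  expect_error(pool_d2(c(1, 2), c(0, 2)), "positive")
  expect_error(pool_d2(c(1, 2), c(2, 2, 2)), "equal length")
})

test_that("negative D2 centres floor at zero with pooled p = 1", {
  quiet({
    r <- pool_d2(c(0, 4), c(100, 100)) # tiny centre, large between-variance
    expect_equal(r$statistic, 0)
    expect_equal(r$p.value, 1)
  })
})

test_that("single imputation takes the first chain's p-value", {
  expect_equal(pool_single(0.5)$p.value, 0.5)
  expect_equal(pool_single(c(0.7, 0.01, 0.02))$p.value, 0.7)
  p <- c(0.7, runif(9))
  expect_equal(pool_single(p)$p.value, pool_single(p[c(1, sample(2:10))])$p.value)
})

test_that("pooled p-values respect range, permutation and monotonicity properties", {
  set.seed(2)
  for (i in 1:50) {
    p <- runif(25)
    perm <- sample(p)
    for (f in list(pool_mpv, pool_mean, pool_cauchy)) {
      r <- f(p)
      expect_gte(r$p.value, 0)
      expect_lte(r$p.value, 1)
      expect_equal(r$p.value, f(perm)$p.value, tolerance = 1e-12)
    }
    expect_gte(pool_mpv(p)$p.value, min(p))
    expect_lte(pool_mpv(p)$p.value, max(p))
    # decreasing one p never increases the pooled p (strict for Cauchy)
    j <- sample(25, 1)
    p2 <- p
    p2[j] <- p[j] / 2
    expect_lte(pool_mpv(p2)$p.value, pool_mpv(p)$p.value)
    expect_lte(pool_mean(p2)$p.value, pool_mean(p)$p.value)
    expect_lt(pool_cauchy(p2)$p.value, pool_cauchy(p)$p.value)
  }
})

test_that("null-uniform p-values produce the expected conservativeness ordering", {
  set.seed(3)
  m <- 25
  B <- 10000
  P <- matrix(runif(B * m), B, m)
  mpv_rej <- mean(apply(P, 1, median) < 0.05)
  mean_rej <- mean(rowMeans(P) < 0.05)
  cauchy_rej <- mean((0.5 - atan(rowSums(tan((0.5 - P) * pi))) / pi) < 0.05)
  # median and mean of 25 independent uniforms essentially never fall
  # below 0.05: both rules are deeply conservative in this regime
  expect_lt(mpv_rej, 0.05)
  expect_lte(mean_rej, mpv_rej)
  expect_lt(mean_rej, 0.005)
  # the summed Cauchy statistic is Cauchy(0, m) under independence, so its
  # rejection rate has the closed form below (heavily anticonservative --
  # the over-rejection the combination is known for in this setting)
  cauchy_exact <- 0.5 - atan(tan(0.45 * pi) / m) / pi
  expect_lt(abs(cauchy_rej - cauchy_exact), 0.02)
  expect_gt(cauchy_rej, mpv_rej)
})

test_that("pool_tests applies every rule per covariate", {
  set.seed(4)
  tests <- tidyr::expand_grid(.imp = 1:5, term = c("x1", "x2"))
  tests$statistic <- rchisq(10, 3)
  tests$df <- 3
  tests$p.value <- pchisq(tests$statistic, 3, lower.tail = FALSE)
  out <- pool_tests(tests)
  expect_equal(nrow(out), 12)
  expect_setequal(unique(out$method),
                  c("mpv", "mean", "cauchy", "d2", "d2_alt", "single"))
  x1 <- tests[tests$term == "x1", ]
  expect_equal(out$p.value[out$term == "x1" & out$method == "mpv"],
               median(x1$p.value))
  expect_equal(out$p.value[out$term == "x1" & out$method == "d2"],
               pool_d2(x1$statistic, x1$df)$p.value)
  expect_error(pool_tests(tests[, c("term", "p.value")]), "columns")
})
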