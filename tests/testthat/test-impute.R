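test_that("initial_fill draws from observed column values and preserves observed cells", {
  toy <- tibble::tibble(a = c(1, 2, NA, NA), b = c(NA, 5, 6, 7))
  f <- initial_fill(toy, seed = 1)
  expect_false(anyNA(f))
  expect_support_contained(f$a[3:4], c(1, 2))
  expect_support_contained(f$b[1], c(5, 6, 7))
  expect_identical(f$a[1:2], c(1, 2))
  expect_identical(initial_fill(toy, seed = 9), initial_fill(toy, seed = 9))
  # complete data pass through untouched
  comp <- tibble::tibble(a = 1:3 * 1.0)
  expect_identical(initial_fill(comp, seed = 1), comp)
  expect_error(initial_fill(tibble::tibble(a = c(NA_real_, NA_real_))),
               "no observed values")
})

test_that("PMM imputations stay on the observed support", {
  set.seed(100)
  for (i in 1:100) {
    n <- 50
    d <- tibble::tibble(
      x1 = runif(n), x2 = runif(n),
      y = rnorm(n, 5 * runif(n))
    )
    miss <- seq_len(n) %in% sample.int(n, 15)
    d$y[miss] <- NA
    work <- initial_fill(d)
    vals <- impute_pmm_column(work, "y", miss, donors = 5)
    expect_support_contained(vals, d$y[!miss])
  }
})

test_that("PMM with a single donor copies the exactly matching donor", {
  # row 5 duplicates row 4's predictor, truth is noiseless, so its
  # prediction coincides with donor 4's and donor_count = 1 must copy it
  d <- tibble::tibble(x1 = c(1, 2, 3, 4, 4), y = 2 * c(1, 2, 3, 4, 4))
  miss <- c(FALSE, FALSE, FALSE, FALSE, TRUE)
  d$y[5] <- NA
  work <- d
  work$y[5] <- 0
  set.seed(1)
  expect_identical(impute_pmm_column(work, "y", miss, donors = 1), 8)
})

test_that("PMM tracks a noiseless linear relationship", {
  lin <- linear_missing_data(500, seed = 2)
  work <- initial_fill(lin$data, seed = 3)
  set.seed(4)
  vals <- impute_pmm_column(work, "y", lin$miss, donors = 5)
  expect_gte(min(vals), min(lin$data$y, na.rm = TRUE))
  expect_lte(max(vals), max(lin$data$y, na.rm = TRUE))
  rho <- cor(vals, lin$data$x1[lin$miss], method = "spearman")
  expect_gt(rho, 0.9)
})

test_that("PMM requires enough donors and complete predictors", {
  d <- tibble::tibble(x1 = runif(6), y = c(rnorm(3), NA, NA, NA))
  expect_error(impute_pmm_column(d, "y", donors = 5), "donors")
  d2 <- tibble::tibble(x1 = c(NA, runif(9)), y = c(rnorm(8), NA, NA))
  expect_error(impute_pmm_column(d2, "y", donors = 2), "complete")
})

test_that("RF imputations stay on the observed support", {
  set.seed(200)
  for (i in 1:20) {
    n <- 60
    d <- tibble::tibble(x1 = runif(n), x2 = runif(n), y = rnorm(n))
    miss <- seq_len(n) %in% sample.int(n, 15)
    d$y[miss] <- NA
    work <- initial_fill(d)
    vals <- impute_rf_column(work, "y", miss, n_trees = 5)
    expect_support_contained(vals, d$y[!miss])
  }
})

test_that("RF imputes a constant observed column as that constant", {
  d <- tibble::tibble(x1 = runif(10), y = c(rep(3, 7), NA, NA, NA))
  miss <- is.na(d$y)
  work <- initial_fill(d, seed = 1)
  expect_warning(vals <- impute_rf_column(work, "y", miss), "constant")
  expect_identical(vals, rep(3, 3))
})

test_that("chained imputation preserves observed cells across all m completions", {
  d <- simulate_friedman(300, seed = 5)
  a <- ampute_data(d, "MAR", seed = 6)
  mask <- amputed_mask(a)
  for (method in c("pmm", "rf")) {
    st <- impute_chained(a, method = method, m = 3, seed = 7)
    for (cc in complete_datasets(st)) {
      expect_false(anyNA(cc))
      expect_identical(as.matrix(cc)[!mask], as.matrix(d)[!mask])
    }
  }
})

test_that("imputed cells vary between chains", {
  d <- simulate_friedman(300, seed = 8)
  a <- ampute_data(d, "MCAR", seed = 9)
  st <- impute_chained(a, m = 5, seed = 10)
  mask <- amputed_mask(a)
  cells <- which(mask, arr.ind = TRUE)
  draws <- vapply(complete_datasets(st), function(cc) {
    as.matrix(cc)[cells[1:50, , drop = FALSE]]
  }, numeric(50))
  # across 50 missing cells, the 5 chains almost surely disagree somewhere
  expect_true(any(apply(draws, 1, function(v) length(unique(v)) > 1)))
  # and most individual cells show between-imputation variability
  expect_gt(mean(apply(draws, 1, function(v) length(unique(v)) > 1)), 0.5)
})

test_that("a dataset without missing cells yields m identical copies", {
  d <- simulate_friedman(100, seed = 11)
  st <- impute_chained(d, m = 3, seed = 12)
  expect_identical(st$completed[[1]], d)
  expect_identical(st$completed[[2]], d)
  expect_identical(st$completed[[3]], d)
})

test_that("chained imputation is reproducible and validates input", {
  d <- simulate_friedman(200, seed = 13)
  a <- ampute_data(d, "MAR", seed = 14)
  s1 <- impute_chained(a, m = 2, seed = 15)
  s2 <- impute_chained(a, m = 2, seed = 15)
  expect_identical(s1$completed, s2$completed)
  expect_false(identical(s1$completed[[1]], s1$completed[[2]]))
  bad <- tibble::tibble(a = rep(NA_real_, 5), b = rnorm(5))
  expect_error(impute_chained(bad, m = 1), "entirely missing")
})

test_that("PMM recovers the true mean of MAR-amputed cells", {
  # under MAR the deleted values are a selected (shifted) subsample; the
  # regression conditioning absorbs the selection, so imputed draws should
  # track the true mean of the deleted cells, not the observed-cell mean
  d <- simulate_friedman(1000, seed = 16)
  a <- ampute_data(d, "MAR", seed = 17)
  st <- impute_chained(a, m = 10, seed = 18)
  mask <- amputed_mask(a)
  for (cl in colnames(mask)[colSums(mask) > 30]) {
    truth <- d[[cl]][mask[, cl]]
    imp <- unlist(lapply(st$completed, function(cc) cc[[cl]][mask[, cl]]))
    # Monte-Carlo SD of a mean of n_miss dependent draws, bounded by the
    # per-cell SD (chains are positively correlated, so this is generous)
    expect_lt(abs(mean(imp) - mean(truth)), 3 * sd(d[[cl]]) / sqrt(length(truth) / 4))
  }
})
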