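# shared fixtures, built in code

# tiny two-column dataset with MCAR-missing y, exact linear truth
linear_missing_data <- function(n, miss_frac = 0.3, seed = 1) {
  set.seed(seed)
  x1 <- runif(n)
  y <- 2 * x1
  miss <- seq_len(n) %in% sample.int(n, round(miss_frac * n))
  ymiss <- y
  ymiss[miss] <- NA
  list(data = tibble::tibble(x1 = x1, y = ymiss), truth = y, miss = miss)
}

expect_support_contained <- function(imputed, observed) {
  expect_true(all(imputed %in% observed))
}

quiet <- function(expr) suppressWarnings(expr)
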