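#' Configure a Monte-Carlo pooling-comparison scenario
#'
#' Bundles every knob of one simulation scenario: generate Friedman
#' benchmark datasets, fit the full-data benchmark model, ampute, fit the
#' complete-case benchmark, multiply impute by chained equations, fit the
#' same smooth model on every completed dataset, and pool the per-covariate
#' tests by every rule. Replicated `S` times, the rejection proportion at
#' level `alpha` estimates power for the signal covariates `x1`--`x5` and
#' the type-I error rate for the null covariate `x6`.
#'
#' Defaults are desk-scale (`S = 500`, `n = 250`); a full-scale study uses
#' `S = 10000`.
#'
#' @param outcome `"normal"` or `"binary"` outcome generation.
#' @param mechanism Missingness mechanism: `"MAR"` (default), `"MCAR"` or
#'   `"MNAR"`.
#' @param imputation Column imputer: `"pmm"` or `"rf"`.
#' @param model Smooth model for testing: `"gam"` or `"bspline"`.
#' @param fit_method GAM smoothing selection: `"ML"` (default), `"REML"`,
#'   `"GCV"`.
#' @param S Number of Monte-Carlo replicates.
#' @param n Rows per simulated dataset.
#' @param m Number of imputations (default 25).
#' @param prop Target incomplete-row proportion (default 0.35).
#' @param alpha Rejection level (default 0.05).
#' @param noise_sd Outcome noise standard deviation (default 3).
#' @param donors,n_trees,n_cycles Imputer settings, see [impute_chained()].
#' @param seed Root seed; it fully determines every replicate through a
#'   per-replicate, per-stage substream hierarchy.
#' @param n_workers Parallel workers for [run_scenario()] (forked; results
#'   are identical for any worker count).
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(outcome = c("normal", "binary"),
                            mechanism = c("MAR", "MCAR", "MNAR"),
                            imputation = c("pmm", "rf"),
                            model = c("gam", "bspline"),
                            fit_method = c("ML", "REML", "GCV"),
                            S = 500,
                            n = 250,
                            m = 25,
                            prop = 0.35,
                            alpha = 0.05,
                            noise_sd = 3,
                            donors = 5,
                            n_trees = 10,
                            n_cycles = 5,
                            seed = 1,
                            n_workers = 1) {
  cfg <- list(
    outcome = match.arg(outcome), mechanism = match.arg(mechanism),
    imputation = match.arg(imputation), model = match.arg(model),
    fit_method = match.arg(fit_method),
    S = S, n = n, m = m, prop = prop, alpha = alpha, noise_sd = noise_sd,
    donors = donors, n_trees = n_trees, n_cycles = n_cycles,
    seed = seed, n_workers = n_workers
  )
  if (cfg$S < 1) abort("`S` must be at least 1.")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) abort("`alpha` must lie in (0, 1).")
  structure(cfg, class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf(
    "<scenario_config> %s outcome, %s, %s imputation, %s (%s)\n  S = %d, n = %d, m = %d, prop = %.2f, alpha = %.2f, seed = %d\n",
    x$outcome, x$mechanism, toupper(x$imputation), x$model, x$fit_method,
    x$S, x$n, x$m, x$prop, x$alpha, x$seed
  ))
  invisible(x)
}

# one replicate's raw ingredients: full-data tests, complete-case tests and
# the per-chain test results (long, with .imp). Stage seeds derive from the
# replicate seed so that e.g. changing m never perturbs the simulated data.
replicate_tests <- function(config, replicate_seed, m = config$m) {
  sim <- simulate_friedman(config$n, outcome = config$outcome,
                           noise_sd = config$noise_sd,
                           seed = child_seed(replicate_seed, 1))
  amp <- ampute_data(sim, mechanism = config$mechanism, prop = config$prop,
                     seed = child_seed(replicate_seed, 2))
  stack <- impute_chained(amp, method = config$imputation, m = m,
                          n_cycles = config$n_cycles, donors = config$donors,
                          n_trees = config$n_trees,
                          seed = child_seed(replicate_seed, 3))
  fit1 <- function(d) {
    smooth_tests(d, model = config$model, k = 10, df = 10,
                 fit_method = config$fit_method)
  }
  list(
    full = fit1(sim),
    complete_case = fit1(listwise_delete(amp)),
    chains = purrr::map_dfr(complete_datasets(stack), fit1, .id = ".imp") |>
      dplyr::mutate(.imp = as.integer(.data$.imp))
  )
}

pool_chain_tests <- function(chains, m) {
  sub <- dplyr::filter(chains, .data$.imp <= m)
  methods <- c("mpv", "mean", "cauchy", "single")
  if (m >= 2) methods <- c(methods, "d2", "d2_alt")
  pool_tests(sub, methods = methods)
}

#' Run one replicate of the simulation pipeline
#'
#' Executes simulate, full-data fit, ampute, complete-case fit, chained
#' imputation, per-imputation fits and all pooling rules for a single
#' replicate, and returns the whole p-value record.
#'
#' @param config A [scenario_config()].
#' @param replicate_seed Integer seed for this replicate; the same seed
#'   reproduces the record bit for bit.
#' @return A tibble with one row per covariate x method (`full_data`,
#'   `complete_case`, plus every pooling rule): `term`, `method`,
#'   `statistic`, `df1`, `df2`, `p.value`.
#' @examples
#' cfg <- scenario_config(S = 1, n = 150, m = 3, model = "bspline")
#' run_replicate(cfg, replicate_seed = 7)
#' @export
run_replicate <- function(config, replicate_seed) {
  stopifnot(inherits(config, "scenario_config"))
  parts <- replicate_tests(config, replicate_seed)
  bench <- function(tests, label) {
    dplyr::transmute(tests, term = .data$term, method = label,
                     statistic = .data$statistic, df1 = .data$df,
                     df2 = NA_real_, p.value = .data$p.value)
  }
  dplyr::bind_rows(
    bench(parts$full, "full_data"),
    bench(parts$complete_case, "complete_case"),
    pool_chain_tests(parts$chains, config$m)
  )
}

run_many <- function(config, worker) {
  seeds <- vapply(seq_len(config$S), function(i) child_seed(config$seed, 100, i),
                  integer(1))
  runner <- if (config$n_workers > 1) {
    function(f) parallel::mclapply(seeds, f, mc.cores = config$n_workers,
                                   mc.preschedule = TRUE)
  } else {
    function(f) lapply(seeds, f)
  }
  res <- runner(function(s) {
    tryCatch(worker(s), error = function(e) structure(conditionMessage(e),
                                                      class = "replicate_failure"))
  })
  failed <- vapply(res, inherits, logical(1), "replicate_failure")
  if (mean(failed) > 0.05) {
    abort(sprintf(
      "%d of %d replicates failed (> 5%%). First failure: %s",
      sum(failed), config$S, res[[which(failed)[1]]]
    ))
  }
  if (any(failed)) {
    warn(sprintf("%d of %d replicates failed and were skipped.", sum(failed), config$S))
  }
  res[!failed]
}

aggregate_rejections <- function(records, alpha, extra_groups = character(0)) {
  dplyr::bind_rows(records) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("term", "method", extra_groups)))) |>
    dplyr::summarise(
      n_reps = dplyr::n(),
      rejections = sum(.data$p.value < alpha),
      rate = .data$rejections / .data$n_reps,
      mc_se = sqrt(.data$rate * (1 - .data$rate) / .data$n_reps),
      .groups = "drop"
    ) |>
    dplyr::left_join(friedman_truth(), by = "term") |>
    dplyr::relocate("term", "truth")
}

#' Run a full Monte-Carlo scenario
#'
#' Repeats [run_replicate()] over `S` independent replicate seeds (optionally
#' in parallel; the result is identical for any worker count) and tabulates
#' the proportion of replicates in which each method rejected each
#' covariate's null at level `alpha`. Replicates whose model fits fail are
#' skipped and counted; more than 5% failures aborts the run.
#'
#' @param config A [scenario_config()].
#' @return A `rejection_table` tibble: one row per covariate x method with
#'   `truth` (`signal`/`null`), `n_reps`, `rejections`, `rate` and the
#'   binomial Monte-Carlo standard error `mc_se`. For signal covariates the
#'   rate is power; for `x6` it is the empirical type-I error.
#' @export
run_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  records <- run_many(config, function(s) run_replicate(config, s))
  out <- aggregate_rejections(records, config$alpha)
  attr(out, "config") <- config
  class(out) <- c("rejection_table", class(out))
  out
}

#' Rejection rates as a function of the number of imputations
#'
#' For each replicate a single set of `max(m_grid)` imputation chains is
#' generated and each grid point `m` pools only the first `m` chains, so
#' the curves are comparable within replicate; full-data and complete-case
#' benchmarks are carried along unchanged. The `m = 1` point of every
#' p-value-based rule coincides with the single-imputation method by
#' construction; the D2 rules require `m >= 2` and are absent at `m = 1`.
#'
#' @param config A [scenario_config()]; its `m` is ignored in favour of
#'   `m_grid`.
#' @param m_grid Increasing vector of positive imputation counts.
#' @return A `rejection_table` tibble with an additional `m` column.
#' @export
sweep_imputations <- function(config, m_grid = c(1, 2, 5, 10, 25)) {
  stopifnot(inherits(config, "scenario_config"))
  m_grid <- sort(unique(as.integer(m_grid)))
  if (any(m_grid < 1)) abort("`m_grid` must contain positive integers.")
  m_max <- max(m_grid)
  records <- run_many(config, function(s) {
    parts <- replicate_tests(config, s, m = m_max)
    purrr::map_dfr(m_grid, function(mm) {
      dplyr::mutate(pool_chain_tests(parts$chains, mm), m = mm)
    })
  })
  out <- aggregate_rejections(records, config$alpha, extra_groups = "m")
  attr(out, "config") <- config
  class(out) <- c("rejection_table", class(out))
  out
}
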