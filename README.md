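# mipool

Pooling significance tests of smooth covariate effects after multiple
imputation.

## The problem

When a dataset with missing values is analysed by multiple imputation via
chained equations (MICE), the analysis is run on each of *m* completed
copies and the *m* results are pooled. Rubin's rules do the pooling when
the analysis yields a normally distributed estimate — but the significance
test of a *smooth* term (the approximate F test of a penalized GAM smooth,
or the likelihood ratio test of a cubic B-spline basis) has no such
estimate. What is available per imputation is a test statistic *d*ᵢ, a
parameter count *k*ᵢ (effective degrees of freedom for a GAM smooth, basis
degrees of freedom for a B-spline) and a p-value *p*ᵢ.

`mipool` implements the practical pooling rules for this situation:

- **median p-value (MPV)** — median(*p*₁, …, *p*ₘ);
- **mean p-value** — the arithmetic mean of the *p*ᵢ;
- **Cauchy combination** — *t*₀ = Σᵢ tan{(0.5 − *p*ᵢ)π}, pooled
  *p* = ½ − arctan(*t*₀)/π;
- **D2** — centre *d̄*/*k̄* shrunk by the between-imputation variance
  *r*₂ = (1 + 1/m)·Var(√*d*ᵢ) and referred to F(*k̄*, *ν*₂) with
  *ν*₂ = *k̄*^(−3/m)(m − 1)(1 + 1/*r*₂)²;
- **alternative D2** — the same with centre mean(*d*ᵢ/*k*ᵢ), for varying
  *k*ᵢ;
- **single imputation** — the first chain's p-value, unpooled.

It also ships the full Monte-Carlo machinery used to compare the rules: a
Friedman-type benchmark generator (five signal covariates of varying
functional form, one exactly null), multivariate amputation under MCAR,
MAR and MNAR, chained-equation imputation with predictive-mean-matching
and random-forest column imputers, both smooth-model families, and a
harness that tabulates power and type-I error against full-data and
complete-case benchmarks.

It is intended for biostatisticians who fit flexible (GAM / spline)
models to incomplete data and need a defensible single p-value per
covariate, and for methodologists who want to study pooling-rule
behaviour under controlled missingness.

## Worked example

Simulate a benchmark dataset, remove 35% of rows' values under MAR,
impute with PMM, fit a B-spline model per imputation, and pool:

```r
library(mipool)
library(purrr)

d  <- simulate_friedman(500, seed = 1)      # x1..x6 uniform, y = f(x) + N(0, 9)
a  <- ampute_data(d, "MAR", prop = 0.35, seed = 2)
incomplete_fraction(a)
#> [1] 0.342

st <- impute_chained(a, method = "pmm", m = 25, seed = 3)
tests <- map_dfr(complete_datasets(st), smooth_tests,
                 model = "bspline", .id = ".imp")
pool_tests(tests) |> dplyr::filter(term %in% c("x4", "x6"))
#> # A tibble: 12 × 6
#>    term  method statistic   df1    df2  p.value
#>    <chr> <chr>      <dbl> <dbl>  <dbl>    <dbl>
#>  1 x4    mpv    NA           NA    NA  6.40e-44
#>  2 x4    mean   NA           NA    NA  8.53e-41
#>  3 x4    cauchy  7.89e+15    NA    NA  0
#>  4 x4    d2      2.89e+ 0    10 18631. 1.32e- 3
#>  5 x4    d2_alt  2.89e+ 0    10 18631. 1.32e- 3
#>  6 x4    single NA           NA    NA  1.40e-41
#>  7 x6    mpv    NA           NA    NA  1.21e- 1
#>  8 x6    mean   NA           NA    NA  1.56e- 1
#>  9 x6    cauchy  8.61e+ 1    NA    NA  3.70e- 3
#> 10 x6    d2      1.36e- 1    10 90329. 9.99e- 1
#> 11 x6    d2_alt  1.36e- 1    10 90329. 9.99e- 1
#> 12 x6    single NA           NA    NA  5.60e- 2
```

Every rule flags the strong linear effect `x4` (p ≪ 0.001), and the D2
rules — which discount their centre by the between-imputation variance of
the statistics — are, as usual, the most conservative about it. The null
covariate `x6` shows the rules' characters in one draw: MPV and mean-p
stay comfortably non-significant (p ≈ 0.12–0.16), single imputation
hovers at 0.056, and the Cauchy combination — dominated by its smallest
inputs — declares p = 0.0037, the over-rejection of a true null it is
known for in this setting.

A Monte-Carlo comparison of the rules (power for `x1`–`x5`, type-I error
for `x6`) runs through one call; `autoplot()` draws the rejection table:

```r
cfg <- scenario_config(outcome = "normal", mechanism = "MAR",
                       imputation = "pmm", model = "gam",
                       S = 200, n = 250, m = 10, seed = 20260928)
rt <- run_scenario(cfg)
dplyr::filter(rt, term == "x6")
#> # A tibble: 8 × 7
#>   term  truth method        n_reps rejections  rate   mc_se
#>   <chr> <chr> <chr>          <int>      <int> <dbl>   <dbl>
#> 1 x6    null  cauchy           200         97 0.485 0.0353
#> 2 x6    null  complete_case    200          9 0.045 0.0147
#> 3 x6    null  d2               200          3 0.015 0.00860
#> 4 x6    null  d2_alt           200          3 0.015 0.00860
#> 5 x6    null  full_data        200         12 0.06  0.0168
#> 6 x6    null  mean             200          8 0.04  0.0139
#> 7 x6    null  mpv              200         13 0.065 0.0174
#> 8 x6    null  single           200         27 0.135 0.0242
autoplot(rt)
```

The type-I error column reproduces the known qualitative picture: the
Cauchy combination heavily over-rejects a true null (0.485), single
imputation is inflated (0.135), the MPV rule (0.065) tracks the
full-data benchmark (0.060), and the D2 rules are conservative (0.015).

A thin command-line wrapper over the same functions is installed at
`inst/scripts/mipool-cli.R` (verbs: `simulate`, `ampute`, `impute`,
`fit`, `pool`, `run-scenario`, `sweep-m`).

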