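test_that("PMM never invents values and respects observed data", {
  set.seed(1)
  n <- 120
  d <- data.frame(y = rnorm(n, 10, 2), x1 = rnorm(n), x2 = rnorm(n))
  d$y[sample(n, 25)] <- NA
  obs_pool <- d$y[!is.na(d$y)]
  done <- pmm_impute(d, "y", c("x1", "x2"), k = 5, m = 4, seed = 3)
  expect_length(done, 4)
  for (comp in done) {
    expect_false(anyNA(comp$y))
    expect_identical(comp$y[!is.na(d$y)], obs_pool)       # untouched
    expect_true(all(comp$y[is.na(d$y)] %in% obs_pool))    # donor property
  }
  # imputations differ across m (parameter draws differ)
  expect_false(identical(done[[1]]$y, done[[2]]$y))
  # determinism
  expect_identical(done, pmm_impute(d, "y", c("x1", "x2"), k = 5, m = 4,
                                    seed = 3))
})

test_that("PMM edge cases: zero missingness and too few observed rows", {
  d <- data.frame(y = rnorm(30), x = rnorm(30))
  done <- pmm_impute(d, "y", "x", m = 3, seed = 1)
  expect_identical(done, list(d, d, d))
  d2 <- data.frame(y = c(rnorm(4), rep(NA, 10)), x = rnorm(14),
                   z = rnorm(14), w = rnorm(14))
  expect_error(pmm_impute(d2, "y", c("x", "z", "w"), k = 5, m = 2),
               "fewer observed rows")
  expect_error(pmm_impute(d, "y", "x", m = 1), "at least two")
})

test_that("PMM matches donors by predicted value", {
  # strong linear signal, tiny noise: donors must come from nearby x
  set.seed(2)
  n <- 200
  d <- data.frame(x = sort(rnorm(n)))
  d$y <- 3 * d$x + rnorm(n, 0, 0.05)
  miss <- c(20, 100, 180)
  truth <- d$y[miss]
  d$y[miss] <- NA
  done <- pmm_impute(d, "y", "x", k = 5, m = 10, seed = 4)
  imput <- sapply(done, function(comp) comp$y[miss])
  expect_lt(max(abs(rowMeans(imput) - truth)), 0.5)
})

test_that("Rubin's rules: worked example, invariant, degenerate cases", {
  pool <- rubin_pool(c(0, 1), c(0, 0))
  expect_equal(pool$estimate, 0.5)
  expect_equal(pool$between_var, 0.5)
  expect_equal(pool$total_var, 0.75)  # 0 + (1 + 1/2) * 0.5
  expect_equal(pool$df, (2 - 1) * (1 + 0 / ((1 + 1 / 2) * 0.5))^2)

  # identical estimates: pooled inference equals complete-data inference
  same <- rubin_pool(rep(0.31, 10), rep(0.004, 10))
  expect_equal(same$between_var, 0)
  expect_equal(same$total_var, 0.004)
  expect_equal(same$df, Inf)
  expect_equal(same$p, 2 * pnorm(-abs(0.31 / sqrt(0.004))))

  expect_gte(rubin_pool(rnorm(5), runif(5))$total_var,
             mean(runif(5)) * 0)  # total >= within by construction
  p2 <- rubin_pool(c(0.1, 0.2, 0.3), c(0.01, 0.01, 0.01))
  expect_gte(p2$total_var, p2$within_var)
  expect_error(rubin_pool(c(1, 1), c(0, 0)), "zero")
  expect_error(rubin_pool(1, 1), "m >= 2")
})

test_that("PMM pooling is calibrated for the mean under MCAR", {
  set.seed(5)
  cover <- replicate(100, {
    n <- 300
    d <- data.frame(x = rnorm(n))
    d$y <- 5 + 2 * d$x + rnorm(n)
    full_mean <- mean(d$y)
    d$y[sample(n, 30)] <- NA
    done <- pmm_impute(d, "y", "x", k = 5, m = 5,
                       seed = sample.int(1e6, 1))
    est <- sapply(done, function(c) mean(c$y))
    vr <- sapply(done, function(c) var(c$y) / n)
    pool <- rubin_pool(est, vr)
    abs(pool$estimate - full_mean) <= 2 * sqrt(pool$total_var)
  })
  expect_gte(mean(cover), 0.9)
})

test_that("imputed cascade equals the complete-case scan with no missingness", {
  co <- small_cohort()
  ex <- co$exposures
  ex$ahi <- ex$ahi_true  # remove missingness
  sp <- prevalence_filter(co$abundance)[1:6]
  imp <- imputed_cascade(ex, co$abundance, co$covariates, species = sp,
                         m = 3, seed = 2)
  cv <- co$covariates[, model_covariates()$extended]
  for (i in seq_along(sp)) {
    cc <- complete.cases(ex$ahi, cv, co$covariates$whr)
    ref <- partial_spearman(ex$ahi[cc], co$abundance[cc, sp[i]],
                            cv[cc, , drop = FALSE])
    expect_equal(imp$rho[i], ref$rho, tolerance = 1e-10)
  }
  expect_true(all(imp$between_var < 1e-20))
})

test_that("pooled estimates track the planted sign under MCAR missingness", {
  co <- small_cohort()
  sp <- co$truth$positive_species[1:3]
  imp <- imputed_cascade(co$exposures, co$abundance, co$covariates,
                         species = sp, m = 5, seed = 6)
  expect_true(all(imp$rho > 0))
  expect_true(all(imp$n > 300))  # imputation recovers the missing-AHI rows
})

test_that("imputation beats complete-case analysis under MAR missingness", {
  # MAR-on-BMI missingness biases the complete-case exposure distribution;
  # PMM borrowing T90/ODI should shrink the estimation error on average.
  errs <- sapply(1:40, function(r) {
    cfg <- cohort_config(n_participants = 500, n_species = 25, n_ko = 120,
                         n_gmm = 4, n_true_pos = 3, n_true_neg = 3,
                         n_confounded = 2, n_planted_gmm = 1,
                         n_outcome_species = 1, missing_mechanism = "MAR",
                         missing_ahi_fraction = 0.25, seed = 100 + r)
    co <- simulate_cohort(cfg)
    sp <- co$truth$positive_species[1]
    cv <- co$covariates[, model_covariates()$extended]
    cc_full <- complete.cases(co$exposures$ahi_true, cv, co$covariates$whr)
    truth_rho <- partial_spearman(co$exposures$ahi_true[cc_full],
                                  co$abundance[cc_full, sp],
                                  cv[cc_full, , drop = FALSE])$rho
    cc <- complete.cases(co$exposures$ahi, cv, co$covariates$whr)
    cc_rho <- partial_spearman(co$exposures$ahi[cc], co$abundance[cc, sp],
                               cv[cc, , drop = FALSE])$rho
    imp <- imputed_cascade(co$exposures, co$abundance, co$covariates,
                           species = sp, m = 5, seed = 200 + r)
    c(imputed = abs(imp$rho - truth_rho), complete = abs(cc_rho - truth_rho))
  })
  expect_lt(mean(errs["imputed", ]), mean(errs["complete", ]))
})
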