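test_that("partial Spearman reduces to classic Spearman and hits the oracle", {
  set.seed(1)
  x <- rnorm(60); y <- 0.4 * x + rnorm(60)
  plain <- partial_spearman(x, y)
  expect_equal(plain$rho, cor(x, y, method = "spearman"), tolerance = 1e-12)
  expect_equal(partial_spearman(x, x, data.frame(z = rnorm(60)))$rho, 1)

  z <- data.frame(z1 = rnorm(50), z2 = sample(c("u", "v"), 50, TRUE))
  x2 <- rnorm(50); y2 <- rnorm(50) + 0.5 * z$z1
  fit <- partial_spearman(x2, y2, z)
  expect_equal(fit$rho, oracle_partial_spearman(x2, y2, z), tolerance = 1e-10)

  # invariance under strictly monotone transforms
  fit2 <- partial_spearman(exp(x2), y2^3 + 10 * y2, z)
  expect_equal(fit2$rho, fit$rho, tolerance = 1e-12)
  expect_equal(fit2$p, fit$p, tolerance = 1e-12)

  # collinearity must fail loudly, never return a silent number
  expect_error(partial_spearman(x2, y2, data.frame(z = rank(x2))),
               "zero-variance")
  expect_error(partial_spearman(rnorm(5), rnorm(5),
                                data.frame(a = rnorm(5), b = rnorm(5),
                                           c = rnorm(5))),
               "too few")
})

test_that("partial Spearman p-values use the t reference with df = n-2-k", {
  set.seed(2)
  n <- 40
  z <- data.frame(z = rnorm(n))
  x <- rnorm(n); y <- rnorm(n)
  fit <- partial_spearman(x, y, z)
  tval <- fit$rho * sqrt((n - 2 - 1) / (1 - fit$rho^2))
  expect_equal(fit$p, 2 * pt(-abs(tval), n - 3), tolerance = 1e-12)
  expect_equal(fit$df, n - 3)
})

test_that("BH adjustment equals the step-up oracle and the worked example", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  set.seed(3)
  for (i in 1:10) {
    p <- runif(sample(3:40, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-14)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  p <- runif(20)
  expect_true(all(bh_adjust(p) >= p))
})

test_that("prevalence filter boundary is exclusive at 1%", {
  n <- 1000
  ab <- matrix(0, n, 3, dimnames = list(NULL, c("at_1pct", "above", "all")))
  ab[1:10, "at_1pct"] <- 1     # exactly 1% -> removed
  ab[1:11, "above"] <- 1       # 1.1% -> retained
  ab[, "all"] <- 1
  ab <- ab / pmax(rowSums(ab), 1)
  kept <- prevalence_filter(ab)
  expect_false("at_1pct" %in% kept)
  expect_true(all(c("above", "all") %in% kept))
})

test_that("combined abundance closure and arithmetic", {
  ab <- random_abundance(8, 5, seed = 9, zero_frac = 0)
  expect_equal(unname(combined_abundance(ab, colnames(ab))), rep(100, 8))
  expect_equal(combined_abundance(ab, character(0)), rep(0, 8))
  two <- matrix(c(0.03, 0.05, 0.92), 1, dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(combined_abundance(two, c("a", "b")), 8)
  expect_error(combined_abundance(ab, "nope"), "unknown species")
})

test_that("cascade hit sets are nested and ns differ per exposure/model", {
  co <- small_cohort()
  casc <- run_cascade(co$exposures, co$abundance, co$covariates)
  for (ex in c("ahi", "t90", "odi")) {
    r <- casc$results[casc$results$exposure == ex, ]
    s1 <- r$feature[r$model == "screening" & r$q < casc$fdr]
    s2 <- r$feature[r$model == "main" & r$q < casc$fdr]
    s3 <- casc$hits[[ex]]
    expect_true(all(r$feature[r$model == "main"] %in% s1))
    expect_true(all(s2 %in% s1))
    expect_true(all(s3 %in% r$feature[r$model == "extended"]))
  }
  # AHI complete-case n smaller than ODI (missing AHI), extended < screening n
  scr <- casc$results[casc$results$model == "screening", ]
  expect_lt(scr$n[scr$exposure == "ahi"][1], scr$n[scr$exposure == "odi"][1])
  r_odi <- casc$results[casc$results$exposure == "odi", ]
  expect_lt(r_odi$n[r_odi$model == "extended"][1],
            r_odi$n[r_odi$model == "screening"][1])
})

test_that("an empty screening stage yields empty downstream tables, no error", {
  co <- small_cohort()
  casc <- run_cascade(co$exposures, co$abundance, co$covariates, fdr = 1e-12)
  expect_equal(unname(lengths(casc$hits)), rep(0L, 3))
  expect_false("extended" %in%
                 casc$results$model[casc$results$exposure == "ahi"])
})

test_that("association_scan agrees with per-feature partial Spearman", {
  co <- small_cohort()
  sp <- prevalence_filter(co$abundance)[1:5]
  cv <- co$covariates[, model_covariates()$main]
  tab <- association_scan(co$exposures$odi, co$abundance[, sp], cv)
  one <- partial_spearman(co$exposures$odi, co$abundance[, sp[3]], cv)
  expect_equal(tab$rho[3], one$rho, tolerance = 1e-12)
  expect_equal(tab$p[3], one$p, tolerance = 1e-12)
  expect_equal(tab$n[3], one$n)
})

test_that("sensitivity variants reduce to the extended model when flags are absent", {
  co <- small_cohort()
  cv <- co$covariates
  cv$antibiotics_6m <- FALSE
  cv$lung_disease <- FALSE
  cv$med_metformin <- FALSE; cv$med_ppi <- FALSE
  cv$med_antihypertensive <- FALSE; cv$med_lipid <- FALSE
  casc <- run_cascade(co$exposures, co$abundance, cv)
  skip_if(sum(lengths(casc$hits)) == 0)
  sens <- suppressWarnings(sensitivity_suite(casc, co$exposures, co$abundance, cv))
  ext <- casc$results[casc$results$model == "extended", ]
  for (ex in names(casc$hits)) {
    hit <- casc$hits[[ex]]
    if (!length(hit)) next
    base <- ext[ext$exposure == ex & ext$feature %in% hit, ]
    for (vn in c("medication", "no_antibiotics", "no_lung_disease")) {
      v <- sens[sens$exposure == ex & sens$variant == vn, ]
      expect_equal(v$rho[match(base$feature, v$feature)], base$rho,
                   tolerance = 1e-12)
      expect_equal(v$n[1], base$n[1])
    }
  }
})

test_that("antibiotic exclusion removes exactly the flagged participants", {
  co <- small_cohort()
  casc <- run_cascade(co$exposures, co$abundance, co$covariates)
  skip_if(length(casc$hits$odi) == 0)
  sens <- suppressWarnings(
    sensitivity_suite(casc, co$exposures, co$abundance, co$covariates))
  v <- sens[sens$exposure == "odi" & sens$variant == "no_antibiotics", ]
  cv_ext <- co$covariates[, model_covariates()$extended]
  cc <- complete.cases(co$exposures$odi, cv_ext)
  expect_equal(v$n[1], sum(cc & !co$covariates$antibiotics_6m))
})
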