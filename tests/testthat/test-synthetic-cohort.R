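test_that("config validation catches inconsistent settings", {
  expect_error(cohort_config(n_participants = 0), "positive")
  expect_error(cohort_config(n_true_pos = 200, n_true_neg = 150,
                             n_species = 300), "exceed")
  expect_error(cohort_config(missing_ahi_fraction = 1.2), "\\[0, 1\\]")
  expect_error(cohort_config(n_planted_gmm = 50, n_gmm = 10), "exceed")
})

test_that("same seed gives a bit-identical cohort; truth partitions species", {
  cfg <- cohort_config(n_participants = 120, n_species = 30, n_ko = 200,
                       n_gmm = 6, n_true_pos = 4, n_true_neg = 4,
                       n_confounded = 3, n_planted_gmm = 2, seed = 99)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
  tr <- synthetic_truth(cfg)
  expect_identical(sort(c(tr$positive_species, tr$negative_species,
                          tr$null_species)), tr$all_species)
  expect_length(intersect(tr$positive_species, tr$negative_species), 0)
  expect_true(all(tr$confounded_species %in% tr$null_species))
  expect_true(all(tr$outcome_species %in%
                    c(tr$positive_species, tr$negative_species)))
})

test_that("exposure marginals and rank correlations hit their targets", {
  cfg <- cohort_config(n_participants = 3000, seed = 1)
  ex <- generate_exposures(cfg)
  expect_true(all(ex$ahi_true >= 0) && all(ex$odi >= 0))
  expect_true(all(ex$t90 >= 0 & ex$t90 <= 100))
  expect_gt(mean(ex$t90 == 0), 0.1)  # the T90 = 0 group exists
  rho <- c(ahi_odi = cor(ex$ahi_true, ex$odi, method = "spearman"),
           ahi_t90 = cor(ex$ahi_true, ex$t90, method = "spearman"),
           t90_odi = cor(ex$t90, ex$odi, method = "spearman"))
  expect_true(all(abs(rho - cfg$target_rho) < 0.08))
  expect_true(rho[["ahi_odi"]] >= 0.84 && rho[["ahi_odi"]] <= 1)
  # skewed, plausible medians
  expect_gt(mean(ex$ahi_true), median(ex$ahi_true))
})

test_that("perfect coupling makes all parameters monotone in severity", {
  cfg <- cohort_config(n_participants = 300, t90_zero_fraction = 0,
                       target_rho = c(ahi_odi = 1, ahi_t90 = 1, t90_odi = 1),
                       seed = 5)
  ex <- generate_exposures(cfg)
  expect_equal(cor(ex$ahi_true, ex$odi, method = "spearman"), 1)
  expect_equal(cor(ex$ahi_true, ex$t90, method = "spearman"), 1)
  expect_equal(cor(ex$ahi_true, ex$latent_severity, method = "spearman"), 1)
})

test_that("covariates carry the configured confounding and factor structure", {
  cfg <- cohort_config(n_participants = 3000, seed = 1)
  ex <- generate_exposures(cfg)
  cv <- generate_covariates(cfg, ex)
  expect_gt(cor(cv$bmi, ex$ahi_true, method = "spearman"), 0.2)
  expect_equal(length(unique(cv$season)), 11L)
  expect_gte(length(unique(cv$plate)), 8L)
  expect_true(all(cv$age >= 50 & cv$age <= 64))
  expect_setequal(unique(cv$sex), c("female", "male"))
  expect_equal(length(unique(cv$education[!is.na(cv$education)])), 4L)
  # hemoglobin sex-specific location shift
  expect_gt(median(cv$hemoglobin[cv$sex == "male"]),
            median(cv$hemoglobin[cv$sex == "female"]) + 5)

  cfg0 <- cohort_config(n_participants = 3000, confounding_strength = 0,
                        seed = 2)
  ex0 <- generate_exposures(cfg0)
  cv0 <- generate_covariates(cfg0, ex0)
  expect_lt(abs(cor(cv0$bmi, ex0$ahi_true, method = "spearman")), 0.05)
})

test_that("abundances close to 1, respond to planted effects, pass the filter", {
  co <- small_cohort()
  expect_equal(rowSums(co$abundance), setNames(rep(1, nrow(co$abundance)),
                                               rownames(co$abundance)),
               tolerance = 1e-9)
  expect_true(all(co$abundance >= 0))
  kept <- prevalence_filter(co$abundance)
  expect_true(all(co$truth$positive_species %in% kept))
  expect_true(all(co$truth$negative_species %in% kept))
  # planted direction visible in raw rank correlation with ODI
  rp <- sapply(co$truth$positive_species, function(s)
    cor(co$exposures$odi, co$abundance[, s], method = "spearman"))
  rn <- sapply(co$truth$negative_species, function(s)
    cor(co$exposures$odi, co$abundance[, s], method = "spearman"))
  expect_gt(mean(rp), 0)
  expect_lt(mean(rn), 0)
})

test_that("event records reproduce the tabulated parameters within rounding", {
  cfg <- cohort_config(n_participants = 500, missing_ahi_fraction = 0.1,
                       seed = 3)
  ex <- generate_exposures(cfg)
  rec <- generate_event_records(cfg, ex)
  par <- compute_osa_parameters(rec)
  ok <- !ex$ahi_missing
  # AHI reproduced to within event-count rounding (0.5 events / hours)
  expect_true(all(abs(par$ahi[ok] - ex$ahi_true[ok]) <=
                    0.5 / (rec$flow_recording_minutes[ok] / 60) + 1e-9))
  expect_true(all(abs(par$odi - ex$odi) <=
                    0.5 / (rec$spo2_recording_minutes / 60) + 1e-9))
  expect_equal(par$t90, ex$t90, tolerance = 1e-9)
  # invalid flow participants keep valid SpO2 parameters
  expect_true(all(is.na(par$ahi[ex$ahi_missing])))
  expect_true(all(par$sat_valid))
  n_invalid <- sum(ex$ahi_missing)
  expect_gt(n_invalid, 0.05 * 500)
  expect_lt(n_invalid, 0.15 * 500)
  # an 8-h recording at AHI 5 carries ~40 events
  i <- which.min(abs(ex$ahi_true - 5))
  expect_equal(rec$n_apnea_hypopnea[i],
               round(ex$ahi_true[i] * rec$flow_recording_minutes[i] / 60))
})

test_that("MAR missingness depends on BMI; MCAR does not", {
  cfg <- cohort_config(n_participants = 4000, missing_mechanism = "MAR",
                       missing_ahi_fraction = 0.15, seed = 7)
  ex <- generate_exposures(cfg)
  expect_gt(mean(ex$bmi_latent[ex$ahi_missing]),
            mean(ex$bmi_latent[!ex$ahi_missing]) + 0.2)
  cfg2 <- cohort_config(n_participants = 4000, missing_ahi_fraction = 0.15,
                        seed = 7)
  ex2 <- generate_exposures(cfg2)
  expect_lt(abs(mean(ex2$bmi_latent[ex2$ahi_missing]) -
                  mean(ex2$bmi_latent[!ex2$ahi_missing])), 0.15)
})

test_that("outcomes carry planted BP effects and configurable medications", {
  co <- small_cohort()
  oc <- co$outcomes
  sp <- co$truth$outcome_species[1]
  sgn <- co$truth$outcome_sign[[sp]]
  expect_gt(sgn * cor(oc$sbp, rank(co$abundance[, sp])), 0)
  cfg <- cohort_config(n_participants = 200, n_species = 20, n_ko = 100,
                       n_gmm = 4, n_true_pos = 2, n_true_neg = 2,
                       n_confounded = 2, n_planted_gmm = 1,
                       n_outcome_species = 1,
                       medication_prevalence = c(antihypertensive = 0,
                                                 antidiabetic = 0, lipid = 0,
                                                 ppi = 0, metformin = 0),
                       seed = 11)
  co0 <- simulate_cohort(cfg)
  expect_equal(sum(co0$outcomes$med_antihypertensive), 0L)
  expect_equal(sum(co0$outcomes$med_antidiabetic), 0L)
})
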