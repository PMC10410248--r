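#' Generate OSA exposure parameters for a synthetic cohort
#'
#' Draws a latent hypoxia severity per participant and maps it to the three
#' OSA parameters through a Gaussian copula whose correlation structure is
#' calibrated so the observed Spearman correlations match the configured
#' targets (defaults: AHI-ODI 0.92, AHI-T90 0.56, T90-ODI 0.63). Marginals:
#' AHI and ODI are exponentiated Gaussians (right-skewed, medians 3.8 and
#' 4.1 events/h); T90 is a hurdle variable -- a configurable point mass at
#' zero and a logistic-normal positive part (median 2\%, bounded in
#' (0, 100)). The BMI latent enters the severity factor with weight
#' `confounding_strength`, creating the confounding path. AHI missingness
#' (invalid flow recording) is drawn here, MCAR by default or MAR with
#' probability increasing in the BMI latent.
#'
#' @param config a [cohort_config()].
#' @return data frame: `participant_id`, `latent_severity`, `bmi_latent`,
#'   `ahi_true` (complete), `ahi` (with `NA` where invalid), `odi`, `t90`,
#'   `ahi_missing`.
#' @export
generate_exposures <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_participants
  if (n <= 0) stop("n_participants must be positive")
  set.seed(derive_seed(config$seed, 1L))

  gam <- config$confounding_strength
  b <- stats::rnorm(n)                       # BMI latent
  h <- gam * b + sqrt(1 - gam^2) * stats::rnorm(n)  # latent severity

  # Factor loadings of the three parameter latents on severity, residual
  # correlations solved so total latent (Pearson) correlations hit the
  # Greiner-transformed Spearman targets: r = 2 sin(pi * rho_s / 6).
  lam <- c(ahi = 0.80, odi = 0.80, t90 = 0.60)
  r_t <- 2 * sin(pi * config$target_rho / 6)
  re <- diag(3)
  dimnames(re) <- list(names(lam), names(lam))
  re["ahi", "odi"] <- re["odi", "ahi"] <-
    (r_t[["ahi_odi"]] - lam["ahi"] * lam["odi"]) /
    sqrt((1 - lam["ahi"]^2) * (1 - lam["odi"]^2))
  re["ahi", "t90"] <- re["t90", "ahi"] <-
    (r_t[["ahi_t90"]] - lam["ahi"] * lam["t90"]) /
    sqrt((1 - lam["ahi"]^2) * (1 - lam["t90"]^2))
  re["odi", "t90"] <- re["t90", "odi"] <-
    (r_t[["t90_odi"]] - lam["odi"] * lam["t90"]) /
    sqrt((1 - lam["odi"]^2) * (1 - lam["t90"]^2))
  if (all(config$target_rho >= 1 - 1e-12)) {
    # degenerate perfect coupling: every parameter is a monotone transform
    # of the latent severity itself
    z <- cbind(ahi = h, odi = h, t90 = h)
  } else {
    if (any(abs(re) > 1)) stop("target_rho incompatible with factor loadings")
    e <- MASS::mvrnorm(n, mu = rep(0, 3), Sigma = re)
    z <- sweep(e, 2L, sqrt(1 - lam^2), `*`) + outer(h, lam)
  }

  ahi_true <- exp(log(3.8) + 1.2 * z[, "ahi"])
  odi <- exp(log(4.1) + 1.2 * z[, "odi"])
  p0 <- config$t90_zero_fraction
  t90 <- 100 * stats::plogis(stats::qlogis(0.02) + 2.8 * z[, "t90"])
  t90[z[, "t90"] <= stats::qnorm(p0)] <- 0

  miss_p <- if (config$missing_mechanism == "MAR")
    stats::plogis(stats::qlogis(pmax(config$missing_ahi_fraction, 1e-8)) + b)
  else rep(config$missing_ahi_fraction, n)
  ahi_missing <- stats::runif(n) < miss_p

  data.frame(participant_id = sprintf("P%05d", seq_len(n)),
             latent_severity = h, bmi_latent = b,
             ahi_true = ahi_true,
             ahi = ifelse(ahi_missing, NA_real_, ahi_true),
             odi = odi, t90 = t90, ahi_missing = ahi_missing)
}

#' Generate the covariate table for a synthetic cohort
#'
#' Demographics, lifestyle, batch and clinical covariates with the marginal
#' structure the association models expect: age uniform on 50-64 y, binary
#' sex, BMI log-normal around 26 kg/m2 and positively rank-correlated with
#' latent severity through the shared BMI latent, smoking (3 levels),
#' education (4), physical activity (4), birth country (4), season (11
#' monthly categories), DNA extraction plate (`n_plates` levels), alcohol,
#' fiber and total energy intake (log-normal), waist-to-hip ratio, and
#' hemoglobin with a sex-specific location shift. A small MCAR fraction of
#' the lifestyle covariates is set missing so the extended model has a
#' smaller complete-case sample than the main model. Antibiotic-use and
#' lung-disease exclusion flags are drawn here.
#'
#' @param config a [cohort_config()].
#' @param exposures result of [generate_exposures()].
#' @return data frame of covariates, rows aligned with `exposures`.
#' @export
generate_covariates <- function(config, exposures) {
  stopifnot(inherits(config, "cohort_config"))
  n <- nrow(exposures)
  set.seed(derive_seed(config$seed, 2L))

  b <- exposures$bmi_latent
  bmi_z <- 0.9 * b + sqrt(1 - 0.9^2) * stats::rnorm(n)
  sex <- sample(c("female", "male"), n, replace = TRUE, prob = c(0.53, 0.47))
  cov <- data.frame(
    participant_id = exposures$participant_id,
    age = stats::runif(n, 50, 64),
    sex = sex,
    bmi = 26.3 * exp(0.14 * bmi_z),
    smoking = sample(c("never", "former", "current"), n, replace = TRUE,
                     prob = c(0.65, 0.27, 0.08)),
    alcohol = exp(log(5.5) + 0.9 * stats::rnorm(n)),
    plate = sample(sprintf("plate%02d", seq_len(config$n_plates)), n,
                   replace = TRUE),
    fiber = exp(log(18.3) + 0.45 * stats::rnorm(n)),
    energy = exp(log(1611) + 0.35 * stats::rnorm(n)),
    physical_activity = sample(c("sedentary", "moderate", "regular_moderate",
                                 "regular_exercise"), n, replace = TRUE,
                               prob = c(0.10, 0.46, 0.32, 0.12)),
    education = sample(c("incomplete_compulsory", "compulsory",
                         "upper_secondary", "university"), n, replace = TRUE,
                       prob = c(0.005, 0.06, 0.41, 0.525)),
    birth_country = sample(c("scandinavia", "europe", "asia", "other"), n,
                           replace = TRUE, prob = c(0.90, 0.04, 0.035, 0.025)),
    season = sample(sprintf("season%02d", 1:11), n, replace = TRUE),
    whr = stats::rnorm(n, 0.93, 0.07),
    hemoglobin = ifelse(sex == "female", 135, 148) + stats::rnorm(n, 0, 9),
    antibiotics_6m = stats::runif(n) < config$antibiotics_prevalence,
    lung_disease = stats::runif(n) < config$lung_disease_prevalence
  )
  f <- config$covariate_missing_fraction
  if (f > 0)
    for (nm in c("fiber", "energy", "physical_activity", "education"))
      cov[[nm]][stats::runif(n) < f] <- NA
  cov
}

#' Generate the relative abundance matrix and species KO profiles
#'
#' Zero-inflated log-normal abundances on a latent Gaussian scale: species
#' `j` has latent log-abundance
#' \eqn{y_{ij} = \mu_j + \beta_j h_i + \gamma_j m_i + \sigma_j \epsilon_{ij}},
#' where \eqn{h} is latent severity and \eqn{m} the standardized log of the
#' participant's observed BMI.
#' \eqn{\beta_j = \pm} `effect_size` for the planted positive/negative
#' species and 0 otherwise; \eqn{\gamma_j =} `effect_size` for the
#' BMI-confounded null species. Because the confounded path runs through
#' the observed BMI itself, conditioning on BMI closes it completely: the
#' confounded species are exactly the false hits the BMI-adjustment stage
#' of the cascade is designed to remove. Structural zeros are drawn per species with
#' Beta-distributed presence probabilities (mean `1 - zero_inflation`);
#' planted species are kept at presence >= 0.5 so they survive the
#' prevalence filter. Rows are renormalized to sum to one (compositional
#' closure).
#'
#' KO profiles: each species receives a random background KO set; species
#' carrying a module receive one complete path of that module. Planted
#' modules are concentrated among positive species (carriage 0.85 vs 0.12
#' background), non-planted modules are spread evenly (0.30), so the
#' module-detection rule holds predominantly among positive species for the
#' planted modules only.
#'
#' @param config a [cohort_config()].
#' @param exposures result of [generate_exposures()].
#' @param covariates result of [generate_covariates()]; supplies the
#'   observed BMI driving the confounded species.
#' @param truth a [synthetic_truth()] ledger.
#' @return list with `abundance` (participants x species matrix, rows sum to
#'   1), `ko_table` (long data frame `species_id`, `ko_id`),
#'   `gmm_definitions` (list of module definitions, see [gmm_definition()]).
#' @export
generate_abundances <- function(config, exposures, covariates, truth) {
  stopifnot(inherits(config, "cohort_config"),
            inherits(truth, "synthetic_truth"))
  n <- nrow(exposures)
  sp <- truth$all_species
  s <- length(sp)
  set.seed(derive_seed(config$seed, 3L))

  mu <- stats::rnorm(s, -2, 1.5)
  sigma <- stats::runif(s, 0.8, 1.6)
  beta <- stats::setNames(numeric(s), sp)
  beta[truth$positive_species] <- config$effect_size
  beta[truth$negative_species] <- -config$effect_size
  gam_b <- stats::setNames(numeric(s), sp)
  gam_b[truth$confounded_species] <- config$effect_size

  zi <- config$zero_inflation
  presence_p <- if (zi > 0) stats::rbeta(s, 1.4, 1.4 * zi / (1 - zi))
                else rep(1, s)
  planted <- sp %in% c(truth$positive_species, truth$negative_species,
                       truth$confounded_species)
  presence_p[planted] <- pmax(presence_p[planted], 0.5)

  h <- exposures$latent_severity
  bz <- as.numeric(scale(log(covariates$bmi)))
  y <- outer(h, beta) + outer(bz, gam_b) +
    matrix(mu, n, s, byrow = TRUE) +
    matrix(stats::rnorm(n * s), n, s) * matrix(sigma, n, s, byrow = TRUE)
  present <- matrix(stats::runif(n * s), n, s) <
    matrix(presence_p, n, s, byrow = TRUE)
  ab <- exp(y) * present
  empty <- rowSums(ab) == 0
  if (any(empty)) {  # guarantee a non-degenerate community per participant
    j <- which.max(presence_p)
    ab[empty, j] <- exp(mu[j])
  }
  ab <- ab / rowSums(ab)
  dimnames(ab) <- list(exposures$participant_id, sp)

  gmms <- generate_gmm_definitions(config, truth)
  ko_table <- assign_ko_profiles(config, truth, gmms)
  list(abundance = ab, ko_table = ko_table, gmm_definitions = gmms)
}

# Synthetic GMM definitions: 2-8 steps per path, 1-3 alternative KOs per
# step, and a second alternative path for roughly a third of the modules, so
# all three branches of the detection rule (all-steps, two-thirds,
# alternative-path) are exercised.
#' @rdname generate_abundances
#' @export
generate_gmm_definitions <- function(config, truth) {
  set.seed(derive_seed(config$seed, 4L))
  ko_universe <- sprintf("K%05d", seq_len(config$n_ko))
  pool <- sample(ko_universe)
  idx <- 0L
  take <- function(k) {
    if (idx + k > length(pool)) {  # recycle (KO reuse across modules is fine)
      pool <<- sample(ko_universe); idx <<- 0L
    }
    out <- pool[(idx + 1L):(idx + k)]
    idx <<- idx + k
    out
  }
  lapply(seq_len(config$n_gmm), function(i) {
    n_paths <- if (stats::runif(1) < 0.35) 2L else 1L
    paths <- lapply(seq_len(n_paths), function(p) {
      n_steps <- sample(2:8, 1L)
      lapply(seq_len(n_steps), function(st) take(sample(1:3, 1L)))
    })
    gmm_definition(id = truth$all_gmms[i],
                   name = sprintf("synthetic module %d", i),
                   paths = paths)
  })
}

# Species KO assignment driving the planted enrichment signal.
assign_ko_profiles <- function(config, truth, gmms) {
  set.seed(derive_seed(config$seed, 5L))
  ko_universe <- sprintf("K%05d", seq_len(config$n_ko))
  carriage <- function(gmm_id, species_id) {
    planted_gmm <- gmm_id %in% truth$planted_gmms
    pos <- species_id %in% truth$positive_species
    if (planted_gmm && pos) 0.85 else if (planted_gmm) 0.12 else 0.30
  }
  rows <- lapply(truth$all_species, function(spid) {
    kos <- sample(ko_universe, 60)
    for (g in gmms) {
      if (stats::runif(1) < carriage(g$id, spid)) {
        path <- g$paths[[sample(length(g$paths), 1L)]]
        kos <- c(kos, vapply(path, function(step) step[[1L]], character(1)))
      }
    }
    data.frame(species_id = spid, ko_id = unique(kos))
  })
  do.call(rbind, rows)
}

#' Generate per-participant respiratory event records
#'
#' Produces nocturnal recording summaries (event counts, hypoxia minutes,
#' channel durations) such that [compute_osa_parameters()] applied to the
#' records reproduces each participant's tabulated AHI/ODI/T90 to within
#' event-count rounding. Participants flagged with missing AHI receive an
#' air-flow recording shorter than 4 h while their oximetry channel remains
#' valid, mirroring a cohort where more participants have valid T90/ODI than
#' valid AHI.
#'
#' @param config a [cohort_config()].
#' @param exposures result of [generate_exposures()].
#' @return data frame: `participant_id`, `n_apnea`, `n_hypopnea`,
#'   `n_apnea_hypopnea`, `n_desaturation`, `minutes_below_90`,
#'   `flow_recording_minutes`, `spo2_recording_minutes`,
#'   `mean_event_duration_s`.
#' @export
generate_event_records <- function(config, exposures) {
  stopifnot(inherits(config, "cohort_config"))
  n <- nrow(exposures)
  set.seed(derive_seed(config$seed, 6L))
  spo2_min <- pmax(300, stats::rnorm(n, 480, 30))
  flow_min <- pmin(spo2_min, pmax(300, stats::rnorm(n, 470, 30)))
  flow_min[exposures$ahi_missing] <- stats::runif(sum(exposures$ahi_missing),
                                                  120, 235)
  n_ah <- round(exposures$ahi_true * flow_min / 60)
  n_apnea <- stats::rbinom(n, n_ah, 0.4)
  n_desat <- round(exposures$odi * spo2_min / 60)
  min_below <- exposures$t90 / 100 * spo2_min
  data.frame(participant_id = exposures$participant_id,
             n_apnea = n_apnea, n_hypopnea = n_ah - n_apnea,
             n_apnea_hypopnea = n_ah, n_desaturation = n_desat,
             minutes_below_90 = min_below,
             flow_recording_minutes = flow_min,
             spo2_recording_minutes = spo2_min,
             mean_event_duration_s = stats::runif(n, 15, 40))
}

#' Generate cardiometabolic outcomes and medication flags
#'
#' Systolic and diastolic blood pressure and HbA1c with age/sex/BMI structure
#' plus a planted linear effect of the truth ledger's outcome species:
#' each outcome species contributes `bp_effect_size` mm Hg (0.6 x for
#' diastolic) per SD of its rank-normalized abundance, signed by the
#' species' planted hypoxia direction. HbA1c carries no species effect by
#' default (mirroring a null finding). Medication indicators are drawn
#' independently at the configured prevalences.
#'
#' @param config a [cohort_config()].
#' @param covariates result of [generate_covariates()].
#' @param abundance abundance matrix from [generate_abundances()].
#' @param truth a [synthetic_truth()] ledger.
#' @return data frame: `participant_id`, `sbp`, `dbp`, `hba1c`,
#'   `med_antihypertensive`, `med_antidiabetic`, `med_metformin`,
#'   `med_lipid`, `med_ppi`.
#' @export
generate_outcomes <- function(config, covariates, abundance, truth) {
  stopifnot(inherits(config, "cohort_config"),
            inherits(truth, "synthetic_truth"))
  n <- nrow(covariates)
  set.seed(derive_seed(config$seed, 7L))
  species_signal <- rep(0, n)
  for (spid in truth$outcome_species) {
    r <- stats::qnorm(midrank(abundance[, spid]) / (n + 1))
    species_signal <- species_signal + truth$outcome_sign[[spid]] * r
  }
  age_c <- covariates$age - 57
  male <- covariates$sex == "male"
  bmi_c <- covariates$bmi - 26.3
  sbp <- 118 + 0.35 * age_c + 4 * male + 0.8 * bmi_c +
    config$bp_effect_size * species_signal + stats::rnorm(n, 0, 12)
  dbp <- 72 + 0.15 * age_c + 2.5 * male + 0.6 * bmi_c +
    0.6 * config$bp_effect_size * species_signal + stats::rnorm(n, 0, 9)
  hba1c <- 35 + 0.12 * age_c + 0.15 * bmi_c + stats::rnorm(n, 0, 4)
  mp <- config$medication_prevalence
  data.frame(participant_id = covariates$participant_id,
             sbp = sbp, dbp = dbp, hba1c = hba1c,
             med_antihypertensive = stats::runif(n) < mp[["antihypertensive"]],
             med_antidiabetic = stats::runif(n) < mp[["antidiabetic"]],
             med_metformin = stats::runif(n) < mp[["metformin"]],
             med_lipid = stats::runif(n) < mp[["lipid"]],
             med_ppi = stats::runif(n) < mp[["ppi"]])
}

#' Simulate a complete synthetic cohort
#'
#' Orchestrates [generate_exposures()], [generate_covariates()],
#' [synthetic_truth()], [generate_abundances()], [generate_event_records()]
#' and [generate_outcomes()] into one seeded, bit-reproducible cohort object.
#' Medication flags from the outcome stage are merged into the covariate
#' table so the sensitivity and downstream analyses can reference them.
#'
#' @param config a [cohort_config()].
#' @return object of class `"osa_cohort"`: list with `config`, `truth`,
#'   `exposures`, `covariates`, `abundance`, `ko_table`, `gmm_definitions`,
#'   `event_records`, `outcomes`.
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_participants = 100,
#'                                         n_species = 40, seed = 7))
#' cohort
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  exposures <- generate_exposures(config)
  covariates <- generate_covariates(config, exposures)
  truth <- synthetic_truth(config)
  ab <- generate_abundances(config, exposures, covariates, truth)
  records <- generate_event_records(config, exposures)
  outcomes <- generate_outcomes(config, covariates, ab$abundance, truth)
  covariates <- cbind(covariates,
                      outcomes[, c("med_antihypertensive", "med_antidiabetic",
                                   "med_metformin", "med_lipid", "med_ppi")])
  structure(list(config = config, truth = truth, exposures = exposures,
                 covariates = covariates, abundance = ab$abundance,
                 ko_table = ab$ko_table, gmm_definitions = ab$gmm_definitions,
                 event_records = records, outcomes = outcomes),
            class = "osa_cohort")
}

#' @export
print.osa_cohort <- function(x, ...) {
  cat(sprintf(paste0(
    "Synthetic OSA-microbiome cohort: %d participants, %d species\n",
    "  planted: %d positive, %d negative, %d BMI-confounded species; ",
    "%d modules; %d outcome species\n",
    "  missing AHI: %d participants (%s)\n"),
    nrow(x$abundance), ncol(x$abundance),
    length(x$truth$positive_species), length(x$truth$negative_species),
    length(x$truth$confounded_species), length(x$truth$planted_gmms),
    length(x$truth$outcome_species),
    sum(x$exposures$ahi_missing), x$config$missing_mechanism))
  invisible(x)
}
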