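#' Configuration for the synthetic cohort generator
#'
#' Bundles every distributional parameter of the generator with validation.
#' Defaults emulate a middle-aged population screened for obstructive sleep
#' apnea with a home two-channel device, with gut microbiota profiled as
#' species-level relative abundances:
#' exposure medians and inter-parameter rank correlations match a
#' population-scale screening cohort (AHI-ODI rho 0.92, AHI-T90 0.56,
#' T90-ODI 0.63; AHI median near 3.8 events/h), abundances follow a
#' zero-inflated log-normal on a latent Gaussian copula, and BMI confounds
#' both the exposures and a subset of species.
#'
#' @param n_participants cohort size.
#' @param n_species number of microbial species.
#' @param n_ko size of the synthetic KEGG-ortholog universe.
#' @param n_gmm number of gut metabolic modules generated.
#' @param n_true_pos,n_true_neg species planted with positive/negative
#'   latent-scale response to hypoxia severity.
#' @param n_confounded null species given a BMI effect only (they should be
#'   picked up by the BMI-free screening model and dropped once BMI enters).
#' @param n_planted_gmm modules whose KO content is concentrated in the
#'   positive species (targets of the enrichment analysis).
#' @param n_outcome_species planted species additionally given a blood
#'   pressure effect.
#' @param effect_size latent-scale slope of log-abundance on severity.
#' @param bp_effect_size planted blood pressure effect (mm Hg per SD of
#'   rank-normalized abundance).
#' @param confounding_strength correlation of the BMI latent with the latent
#'   severity (BMI -> exposure path weight; 0 disables confounding).
#' @param missing_ahi_fraction fraction of participants with an invalid
#'   (< 4 h) air-flow recording and hence missing AHI.
#' @param missing_mechanism `"MCAR"` (default) or `"MAR"` (missingness
#'   probability increases with BMI).
#' @param zero_inflation mean fraction of structural zeros per species.
#' @param t90_zero_fraction point mass of the T90 = 0 group.
#' @param target_rho named Spearman targets among the exposures
#'   (`ahi_odi`, `ahi_t90`, `t90_odi`).
#' @param covariate_missing_fraction small MCAR missingness applied to the
#'   lifestyle covariates of the extended model.
#' @param n_plates number of DNA extraction plates (batch factor levels).
#' @param medication_prevalence named prevalences for
#'   `antihypertensive`, `antidiabetic`, `lipid`, `ppi`, `metformin`.
#' @param antibiotics_prevalence,lung_disease_prevalence exclusion-flag
#'   prevalences.
#' @param seed integer; the same config is guaranteed to regenerate a
#'   bit-identical cohort.
#' @return object of class `"cohort_config"` (validated named list).
#' @export
cohort_config <- function(n_participants = 2000,
                          n_species = 300,
                          n_ko = 1500,
                          n_gmm = 20,
                          n_true_pos = 20,
                          n_true_neg = 20,
                          n_confounded = 20,
                          n_planted_gmm = 5,
                          n_outcome_species = 5,
                          effect_size = 0.5,
                          bp_effect_size = 2,
                          confounding_strength = 0.45,
                          missing_ahi_fraction = 0.1,
                          missing_mechanism = c("MCAR", "MAR"),
                          zero_inflation = 0.3,
                          t90_zero_fraction = 0.25,
                          target_rho = c(ahi_odi = 0.92, ahi_t90 = 0.56,
                                         t90_odi = 0.63),
                          covariate_missing_fraction = 0.02,
                          n_plates = 16,
                          medication_prevalence = c(antihypertensive = 0.18,
                                                    antidiabetic = 0.04,
                                                    lipid = 0.07,
                                                    ppi = 0.03,
                                                    metformin = 0.03),
                          antibiotics_prevalence = 0.10,
                          lung_disease_prevalence = 0.01,
                          seed = 1L) {
  missing_mechanism <- match.arg(missing_mechanism)
  cfg <- list(n_participants = as.integer(n_participants),
              n_species = as.integer(n_species), n_ko = as.integer(n_ko),
              n_gmm = as.integer(n_gmm), n_true_pos = as.integer(n_true_pos),
              n_true_neg = as.integer(n_true_neg),
              n_confounded = as.integer(n_confounded),
              n_planted_gmm = as.integer(n_planted_gmm),
              n_outcome_species = as.integer(n_outcome_species),
              effect_size = effect_size, bp_effect_size = bp_effect_size,
              confounding_strength = confounding_strength,
              missing_ahi_fraction = missing_ahi_fraction,
              missing_mechanism = missing_mechanism,
              zero_inflation = zero_inflation,
              t90_zero_fraction = t90_zero_fraction,
              target_rho = target_rho,
              covariate_missing_fraction = covariate_missing_fraction,
              n_plates = as.integer(n_plates),
              medication_prevalence = medication_prevalence,
              antibiotics_prevalence = antibiotics_prevalence,
              lung_disease_prevalence = lung_disease_prevalence,
              seed = as.integer(seed))
  if (cfg$n_participants <= 0) stop("n_participants must be positive")
  if (cfg$n_species <= 0) stop("n_species must be positive")
  if (cfg$n_true_pos + cfg$n_true_neg > cfg$n_species)
    stop("n_true_pos + n_true_neg must not exceed n_species")
  if (cfg$n_planted_gmm > cfg$n_gmm)
    stop("n_planted_gmm must not exceed n_gmm")
  props <- c(cfg$missing_ahi_fraction, cfg$zero_inflation,
             cfg$t90_zero_fraction, cfg$covariate_missing_fraction,
             cfg$medication_prevalence, cfg$antibiotics_prevalence,
             cfg$lung_disease_prevalence)
  if (any(props < 0 | props > 1)) stop("all proportions must lie in [0, 1]")
  if (abs(cfg$confounding_strength) > 1)
    stop("confounding_strength must lie in [-1, 1]")
  structure(cfg, class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(paste0(
    "Synthetic cohort config: n = %d, %d species, effect %.2f, ",
    "confounding %.2f, %.0f%% missing AHI (%s), seed %d\n"),
    x$n_participants, x$n_species, x$effect_size, x$confounding_strength,
    100 * x$missing_ahi_fraction, x$missing_mechanism, x$seed))
  invisible(x)
}

#' Planted-effect truth ledger
#'
#' Draws the disjoint species sets against which recovery is scored:
#' positively and negatively hypoxia-responsive species, BMI-only confounded
#' species (a subset of the null species), the modules planted for
#' enrichment, and the species carrying a blood pressure effect.
#'
#' @param config a [cohort_config()].
#' @return object of class `"synthetic_truth"`: list with
#'   `positive_species`, `negative_species`, `null_species`,
#'   `confounded_species`, `planted_gmms`, `outcome_species`,
#'   `outcome_sign` (named +1/-1 per outcome species).
#' @export
synthetic_truth <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(derive_seed(config$seed, 11L))
  species <- sprintf("sp%04d", seq_len(config$n_species))
  planted <- sample(species, config$n_true_pos + config$n_true_neg)
  positive <- sort(planted[seq_len(config$n_true_pos)])
  negative <- sort(setdiff(planted, positive))
  null_sp <- sort(setdiff(species, planted))
  confounded <- sort(sample(null_sp, min(config$n_confounded, length(null_sp))))
  gmms <- sprintf("GM%03d", seq_len(config$n_gmm))
  planted_gmms <- sort(sample(gmms, config$n_planted_gmm))
  n_out <- min(config$n_outcome_species, length(planted))
  n_out_pos <- min(ceiling(n_out / 2), length(positive))
  outcome <- c(sample(positive, n_out_pos),
               sample(negative, min(n_out - n_out_pos, length(negative))))
  outcome_sign <- stats::setNames(ifelse(outcome %in% positive, 1, -1), outcome)
  structure(list(positive_species = positive, negative_species = negative,
                 null_species = null_sp, confounded_species = confounded,
                 planted_gmms = planted_gmms,
                 outcome_species = sort(outcome),
                 outcome_sign = outcome_sign[sort(outcome)],
                 all_species = species, all_gmms = gmms),
            class = "synthetic_truth")
}
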