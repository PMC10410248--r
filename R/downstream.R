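#' Associations of hit species with blood pressure and HbA1c
#'
#' Post hoc analysis relating the cascade's hit species (and their combined
#' relative abundance) to systolic BP, diastolic BP and HbA1c by partial
#' Spearman correlation, adjusted for age, sex, alcohol intake, smoking,
#' fiber intake, total energy intake, physical activity, birth country, DNA
#' extraction plate and all three OSA parameters (so any association is
#' independent of OSA severity itself). Users of antihypertensive medication
#' are excluded from the BP models and users of antidiabetic medication from
#' the HbA1c model. A second pass appends BMI to the covariate set. BH
#' adjustment is applied across features within each (outcome, pass) family.
#'
#' @param hit_species character vector of species ids (the cascade hit set).
#' @param abundance participants x species matrix.
#' @param outcomes data frame with columns `sbp`, `dbp`, `hba1c`.
#' @param exposures data frame with columns `ahi`, `t90`, `odi`.
#' @param covariates covariate data frame; must contain the adjustment
#'   covariates plus `med_antihypertensive` and `med_antidiabetic`.
#' @param base_covs adjustment covariate names (default: the post hoc set
#'   described above, without season).
#' @param include_combined also test the summed relative abundance of the
#'   hit set as one feature (`"combined"`).
#' @return data frame: `outcome`, `feature`, `bmi_adjusted`, `rho`, `p`,
#'   `q`, `n`, `n_excluded`.
#' @export
outcome_associations <- function(hit_species, abundance, outcomes, exposures,
                                 covariates,
                                 base_covs = c("age", "sex", "alcohol",
                                               "smoking", "fiber", "energy",
                                               "physical_activity",
                                               "birth_country", "plate"),
                                 include_combined = TRUE) {
  if (!length(hit_species)) stop("empty hit set")
  abundance <- as.matrix(abundance)
  feats <- abundance[, hit_species, drop = FALSE]
  if (include_combined)
    feats <- cbind(feats, combined = combined_abundance(abundance,
                                                        hit_species))
  osa <- exposures[, c("ahi", "t90", "odi"), drop = FALSE]
  spec <- list(sbp = "med_antihypertensive", dbp = "med_antihypertensive",
               hba1c = "med_antidiabetic")
  out <- list()
  for (oc in names(spec)) {
    y <- outcomes[[oc]]
    excl <- covariates[[spec[[oc]]]]
    if (is.null(excl)) stop("covariates must contain '", spec[[oc]], "'")
    eligible <- !is.na(y)
    for (bmi_adj in c(FALSE, TRUE)) {
      covs <- cbind(covariates[, base_covs, drop = FALSE], osa)
      if (bmi_adj) covs$bmi <- covariates$bmi
      cc <- eligible & !excl & stats::complete.cases(y, covs)
      if (!any(cc)) stop("exclusions empty the sample for '", oc, "'")
      tab <- ps_many(y[cc], feats[cc, , drop = FALSE],
                     covs[cc, , drop = FALSE])
      tab$q <- bh_adjust(tab$p)
      out[[paste(oc, bmi_adj)]] <- cbind(
        outcome = oc, tab[, "feature", drop = FALSE],
        bmi_adjusted = bmi_adj, tab[, c("rho", "p", "q", "n")],
        n_excluded = sum(eligible & (excl | !stats::complete.cases(covs))))
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
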