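#' Split participants into hemoglobin strata
#'
#' Dichotomizes at the sex-specific median hemoglobin: within each sex,
#' participants at or below their sex's median go to the `low` stratum,
#' those above to `high` (ties at the median are assigned low). Participants
#' with missing hemoglobin or sex get `NA`.
#'
#' @param covariates data frame with columns `hemoglobin` and `sex`.
#' @return factor of labels `"low"`/`"high"`, one per row.
#' @export
split_by_hemoglobin <- function(covariates) {
  hb <- covariates$hemoglobin
  sex <- covariates$sex
  if (is.null(hb) || is.null(sex))
    stop("covariates must contain 'hemoglobin' and 'sex'")
  out <- rep(NA_character_, length(hb))
  for (s in unique(sex[!is.na(sex)])) {
    i <- which(sex == s & !is.na(hb))
    if (!length(i)) stop("empty stratum for sex '", s, "'")
    med <- stats::median(hb[i])
    out[i] <- ifelse(hb[i] <= med, "low", "high")
  }
  factor(out, levels = c("low", "high"))
}

#' Bootstrap standard error of a statistic
#'
#' Nonparametric bootstrap over rows of `data`: the statistic is recomputed
#' on `B` resamples drawn with replacement and its sample standard deviation
#' is returned. Any covariate residualization inside `statistic` is thereby
#' recomputed per resample (full-pipeline bootstrap).
#'
#' @param data data frame or matrix whose rows are resampled.
#' @param statistic function of one argument (the resampled data) returning
#'   a scalar; may return `NA` on degenerate resamples.
#' @param B number of bootstrap iterations (>= 100; default 1000).
#' @param seed integer seed.
#' @return bootstrap standard error (scalar).
#' @export
bootstrap_se <- function(data, statistic, B = 1000, seed = 1L) {
  if (B < 100) stop("need at least 100 bootstrap iterations")
  n <- nrow(data)
  set.seed(seed)
  vals <- vapply(seq_len(B), function(b) {
    idx <- sample.int(n, replace = TRUE)
    tryCatch(statistic(data[idx, , drop = FALSE]),
             error = function(e) NA_real_)
  }, numeric(1))
  if (mean(is.na(vals)) > 0.1)
    stop("statistic undefined in more than 10% of resamples")
  stats::sd(vals, na.rm = TRUE)
}

#' Compare two correlation coefficients across strata
#'
#' Two-group comparison of coefficients with independent standard errors:
#' \eqn{z = (\rho_{low} - \rho_{high}) / \sqrt{se_{low}^2 + se_{high}^2}},
#' referred to a standard normal, two-sided. A Fisher-z variant (compare
#' atanh-transformed coefficients with the supplied SEs rescaled by the
#' delta method) is available behind `fisher_z = TRUE`.
#'
#' @param rho_low,rho_high stratum correlation coefficients.
#' @param se_low,se_high their (e.g. bootstrap) standard errors, > 0.
#' @param fisher_z compare on the Fisher-z scale instead of the raw scale.
#' @return list with `z` and `p_het`.
#' @export
compare_correlations <- function(rho_low, se_low, rho_high, se_high,
                                 fisher_z = FALSE) {
  if (se_low <= 0 || se_high <= 0) stop("standard errors must be positive")
  if (fisher_z) {
    d <- atanh(rho_low) - atanh(rho_high)
    v <- (se_low / (1 - rho_low^2))^2 + (se_high / (1 - rho_high^2))^2
    z <- d / sqrt(v)
  } else {
    z <- (rho_low - rho_high) / sqrt(se_low^2 + se_high^2)
  }
  list(z = z, p_het = 2 * stats::pnorm(-abs(z)))
}

#' Hemoglobin effect-modification screen over hit species
#'
#' For every (species, exposure) combination, computes the covariate-
#' adjusted partial Spearman correlation separately in the low and high
#' hemoglobin strata, estimates each coefficient's standard error by a
#' full-pipeline bootstrap (ranks and residualization recomputed per
#' resample, participants resampled within stratum), and compares the pair
#' of coefficients with [compare_correlations()]. BH adjustment is applied
#' across species within each exposure.
#'
#' Bootstrap resamples are shared across species within a stratum (one
#' resampling stream per stratum), which keeps the screen at two
#' residualizations per resample regardless of the number of species.
#'
#' @param species character vector of species to screen (typically the
#'   cascade hit set).
#' @param exposures,abundance,covariates as in [run_cascade()].
#' @param strata factor from [split_by_hemoglobin()].
#' @param exposure_names exposures to screen (default `c("t90", "odi")`).
#' @param model_covs covariate names for adjustment (default the extended
#'   model minus nothing, see [model_covariates()]).
#' @param B bootstrap iterations (default 1000).
#' @param seed integer seed.
#' @return data frame: `feature`, `exposure`, `n_low`, `n_high`, `rho_low`,
#'   `se_low`, `rho_high`, `se_high`, `z`, `p_het`, `q_het`.
#' @export
heterogeneity_screen <- function(species, exposures, abundance, covariates,
                                 strata, exposure_names = c("t90", "odi"),
                                 model_covs = model_covariates()$extended,
                                 B = 1000, seed = 1L) {
  abundance <- as.matrix(abundance)
  out <- list()
  for (ex in exposure_names) {
    x_all <- exposures[[ex]]
    cov_m <- covariates[, model_covs, drop = FALSE]
    per_stratum <- lapply(c("low", "high"), function(sl) {
      sel <- which(strata == sl & stats::complete.cases(x_all, cov_m))
      k_needed <- ncol(build_design(cov_m[sel, , drop = FALSE],
                                    n = length(sel))) + 3L
      if (length(sel) < k_needed)
        stop("stratum '", sl, "' too small for the covariate set")
      point <- ps_many(x_all[sel], abundance[sel, species, drop = FALSE],
                       cov_m[sel, , drop = FALSE])
      set.seed(derive_seed(seed, match(ex, exposure_names) * 10L +
                                   match(sl, c("low", "high"))))
      boot <- matrix(NA_real_, B, length(species))
      for (b in seq_len(B)) {
        idx <- sel[sample.int(length(sel), replace = TRUE)]
        boot[b, ] <- tryCatch(
          ps_many(x_all[idx], abundance[idx, species, drop = FALSE],
                  cov_m[idx, , drop = FALSE])$rho,
          error = function(e) rep(NA_real_, length(species)))
      }
      list(rho = point$rho, n = point$n,
           se = apply(boot, 2L, stats::sd, na.rm = TRUE),
           na_frac = colMeans(is.na(boot)))
    })
    lo <- per_stratum[[1L]]; hi <- per_stratum[[2L]]
    keep <- lo$na_frac <= 0.1 & hi$na_frac <= 0.1 &
      lo$se > 0 & hi$se > 0
    if (any(!keep))
      warning(sum(!keep), " species skipped (degenerate bootstrap)")
    z <- (lo$rho - hi$rho) / sqrt(lo$se^2 + hi$se^2)
    tab <- data.frame(feature = species, exposure = ex,
                      n_low = lo$n, n_high = hi$n,
                      rho_low = lo$rho, se_low = lo$se,
                      rho_high = hi$rho, se_high = hi$se,
                      z = z, p_het = 2 * stats::pnorm(-abs(z)))[keep, ,
                                                                drop = FALSE]
    tab$q_het <- bh_adjust(tab$p_het)
    out[[ex]] <- tab
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
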