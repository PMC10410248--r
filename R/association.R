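#' Covariate-adjusted partial Spearman correlation
#'
#' Rank-based correlation between `x` and `y` after removing the linear
#' dependence of their ranks on a covariate set: both variables are
#' transformed to average ranks (mid-ranks for ties), each rank vector is
#' regressed by least squares on the covariate design matrix (categoricals
#' one-hot, intercept included), and the partial correlation is the Pearson
#' correlation of the two residual vectors. The p-value uses
#' \eqn{t = \rho\sqrt{(n-2-k)/(1-\rho^2)}} on \eqn{n-2-k} degrees of freedom,
#' with \eqn{k} the number of non-intercept design columns; two-sided.
#' Complete-case analysis: rows with any missing value in `x`, `y` or the
#' covariates are dropped.
#'
#' With an empty covariate set this reduces exactly to the classic Spearman
#' rank correlation.
#'
#' @param x,y numeric vectors of equal length.
#' @param covariates optional data frame of adjustment covariates.
#' @return list with `rho`, `p`, `n` (analyzed rows) and `df`.
#' @examples
#' set.seed(1)
#' x <- rnorm(50); y <- x + rnorm(50); z <- data.frame(z = rnorm(50))
#' partial_spearman(x, y, z)
#' @export
partial_spearman <- function(x, y, covariates = NULL) {
  stopifnot(length(x) == length(y))
  cc <- stats::complete.cases(x, y,
                              if (is.null(covariates)) rep(TRUE, length(x))
                              else covariates)
  x <- x[cc]; y <- y[cc]
  covariates <- if (is.null(covariates)) NULL
                else as.data.frame(covariates)[cc, , drop = FALSE]
  n <- length(x)
  design <- build_design(covariates, n = n)
  k <- qr(design)$rank - 1L
  if (n <= k + 3L) stop("too few complete cases for the covariate set")
  rkx <- midrank(x); rky <- midrank(y)
  rx <- residualize(cbind(rkx), design)[, 1L]
  ry <- residualize(cbind(rky), design)[, 1L]
  if (stats::sd(rx) < 1e-8 * stats::sd(rkx) ||
      stats::sd(ry) < 1e-8 * stats::sd(rky))
    stop("zero-variance residuals: a variable is collinear with the covariates")
  rho <- stats::cor(rx, ry)
  df <- n - 2L - k
  tval <- rho * sqrt(df / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tval), df = df), n = n, df = df)
}

# Vectorized partial Spearman of one exposure against every column of a
# feature matrix, sharing one residualization of the design. Rows must
# already be complete cases. Returns data.frame(feature, rho, p, n).
ps_many <- function(x, features, covariates = NULL) {
  n <- length(x)
  design <- build_design(covariates, n = n)
  k <- qr(design)$rank - 1L
  if (n <= k + 3L) stop("too few complete cases for the covariate set")
  rx <- residualize(cbind(midrank(x)), design)[, 1L]
  ry <- residualize(apply(features, 2L, midrank), design)
  rho <- cor_vec_mat(rx, ry)
  df <- n - 2L - k
  tval <- rho * sqrt(df / (1 - rho^2))
  p <- 2 * stats::pt(-abs(tval), df = df)
  data.frame(feature = colnames(features) %||% seq_len(ncol(features)),
             rho = rho, p = p, n = n, row.names = NULL)
}

#' Single-model association scan over a feature matrix
#'
#' Partial Spearman correlation of one exposure against every feature column
#' under one covariate set, sharing a single residualization of the design
#' (complete cases on the exposure and covariates are selected internally).
#' This is the flat input the ranked-p enrichment analysis expects: one row
#' per feature with its signed coefficient, unlike the staged
#' [run_cascade()] whose later models only retain screened species.
#'
#' @param x exposure vector (missing values allowed).
#' @param features numeric matrix, participants x features, aligned with `x`.
#' @param covariates data frame of adjustment covariates (aligned rows).
#' @return data frame: `feature`, `rho`, `p`, `q` (BH across features), `n`.
#' @export
association_scan <- function(x, features, covariates = NULL) {
  features <- as.matrix(features)
  cc <- stats::complete.cases(x, if (is.null(covariates)) rep(TRUE, length(x))
                                 else covariates)
  tab <- ps_many(x[cc], features[cc, , drop = FALSE],
                 if (is.null(covariates)) NULL
                 else covariates[cc, , drop = FALSE])
  tab$q <- bh_adjust(tab$p)
  tab[, c("feature", "rho", "p", "q", "n")]
}

#' Benjamini-Hochberg adjusted p-values (q-values)
#'
#' Step-up false discovery rate adjustment:
#' \eqn{q_{(i)} = \min_{j \ge i} m\, p_{(j)} / j}, capped at 1.
#'
#' @param p numeric vector of p-values in \[0, 1\] (`NA` passed through).
#' @return vector of q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Prevalence filter for species
#'
#' Retains species detected (abundance > 0) in more than the given fraction
#' of participants; species present in at most that fraction are removed
#' (the boundary itself is excluded).
#'
#' @param abundance participants x species relative abundance matrix.
#' @param min_prevalence exclusive prevalence threshold (default 0.01).
#' @return character vector of retained species ids (column names).
#' @export
prevalence_filter <- function(abundance, min_prevalence = 0.01) {
  abundance <- as.matrix(abundance)
  prev <- colMeans(abundance > 0)
  colnames(abundance)[prev > min_prevalence]
}

#' Combined relative abundance of a species set
#'
#' Row-wise sum of relative abundances over a species set, reported as a
#' percentage of the community.
#'
#' @param abundance participants x species relative abundance matrix.
#' @param species character vector of species ids (must be columns).
#' @return numeric vector, one percentage per participant.
#' @export
combined_abundance <- function(abundance, species) {
  abundance <- as.matrix(abundance)
  unknown <- setdiff(species, colnames(abundance))
  if (length(unknown))
    stop("unknown species id(s): ", paste(utils::head(unknown, 5), collapse = ", "))
  if (!length(species)) return(rep(0, nrow(abundance)))
  100 * rowSums(abundance[, species, drop = FALSE])
}

#' Covariate sets for the association model cascade
#'
#' The three adjustment models used throughout:
#' \describe{
#'   \item{screening}{age, sex, smoking, alcohol, DNA extraction plate --
#'     the main model without BMI, used as the first-pass screen because BMI
#'     may be either a confounder or a downstream consequence of the
#'     microbiota.}
#'   \item{main}{screening + BMI.}
#'   \item{extended}{main + fiber intake, total energy intake, physical
#'     activity, education, birth country and season.}
#' }
#' Covariate names refer to columns of the cohort covariate table.
#'
#' @return named list of character vectors of covariate names.
#' @export
model_covariates <- function() {
  screening <- c("age", "sex", "smoking", "alcohol", "plate")
  main <- c(screening, "bmi")
  extended <- c(main, "fiber", "energy", "physical_activity", "education",
                "birth_country", "season")
  list(screening = screening, main = main, extended = extended)
}

#' Run the screening/main/extended association cascade
#'
#' The core inference engine. For each exposure (AHI, T90, ODI):
#' \enumerate{
#'   \item \strong{screening}: every prevalence-filtered species is tested by
#'     partial Spearman correlation under the main model \emph{without} BMI;
#'     BH adjustment within the (exposure, stage) family.
#'   \item \strong{main}: species with screening q below `fdr` are re-tested
#'     adding BMI; BH within the reduced family.
#'   \item \strong{extended}: the same screened species under the extended
#'     covariate set; BH within the reduced family. Species with extended
#'     q < `fdr` form the final hit set.
#' }
#' Complete-case sets are recomputed per exposure and per model (the AHI
#' sample is smaller than the T90/ODI sample when AHI validity fails, and the
#' extended model loses participants with missing lifestyle covariates).
#'
#' Diversity associations are obtained by passing the Shannon index as a
#' one-column feature matrix with `filter_species = FALSE`.
#'
#' @param exposures data frame with exposure columns (default
#'   `c("ahi", "t90", "odi")`; missing values allowed).
#' @param abundance participants x species (or features) matrix, rows aligned
#'   with `exposures` and `covariates`.
#' @param covariates covariate data frame containing every column named by
#'   `models`.
#' @param exposure_names exposures to analyze (columns of `exposures`).
#' @param models named list of covariate sets as from [model_covariates()];
#'   must contain `screening`, `main`, `extended`.
#' @param fdr false discovery rate for stage-to-stage passing and final hits
#'   (default 0.05).
#' @param filter_species apply the 1\% prevalence filter first? (default TRUE)
#' @return object of class `"osa_cascade"`: list with `results` (tidy data
#'   frame: exposure, feature, model, rho, p, q, n), `hits` (named list of
#'   final hit species per exposure), `fdr`, `species` (tested set).
#' @export
run_cascade <- function(exposures, abundance, covariates,
                        exposure_names = c("ahi", "t90", "odi"),
                        models = model_covariates(), fdr = 0.05,
                        filter_species = TRUE) {
  abundance <- as.matrix(abundance)
  stopifnot(nrow(abundance) == nrow(exposures),
            nrow(abundance) == nrow(covariates))
  species <- if (filter_species) prevalence_filter(abundance)
             else colnames(abundance)
  stages <- c("screening", "main", "extended")
  res <- list(); hits <- list()
  for (ex in exposure_names) {
    x_all <- exposures[[ex]]
    if (is.null(x_all)) stop("exposure column '", ex, "' not found")
    screened <- species  # stage 1 tests everything; 2 and 3 the screened set
    for (st in stages) {
      tested <- screened
      if (!length(tested)) {
        hits[[ex]] <- character(0)
        break
      }
      cov_st <- covariates[, models[[st]], drop = FALSE]
      cc <- stats::complete.cases(x_all, cov_st)
      tab <- ps_many(x_all[cc], abundance[cc, tested, drop = FALSE],
                     cov_st[cc, , drop = FALSE])
      tab$q <- bh_adjust(tab$p)
      tab <- cbind(exposure = ex, tab[, "feature", drop = FALSE],
                   model = st, tab[, c("rho", "p", "q", "n")])
      res[[paste(ex, st)]] <- tab
      if (st == "screening")
        screened <- tab$feature[!is.na(tab$q) & tab$q < fdr]
      if (st == "extended")
        hits[[ex]] <- tab$feature[!is.na(tab$q) & tab$q < fdr]
    }
    if (is.null(hits[[ex]])) hits[[ex]] <- character(0)
  }
  structure(list(results = do.call(rbind, c(res, make.row.names = FALSE)),
                 hits = hits, fdr = fdr, species = species),
            class = "osa_cascade")
}

#' @export
print.osa_cascade <- function(x, ...) {
  cat(sprintf("Association cascade: %d species tested, FDR %.2g\n",
              length(x$species), x$fdr))
  for (ex in names(x$hits)) {
    per_stage <- vapply(c("screening", "main", "extended"), function(st) {
      sub <- x$results[x$results$exposure == ex & x$results$model == st, ]
      sum(!is.na(sub$q) & sub$q < x$fdr)
    }, integer(1))
    cat(sprintf("  %s: screening %d -> main %d -> extended %d hits\n",
                toupper(ex), per_stage[1L], per_stage[2L], per_stage[3L]))
  }
  invisible(x)
}

#' Sensitivity analyses on the final hit set
#'
#' Re-tests the extended-model hits under four pre-specified variants:
#' \enumerate{
#'   \item extended model + medication use (metformin, proton pump
#'     inhibitors, antihypertensive and lipid-lowering medication);
#'   \item extended model + waist-to-hip ratio;
#'   \item exclusion of participants with antibiotic use in the previous
#'     6 months;
#'   \item exclusion of participants with lung disease.
#' }
#' BH adjustment is applied within each (exposure, variant) family over the
#' hit species.
#'
#' @param cascade an [run_cascade()] result.
#' @param exposures,abundance,covariates as in [run_cascade()]. `covariates`
#'   must additionally contain `med_metformin`, `med_ppi`,
#'   `med_antihypertensive`, `med_lipid`, `whr`, `antibiotics_6m`,
#'   `lung_disease` for the respective variants.
#' @param models covariate sets; the `extended` entry is the base model.
#' @return data frame (exposure, feature, variant, rho, p, q, n, retained).
#' @export
sensitivity_suite <- function(cascade, exposures, abundance, covariates,
                              models = model_covariates()) {
  abundance <- as.matrix(abundance)
  variants <- list(
    medication = list(add = c("med_metformin", "med_ppi",
                              "med_antihypertensive", "med_lipid"),
                      keep = NULL),
    whr = list(add = "whr", keep = NULL),
    no_antibiotics = list(add = NULL, keep = quote(!antibiotics_6m)),
    no_lung_disease = list(add = NULL, keep = quote(!lung_disease))
  )
  out <- list()
  for (ex in names(cascade$hits)) {
    hit <- cascade$hits[[ex]]
    if (!length(hit)) next
    x_all <- exposures[[ex]]
    for (vn in names(variants)) {
      v <- variants[[vn]]
      covs <- unique(c(models$extended, v$add))
      keep <- if (is.null(v$keep)) rep(TRUE, nrow(covariates))
              else eval(v$keep, covariates)
      keep[is.na(keep)] <- FALSE
      cov_v <- covariates[, covs, drop = FALSE]
      cc <- keep & stats::complete.cases(x_all, cov_v)
      if (!any(cc)) stop("variant '", vn, "' empties the sample")
      tab <- ps_many(x_all[cc], abundance[cc, hit, drop = FALSE],
                     cov_v[cc, , drop = FALSE])
      tab$q <- bh_adjust(tab$p)
      out[[paste(ex, vn)]] <- cbind(
        exposure = ex, tab[, "feature", drop = FALSE], variant = vn,
        tab[, c("rho", "p", "q", "n")],
        retained = !is.na(tab$q) & tab$q < cascade$fdr)
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
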