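#' Multiple imputation by predictive mean matching
#'
#' Type-1 PMM with a Bayesian parameter draw. Per imputation: the target is
#' regressed on the predictor design matrix over the observed rows; the
#' residual variance is drawn from its scaled inverse-chi-squared posterior
#' and the coefficients from their normal posterior given that draw;
#' predictions for the observed rows use the least-squares coefficients and
#' predictions for the missing rows use the drawn coefficients; each missing
#' row is matched to the `k` observed rows with the nearest predictions and
#' one donor is drawn uniformly among them. Observed target values are never
#' altered, and every imputed value is a member of the observed donor pool.
#'
#' @param data data frame containing the target and predictors.
#' @param target name of the (partially missing) numeric target column.
#' @param predictors character vector of predictor column names (must be
#'   complete on rows where they are used).
#' @param k number of nearest donors (default 5).
#' @param m number of imputations (>= 2; default 10).
#' @param seed integer seed; the full round is deterministic given it.
#' @return list of `m` completed data frames.
#' @export
pmm_impute <- function(data, target, predictors, k = 5L, m = 10L, seed = 1L) {
  if (m < 2) stop("need at least two imputations")
  if (k < 1) stop("need at least one donor")
  y <- data[[target]]
  if (is.null(y)) stop("target column '", target, "' not found")
  design <- build_design(data[, predictors, drop = FALSE], n = nrow(data))
  obs <- which(!is.na(y) & stats::complete.cases(design))
  mis <- which(is.na(y) & stats::complete.cases(design))
  if (!length(mis)) return(replicate(m, data, simplify = FALSE))
  p <- ncol(design)
  if (length(obs) < p + k)
    stop("fewer observed rows than predictors + donors")
  xo <- design[obs, , drop = FALSE]
  qx <- qr(xo)
  beta_hat <- qr.coef(qx, y[obs])
  beta_hat[is.na(beta_hat)] <- 0
  res <- y[obs] - xo %*% beta_hat
  df <- length(obs) - qx$rank
  ssr <- sum(res^2)
  r_inv_cols <- qx$pivot[seq_len(qx$rank)]
  rmat <- qr.R(qx)[seq_len(qx$rank), seq_len(qx$rank), drop = FALSE]
  eta_obs <- as.numeric(xo %*% beta_hat)
  set.seed(seed)
  lapply(seq_len(m), function(im) {
    sigma2 <- ssr / stats::rchisq(1L, df)
    zdraw <- backsolve(rmat, stats::rnorm(qx$rank)) * sqrt(sigma2)
    beta_star <- beta_hat
    beta_star[r_inv_cols] <- beta_star[r_inv_cols] + zdraw
    eta_mis <- as.numeric(design[mis, , drop = FALSE] %*% beta_star)
    donors <- vapply(eta_mis, function(e) {
      nearest <- order(abs(eta_obs - e))[seq_len(k)]
      obs[nearest[sample.int(k, 1L)]]
    }, integer(1))
    completed <- data
    completed[[target]][mis] <- y[donors]
    completed
  })
}

#' Pool estimates across imputations with Rubin's rules
#'
#' Pooled estimate = mean of the per-imputation estimates; total variance =
#' within-imputation variance + (1 + 1/m) x between-imputation variance;
#' degrees of freedom by the small-sample formula
#' \eqn{(m-1)\left(1 + \bar U / ((1+1/m) B)\right)^2}. When the estimates are
#' identical across imputations (between-variance 0) the degrees of freedom
#' are infinite and pooled inference equals the complete-data inference.
#'
#' @param estimates numeric vector of per-imputation estimates (length m
#'   >= 2).
#' @param variances per-imputation sampling variances.
#' @return object of class `"pooled_estimate"`: list with `estimate`,
#'   `within_var`, `between_var`, `total_var`, `df`, `statistic`, `p`, `m`.
#' @export
rubin_pool <- function(estimates, variances) {
  m <- length(estimates)
  if (m < 2 || length(variances) != m)
    stop("need m >= 2 matching estimate/variance pairs")
  qbar <- mean(estimates)
  ubar <- mean(variances)
  bvar <- stats::var(estimates)
  if (bvar == 0 && ubar == 0)
    stop("all variance components are zero; nothing to pool")
  tvar <- ubar + (1 + 1 / m) * bvar
  df <- if (bvar == 0) Inf
        else (m - 1) * (1 + ubar / ((1 + 1 / m) * bvar))^2
  stat <- qbar / sqrt(tvar)
  structure(list(estimate = qbar, within_var = ubar, between_var = bvar,
                 total_var = tvar, df = df,
                 statistic = stat,
                 p = 2 * stats::pt(-abs(stat), df = df), m = m),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf(
    "Pooled estimate over %d imputations: %.4f (total var %.3g, df %.1f, p = %.3g)\n",
    x$m, x$estimate, x$total_var, x$df, x$p))
  invisible(x)
}

#' Association cascade on multiply imputed AHI
#'
#' For each species, runs one round of predictive mean matching on the
#' missing AHI values -- predictors are the extended-model covariates plus
#' the Shannon index, T90, ODI, waist-to-hip ratio and the species' own
#' relative abundance (rank-transformed to tame skew) -- computes the
#' covariate-adjusted partial Spearman correlation in each completed
#' dataset, pools across imputations on the Fisher-z scale (per-imputation
#' variance 1/(n-3)) with [rubin_pool()], and back-transforms the pooled
#' value. BH adjustment across species on the pooled p-values. With raw
#' pooling (`fisher_z = FALSE`) the per-imputation estimates are pooled on
#' the rho scale directly.
#'
#' @param exposures,abundance,covariates as in [run_cascade()]; `exposures`
#'   must contain `ahi` (with missing values), `t90` and `odi`; `covariates`
#'   must contain `whr`.
#' @param species species ids to analyze (default: prevalence-filtered
#'   columns).
#' @param model_covs adjustment covariates for the association (default the
#'   extended model).
#' @param k,m PMM donors and imputation count (defaults 5 and 10).
#' @param fisher_z pool on the Fisher-z scale (default TRUE).
#' @param seed integer seed.
#' @return data frame: `feature`, `rho` (pooled, back-transformed), `p`,
#'   `q`, `n`, `between_var`, `df`.
#' @export
imputed_cascade <- function(exposures, abundance, covariates,
                            species = prevalence_filter(abundance),
                            model_covs = model_covariates()$extended,
                            k = 5L, m = 10L, fisher_z = TRUE, seed = 1L) {
  abundance <- as.matrix(abundance)
  shannon <- apply(abundance, 1L, shannon_index)
  base <- data.frame(ahi = exposures$ahi, t90 = exposures$t90,
                     odi = exposures$odi, shannon = shannon,
                     covariates[, unique(c(model_covs, "whr")), drop = FALSE])
  pred_base <- c(model_covs, "whr", "shannon", "t90", "odi")
  rows <- lapply(seq_along(species), function(si) {
    spid <- species[si]
    dat <- base
    dat$species_rank <- midrank(abundance[, spid])
    usable <- stats::complete.cases(dat[, c(pred_base, "species_rank")])
    dat <- dat[usable, , drop = FALSE]
    completed <- pmm_impute(dat, target = "ahi",
                            predictors = c(pred_base, "species_rank"),
                            k = k, m = m, seed = derive_seed(seed, si))
    fits <- lapply(completed, function(d)
      partial_spearman(d$ahi, d$species_rank,
                       d[, model_covs, drop = FALSE]))
    rho <- vapply(fits, `[[`, numeric(1), "rho")
    n <- fits[[1L]]$n
    if (fisher_z) {
      pool <- rubin_pool(atanh(rho), rep(1 / (n - 3), m))
      est <- tanh(pool$estimate)
    } else {
      pool <- rubin_pool(rho, vapply(fits, function(f)
        (1 - f$rho^2)^2 / (f$n - 3), numeric(1)))
      est <- pool$estimate
    }
    data.frame(feature = spid, rho = est, p = pool$p, n = n,
               between_var = pool$between_var, df = pool$df)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out[, c("feature", "rho", "p", "q", "n", "between_var", "df")]
}
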