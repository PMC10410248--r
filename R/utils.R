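# Internal helpers shared across modules.

#' Build a least-squares design matrix from a covariate table
#'
#' Categorical covariates (factors or characters) are expanded to one-hot
#' indicator columns; an intercept is always included. Factors that collapse
#' to a single observed level (e.g. after exclusions) are dropped with a
#' warning rather than producing a rank-deficient design.
#'
#' @param covariates data frame of covariates, or `NULL` for intercept-only.
#' @param n number of rows when `covariates` is `NULL`.
#' @param standardize standardize quantitative columns to unit variance?
#' @return numeric matrix with an `"(Intercept)"` column first.
#' @keywords internal
#' @noRd
build_design <- function(covariates, n = NULL, standardize = FALSE) {
  if (is.null(covariates) || (is.data.frame(covariates) && ncol(covariates) == 0L)) {
    stopifnot(!is.null(n))
    return(matrix(1, nrow = n, ncol = 1L, dimnames = list(NULL, "(Intercept)")))
  }
  covariates <- as.data.frame(covariates)
  keep <- vapply(names(covariates), function(nm) {
    v <- covariates[[nm]]
    if (is.character(v) || is.factor(v) || is.logical(v)) {
      nl <- length(unique(v[!is.na(v)]))
      if (nl < 2L) {
        warning(sprintf("covariate '%s' has a single observed level; dropped", nm),
                call. = FALSE)
        return(FALSE)
      }
    } else if (stats::var(as.numeric(v), na.rm = TRUE) == 0) {
      warning(sprintf("covariate '%s' has zero variance; dropped", nm), call. = FALSE)
      return(FALSE)
    }
    TRUE
  }, logical(1))
  covariates <- covariates[, keep, drop = FALSE]
  if (ncol(covariates) == 0L)
    return(matrix(1, nrow = nrow(as.data.frame(covariates)),
                  ncol = 1L, dimnames = list(NULL, "(Intercept)")))
  for (nm in names(covariates)) {
    if (is.character(covariates[[nm]]) || is.logical(covariates[[nm]]))
      covariates[[nm]] <- factor(covariates[[nm]])
    else if (is.numeric(covariates[[nm]]) && standardize)
      covariates[[nm]] <- as.numeric(scale(covariates[[nm]]))
  }
  stats::model.matrix(~ ., data = covariates)
}

# Average (mid) ranks, keeping NA as NA.
midrank <- function(x) rank(x, ties.method = "average", na.last = "keep")

# Residuals of each column of Y after least-squares projection on X.
# X must be full column rank after QR pivoting; rank-deficient columns are
# dropped silently (pivoted QR).
residualize <- function(Y, X) {
  qr_x <- qr(X)
  Y - qr.fitted(qr_x, Y)
}

# Column-wise Pearson correlation between a vector x and each column of Y.
cor_vec_mat <- function(x, Y) {
  x <- x - mean(x)
  Y <- sweep(Y, 2L, colMeans(Y))
  sx <- sqrt(sum(x^2))
  sy <- sqrt(colSums(Y^2))
  out <- as.numeric(crossprod(Y, x)) / (sx * sy)
  out[sx == 0 | sy == 0] <- NA_real_
  pmin(1, pmax(-1, out))
}

# Deterministic per-purpose seed derived from a user seed; stays < 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(offset) %% 100000L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
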