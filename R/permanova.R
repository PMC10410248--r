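#' Covariate-adjusted PERMANOVA on a dissimilarity matrix
#'
#' Permutational multivariate analysis of variance with sequential
#' (covariates-first) partitioning of the sums of squares, following the
#' direct distance-based formulation: the Gower-centered matrix
#' \eqn{G = -\tfrac12 C D^{(2)} C} is projected on nested least-squares hat
#' matrices, the group term's sum of squares is
#' \eqn{tr(H_{full} G) - tr(H_{cov} G)}, and a pseudo-F statistic is referred
#' to its permutation distribution under free permutation of samples
#' (covariate and group rows are permuted jointly against the distance
#' matrix). \eqn{R^2} is the group sum of squares over the total.
#'
#' Quantitative covariates are standardized before the partition for
#' conditioning; categorical covariates enter as one-hot indicators.
#'
#' @param d symmetric dissimilarity matrix.
#' @param groups factor with >= 2 levels, one per sample.
#' @param covariates optional covariate data frame entered before the group
#'   term.
#' @param n_permutations number of permutations (>= 99; default 9999, enough
#'   to resolve p-values near 1e-4).
#' @param seed integer seed for the permutation stream.
#' @return object of class `"permanova"`: list with `r_squared`, `p_value`,
#'   `f_statistic`, `df`, `ss` (group/residual/total) and `n_permutations`.
#' @export
permanova <- function(d, groups, covariates = NULL, n_permutations = 9999,
                      seed = 1L) {
  d <- as.matrix(d)
  n <- nrow(d)
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least two group levels")
  if (length(groups) != n) stop("one group label per sample required")
  if (n_permutations < 99) stop("need at least 99 permutations")

  a <- -0.5 * d^2
  g <- sweep(sweep(a, 1L, rowMeans(a)), 2L, colMeans(a)) + mean(a)

  x0 <- build_design(covariates, n = n, standardize = TRUE)
  x1 <- cbind(x0, stats::model.matrix(~ groups)[, -1L, drop = FALSE])
  q0 <- qr(x0); q1 <- qr(x1)
  df_group <- q1$rank - q0$rank
  if (df_group == 0L)
    stop("group term is collinear with the covariates (confounded design)")
  df_resid <- n - q1$rank
  h0 <- tcrossprod(qr.Q(q0)[, seq_len(q0$rank), drop = FALSE])
  h1 <- tcrossprod(qr.Q(q1)[, seq_len(q1$rank), drop = FALSE])

  ss_total <- sum(diag(g))
  stat <- function(gm) {
    ss_grp <- sum(h1 * gm) - sum(h0 * gm)
    ss_res <- sum(diag(gm)) - sum(h1 * gm)
    c(ss_grp, ss_res, (ss_grp / df_group) / (ss_res / df_resid))
  }
  obs <- stat(g)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_permutations)) {
    p <- sample.int(n)
    if (stat(g[p, p])[3L] >= obs[3L]) exceed <- exceed + 1L
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  structure(list(
    r_squared = obs[1L] / ss_total,
    p_value = (1 + exceed) / (1 + n_permutations),
    f_statistic = obs[3L],
    df = c(group = df_group, residual = df_resid),
    ss = c(group = obs[1L], residual = obs[2L], total = ss_total),
    n_permutations = n_permutations
  ), class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA: R2 = %.3f%%, pseudo-F = %.3f (df %d, %d), P = %.4g (%d permutations)\n",
    100 * x$r_squared, x$f_statistic, x$df[["group"]], x$df[["residual"]],
    x$p_value, x$n_permutations))
  invisible(x)
}

#' Pairwise PERMANOVA over group pairs
#'
#' Applies [permanova()] to every pair of group levels, subsetting the
#' dissimilarity matrix and covariates to the two groups compared.
#'
#' @inheritParams permanova
#' @return data frame with one row per pair: `group_a`, `group_b`, `r_squared`,
#'   `f_statistic`, `p_value`, `n`.
#' @export
pairwise_permanova <- function(d, groups, covariates = NULL,
                               n_permutations = 999, seed = 1L) {
  groups <- factor(groups)
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2L)
  out <- lapply(seq_len(ncol(pairs)), function(j) {
    sel <- which(groups %in% pairs[, j] & !is.na(groups))
    fit <- permanova(d[sel, sel, drop = FALSE], droplevels(groups[sel]),
                     covariates = if (is.null(covariates)) NULL
                                  else covariates[sel, , drop = FALSE],
                     n_permutations = n_permutations,
                     seed = derive_seed(seed, j))
    data.frame(group_a = pairs[1L, j], group_b = pairs[2L, j],
               r_squared = fit$r_squared, f_statistic = fit$f_statistic,
               p_value = fit$p_value, n = length(sel))
  })
  do.call(rbind, out)
}
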