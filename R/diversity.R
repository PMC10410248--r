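#' Shannon diversity index
#'
#' Alpha diversity of one community profile: \eqn{H = -\sum_i p_i \log p_i}
#' over taxa with positive abundance, after renormalizing the row to sum to
#' one. Natural logarithm by default.
#'
#' @param x numeric vector of non-negative abundances with a positive sum.
#' @param base logarithm base (default `exp(1)`, i.e. nats).
#' @return Shannon index (scalar).
#' @examples
#' shannon_index(rep(1, 100))  # log(100)
#' @export
shannon_index <- function(x, base = exp(1)) {
  if (any(x < 0, na.rm = TRUE)) stop("abundances must be non-negative")
  s <- sum(x, na.rm = TRUE)
  if (!is.finite(s) || s <= 0) stop("abundance row sums to zero")
  p <- x[!is.na(x) & x > 0] / s
  -sum(p * log(p, base = base))
}

#' Bray-Curtis dissimilarity matrix
#'
#' \eqn{d(x,y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)}, computed for all
#' sample pairs of an abundance matrix (samples in rows).
#'
#' @param abundance numeric matrix, samples x species, non-negative with at
#'   least one positive entry per row.
#' @return symmetric dissimilarity matrix in \[0, 1\] with zero diagonal and
#'   row/column names taken from `abundance` row names.
#' @export
bray_curtis <- function(abundance) {
  abundance <- as.matrix(abundance)
  if (any(abundance < 0)) stop("abundances must be non-negative")
  rs <- rowSums(abundance)
  if (any(rs <= 0)) stop("every sample needs at least one positive abundance")
  n <- nrow(abundance)
  # sum |x-y| = sum(x) + sum(y) - 2*sum(pmin(x,y)); pairwise min via crossprod
  # trick is not exact, so compute with a blocked loop on rows (still O(n^2 p))
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    xi <- abundance[i, ]
    rest <- (i + 1L):n
    num <- colSums(abs(t(abundance[rest, , drop = FALSE]) - xi))
    den <- rs[i] + rs[rest]
    d[i, rest] <- d[rest, i] <- num / den
  }
  dimnames(d) <- list(rownames(abundance), rownames(abundance))
  d
}

#' Principal coordinate analysis (classical multidimensional scaling)
#'
#' Double-centers the squared dissimilarity matrix (Gower centering) and
#' eigendecomposes it. Axes are ordered by decreasing eigenvalue; coordinates
#' are eigenvectors scaled by the square root of their (positive) eigenvalues.
#' Negative eigenvalues, which arise for non-Euclidean dissimilarities such
#' as Bray-Curtis, are kept in the eigenvalue vector but excluded from the
#' explained-variance denominator; no Lingoes/Cailliez correction is applied.
#'
#' @param d symmetric dissimilarity matrix (zero diagonal, finite entries).
#' @param n_axes number of axes to return (truncated with a warning if it
#'   exceeds the number of positive eigenvalues).
#' @return object of class `"pcoa"`: list with `coordinates`
#'   (samples x axes), `explained_variance` (proportion per returned axis),
#'   and `eigenvalues` (all, decreasing).
#' @export
pcoa <- function(d, n_axes = 2) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n != ncol(d) || any(!is.finite(d))) stop("'d' must be a finite square matrix")
  if (max(abs(d - t(d))) > 1e-8) stop("'d' must be symmetric")
  a <- -0.5 * d^2
  g <- sweep(sweep(a, 1L, rowMeans(a)), 2L, colMeans(a)) + mean(a)
  eig <- eigen(g, symmetric = TRUE)
  pos <- which(eig$values > max(eig$values) * 1e-12 & eig$values > 0)
  if (n_axes > length(pos)) {
    warning(sprintf("only %d positive eigenvalues; truncating n_axes", length(pos)))
    n_axes <- length(pos)
  }
  take <- pos[seq_len(n_axes)]
  coords <- eig$vectors[, take, drop = FALSE] %*%
    diag(sqrt(eig$values[take]), n_axes, n_axes)
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("PCo", seq_len(n_axes))
  structure(list(
    coordinates = coords,
    explained_variance = eig$values[take] / sum(eig$values[pos]),
    eigenvalues = eig$values
  ), class = "pcoa")
}

#' @export
print.pcoa <- function(x, ...) {
  cat(sprintf("Principal coordinate analysis: %d samples, %d axes returned\n",
              nrow(x$coordinates), ncol(x$coordinates)))
  cat("Explained variance:",
      paste(sprintf("%.1f%%", 100 * x$explained_variance), collapse = ", "), "\n")
  invisible(x)
}

#' Per-group ordination centroids with standard errors
#'
#' Mean coordinate per group and axis, with the standard error of the mean
#' (sample SD / sqrt(group size)). Singleton groups get `NA` standard errors.
#'
#' @param ordination a [pcoa()] result (or any list with a `coordinates`
#'   matrix).
#' @param groups factor/character group labels, one per sample.
#' @return data frame with one row per (group, axis): `group`, `axis`,
#'   `mean`, `se`, `n`.
#' @export
group_centroids <- function(ordination, groups) {
  coords <- ordination$coordinates
  if (length(groups) != nrow(coords)) stop("one group label per sample required")
  groups <- factor(groups)
  out <- do.call(rbind, lapply(levels(groups), function(g) {
    m <- coords[groups == g & !is.na(groups), , drop = FALSE]
    data.frame(group = g, axis = colnames(coords),
               mean = colMeans(m),
               se = if (nrow(m) > 1) apply(m, 2L, stats::sd) / sqrt(nrow(m))
                    else NA_real_,
               n = nrow(m), row.names = NULL)
  }))
  out
}
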