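#' Presence/absence matrix for co-occurrence analysis
#'
#' Presence is defined as relative abundance strictly greater than zero,
#' consistent with the prevalence-filter convention.
#'
#' @param abundance participants x species matrix.
#' @param species species ids to keep (default: all columns).
#' @return logical participants x species matrix.
#' @export
presence_matrix <- function(abundance, species = colnames(abundance)) {
  abundance <- as.matrix(abundance)
  unknown <- setdiff(species, colnames(abundance))
  if (length(unknown))
    stop("unknown species id(s): ", paste(utils::head(unknown, 5), collapse = ", "))
  abundance[, species, drop = FALSE] > 0
}

#' Exact probabilistic co-occurrence for one species pair
#'
#' Under random, independent placement of two species with fixed prevalences
#' across `n_sites` sites, the number of co-occupied sites is
#' hypergeometric:
#' \eqn{P(j) = \binom{p_a}{j}\binom{n - p_a}{p_b - j} / \binom{n}{p_b}}.
#' `p_gt` sums the mass at or above the observed count, `p_lt` at or below
#' (both include the observed point mass, so `p_lt + p_gt >= 1`); the
#' expected count is \eqn{p_a p_b / n}.
#'
#' @param n_sites number of sites (participants).
#' @param prev_a,prev_b number of sites occupied by each species.
#' @param obs observed number of co-occupied sites.
#' @return list with `p_lt`, `p_gt`, `expected`.
#' @examples
#' pair_probability(4, 2, 2, 2)  # p_gt = 1/6
#' @export
pair_probability <- function(n_sites, prev_a, prev_b, obs) {
  if (prev_a > n_sites || prev_b > n_sites)
    stop("prevalence cannot exceed the number of sites")
  lo <- max(0L, prev_a + prev_b - n_sites)
  hi <- min(prev_a, prev_b)
  if (obs < lo || obs > hi)
    stop(sprintf("observed co-occurrence %d outside support [%d, %d]",
                 obs, lo, hi))
  j <- lo:hi
  mass <- stats::dhyper(j, prev_a, n_sites - prev_a, prev_b)
  list(p_lt = sum(mass[j <= obs]),
       p_gt = sum(mass[j >= obs]),
       expected = prev_a * prev_b / n_sites)
}

#' Build the probabilistic co-occurrence network
#'
#' Evaluates every species pair of a presence/absence matrix with
#' [pair_probability()] and classifies it as `positive` (p_gt < alpha),
#' `negative` (p_lt < alpha) or `random`. Pairs whose prevalences make any
#' deviation undetectable at `alpha` (the extreme attainable tail masses
#' both exceed `alpha`) are flagged `untestable`. No multiple-testing
#' correction is applied to the pair classifications, following the
#' convention of probabilistic co-occurrence analysis; treat edge counts
#' descriptively.
#'
#' @param presence logical participants x species matrix (>= 2 species).
#' @param alpha classification threshold (default 0.05).
#' @return object of class `"cooccurrence_network"`: list with `pairs`
#'   (data frame: `species_a`, `species_b`, `n_sites`, `prev_a`, `prev_b`,
#'   `obs_cooccur`, `exp_cooccur`, `p_lt`, `p_gt`, `classification`,
#'   `untestable`) and `edges` (the non-random, testable subset).
#' @export
build_network <- function(presence, alpha = 0.05) {
  presence <- as.matrix(presence)
  if (ncol(presence) < 2L) stop("need at least two species")
  storage.mode(presence) <- "integer"
  n <- nrow(presence)
  prev <- colSums(presence)
  co <- crossprod(presence)   # pairwise co-occurrence counts
  sp <- colnames(presence) %||% as.character(seq_len(ncol(presence)))
  idx <- which(upper.tri(co), arr.ind = TRUE)
  rows <- lapply(seq_len(nrow(idx)), function(r) {
    i <- idx[r, 1L]; j <- idx[r, 2L]
    pp <- pair_probability(n, prev[i], prev[j], co[i, j])
    lo <- max(0L, prev[i] + prev[j] - n)
    hi <- min(prev[i], prev[j])
    best_gt <- stats::dhyper(hi, prev[i], n - prev[i], prev[j])
    best_lt <- stats::dhyper(lo, prev[i], n - prev[i], prev[j])
    untestable <- best_gt > alpha && best_lt > alpha
    cls <- if (pp$p_gt < alpha) "positive"
           else if (pp$p_lt < alpha) "negative" else "random"
    data.frame(species_a = sp[i], species_b = sp[j], n_sites = n,
               prev_a = prev[[i]], prev_b = prev[[j]],
               obs_cooccur = co[i, j], exp_cooccur = pp$expected,
               p_lt = pp$p_lt, p_gt = pp$p_gt,
               classification = cls, untestable = untestable)
  })
  pairs <- do.call(rbind, rows)
  structure(list(pairs = pairs,
                 edges = pairs[pairs$classification != "random" &
                               !pairs$untestable, , drop = FALSE],
                 alpha = alpha),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  tab <- table(factor(x$pairs$classification,
                      levels = c("positive", "negative", "random")))
  cat(sprintf(paste0("Co-occurrence network (alpha = %.2g): %d pairs -- ",
                     "%d positive, %d negative, %d random (%d untestable)\n"),
              x$alpha, nrow(x$pairs), tab[["positive"]], tab[["negative"]],
              tab[["random"]], sum(x$pairs$untestable)))
  invisible(x)
}
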