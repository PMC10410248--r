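# Shared fixtures, built in code at test time.

# Small cohort used by several module tests (cached per session).
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_cohort(cohort_config(
        n_participants = 400, n_species = 60, n_ko = 300, n_gmm = 8,
        n_true_pos = 6, n_true_neg = 6, n_confounded = 5, n_planted_gmm = 2,
        n_outcome_species = 2, seed = 42))
    cache
  }
})

# Random compositional abundance matrix (rows sum to 1).
random_abundance <- function(n, s, seed = 1, zero_frac = 0.3) {
  set.seed(seed)
  m <- matrix(rexp(n * s), n, s)
  m[runif(n * s) < zero_frac] <- 0
  empty <- rowSums(m) == 0
  m[empty, 1] <- 1
  m <- m / rowSums(m)
  dimnames(m) <- list(sprintf("P%03d", seq_len(n)), sprintf("sp%03d", seq_len(s)))
  m
}

# Independent brute-force partial Spearman: explicit normal equations.
oracle_partial_spearman <- function(x, y, z_df) {
  rx <- rank(x); ry <- rank(y)
  zm <- stats::model.matrix(~ ., data = z_df)
  bx <- solve(t(zm) %*% zm, t(zm) %*% rx)
  by <- solve(t(zm) %*% zm, t(zm) %*% ry)
  ex <- rx - zm %*% bx
  ey <- ry - zm %*% by
  sum(ex * ey) / sqrt(sum(ex^2) * sum(ey^2))
}

# Independent step-up BH oracle.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    prev <- min(prev, m * p[o[i]] / i)
    q[o[i]] <- prev
  }
  pmin(q, 1)
}

# Independent module-detection oracle (explicit set logic, no shared code).
oracle_has_gmm <- function(kos, gmm) {
  for (path in gmm$paths) {
    ns <- length(path)
    cov <- 0L
    for (st in path) if (length(intersect(st, kos)) > 0) cov <- cov + 1L
    need <- if (ns <= 3) ns else ceiling(2 * ns / 3)
    if (cov >= need && (ns > 3 || cov == ns)) return(TRUE)
  }
  FALSE
}

# Exhaustive co-occurrence tail probabilities by enumerating all placements
# of species B over n sites (species A fixed in the first prev_a sites).
oracle_cooccur <- function(n, prev_a, prev_b, obs) {
  placements <- utils::combn(n, prev_b)
  co <- colSums(placements <= prev_a)
  list(p_lt = mean(co <= obs), p_gt = mean(co >= obs))
}
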