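#' Construct a gut metabolic module definition
#'
#' A GMM is one or more alternative paths, each an ordered list of enzymatic
#' steps, each step a set of interchangeable KEGG-ortholog (KO) identifiers.
#'
#' @param id module identifier (e.g. `"MF0001"` or a synthetic id).
#' @param name human-readable label.
#' @param paths list of paths; each path a list of steps; each step a
#'   non-empty character vector of KO ids.
#' @return object of class `"gmm_definition"`.
#' @export
gmm_definition <- function(id, name, paths) {
  if (!length(paths)) stop("a module needs at least one path")
  for (p in paths) {
    if (!length(p)) stop("a path needs at least one step")
    for (st in p) {
      if (!length(st) || !is.character(st) || any(!nzchar(st)))
        stop("every step needs at least one KO id")
      if (any(!grepl("^K[0-9A-Za-z]+$", st)))
        stop("KO ids must be K-prefixed alphanumerics")
    }
  }
  structure(list(id = id, name = name, paths = paths),
            class = "gmm_definition")
}

#' @export
print.gmm_definition <- function(x, ...) {
  cat(sprintf("GMM %s (%s): %d path(s), %s steps\n", x$id, x$name,
              length(x$paths),
              paste(vapply(x$paths, length, integer(1)), collapse = "/")))
  invisible(x)
}

#' Does a species carry a gut metabolic module?
#'
#' Coverage rule: a step is covered when the species' KO set intersects the
#' step's KO alternatives. A path fulfils the criterion when covered steps
#' reach at least two-thirds of its steps (ceiling) -- except that paths
#' with three or fewer steps require \emph{all} steps. The module is present
#' if any alternative path fulfils its criterion. A per-KO-fraction variant
#' (`rule = "ko_fraction"`: at least two-thirds of the path's distinct KO
#' ids present, all-steps rule kept for short paths) is available; step
#' counting is the default.
#'
#' @param ko_set character vector of KO ids carried by the species (empty
#'   set allowed and yields `FALSE`).
#' @param gmm a [gmm_definition()].
#' @param rule `"steps"` (default) or `"ko_fraction"`.
#' @return logical scalar.
#' @export
species_has_gmm <- function(ko_set, gmm, rule = c("steps", "ko_fraction")) {
  rule <- match.arg(rule)
  if (!length(ko_set)) return(FALSE)
  for (path in gmm$paths) {
    ns <- length(path)
    covered <- vapply(path, function(st) any(st %in% ko_set), logical(1))
    ok <- if (rule == "steps") {
      if (ns <= 3L) all(covered) else sum(covered) >= ceiling(2 / 3 * ns)
    } else {
      kos <- unique(unlist(path))
      if (ns <= 3L) all(covered)
      else sum(kos %in% ko_set) >= ceiling(2 / 3 * length(kos))
    }
    if (ok) return(TRUE)
  }
  FALSE
}

#' Species-by-module presence matrix
#'
#' Applies [species_has_gmm()] to every (species, module) pair.
#'
#' @param ko_table long data frame with columns `species_id`, `ko_id`.
#' @param gmm_definitions list of [gmm_definition()] objects.
#' @param rule coverage rule, see [species_has_gmm()].
#' @return logical matrix, species x modules.
#' @export
annotate_species <- function(ko_table, gmm_definitions,
                             rule = c("steps", "ko_fraction")) {
  rule <- match.arg(rule)
  if (!all(c("species_id", "ko_id") %in% names(ko_table)))
    stop("ko_table needs columns 'species_id' and 'ko_id'")
  sets <- split(ko_table$ko_id, ko_table$species_id)
  out <- vapply(gmm_definitions,
                function(g) vapply(sets, species_has_gmm, logical(1),
                                   gmm = g, rule = rule),
                logical(length(sets)))
  out <- matrix(out, nrow = length(sets),
                dimnames = list(names(sets),
                                vapply(gmm_definitions, `[[`, character(1), "id")))
  out
}

#' Direction-stratified GMM enrichment on ranked p-values
#'
#' Tests whether module carriers concentrate at the top of the association
#' ranking within one direction of effect. Species are restricted to those
#' whose correlation has the requested sign, ranked by ascending p-value,
#' and each module's carriers are compared with non-carriers by a one-sided
#' Mann-Whitney rank-sum test (alternative: carriers have lower ranks, i.e.
#' smaller p-values). The reported `score` is the standardized (normal
#' approximation, tie-corrected, continuity-corrected) rank-sum statistic,
#' positive when carriers are enriched near the top. BH adjustment is
#' applied across modules within the direction.
#'
#' @param results data frame with one row per species: columns `feature`,
#'   `rho`, `p` (typically the extended-model slice of a cascade result).
#' @param presence logical species x modules matrix from
#'   [annotate_species()].
#' @param direction `"positive"` or `"negative"`: sign of `rho` defining the
#'   stratum.
#' @param min_carriers modules carried by fewer species than this (or with
#'   fewer non-carriers) are skipped with a warning (default 3).
#' @return data frame (`gmm_id`, `direction`, `n_carriers`, `score`, `p`,
#'   `q`), one row per testable module.
#' @export
gmm_enrichment <- function(results, presence, direction = c("positive",
                                                            "negative"),
                           min_carriers = 3L) {
  direction <- match.arg(direction)
  keep <- if (direction == "positive") results$rho > 0 else results$rho < 0
  res <- results[keep & !is.na(results$rho), , drop = FALSE]
  sp <- intersect(res$feature, rownames(presence))
  res <- res[match(sp, res$feature), , drop = FALSE]
  if (!nrow(res)) stop("no species in the requested direction stratum")
  r <- midrank(res$p)
  n <- length(r)
  out <- lapply(colnames(presence), function(gid) {
    carrier <- presence[sp, gid]
    n1 <- sum(carrier); n2 <- n - n1
    if (n1 < min_carriers || n2 < min_carriers) {
      warning(sprintf("module %s: %d carriers in stratum; skipped", gid, n1))
      return(NULL)
    }
    w <- sum(r[carrier])                       # rank-sum of carriers
    mu <- n1 * (n + 1) / 2
    ties <- table(r)
    tie_adj <- sum(ties^3 - ties) / (n * (n - 1))
    v <- n1 * n2 / 12 * ((n + 1) - tie_adj)
    z <- (mu - w - 0.5) / sqrt(v)              # >0: carriers at low ranks
    data.frame(gmm_id = gid, direction = direction, n_carriers = n1,
               score = z, p = stats::pnorm(-z))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(data.frame(gmm_id = character(0),
                                      direction = character(0),
                                      n_carriers = integer(0),
                                      score = numeric(0), p = numeric(0),
                                      q = numeric(0)))
  out$q <- bh_adjust(out$p)
  out
}
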