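# Readers and writers for the pipeline's interchange formats (all plain
# text: TSV with a header row, UTF-8; JSON for manifests and ledgers), plus
# the end-to-end pipeline driver.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

#' Read and write the abundance matrix TSV
#'
#' Layout: one header row (`participant_id` then species ids), one row per
#' participant, relative abundances. On read, participant ids must be
#' unique and every row must sum to 1 within `tol`, otherwise the file is
#' rejected with a message naming the offending row.
#'
#' @param path file path.
#' @param tol closure tolerance on row sums (default 1e-6).
#' @return `read_abundance`: numeric matrix with participant ids as row
#'   names.
#' @export
read_abundance <- function(path, tol = 1e-6) {
  df <- read_tsv(path)
  if (names(df)[1L] != "participant_id")
    stop("abundance file must start with a 'participant_id' column")
  ids <- df$participant_id
  if (anyDuplicated(ids)) stop("duplicate participant ids in abundance file")
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rs <- rowSums(m)
  bad <- which(abs(rs - 1) > tol)
  if (length(bad))
    stop(sprintf("abundance row %d ('%s') sums to %.8f, not 1",
                 bad[1L], ids[bad[1L]], rs[bad[1L]]))
  rownames(m) <- ids
  m
}

#' @rdname read_abundance
#' @param abundance participants x species matrix with row names.
#' @export
write_abundance <- function(abundance, path) {
  df <- data.frame(participant_id = rownames(abundance),
                   as.data.frame(abundance), check.names = FALSE)
  write_tsv(df, path)
}

#' Read a covariate or exposure table
#'
#' Plain TSV with a header row and one row per participant. Participant ids
#' must be present and unique; logical columns (`TRUE`/`FALSE`) and numeric
#' columns are restored with their types.
#'
#' @param path file path.
#' @return data frame.
#' @export
read_covariates <- function(path) {
  df <- read_tsv(path)
  if (!"participant_id" %in% names(df))
    stop("covariate file needs a 'participant_id' column")
  if (anyDuplicated(df$participant_id))
    stop("duplicate participant ids in covariate file")
  df
}

#' @rdname read_covariates
#' @export
read_exposures <- read_covariates

#' Read a species-to-KO annotation table
#'
#' Two-column TSV (`species_id`, `ko_id`). Unknown species (not in
#' `species`, when given) are dropped with a warning.
#'
#' @param path file path.
#' @param species optional character vector of known species ids.
#' @return long data frame (`species_id`, `ko_id`).
#' @export
read_ko <- function(path, species = NULL) {
  df <- read_tsv(path)
  if (!all(c("species_id", "ko_id") %in% names(df)))
    stop("KO table needs columns 'species_id' and 'ko_id'")
  if (!is.null(species)) {
    unknown <- setdiff(unique(df$species_id), species)
    if (length(unknown)) {
      warning(length(unknown), " unknown species in KO table; excluded")
      df <- df[df$species_id %in% species, , drop = FALSE]
    }
  }
  df
}

#' Read and write gut metabolic module definitions
#'
#' Flat text format mirroring public GMM reference distributions:
#' \preformatted{
#' GM001<TAB>module name
#' K00001,K00002      # step 1: alternative KOs, comma-separated
#' K00003             # step 2
#' //                 # delimiter starting an alternative path
#' K00010
#' ===                # module terminator
#' }
#'
#' A small synthetic example file ships with the package (see the example).
#'
#' @param path file path.
#' @return `read_gmm`: list of [gmm_definition()] objects.
#' @examples
#' defs <- read_gmm(system.file("extdata", "example_gmm_definitions.txt",
#'                              package = "apneabiome"))
#' defs[[2]]
#' @export
read_gmm <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(lines)
  mods <- list()
  header <- NULL; paths <- list(); steps <- list()
  flush_path <- function() {
    if (length(steps)) paths[[length(paths) + 1L]] <<- steps
    steps <<- list()
  }
  for (ln in lines[nzchar(lines)]) {
    if (ln == "===") {
      flush_path()
      if (is.null(header)) stop("module terminator before any header")
      mods[[length(mods) + 1L]] <- gmm_definition(header[1L], header[2L],
                                                  paths)
      header <- NULL; paths <- list()
    } else if (ln == "//") {
      flush_path()
    } else if (grepl("\t", ln)) {
      if (!is.null(header)) stop("module '", header[1L], "' not terminated")
      header <- strsplit(ln, "\t", fixed = TRUE)[[1L]][1:2]
    } else {
      if (is.null(header)) stop("step line outside a module: ", ln)
      steps[[length(steps) + 1L]] <- strsplit(ln, ",", fixed = TRUE)[[1L]]
    }
  }
  if (!is.null(header)) stop("unterminated final module")
  mods
}

#' @rdname read_gmm
#' @param gmm_definitions list of [gmm_definition()] objects.
#' @export
write_gmm <- function(gmm_definitions, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (g in gmm_definitions) {
    writeLines(paste(g$id, g$name, sep = "\t"), con)
    for (pi in seq_along(g$paths)) {
      if (pi > 1L) writeLines("//", con)
      for (st in g$paths[[pi]])
        writeLines(paste(st, collapse = ","), con)
    }
    writeLines("===", con)
  }
  invisible(path)
}

#' Write a synthetic cohort to a directory of plain-text files
#'
#' Emits `exposures.tsv`, `covariates.tsv`, `abundance.tsv`,
#' `event_records.tsv`, `outcomes.tsv`, `ko_table.tsv`, `gmm_definitions.txt`
#' and `truth.json`.
#'
#' @param cohort an [simulate_cohort()] result.
#' @param dir output directory (created if absent).
#' @return invisibly, the vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "osa_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    write_tsv(cohort$exposures, file.path(dir, "exposures.tsv")),
    write_tsv(cohort$covariates, file.path(dir, "covariates.tsv")),
    write_abundance(cohort$abundance, file.path(dir, "abundance.tsv")),
    write_tsv(cohort$event_records, file.path(dir, "event_records.tsv")),
    write_tsv(cohort$outcomes, file.path(dir, "outcomes.tsv")),
    write_tsv(cohort$ko_table, file.path(dir, "ko_table.tsv")),
    write_gmm(cohort$gmm_definitions, file.path(dir, "gmm_definitions.txt")))
  truth <- cohort$truth
  jsonlite::write_json(truth[setdiff(names(truth), "outcome_sign")],
                       file.path(dir, "truth.json"), pretty = TRUE)
  invisible(c(paths, file.path(dir, "truth.json")))
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes the stages in dependency order -- OSA parameter construction
#' from event records, severity grouping, alpha/beta diversity with
#' PERMANOVA, the association cascade with sensitivity analyses, optional
#' multiple imputation of AHI, the hemoglobin heterogeneity screen, GMM
#' annotation and enrichment, species co-occurrence, and the blood
#' pressure/HbA1c post hoc models -- writing each stage's result as TSV
#' under `out_dir` together with a JSON manifest recording the package
#' version, seeds, input checksums and per-stage row counts. All
#' randomness flows from `seed` (permutations, bootstrap, imputation);
#' rerunning with an identical cohort and seed reproduces every output
#' byte for byte.
#'
#' @param cohort an [simulate_cohort()] result.
#' @param out_dir output directory.
#' @param fdr false discovery rate (default 0.05).
#' @param n_permutations PERMANOVA permutations (default 999 at pipeline
#'   scale; see [permanova()] for the module-level default).
#' @param bootstrap_B heterogeneity bootstrap iterations (default 200 at
#'   pipeline scale; 1000 is the module-level default).
#' @param impute run the imputed AHI cascade? (default TRUE)
#' @param m,k imputation count and PMM donors.
#' @param seed integer master seed.
#' @return invisibly, a list with the in-memory stage results
#'   (`parameters`, `groups`, `diversity`, `cascade`, `sensitivity`,
#'   `imputed`, `heterogeneity`, `gmm_enrichment`, `network`, `outcomes`,
#'   `manifest`).
#' @export
run_pipeline <- function(cohort, out_dir, fdr = 0.05, n_permutations = 999,
                         bootstrap_B = 200, impute = TRUE, m = 10L, k = 5L,
                         seed = 1L) {
  stopifnot(inherits(cohort, "osa_cohort"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(...) message(sprintf(...))

  # -- OSA parameters from event records ---------------------------------
  params <- compute_osa_parameters(cohort$event_records)
  groups <- assign_severity_groups(params)
  write_tsv(cbind(params, groups), file.path(out_dir, "osa_parameters.tsv"))
  log_stage("osa-params: %d participants, %d valid AHI, %d valid SpO2",
            nrow(params), sum(params$ahi_valid), sum(params$sat_valid))
  exposures <- data.frame(ahi = params$ahi, t90 = params$t90,
                          odi = params$odi)
  covariates <- cohort$covariates
  covariates$energy <- clean_energy_intake(covariates$energy)
  abundance <- cohort$abundance

  # -- Diversity ----------------------------------------------------------
  shannon <- apply(abundance, 1L, shannon_index)
  d <- bray_curtis(abundance)
  ord <- pcoa(d, n_axes = 2)
  perm <- list()
  for (g in names(groups)) {
    lab <- groups[[g]]
    cc <- !is.na(lab) & stats::complete.cases(
      covariates[, model_covariates()$main, drop = FALSE])
    perm[[g]] <- permanova(d[cc, cc], droplevels(lab[cc]),
                           covariates[cc, model_covariates()$main,
                                      drop = FALSE],
                           n_permutations = n_permutations,
                           seed = derive_seed(seed, 21L + match(g, names(groups))))
  }
  div_tab <- data.frame(
    grouping = names(perm),
    r_squared = vapply(perm, `[[`, numeric(1), "r_squared"),
    p_value = vapply(perm, `[[`, numeric(1), "p_value"))
  write_tsv(data.frame(participant_id = rownames(abundance),
                       shannon = shannon,
                       ord$coordinates),
            file.path(out_dir, "diversity.tsv"))
  write_tsv(div_tab, file.path(out_dir, "permanova.tsv"))
  log_stage("diversity: PERMANOVA over %d groupings", length(perm))

  # -- Association cascade ------------------------------------------------
  shannon_assoc <- do.call(rbind, lapply(c("ahi", "t90", "odi"), function(ex) {
    do.call(rbind, lapply(c("main", "extended"), function(mod) {
      cv <- covariates[, model_covariates()[[mod]], drop = FALSE]
      cc <- stats::complete.cases(exposures[[ex]], cv)
      fit <- partial_spearman(exposures[[ex]][cc], shannon[cc],
                              cv[cc, , drop = FALSE])
      data.frame(exposure = ex, feature = "shannon", model = mod,
                 rho = fit$rho, p = fit$p, n = fit$n)
    }))
  }))
  write_tsv(shannon_assoc, file.path(out_dir, "shannon_associations.tsv"))
  cascade <- run_cascade(exposures, abundance, covariates, fdr = fdr)
  write_tsv(cascade$results, file.path(out_dir, "associations.tsv"))
  hits <- sort(unique(unlist(cascade$hits[c("t90", "odi")])))
  log_stage("associate: %d species tested, %d T90/ODI hits",
            length(cascade$species), length(hits))
  sens <- if (length(hits))
    sensitivity_suite(cascade, exposures, abundance, covariates) else NULL
  if (!is.null(sens))
    write_tsv(sens, file.path(out_dir, "sensitivity.tsv"))

  # -- Imputed AHI cascade ------------------------------------------------
  imputed <- NULL
  if (impute && anyNA(exposures$ahi)) {
    imputed <- imputed_cascade(exposures, abundance, covariates,
                               species = cascade$species, k = k, m = m,
                               seed = derive_seed(seed, 31L))
    write_tsv(imputed, file.path(out_dir, "imputed_ahi.tsv"))
    log_stage("impute: %d species, m = %d", nrow(imputed), m)
  }

  # -- Heterogeneity by hemoglobin ---------------------------------------
  het <- NULL
  if (length(hits)) {
    strata <- split_by_hemoglobin(covariates)
    het <- heterogeneity_screen(hits, exposures, abundance, covariates,
                                strata, B = bootstrap_B,
                                seed = derive_seed(seed, 41L))
    write_tsv(het, file.path(out_dir, "heterogeneity.tsv"))
    log_stage("heterogeneity: %d rows screened", nrow(het))
  }

  # -- GMM enrichment -----------------------------------------------------
  presence <- annotate_species(cohort$ko_table, cohort$gmm_definitions)
  cov_ext <- covariates[, model_covariates()$extended, drop = FALSE]
  enr <- do.call(rbind, lapply(c("t90", "odi", "ahi"), function(ex) {
    # ranked-p enrichment input: the extended model over ALL tested species
    ext <- association_scan(exposures[[ex]],
                            abundance[, cascade$species, drop = FALSE],
                            cov_ext)
    do.call(rbind, lapply(c("positive", "negative"), function(dr) {
      tab <- withCallingHandlers(
        gmm_enrichment(ext, presence, direction = dr),
        warning = function(w) invokeRestart("muffleWarning"))
      if (nrow(tab)) cbind(exposure = ex, tab) else NULL
    }))
  }))
  if (!is.null(enr))
    write_tsv(enr, file.path(out_dir, "gmm_enrichment.tsv"))

  # -- Co-occurrence ------------------------------------------------------
  network <- NULL
  if (length(hits) >= 2) {
    network <- build_network(presence_matrix(abundance, hits))
    write_tsv(network$pairs, file.path(out_dir, "cooccurrence.tsv"))
    log_stage("cooccur: %d pairs, %d edges", nrow(network$pairs),
              nrow(network$edges))
  }

  # -- Downstream outcomes ------------------------------------------------
  outc <- NULL
  if (length(hits)) {
    outc <- outcome_associations(hits, abundance, cohort$outcomes,
                                 exposures, covariates)
    write_tsv(outc, file.path(out_dir, "outcome_associations.tsv"))
    log_stage("outcomes: %d rows", nrow(outc))
  }

  # -- Manifest -----------------------------------------------------------
  files <- list.files(out_dir, pattern = "\\.tsv$", full.names = TRUE)
  manifest <- list(
    package = as.character(utils::packageVersion("apneabiome")),
    seed = seed, cohort_seed = cohort$config$seed,
    n_participants = nrow(abundance), n_species = ncol(abundance),
    fdr = fdr, n_permutations = n_permutations,
    bootstrap_B = bootstrap_B, imputations = if (impute) m else 0L,
    checksums = as.list(tools::md5sum(files)),
    rows = stats::setNames(
      lapply(files, function(f) length(readLines(f)) - 1L),
      basename(files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(parameters = params, groups = groups,
                 diversity = div_tab, shannon = shannon_assoc,
                 cascade = cascade, sensitivity = sens, imputed = imputed,
                 heterogeneity = het, gmm_enrichment = enr,
                 network = network, outcomes = outc, manifest = manifest))
}
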