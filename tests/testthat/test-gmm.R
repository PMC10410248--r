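test_that("module detection implements the step-coverage rules", {
  g3 <- gmm_definition("GMX01", "three step", list(list("K00001", "K00002",
                                                        "K00003")))
  # 3-step module with 2 of 3 covered: absent (all steps required)
  expect_false(species_has_gmm(c("K00001", "K00002"), g3))
  expect_true(species_has_gmm(c("K00001", "K00002", "K00003"), g3))

  g6 <- gmm_definition("GMX02", "six step",
                       list(lapply(sprintf("K%05d", 1:6), identity)))
  # 4 of 6 covered: present (two-thirds rule)
  expect_true(species_has_gmm(sprintf("K%05d", 1:4), g6))
  expect_false(species_has_gmm(sprintf("K%05d", 1:3), g6))

  # 5 steps: ceiling(10/3) = 4 required
  g5 <- gmm_definition("GMX03", "five step",
                       list(lapply(sprintf("K%05d", 1:5), identity)))
  expect_false(species_has_gmm(sprintf("K%05d", 1:3), g5))
  expect_true(species_has_gmm(sprintf("K%05d", 1:4), g5))

  # alternative path: one fulfilled path suffices
  g2p <- gmm_definition("GMX04", "two paths", list(
    list("K00001", "K00002", "K00003"),
    list("K00010", "K00011", "K00012")))
  expect_true(species_has_gmm(c("K00010", "K00011", "K00012"), g2p))
  expect_false(species_has_gmm(c("K00001", "K00010"), g2p))

  # a step is covered by any of its alternative KOs
  galt <- gmm_definition("GMX05", "alt kos",
                         list(list(c("K00001", "K00009"), "K00002")))
  expect_true(species_has_gmm(c("K00009", "K00002"), galt))

  expect_false(species_has_gmm(character(0), g3))
  expect_error(gmm_definition("bad", "x", list()), "at least one path")
  expect_error(gmm_definition("bad", "x", list(list("notako"))), "K-prefixed")
})

test_that("detection is monotone in the KO set", {
  co <- small_cohort()
  set.seed(5)
  universe <- sprintf("K%05d", 1:300)
  for (g in co$gmm_definitions[1:4]) {
    for (r in 1:10) {
      kos <- sample(universe, sample(10:120, 1))
      extra <- union(kos, sample(universe, 30))
      expect_true(species_has_gmm(kos, g) <= species_has_gmm(extra, g))
    }
  }
})

test_that("annotation matrix equals the element-wise oracle", {
  co <- small_cohort()
  gmms <- co$gmm_definitions
  ko10 <- co$ko_table[co$ko_table$species_id %in%
                        unique(co$ko_table$species_id)[1:10], ]
  pres <- annotate_species(ko10, gmms)
  sets <- split(ko10$ko_id, ko10$species_id)
  for (sp in rownames(pres))
    for (j in seq_along(gmms))
      expect_identical(pres[sp, gmms[[j]]$id],
                       oracle_has_gmm(sets[[sp]], gmms[[j]]))
  # degenerate species
  allko <- data.frame(species_id = "sp_all",
                      ko_id = unique(unlist(lapply(gmms, function(g)
                        unlist(g$paths)))))
  expect_true(all(annotate_species(allko, gmms)))
})

test_that("ko_fraction variant differs from step counting where it should", {
  # 4 steps; step 1 has 3 alternative KOs, others 1 each => 6 KOs total.
  g <- gmm_definition("GMX06", "weighted", list(list(
    c("K00001", "K00002", "K00003"), "K00004", "K00005", "K00006")))
  kos <- c("K00004", "K00005", "K00006")  # 3 of 4 steps, 3 of 6 KOs
  expect_true(species_has_gmm(kos, g, rule = "steps"))     # 3 >= ceil(8/3)
  expect_false(species_has_gmm(kos, g, rule = "ko_fraction"))  # 3 < ceil(4)
})

test_that("enrichment ranks carriers low and agrees with a permutation oracle", {
  set.seed(8)
  n <- 50
  res <- data.frame(feature = sprintf("s%02d", 1:n),
                    rho = runif(n, 0.05, 0.5), p = sort(runif(n)))
  pres <- matrix(FALSE, n, 2, dimnames = list(res$feature, c("GMA", "GMB")))
  pres[1:5, "GMA"] <- TRUE                  # carriers = 5 smallest p
  pres[sample(n, 20), "GMB"] <- TRUE        # random carriers
  enr <- gmm_enrichment(res, pres, "positive")
  expect_lt(enr$p[enr$gmm_id == "GMA"], 0.01)
  expect_gt(enr$score[enr$gmm_id == "GMA"], 2)

  # permutation oracle on the rank-sum of carriers
  r <- rank(res$p)
  w_obs <- sum(r[pres[, "GMA"]])
  set.seed(9)
  w_perm <- replicate(10000, sum(r[sample(n, 5)]))
  p_perm <- mean(w_perm <= w_obs)
  expect_lt(abs(enr$p[enr$gmm_id == "GMA"] - p_perm),
            3 * sqrt(max(p_perm, 1e-4) / 10000) + 0.002)
  # and agreement with the base-R one-sided rank-sum test
  ref <- suppressWarnings(wilcox.test(res$p[pres[, "GMB"]],
                                      res$p[!pres[, "GMB"]],
                                      alternative = "less"))
  expect_equal(enr$p[enr$gmm_id == "GMB"], ref$p.value, tolerance = 0.01)

  # saturated or near-empty modules are skipped
  pres2 <- cbind(pres, GMC = TRUE, GMD = c(TRUE, rep(FALSE, n - 1)))
  warns <- capture_warnings(enr2 <- gmm_enrichment(res, pres2, "positive"))
  expect_true(length(warns) >= 2 && all(grepl("skipped", warns)))
  expect_false(any(c("GMC", "GMD") %in% enr2$gmm_id))
})

test_that("direction stratification selects by coefficient sign", {
  res <- data.frame(feature = c("a", "b", "c", "d", "e", "f", "g", "h"),
                    rho = c(0.2, 0.3, -0.1, 0.25, -0.3, 0.15, 0.1, -0.2),
                    p = c(0.001, 0.002, 0.5, 0.01, 0.9, 0.3, 0.4, 0.05))
  pres <- matrix(c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE), 8, 1,
                 dimnames = list(res$feature, "GM1"))
  enr_pos <- gmm_enrichment(res, pres, "positive", min_carriers = 2L)
  expect_equal(enr_pos$n_carriers, 3L)  # only the rho > 0 carriers counted
  expect_error(gmm_enrichment(res[res$rho > 0, ], pres, "negative"),
               "no species")
})
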