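test_that("default template matches the intended study composition", {
  tpl <- default_template()
  expect_equal(nrow(tpl), 89)
  expect_equal(sum(tpl$at_share), 100, tolerance = 1e-9)
  expect_equal(length(unique(tpl$class)), 12)
  shares <- tapply(tpl$at_share, tpl$class, sum)
  expect_gte(shares[["PC"]], 38)
  expect_lte(shares[["PC"]], 49)
  expect_gte(shares[["PE"]], 14)
  expect_lte(shares[["PE"]], 23)
  expect_gte(shares[["TAG"]], 5)
  expect_lte(shares[["TAG"]], 13)
  # every analyte name is parseable and unique
  expect_false(anyDuplicated(tpl$analyte) > 0)
  expect_silent(parse_lipid_name(tpl$analyte))
})

test_that("planted structure is internally consistent", {
  tpl <- default_template()
  expect_true(all(tpl$response[tpl$block %in% c("pc_poly", "pe_all")] ==
                    "down"))
  expect_true(all(tpl$response[tpl$block %in% c("tag_a", "tag_b")] == "up"))
  expect_true(all(tpl$class[tpl$response == "up"] == "TAG"))
  expect_false(any(tpl$response[tpl$class %in% c("SE", "SG", "ASG")] !=
                     "none"))
})

test_that("the same seed reproduces bit-identical tables", {
  s1 <- simulate_study(sim_config(), seed = 7)
  s2 <- simulate_study(sim_config(), seed = 7)
  expect_identical(s1$dataset$values, s2$dataset$values)
  expect_identical(s1$dataset$meta, s2$dataset$meta)
  s3 <- simulate_study(sim_config(), seed = 8)
  expect_false(identical(s1$dataset$values, s3$dataset$values))
})

test_that("zero noise and unit multipliers reproduce the baseline exactly", {
  cfg <- sim_config(
    genotypes = tibble::tibble(genotype = "G1", depletion = 1, tag_gain = 1),
    noise_cv = 0, qc_cv = 0, year_effect = 1, block_effect = 1)
  sim <- simulate_study(cfg, seed = 1)
  keep <- !sim$dataset$meta$is_qc_pool
  baseline <- unname(cfg$template$at_share / 100 * cfg$total_signal)
  for (i in which(keep)) {
    expect_equal(unname(sim$dataset$values[i, ]), baseline,
                 tolerance = 1e-12)
  }
})

test_that("adding analytes does not perturb the noise of existing ones", {
  base <- simulate_study(sim_config(), seed = 4)
  more <- simulate_study(sim_config(n_below_lod = 3), seed = 4)
  keep <- !base$dataset$meta$is_qc_pool
  common <- colnames(base$dataset$values)
  expect_identical(base$dataset$values[keep, common],
                   more$dataset$values[keep, common])
})

test_that("a planted 18:3 depletion of 0.6 is recovered from the data", {
  cfg <- sim_config(genotypes = tibble::tibble(
    genotype = "G1", depletion = 0.6, tag_gain = 2))
  # the PC 18:3 species share a planted co-occurrence factor, so a single
  # study carries correlated noise; average the recovery over a few seeds
  folds <- ratios <- numeric(5)
  for (k in 1:5) {
    sim <- simulate_study(cfg, seed = 20 + k)
    # the 18:3 pool of PC comes entirely from depleted species, so its
    # HT/AT fold recovers the planted factor directly
    fc <- fatty_acid_fold_change(sim$dataset, "PC")$fold
    folds[k] <- fc$fold[fc$fatty_acid == "18:3"]
    r <- fa_18_3_to_18_2_ratio(sim$dataset)
    ratios[k] <- r$ratio[r$treatment == "HT"] / r$ratio[r$treatment == "AT"]
  }
  expect_equal(mean(folds), 0.6, tolerance = 0.05)
  # the 18:3/18:2 ratio shifts by the depletion corrected for the depleted
  # share of the 18:2 pool (PC 36:5 carries one 18:2 chain); the noise-free
  # expectation comes from a zero-noise run of the same configuration
  cfg0 <- sim_config(genotypes = cfg$genotypes, noise_cv = 0, qc_cv = 0,
                     year_effect = 1, block_effect = 1)
  r0 <- fa_18_3_to_18_2_ratio(simulate_study(cfg0, seed = 1)$dataset)
  expected <- r0$ratio[r0$treatment == "HT"] / r0$ratio[r0$treatment == "AT"]
  expect_lt(expected, 0.75)   # strictly below 1: depletion dominates
  expect_equal(mean(ratios), expected, tolerance = 0.05)
})

test_that("junk analytes are planted to fail the QC filter", {
  cfg <- sim_config(n_below_lod = 2, n_high_cov = 2)
  sim <- simulate_study(cfg, seed = 9)
  expect_equal(ncol(sim$dataset$values), 93)
  res <- qc_filter(sim$dataset)
  expect_equal(ncol(res$dataset$values), 89)
  reasons <- res$report[res$report$verdict == "drop", ]
  expect_setequal(unique(reasons$reason[grepl("^PA\\(40", reasons$analyte)]),
                  "below_LOD")
  expect_setequal(unique(reasons$reason[grepl("^PG\\(40", reasons$analyte)]),
                  "high_CoV")
})

test_that("CT simulation recovers planted folds (exactly without noise)", {
  exact <- simulate_ct_table(sim_config(), seed = 2, bio_sd = 0, tech_sd = 0)
  res <- ddct_fold_change(exact$ct)
  joined <- dplyr::inner_join(res, exact$truth, by = c("genotype", "gene"))
  expect_equal(joined$fold.x, joined$fold.y, tolerance = 1e-10)

  noisy <- simulate_ct_table(sim_config(), seed = 3, bio_sd = 0.1,
                             tech_sd = 0.05)
  resn <- ddct_fold_change(noisy$ct)
  joinedn <- dplyr::inner_join(resn, noisy$truth, by = c("genotype", "gene"))
  planted <- joinedn[joinedn$fold.y != 1, ]
  expect_true(all(abs(planted$fold.x / planted$fold.y - 1) < 0.10))
})

test_that("full-pipeline recovery on a default simulated study", {
  sim <- simulate_study(sim_config(), seed = 2024)
  qc <- qc_filter(sim$dataset)
  pct <- percent_of_total(qc$dataset)

  # (a) PC and PE unsaturation indices drop under HT for every genotype
  for (cl in c("PC", "PE")) {
    idx <- unsaturation_index_class(pct, cl)
    wide <- tidyr::pivot_wider(idx[, c("genotype", "treatment", "index")],
                               names_from = "treatment",
                               values_from = "index")
    expect_true(all(wide$HT < wide$AT))
  }

  # (b) planted heat-responsive analytes dominate the VIP top-10
  m <- fit_plsda(pct)
  top10 <- rank_top_k(m, 10)$analyte
  responsive <- sim$truth$template$analyte[
    sim$truth$template$response != "none"]
  expect_gte(sum(top10 %in% responsive), 8)

  # (c) planted correlation blocks come back as the rho >= 0.90 groups
  rho <- spearman_matrix(pct)
  groups <- extract_groups(rho, 0.90)
  expect_setequal(lapply(groups, sort),
                  lapply(unname(sim$truth$blocks), sort))
})

test_that("stronger 18:3 depletion produces the larger unsaturation drop", {
  cfg <- sim_config(genotypes = tibble::tibble(
    genotype = c("Bailey", "SPT 06-07"),
    depletion = c(0.9, 0.6), tag_gain = c(2, 4)))
  drops <- vapply(1:10, function(seed) {
    sim <- simulate_study(cfg, seed = seed)
    pct <- percent_of_total(sim$dataset)
    idx <- unsaturation_index_class(pct, "PC")
    wide <- tidyr::pivot_wider(idx[, c("genotype", "treatment", "index")],
                               names_from = "treatment",
                               values_from = "index")
    drop <- wide$AT - wide$HT
    drop[wide$genotype == "SPT 06-07"] - drop[wide$genotype == "Bailey"]
  }, numeric(1))
  expect_gte(mean(drops > 0), 0.95)
})
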