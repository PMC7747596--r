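pct_toy <- function(values, analytes, meta = NULL) {
  percent_of_total(toy_dataset(values, analytes, meta))
}

test_that("class composition sums analyte percentages within classes", {
  ds <- pct_toy(matrix(c(30, 20, 50), 1, 3, byrow = TRUE),
                c("PC(34:3)", "PC(34:2)", "TAG(52:3)"), toy_meta("S1"))
  comp <- class_composition(ds, by = "treatment")
  expect_equal(comp$share[comp$class == "PC"], 50)
  expect_equal(comp$share[comp$class == "TAG"], 50)
})

test_that("class shares partition 100 and ignore column order", {
  sim <- simulate_study(sim_config(), seed = 2)
  pct <- percent_of_total(sim$dataset)
  comp <- class_composition(pct)
  sums <- dplyr::summarise(dplyr::group_by(comp, genotype,
                                           treatment),
                           total = sum(share))
  expect_true(all(abs(sums$total - 100) < 1e-9))
  # permuted analyte order gives identical results
  perm <- sample(ncol(pct$values))
  shuffled <- pct
  shuffled$values <- shuffled$values[, perm]
  shuffled$analytes <- shuffled$analytes[perm, ]
  comp2 <- class_composition(shuffled)
  expect_equal(dplyr::arrange(comp2, genotype, treatment,
                              class),
               dplyr::arrange(comp, genotype, treatment,
                              class))
})

test_that("species composition pools classes by the c:d key", {
  ds <- pct_toy(matrix(c(1, 3), 1, 2, byrow = TRUE),
                c("PC(34:3)", "PE(34:3)"), toy_meta("S1"))
  sp <- species_composition(ds, by = "treatment")
  expect_equal(nrow(sp), 1)
  expect_equal(sp$species, "34:3")
  expect_equal(sp$share, 100)

  sim <- simulate_study(sim_config(), seed = 2)
  pct <- percent_of_total(sim$dataset)
  sp2 <- species_composition(pct)
  sums <- dplyr::summarise(dplyr::group_by(sp2, genotype,
                                           treatment),
                           total = sum(share))
  expect_true(all(abs(sums$total - 100) < 1e-9))
  expect_error(species_composition(ds, classes = "TAG"), "no analytes")
})

test_that("dominant diacyl species cover >= 85% under ambient temperature", {
  sim <- simulate_study(sim_config(), seed = 2)
  pct <- percent_of_total(sim$dataset)
  sp <- species_composition(pct)
  at <- sp[sp$treatment == "AT" &
             sp$species %in% c("34:3", "34:2", "36:6", "36:5", "36:4"), ]
  cover <- dplyr::summarise(dplyr::group_by(at, genotype),
                            total = sum(share))
  expect_true(all(cover$total >= 85))
})

test_that("species unsaturation index is double bonds per chain", {
  expect_equal(unsaturation_index_species("PC(36:6)"), 3.0)
  expect_equal(unsaturation_index_species("TAG(18:2/16:0/18:1)"), 1.0)
  expect_equal(unsaturation_index_species("PE(34:0)"), 0.0)
  expect_error(unsaturation_index_species("SG"), "chain-less")
})

test_that("class unsaturation index is the amount-weighted species mean", {
  ds <- toy_dataset(matrix(c(2, 1), 1, 2, byrow = TRUE),
                    c("PC(34:3)", "PC(36:6)"), toy_meta("S1"))
  idx <- unsaturation_index_samples(ds, "PC")
  expect_equal(idx$index, (1.5 * 2 + 3.0 * 1) / 3)   # = 2.0

  # single-species class: index equals the species index
  one <- toy_dataset(matrix(5, 1, 1), "PE(36:5)", toy_meta("S1"))
  expect_equal(unsaturation_index_samples(one, "PE")$index, 2.5)

  # doubling amounts leaves the index unchanged
  ds2 <- ds
  ds2$values <- ds2$values * 2
  expect_equal(unsaturation_index_samples(ds2, "PC")$index, 2.0)
})

test_that("class unsaturation index matches a brute-force oracle and its
           bounds on random datasets", {
  withr::with_seed(41, {
    for (rep in 1:20) {
      analytes <- sample(default_template()$analyte, 12)
      cls <- parse_lipid_name(analytes)$class
      ok <- cls != "SG"
      analytes <- analytes[ok]
      cls <- cls[ok]
      values <- matrix(stats::runif(4 * length(analytes), 0.01, 5), 4)
      colnames(values) <- analytes
      ds <- toy_dataset(values, analytes, toy_meta(paste0("S", 1:4)))
      for (cl in unique(cls)) {
        got <- unsaturation_index_samples(ds, cl)$index
        sel <- which(cls == cl)
        ui <- vapply(analytes[sel], unsaturation_index_species, numeric(1))
        oracle <- apply(values[, sel, drop = FALSE], 1,
                        function(v) sum(v * ui) / sum(v))
        expect_equal(got, unname(oracle), tolerance = 1e-12)
        expect_true(all(got >= 0 & got <= max(ui) + 1e-12))
      }
    }
  })
})

test_that("fatty-acid totals apply occurrence weighting with exclusions", {
  ds <- toy_dataset(matrix(1, 1, 1), "PC(36:6)", toy_meta("S1"))
  ft <- fatty_acid_totals(ds, "PC")
  expect_equal(ft$totals$amount[ft$totals$fatty_acid == "18:3"], 2)
  expect_equal(sum(ft$totals$amount), 2)
  expect_length(ft$excluded, 0)

  amb <- toy_dataset(matrix(1, 1, 1), "PC(36:4)", toy_meta("S1"))
  fta <- fatty_acid_totals(amb, "PC")
  expect_true(all(fta$totals$amount == 0))
  expect_equal(fta$excluded, "PC(36:4)")

  sim <- simulate_study(sim_config(), seed = 1)
  ftt <- fatty_acid_totals(sim$dataset, "TAG")
  expect_equal(ftt$excluded, "TAG(54:5)")
})

test_that("fatty-acid totals agree with per-chain enumeration on random
           assignments", {
  withr::with_seed(13, {
    tpl <- default_template()
    tag <- tpl$analyte[tpl$class == "TAG"]
    values <- matrix(stats::runif(3 * length(tag), 0, 2), 3)
    colnames(values) <- tag
    ds <- toy_dataset(values, tag, toy_meta(paste0("S", 1:3)))
    got <- fatty_acid_totals(ds, "TAG")$totals
    parsed <- parse_lipid_name(tag)
    fas <- c("16:0", "16:1", "18:0", "18:1", "18:2", "18:3")
    for (s in 1:3) {
      for (fa in fas) {
        oracle <- 0
        for (j in seq_along(tag)) {
          ch <- parsed$chains[[j]]
          if (is.null(ch)) next
          cd <- as.integer(strsplit(fa, ":")[[1]])
          oracle <- oracle + values[s, j] *
            sum(ch$carbons == cd[1] & ch$double_bonds == cd[2])
        }
        got_one <- got$amount[got$sample_id == paste0("S", s) &
                                got$fatty_acid == fa]
        expect_equal(got_one, unname(oracle), tolerance = 1e-12)
      }
    }
  })
})

test_that("fatty-acid fold change is 1 for identical profiles and tracks a
           planted 18:3 halving", {
  meta <- dplyr::bind_rows(toy_meta(c("A1", "A2"), treatment = "AT"),
                           toy_meta(c("H1", "H2"), treatment = "HT"))
  meta$replicate <- 1:4
  analytes <- c("PC(34:3)", "PC(36:6)", "PC(36:1)", "PC(34:1)")
  base <- c(2, 1, 1, 1)
  values <- rbind(base, base, base, base)
  colnames(values) <- analytes
  ds <- toy_dataset(values, analytes, meta)
  fc <- fatty_acid_fold_change(ds, "PC")$fold
  expect_true(all(abs(fc$fold[!is.na(fc$fold)] - 1) < 1e-12))

  # halve every 18:3-containing species under HT
  values2 <- values
  values2[3:4, c("PC(34:3)", "PC(36:6)")] <-
    values2[3:4, c("PC(34:3)", "PC(36:6)")] / 2
  ds2 <- toy_dataset(values2, analytes, meta)
  fc2 <- fatty_acid_fold_change(ds2, "PC")$fold
  expect_equal(fc2$fold[fc2$fatty_acid == "18:3"], 0.5)
  expect_equal(fc2$fold[fc2$fatty_acid == "18:0"], 1.0)
  # scale invariance
  ds3 <- ds2
  ds3$values <- ds3$values * 7
  fc3 <- fatty_acid_fold_change(ds3, "PC")$fold
  expect_equal(fc3$fold, fc2$fold, tolerance = 1e-12)
})

test_that("the PC 18:3/18:2 ratio uses occurrence weighting", {
  ds <- toy_dataset(matrix(c(1, 1), 1, 2, byrow = TRUE),
                    c("PC(36:6)", "PC(36:5)"), toy_meta("S1"))
  r <- fa_18_3_to_18_2_ratio(ds, by = "treatment")
  expect_equal(r$ratio, 3.0)   # (2*1 + 1*1) / (1*1)

  no183 <- toy_dataset(matrix(c(1, 1), 1, 2, byrow = TRUE),
                       c("PC(34:1)", "PC(36:1)"), toy_meta("S1"))
  expect_equal(fa_18_3_to_18_2_ratio(no183, by = "treatment")$ratio, NA_real_)

  only_amb <- toy_dataset(matrix(1, 1, 1), "PC(36:4)", toy_meta("S1"))
  expect_true(is.na(fa_18_3_to_18_2_ratio(only_amb,
                                          by = "treatment")$ratio))
})

test_that("zero 18:3 with positive 18:2 gives ratio zero", {
  ds <- toy_dataset(matrix(1, 1, 1), "PC(34:2)", toy_meta("S1"))
  expect_equal(fa_18_3_to_18_2_ratio(ds, by = "treatment")$ratio, 0)
})

test_that("TAG:PC ratio is a per-sample ratio, invariant to normalization", {
  ds <- toy_dataset(matrix(c(20, 40), 1, 2, byrow = TRUE),
                    c("TAG(52:3)", "PC(34:3)"), toy_meta("S1"))
  expect_equal(tag_pc_ratio(ds, by = "treatment")$ratio, 0.5)
  expect_equal(tag_pc_ratio(percent_of_total(ds), by = "treatment")$ratio,
               0.5)
  zero_pc <- toy_dataset(matrix(c(20, 0), 1, 2, byrow = TRUE),
                         c("TAG(52:3)", "PC(34:3)"), toy_meta("S1"))
  expect_error(tag_pc_ratio(zero_pc, by = "treatment"), "S1")
})
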