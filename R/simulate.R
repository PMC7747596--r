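# Seeded synthetic lipidome studies with planted heat effects, co-occurrence
# blocks, QC pools, and CT tables, emulating a 2-year x 2-block x 4-rep
# split-plot field design.

# deterministic substream seed derived from the master seed and a name, so
# that adding analytes does not perturb the noise of existing ones
.substream <- function(seed, name) {
  codes <- utf8ToInt(name)
  h <- 0
  for (cd in codes) h <- (h * 31 + cd) %% 1000000007
  as.integer((as.numeric(seed) %% 97651 * 21503 + h) %% 2147483629) + 1L
}

.template_class <- function(class, species, weights, chains = NULL) {
  stopifnot(abs(sum(weights) - 1) < 1e-9, length(species) == length(weights))
  name <- if (is.null(chains)) {
    ifelse(species == "", class, paste0(class, "(", species, ")"))
  } else {
    chains
  }
  tibble::tibble(name = name, class = class, weight = weights)
}

#' Default synthetic analyte template
#'
#' Eighty-nine analytes across the twelve headgroup classes, with ambient-
#' temperature class shares (PC 43%, PE 18%, TAG 9%, ...) and within-class
#' species weights placing the diacyl species 34:3, 34:2, 36:6, 36:5, 36:4
#' at dominant shares.  TAG, DAG, ASG, and SE analytes carry explicit acyl
#' chains (with `_A`/`_B` variants for isobaric chain sets); `TAG(54:5)` is
#' deliberately left in totals form, so its fatty-acyl composition stays
#' ambiguous.
#'
#' @return Tibble `analyte`, `class`, `at_share` (percent of total signal,
#'   summing to 100), plus the planted-structure annotations `has_18_3`,
#'   `response` (`"down"`/`"up"`/`"none"`), `up_exponent`, and `block`.
#' @export
default_template <- function() {
  class_share <- c(PC = 43, PE = 18, TAG = 9, PG = 5, PI = 5, MGDG = 4,
                   DAG = 4, PA = 3, ASG = 2.5, SG = 2.5, SE = 2, SQDG = 2)
  parts <- list(
    .template_class("PC",
      c("34:4", "34:3", "34:2", "34:1", "36:6", "36:5", "36:4", "36:3",
        "36:2", "36:1", "32:0"),
      c(.02, .26, .25, .015, .11, .16, .12, .02, .02, .015, .01)),
    .template_class("PE",
      c("34:3", "34:2", "34:1", "36:6", "36:5", "36:4", "36:3", "36:2",
        "36:1", "32:0"),
      c(.26, .25, .03, .11, .16, .12, .03, .01, .01, .02)),
    .template_class("PI",
      c("34:3", "34:2", "34:1", "36:6", "36:5", "36:4", "36:2"),
      c(.30, .30, .05, .05, .08, .12, .10)),
    .template_class("PA",
      c("34:3", "34:2", "36:6", "36:5", "36:4", "36:2"),
      c(.28, .30, .08, .12, .14, .08)),
    .template_class("PG",
      c("34:4", "34:3", "34:2", "34:1", "36:6", "36:5", "36:4", "36:2",
        "32:0"),
      c(.10, .25, .23, .10, .08, .10, .07, .05, .02)),
    .template_class("MGDG",
      c("34:6", "34:3", "36:6", "36:5", "36:4", "36:3", "36:2"),
      c(.20, .15, .37, .15, .05, .05, .03)),
    .template_class("SQDG",
      c("34:3", "34:2", "34:1", "36:6", "36:5"),
      c(.30, .25, .10, .20, .15)),
    .template_class("DAG",
      species = rep("", 8),
      weights = c(.20, .20, .10, .12, .13, .10, .10, .05),
      chains = c("DAG(16:0/18:3)", "DAG(16:0/18:2)", "DAG(18:3/18:3)",
                 "DAG(18:2/18:3)", "DAG(18:2/18:2)", "DAG(18:3/18:0)_A",
                 "DAG(18:2/18:1)_B", "DAG(18:1/18:1)")),
    .template_class("TAG",
      species = c(rep("", 12), "54:5", rep("", 5)),
      weights = c(.03, .05, .07, .05, .05, .10, .06, .08, .08, .04, .04,
                  .06, .05, .08, .06, .04, .03, .03),
      chains = c("TAG(16:0/16:0/16:0)", "TAG(16:0/16:0/18:1)",
                 "TAG(18:2/16:0/16:0)", "TAG(16:0/16:0/18:3)",
                 "TAG(18:1/18:1/16:0)", "TAG(18:2/16:0/18:1)",
                 "TAG(18:3/16:0/18:1)_A", "TAG(18:2/18:2/16:0)_B",
                 "TAG(16:0/18:3/18:2)", "TAG(16:0/18:3/18:3)",
                 "TAG(18:1/18:1/18:1)", "TAG(18:1/18:2/18:1)",
                 "TAG(54:5)", "TAG(18:1/18:3/18:2)",
                 "TAG(18:2/18:2/18:3)_A", "TAG(18:1/18:3/18:3)_B",
                 "TAG(18:2/18:3/18:3)", "TAG(18:3/18:3/18:3)")),
    .template_class("ASG", species = rep("", 4),
                    weights = c(.35, .25, .25, .15),
                    chains = c("ASG(16:0)", "ASG(18:1)", "ASG(18:2)",
                               "ASG(18:3)")),
    .template_class("SG", "", 1),
    .template_class("SE", species = rep("", 3),
                    weights = c(.40, .35, .25),
                    chains = c("SE(16:0)", "SE(18:1)", "SE(18:2)"))
  )
  tpl <- dplyr::bind_rows(parts)
  tpl$at_share <- tpl$weight * class_share[tpl$class]
  tpl$weight <- NULL
  stopifnot(nrow(tpl) == 89, abs(sum(tpl$at_share) - 100) < 1e-9)
  parsed <- parse_lipid_name(tpl$name)
  tpl$name <- parsed$name
  # 18:3 content: explicit chains where present; for totals-form diacyl
  # species the canonical chain sets put one or two 18:3 chains in 34:4,
  # 34:3, 34:6, 36:5, and 36:6 (36:4 = 18:2/18:2, 36:3 = 18:2/18:1)
  tpl$has_18_3 <- purrr::map2_lgl(parsed$chains, seq_len(nrow(tpl)),
    function(ch, i) {
      if (!is.null(ch)) {
        any(ch$carbons == 18 & ch$double_bonds == 3)
      } else {
        parsed$class[i] %in% diacyl_classes() &&
          paste0(parsed$total_carbons[i], ":",
                 parsed$total_double_bonds[i]) %in%
            c("34:4", "34:3", "34:6", "36:5", "36:6")
      }
    })
  # planted co-occurrence blocks (shared latent replicate factor)
  blocks <- list(
    pc_poly = c("PC(34:3)", "PC(36:5)", "PC(36:6)"),
    pe_all = c("PE(34:3)", "PE(34:2)", "PE(36:6)", "PE(36:5)", "PE(36:4)"),
    tag_a = c("TAG(18:2/16:0/18:1)", "TAG(18:2/18:2/16:0)_B",
              "TAG(16:0/18:3/18:2)", "TAG(18:1/18:2/18:1)",
              "TAG(18:1/18:3/18:2)", "TAG(18:2/16:0/16:0)"),
    tag_b = c("TAG(18:2/18:2/18:3)_A", "TAG(18:1/18:3/18:3)_B",
              "TAG(18:3/16:0/18:1)_A", "TAG(18:2/18:3/18:3)",
              "TAG(16:0/18:3/18:3)", "TAG(18:1/18:1/16:0)")
  )
  stopifnot(all(unlist(blocks) %in% tpl$name))
  tpl$block <- NA_character_
  for (b in names(blocks)) tpl$block[tpl$name %in% blocks[[b]]] <- b
  # heat response: all 18:3-containing membrane (non-TAG, non-sterol)
  # species go down, the whole PE block goes down with them (coordinated
  # headgroup-level remodeling); TAG species go up, strongly in block A,
  # with a damped response in block B, weakly elsewhere, and not at all for
  # the fully saturated and fully tri-unsaturated extremes
  tpl$response <- "none"
  tpl$response[tpl$has_18_3 &
                 tpl$class %in% diacyl_classes()] <- "down"
  tpl$response[!is.na(tpl$block) & tpl$block == "pe_all"] <- "down"
  tpl$up_exponent <- 0
  is_tag <- tpl$class == "TAG"
  tpl$up_exponent[is_tag] <- 0.25
  tpl$up_exponent[is_tag & !is.na(tpl$block) & tpl$block == "tag_a"] <- 1
  tpl$up_exponent[is_tag & !is.na(tpl$block) & tpl$block == "tag_b"] <- 0.45
  tpl$up_exponent[tpl$name %in% c("TAG(16:0/16:0/16:0)",
                                  "TAG(18:3/18:3/18:3)")] <- 0
  tpl$response[is_tag & tpl$up_exponent > 0] <- "up"
  dplyr::select(tpl, analyte = "name", "class", "at_share", "has_18_3",
                "response", "up_exponent", "block")
}

#' Configuration of a synthetic study
#'
#' Defaults emulate a two-season field experiment: 2 years x 2 blocks x 4
#' replications per genotype x treatment cell, three genotypes spanning the
#' heat-tolerance range via their 18:3-depletion factor (HT multiplier on
#' 18:3-containing membrane species; tolerant genotypes deplete more) and
#' TAG gain, multiplicative lognormal replicate noise (CoV 0.2
#' experimental, 0.1 QC pool), and year/block effects acting as pure
#' per-sample scale factors.
#'
#' @param genotypes Tibble with `genotype`, `depletion` (HT multiplier on
#'   18:3 membrane species, in (0, 1] for a decrease), `tag_gain` (HT
#'   multiplier on the strong-response TAG block).
#' @param years Calendar years (length >= 1).
#' @param blocks_per_year,reps Integers.
#' @param noise_cv,qc_cv Lognormal coefficients of variation of experimental
#'   and QC-pool replicates.
#' @param qc_pool_n QC-pool injections per year.
#' @param block_share Fraction of replicate noise variance shared within a
#'   planted co-occurrence block (default 0.95).
#' @param total_signal Total normalized signal per sample (signal units).
#' @param year_effect,block_effect Per-sample scale factors (recycled).
#' @param n_below_lod,n_high_cov Number of junk analytes planted below the
#'   detection limit / with excessive QC variability, to exercise QC
#'   filtering (default 0: the 89 template analytes all pass).
#' @param template Analyte template, see [default_template()].
#' @return A `sim_config` list.
#' @export
sim_config <- function(genotypes = NULL,
                       years = c(2018, 2019),
                       blocks_per_year = 2, reps = 4,
                       noise_cv = 0.2, qc_cv = 0.1, qc_pool_n = 4,
                       block_share = 0.95, total_signal = 2,
                       year_effect = c(1, 1.08),
                       block_effect = c(0.96, 1.04),
                       n_below_lod = 0, n_high_cov = 0,
                       template = default_template()) {
  if (is.null(genotypes)) {
    genotypes <- tibble::tibble(
      genotype = c("Bailey", "Georgia 12Y", "SPT 06-07"),
      depletion = c(0.85, 0.70, 0.55),
      tag_gain = c(2.0, 3.0, 4.0)
    )
  }
  genotypes <- tibble::as_tibble(genotypes)
  stopifnot(all(c("genotype", "depletion", "tag_gain") %in%
                  names(genotypes)),
            all(genotypes$depletion > 0), all(genotypes$tag_gain > 0),
            blocks_per_year >= 1, reps >= 1, noise_cv >= 0, qc_cv >= 0,
            qc_pool_n >= 2, block_share >= 0, block_share <= 1,
            total_signal > 0,
            abs(sum(template$at_share) - 100) < 1e-6)
  structure(
    list(genotypes = genotypes, years = years,
         blocks_per_year = blocks_per_year, reps = reps,
         noise_cv = noise_cv, qc_cv = qc_cv, qc_pool_n = qc_pool_n,
         block_share = block_share, total_signal = total_signal,
         year_effect = rep_len(year_effect, length(years)),
         block_effect = rep_len(block_effect, blocks_per_year),
         n_below_lod = n_below_lod, n_high_cov = n_high_cov,
         template = template),
    class = "sim_config"
  )
}

.ht_multiplier <- function(template, genotypes) {
  tidyr::crossing(genotypes, analyte = template$analyte) |>
    dplyr::left_join(template, by = "analyte") |>
    dplyr::mutate(ht_multiplier = dplyr::case_when(
      .data$response == "down" ~ .data$depletion,
      .data$response == "up" ~ .data$tag_gain^.data$up_exponent,
      TRUE ~ 1
    )) |>
    dplyr::select("genotype", "analyte", "ht_multiplier")
}

.junk_analytes <- function(config) {
  junk <- tibble::tibble(analyte = character(0), kind = character(0))
  if (config$n_below_lod > 0) {
    junk <- dplyr::bind_rows(junk, tibble::tibble(
      analyte = sprintf("PA(40:%d)", seq_len(config$n_below_lod)),
      kind = "below_lod"))
  }
  if (config$n_high_cov > 0) {
    junk <- dplyr::bind_rows(junk, tibble::tibble(
      analyte = sprintf("PG(40:%d)", seq_len(config$n_high_cov)),
      kind = "high_cov"))
  }
  junk
}

#' Simulate a complete synthetic study
#'
#' Per-sample analyte values are baseline x treatment multiplier (genotype-
#' specific 18:3 depletion / TAG gain under HT) x year and block scale
#' factors x multiplicative lognormal noise; analytes of a planted
#' co-occurrence block share `block_share` of their noise variance through a
#' per-sample latent factor.  QC-pool injections are drawn around each
#' year's grand mean with the QC CoV.  Every random draw comes from a named
#' substream of the master seed, so the same seed gives bit-identical
#' output and adding analytes does not perturb existing ones.
#'
#' @param config A [sim_config()].
#' @param seed Master integer seed.
#' @return List with `dataset` (a `lipid_dataset` in signal units, QC-pool
#'   rows flagged in the metadata) and `truth` (template, per-genotype HT
#'   multipliers, planted block membership, junk analytes).
#' @export
simulate_study <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  tpl <- config$template
  junk <- .junk_analytes(config)
  meta <- tidyr::expand_grid(
    genotype = config$genotypes$genotype,
    treatment = c("AT", "HT"),
    year = config$years,
    block = seq_len(config$blocks_per_year),
    replicate = seq_len(config$reps)
  )
  meta$sample_id <- sprintf("%s_%s_%d_B%d_R%d",
                            gsub("[^A-Za-z0-9]", "", meta$genotype),
                            meta$treatment, meta$year, meta$block,
                            meta$replicate)
  meta$is_qc_pool <- FALSE
  n <- nrow(meta)
  sigma <- sqrt(log(1 + config$noise_cv^2))
  mult <- .ht_multiplier(tpl, config$genotypes)
  year_fac <- config$year_effect[match(meta$year, config$years)]
  block_fac <- config$block_effect[meta$block]
  # shared latent factor per planted block
  block_names <- unique(stats::na.omit(tpl$block))
  latent <- purrr::map(block_names, function(b) {
    withr::with_seed(.substream(seed, paste0("latent:", b)),
                     stats::rnorm(n))
  })
  names(latent) <- block_names
  analytes <- c(tpl$analyte, junk$analyte)
  values <- matrix(0, n, length(analytes),
                   dimnames = list(meta$sample_id, analytes))
  for (j in seq_len(nrow(tpl))) {
    a <- tpl$analyte[j]
    base <- tpl$at_share[j] / 100 * config$total_signal
    m <- mult$ht_multiplier[mult$analyte == a]
    m <- m[match(meta$genotype, config$genotypes$genotype)]
    m[meta$treatment == "AT"] <- 1
    z <- withr::with_seed(.substream(seed, paste0("noise:", a)),
                          stats::rnorm(n))
    noise <- if (!is.na(tpl$block[j])) {
      sqrt(config$block_share) * latent[[tpl$block[j]]] +
        sqrt(1 - config$block_share) * z
    } else {
      z
    }
    values[, j] <- base * m * year_fac * block_fac * exp(sigma * noise)
  }
  if (nrow(junk) > 0) {
    for (jj in seq_len(nrow(junk))) {
      a <- junk$analyte[jj]
      base <- if (junk$kind[jj] == "below_lod") 1e-6 else
        0.001 * config$total_signal
      z <- withr::with_seed(.substream(seed, paste0("noise:", a)),
                            stats::rnorm(n))
      values[, nrow(tpl) + jj] <- base * exp(sigma * z)
    }
  }
  # QC pool: per year, injections drawn around that year's grand mean
  qc_sigma <- sqrt(log(1 + config$qc_cv^2))
  qc_rows <- purrr::map(config$years, function(yr) {
    grand <- colMeans(values[meta$year == yr, , drop = FALSE])
    z <- withr::with_seed(
      .substream(seed, paste0("qc:", yr)),
      matrix(stats::rnorm(config$qc_pool_n * length(analytes)),
             config$qc_pool_n))
    s <- rep(qc_sigma, length(analytes))
    if (nrow(junk) > 0) {
      s_per <- ifelse(c(rep(FALSE, nrow(tpl)), junk$kind == "high_cov"),
                      sqrt(log(1 + 0.6^2)), qc_sigma)
      s <- s_per
    }
    sweep(exp(sweep(z, 2, s, "*")), 2, grand, "*")
  })
  qc_values <- do.call(rbind, qc_rows)
  qc_meta <- tidyr::expand_grid(year = config$years,
                                replicate = seq_len(config$qc_pool_n))
  qc_meta <- tibble::tibble(
    sample_id = sprintf("QC_%d_%d", qc_meta$year, qc_meta$replicate),
    genotype = NA_character_, treatment = NA_character_,
    year = qc_meta$year, block = NA_integer_,
    replicate = qc_meta$replicate, is_qc_pool = TRUE
  )
  rownames(qc_values) <- qc_meta$sample_id
  all_values <- rbind(values, qc_values)
  all_meta <- dplyr::bind_rows(
    meta[, c("sample_id", "genotype", "treatment", "year", "block",
             "replicate", "is_qc_pool")],
    qc_meta
  )
  ds <- lipid_dataset(all_values, all_meta, unit = "signal_per_mg_dw")
  blocks <- split(tpl$analyte[!is.na(tpl$block)],
                  tpl$block[!is.na(tpl$block)])
  truth <- list(template = tpl, multipliers = mult, blocks = blocks,
                junk = junk, seed = seed)
  list(dataset = ds, truth = truth)
}

#' Default planted expression fold changes
#'
#' Genotype x gene fold table used by [simulate_ct_table()]: one oleate-
#' desaturase induction for the susceptible genotype, an omega-3 desaturase
#' (FAD3-2) induction for one tolerant genotype and a reduction for the
#' other, all other genes unchanged.
#'
#' @param genotypes Character vector of genotype names.
#' @return Tibble `genotype`, `gene`, `fold`.
#' @export
default_ct_folds <- function(genotypes = c("Bailey", "Georgia 12Y",
                                           "SPT 06-07")) {
  genes <- c("FAD2-1", "FAD2-2", "FAD3-1", "FAD3-2")
  folds <- tidyr::expand_grid(genotype = genotypes, gene = genes)
  folds$fold <- 1
  folds$fold[folds$genotype == "Bailey" & folds$gene == "FAD2-2"] <- 3.9
  folds$fold[folds$genotype == "Georgia 12Y" & folds$gene == "FAD2-1"] <- 3.2
  folds$fold[folds$genotype == "Georgia 12Y" & folds$gene == "FAD3-2"] <- 1.8
  folds$fold[folds$genotype == "SPT 06-07" & folds$gene == "FAD3-2"] <- 1 / 1.7
  folds
}

#' Simulate a CT (qPCR cycle-threshold) table
#'
#' Plants the given per-genotype fold changes as shifts of the target-gene
#' dCT under HT, with additive biological- and technical-replicate noise, so
#' that [ddct_fold_change()] recovers the planted fold.
#'
#' @param config A [sim_config()] (its genotypes define the table) or a
#'   character vector of genotypes.
#' @param seed Master integer seed.
#' @param folds Planted folds, see [default_ct_folds()].
#' @param bio_reps,tech_reps Replicate counts (default 3 and 2).
#' @param bio_sd,tech_sd Additive CT noise (cycles).
#' @param reference Reference gene name.
#' @return List with `ct` (a CT table as consumed by [ddct_fold_change()])
#'   and `truth` (the planted folds).
#' @export
simulate_ct_table <- function(config = sim_config(), seed = 1,
                              folds = NULL, bio_reps = 3, tech_reps = 2,
                              bio_sd = 0.12, tech_sd = 0.08,
                              reference = "Actin-7") {
  genotypes <- if (inherits(config, "sim_config")) {
    config$genotypes$genotype
  } else {
    as.character(config)
  }
  if (is.null(folds)) folds <- default_ct_folds(genotypes)
  stopifnot(all(folds$fold > 0))
  genes <- unique(folds$gene)
  grid <- tidyr::expand_grid(
    genotype = genotypes, treatment = c("AT", "HT"),
    biological_rep = seq_len(bio_reps), technical_rep = seq_len(tech_reps),
    gene = c(reference, genes)
  )
  grid <- dplyr::left_join(grid, folds, by = c("genotype", "gene"))
  base_dct <- 4   # target genes sit ~4 cycles above the reference at AT
  grid$mu <- ifelse(
    grid$gene == reference, 20,
    20 + base_dct -
      ifelse(grid$treatment == "HT", log2(grid$fold), 0)
  )
  key_bio <- paste(grid$genotype, grid$treatment, grid$biological_rep,
                   grid$gene)
  ub <- unique(key_bio)
  e_bio <- withr::with_seed(.substream(seed, "ct:bio"),
                            stats::rnorm(length(ub), sd = bio_sd))
  e_tech <- withr::with_seed(.substream(seed, "ct:tech"),
                             stats::rnorm(nrow(grid), sd = tech_sd))
  grid$ct <- grid$mu + e_bio[match(key_bio, ub)] + e_tech
  ct <- dplyr::select(grid, "genotype", "treatment", "biological_rep",
                      "technical_rep", "gene", "ct")
  list(ct = ct, truth = folds)
}
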