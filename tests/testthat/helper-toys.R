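# Small in-code fixtures shared across test files.

toy_meta <- function(sample_ids, genotype = "G1", treatment = "AT",
                     year = 2018, block = 1, is_qc_pool = FALSE) {
  tibble::tibble(
    sample_id = sample_ids,
    genotype = rep_len(genotype, length(sample_ids)),
    treatment = rep_len(treatment, length(sample_ids)),
    year = rep_len(year, length(sample_ids)),
    block = rep_len(block, length(sample_ids)),
    replicate = seq_along(sample_ids),
    is_qc_pool = rep_len(is_qc_pool, length(sample_ids))
  )
}

toy_dataset <- function(values, analytes, meta = NULL,
                        unit = "signal_per_mg_dw") {
  values <- matrix(values, ncol = length(analytes),
                   dimnames = list(NULL, analytes))
  if (is.null(meta)) {
    meta <- toy_meta(paste0("S", seq_len(nrow(values))))
  }
  rownames(values) <- meta$sample_id
  lipid_dataset(values, meta, unit = unit)
}

# balanced two-treatment design for one or more genotypes
factorial_meta <- function(genotypes = c("G1", "G2"), years = c(2018, 2019),
                           blocks = 2, reps = 2) {
  meta <- tidyr::expand_grid(genotype = genotypes,
                             treatment = c("AT", "HT"),
                             year = years, block = seq_len(blocks),
                             replicate = seq_len(reps))
  meta$sample_id <- sprintf("%s_%s_%d_%d_%d", meta$genotype, meta$treatment,
                            meta$year, meta$block, meta$replicate)
  meta$is_qc_pool <- FALSE
  meta[, c("sample_id", "genotype", "treatment", "year", "block",
           "replicate", "is_qc_pool")]
}

# names of every analyte style appearing in the study's figures
figure_analyte_names <- function() {
  c("PC(34:3)", "PC(36:6)", "PC(36:5)", "PE(34:3)", "PE(34:2)", "PI(34:2)",
    "MGDG(36:6)", "SQDG(34:3)", "PG(34:4)", "PA(34:2)", "SG", "SE(18:1)",
    "ASG(16:0)", "DAG(36:3)_A", "DAG(36:3)_B", "DAG(18:3/18:0)",
    "TAG(18:2/16:0/18:1)", "TAG(52:4)_A", "TAG(54:7)_B",
    "TAG(18:3/18:3/18:3)", "TAG(54:5)")
}

rand_rho <- function(p, seed) {
  withr::local_seed(seed)
  x <- matrix(stats::rnorm(12 * p), 12, p,
              dimnames = list(NULL, paste0("a", seq_len(p))))
  suppressWarnings(stats::cor(x, method = "spearman"))
}

# naive agglomeration: at each step join the two clusters with the smallest
# minimum pairwise distance
single_linkage_oracle <- function(d) {
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    bd <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        dij <- min(d[clusters[[i]], clusters[[j]]])
        if (dij < bd) {
          bd <- dij
          best <- c(i, j)
        }
      }
    }
    heights <- c(heights, bd)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  sort(heights)
}

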