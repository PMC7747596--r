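# Descriptive lipidome metrics: class/species composition, unsaturation
# indices, fatty-acid decomposition and fold changes, ratio metrics.

.grouped_samples <- function(ds, by) {
  meta <- ds$meta[!ds$meta$is_qc_pool, ]
  bad <- setdiff(by, names(meta))
  if (length(bad) > 0) {
    stop("grouping column(s) not in metadata: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  meta
}

.long_values <- function(ds, by) {
  long <- tidy(ds)
  long <- long[!long$is_qc_pool, ]
  dplyr::select(long, dplyr::all_of(c("sample_id", by)),
                "analyte", "class", "value")
}

#' Headgroup-class composition
#'
#' Sums analyte percentages within each headgroup class per sample, then
#' averages over the cells of the grouping.
#'
#' @param ds A `lipid_dataset` in percent-of-total units.
#' @param by Character vector of metadata columns defining the grouping cells
#'   (default genotype x treatment).
#' @return Tibble with the grouping columns, `class`, and `share` (percent of
#'   total signal; shares sum to 100 within each cell).
#' @export
class_composition <- function(ds, by = c("genotype", "treatment")) {
  stopifnot(inherits(ds, "lipid_dataset"))
  if (ds$unit != "percent_of_total") {
    stop("class_composition requires percent_of_total units", call. = FALSE)
  }
  .grouped_samples(ds, by)
  long <- .long_values(ds, by)
  per_sample <- dplyr::summarise(
    dplyr::group_by(long, dplyr::across(dplyr::all_of(
      c("sample_id", by, "class")))),
    share = sum(.data$value), .groups = "drop"
  )
  out <- dplyr::summarise(
    dplyr::group_by(per_sample, dplyr::across(dplyr::all_of(c(by, "class")))),
    share = mean(.data$share), n = dplyr::n(), .groups = "drop"
  )
  if (any(out$n == 0)) stop("empty grouping cell", call. = FALSE)
  dplyr::select(out, -"n")
}

#' Structural glycerolipid classes
#'
#' Default class set for molecular-species composition: the diacyl
#' membrane-forming glycerolipids plus DAG; TAG and the sterol lipids are
#' excluded.
#'
#' @return Character vector.
#' @export
structural_glycerolipid_classes <- function() {
  c("PC", "PE", "PI", "PA", "PG", "MGDG", "SQDG", "DAG")
}

#' Molecular-species composition of selected classes
#'
#' Analytes of the selected classes are pooled by their total acyl carbons :
#' total double bonds key and expressed as percent of the pooled total per
#' sample, then averaged over grouping cells.
#'
#' @inheritParams class_composition
#' @param classes Class set to pool (default
#'   [structural_glycerolipid_classes()]).
#' @return Tibble with the grouping columns, `species` (the `c:d` key), and
#'   `share` (percent of the selected-class total).
#' @export
species_composition <- function(ds,
                                classes = structural_glycerolipid_classes(),
                                by = c("genotype", "treatment")) {
  stopifnot(inherits(ds, "lipid_dataset"), length(classes) > 0)
  if (ds$unit != "percent_of_total") {
    stop("species_composition requires percent_of_total units",
         call. = FALSE)
  }
  sel <- ds$analytes$class %in% classes
  if (!any(sel)) {
    stop("class set selects no analytes: ",
         paste(classes, collapse = ", "), call. = FALSE)
  }
  key <- paste0(ds$analytes$total_carbons, ":",
                ds$analytes$total_double_bonds)[sel]
  long <- .long_values(ds, by)
  long <- long[long$class %in% classes, ]
  long$species <- key[match(long$analyte, ds$analytes$name[sel])]
  per_sample <- dplyr::summarise(
    dplyr::group_by(long, dplyr::across(dplyr::all_of(
      c("sample_id", by, "species")))),
    value = sum(.data$value), .groups = "drop_last"
  )
  per_sample <- dplyr::mutate(per_sample,
                              share = 100 * .data$value / sum(.data$value))
  dplyr::summarise(
    dplyr::group_by(dplyr::ungroup(per_sample),
                    dplyr::across(dplyr::all_of(c(by, "species")))),
    share = mean(.data$share), .groups = "drop"
  )
}

#' Unsaturation index of a lipid molecular species
#'
#' The average number of carbon-carbon double bonds per acyl chain: total
#' double bonds divided by the number of acyl chains.
#'
#' @param x Character vector of lipid names or a parsed species tibble.
#' @return Numeric vector.
#' @examples
#' unsaturation_index_species("PC(36:6)")   # 3
#' @export
unsaturation_index_species <- function(x) {
  species <- .as_species(x)
  nc <- chain_count(species)
  if (any(nc == 0L)) {
    stop("unsaturation index undefined for chain-less species: ",
         paste(species$name[nc == 0L], collapse = ", "), call. = FALSE)
  }
  species$total_double_bonds / nc
}

#' Amount-weighted unsaturation index of a headgroup class
#'
#' Per sample, the sum over the class's species of (species unsaturation
#' index x species amount) divided by the class total amount; then averaged
#' over grouping cells.
#'
#' @inheritParams class_composition
#' @param class Headgroup class (single string).
#' @return Tibble with grouping columns, `class`, `index` (cell mean of the
#'   per-sample index), `se`, and `n`.  A sample with zero class total
#'   contributes a flagged missing value, not a silent zero.
#' @export
unsaturation_index_class <- function(ds, class,
                                     by = c("genotype", "treatment")) {
  stopifnot(inherits(ds, "lipid_dataset"), length(class) == 1L)
  idx <- unsaturation_index_samples(ds, class)
  meta <- .grouped_samples(ds, by)
  joined <- dplyr::left_join(meta, idx, by = "sample_id")
  out <- dplyr::summarise(
    dplyr::group_by(joined, dplyr::across(dplyr::all_of(by))),
    .idx_mean = mean(.data$index[!is.na(.data$index)]),
    se = stats::sd(.data$index[!is.na(.data$index)]) /
      sqrt(sum(!is.na(.data$index))),
    n = sum(!is.na(.data$index)), .groups = "drop"
  )
  out <- dplyr::rename(out, index = ".idx_mean")
  dplyr::bind_cols(tibble::tibble(class = class), out)[
    , c(by, "class", "index", "se", "n")]
}

#' Per-sample unsaturation index of a class
#'
#' @param ds A `lipid_dataset` (any unit; the index is amount-scale
#'   invariant).
#' @param class Headgroup class.
#' @return Tibble `sample_id`, `index` (`NA` where the class total is zero).
#' @export
unsaturation_index_samples <- function(ds, class) {
  stopifnot(inherits(ds, "lipid_dataset"))
  sel <- ds$analytes$class == class
  if (!any(sel)) stop("no analytes of class ", class, call. = FALSE)
  ui <- unsaturation_index_species(ds$analytes[sel, ])
  amounts <- ds$values[, sel, drop = FALSE]
  totals <- unname(rowSums(amounts))
  index <- as.vector(amounts %*% ui) / totals
  index[totals <= 0] <- NA_real_
  tibble::tibble(sample_id = rownames(ds$values), index = index)
}

#' Occurrence-weighted fatty-acid totals for one class
#'
#' For each sample and fatty acid, the sum over the class's
#' unambiguously-assigned species of (species amount x number of occurrences
#' of the fatty acid in that species).  Species whose chains are neither
#' explicit in the name nor covered by the assignment map contribute nothing
#' and are listed in the exclusion log.
#'
#' @param ds A `lipid_dataset`.
#' @param class Headgroup class.
#' @param fatty_acids Fatty acids to tabulate, as `"c:d"` strings.
#' @param assignment Assignment map, see [default_fa_assignments()].
#' @return List with `totals` (tibble `sample_id`, `fatty_acid`, `amount`)
#'   and `excluded` (character vector of unassigned analytes).
#' @export
fatty_acid_totals <- function(ds, class,
                              fatty_acids = c("16:0", "16:1", "18:0",
                                              "18:1", "18:2", "18:3"),
                              assignment = default_fa_assignments()) {
  stopifnot(inherits(ds, "lipid_dataset"))
  sel <- which(ds$analytes$class == class)
  chains <- purrr::map(sel, ~ .species_chains(ds$analytes[.x, ], assignment))
  assigned <- !purrr::map_lgl(chains, is.null)
  excluded <- ds$analytes$name[sel][!assigned]
  # occurrence matrix: analyte x fatty acid
  occ <- vapply(fatty_acids, function(fa) {
    target <- .parse_chain_tokens(fa, fa)
    purrr::map_dbl(chains, function(ch) {
      if (is.null(ch)) 0 else
        sum(ch$carbons == target$carbons &
              ch$double_bonds == target$double_bonds)
    })
  }, numeric(length(sel)))
  occ <- matrix(occ, nrow = length(sel),
                dimnames = list(NULL, fatty_acids))
  totals_mat <- ds$values[, sel, drop = FALSE] %*% occ
  totals <- tibble::as_tibble(totals_mat)
  totals$sample_id <- rownames(ds$values)
  totals <- tidyr::pivot_longer(totals, -"sample_id",
                                names_to = "fatty_acid",
                                values_to = "amount")
  list(totals = totals, excluded = excluded)
}

#' Fatty-acid fold change between treatments
#'
#' Per grouping cell (default genotype) and fatty acid: the occurrence-
#' weighted sum averaged over the treatment's samples, taken as
#' treatment / calibrator (HT/AT).
#'
#' @inheritParams fatty_acid_totals
#' @param by Metadata column(s) defining the cells (default `"genotype"`).
#' @param treatment,calibrator Treatment labels of numerator and denominator.
#' @return List with `fold` (tibble with the cell columns, `fatty_acid`,
#'   `fold`; `NA` flags an undefined ratio with zero calibrator amount) and
#'   `excluded` (unassigned analytes).
#' @export
fatty_acid_fold_change <- function(ds, class, by = "genotype",
                                   treatment = "HT", calibrator = "AT",
                                   fatty_acids = c("16:0", "16:1", "18:0",
                                                   "18:1", "18:2", "18:3"),
                                   assignment = default_fa_assignments()) {
  ft <- fatty_acid_totals(ds, class, fatty_acids, assignment)
  meta <- .grouped_samples(ds, c(by, "treatment"))
  joined <- dplyr::inner_join(ft$totals, meta, by = "sample_id")
  means <- dplyr::summarise(
    dplyr::group_by(joined, dplyr::across(dplyr::all_of(
      c(by, "treatment", "fatty_acid")))),
    amount = mean(.data$amount), .groups = "drop"
  )
  wide <- tidyr::pivot_wider(means, names_from = "treatment",
                             values_from = "amount")
  if (!all(c(treatment, calibrator) %in% names(wide))) {
    stop("both ", treatment, " and ", calibrator,
         " samples are required", call. = FALSE)
  }
  wide$fold <- ifelse(wide[[calibrator]] > 0,
                      wide[[treatment]] / wide[[calibrator]], NA_real_)
  list(fold = dplyr::select(wide, dplyr::all_of(c(by, "fatty_acid", "fold"))),
       excluded = ft$excluded)
}

#' 18:3 / 18:2 ratio within a class
#'
#' Per sample, occurrence-weighted 18:3 amount over 18:2 amount in the given
#' class (default PC), then averaged per grouping cell (mean of per-sample
#' ratios).
#'
#' @inheritParams fatty_acid_totals
#' @param by Grouping columns.
#' @return Tibble with the grouping columns, `ratio`, `se`, `n`.  Cells are
#'   `NA` when no sample has positive 18:2 amount.
#' @export
fa_18_3_to_18_2_ratio <- function(ds, class = "PC",
                                  by = c("genotype", "treatment"),
                                  assignment = default_fa_assignments()) {
  ft <- fatty_acid_totals(ds, class, fatty_acids = c("18:2", "18:3"),
                          assignment = assignment)
  wide <- tidyr::pivot_wider(ft$totals, names_from = "fatty_acid",
                             values_from = "amount")
  wide$ratio <- ifelse(wide[["18:2"]] > 0,
                       wide[["18:3"]] / wide[["18:2"]], NA_real_)
  meta <- .grouped_samples(ds, by)
  joined <- dplyr::inner_join(meta, wide, by = "sample_id")
  dplyr::summarise(
    dplyr::group_by(joined, dplyr::across(dplyr::all_of(by))),
    se = stats::sd(.data$ratio[!is.na(.data$ratio)]) /
      sqrt(sum(!is.na(.data$ratio))),
    n = sum(!is.na(.data$ratio)),
    ratio = mean(.data$ratio[!is.na(.data$ratio)]), .groups = "drop"
  )[, c(by, "ratio", "se", "n")]
}

#' TAG : PC signal ratio
#'
#' Per sample, the summed TAG signal over the summed PC signal; then averaged
#' per grouping cell (mean of per-sample ratios).  Invariant under
#' percent-of-total re-normalization.
#'
#' @inheritParams class_composition
#' @return Tibble with the grouping columns, `ratio`, `se`, `n`.
#' @export
tag_pc_ratio <- function(ds, by = c("genotype", "treatment")) {
  stopifnot(inherits(ds, "lipid_dataset"))
  meta <- .grouped_samples(ds, by)
  tag <- rowSums(ds$values[, ds$analytes$class == "TAG", drop = FALSE])
  pc <- rowSums(ds$values[, ds$analytes$class == "PC", drop = FALSE])
  keep <- rownames(ds$values) %in% meta$sample_id
  if (any(pc[keep] <= 0)) {
    stop("zero PC total for sample(s): ",
         paste(rownames(ds$values)[keep & pc <= 0], collapse = ", "),
         call. = FALSE)
  }
  per_sample <- tibble::tibble(sample_id = rownames(ds$values),
                               ratio = tag / pc)
  joined <- dplyr::inner_join(meta, per_sample, by = "sample_id")
  dplyr::summarise(
    dplyr::group_by(joined, dplyr::across(dplyr::all_of(by))),
    se = stats::sd(.data$ratio) / sqrt(dplyr::n()),
    ratio = mean(.data$ratio),
    n = dplyr::n(), .groups = "drop"
  )[, c(by, "ratio", "se", "n")]
}
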