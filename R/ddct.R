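# Delta-delta-Ct relative expression: target normalized to a reference gene,
# heat treatment calibrated against ambient, fold = 2^-DDCT (amplification
# efficiency fixed at 2), with a fold-threshold direction call.

#' Delta-delta-Ct fold change of target genes
#'
#' Per biological replicate, technical replicates are averaged first and
#' `dCT = CT_target - CT_reference`; per treatment the biological-replicate
#' dCT values are averaged; `ddCT = mean dCT(treatment) - mean
#' dCT(calibrator)` and `fold = 2^-ddCT`.  A plate-wide shift of all CT
#' values leaves every fold unchanged, and swapping the two treatments
#' inverts every fold.
#'
#' @param ct Tibble with columns `genotype`, `treatment`, `biological_rep`,
#'   `technical_rep`, `gene`, `ct` (cycles, must be positive).
#' @param target Gene(s) to quantify; default all genes except the reference.
#' @param reference Reference (housekeeping) gene, default `"Actin-7"`.
#' @param treatment,calibrator Treatment labels; fold is
#'   treatment-vs-calibrator (default HT vs AT).
#' @param threshold Fold threshold for the direction call (default 1.5).
#' @return Tibble `genotype`, `gene`, `delta_delta_ct`, `fold`, `call`
#'   (`"up"` if fold > threshold, `"down"` if fold < 1/threshold, else
#'   `"nc"`).
#' @examples
#' ct <- tidyr::expand_grid(
#'   genotype = "G1", treatment = c("AT", "HT"),
#'   biological_rep = 1:3, technical_rep = 1:2,
#'   gene = c("FAD3-2", "Actin-7"))
#' ct$ct <- 20 + (ct$gene == "FAD3-2") * 4 +
#'   (ct$gene == "FAD3-2" & ct$treatment == "HT") * 1  # half expression
#' ddct_fold_change(ct)
#' @export
ddct_fold_change <- function(ct, target = NULL, reference = "Actin-7",
                             treatment = "HT", calibrator = "AT",
                             threshold = 1.5) {
  ct <- tibble::as_tibble(ct)
  need <- c("genotype", "treatment", "biological_rep", "technical_rep",
            "gene", "ct")
  stopifnot(all(need %in% names(ct)))
  if (any(!is.finite(ct$ct)) || any(ct$ct <= 0)) {
    stop("CT values must be positive and finite", call. = FALSE)
  }
  if (!reference %in% ct$gene) {
    stop("reference gene '", reference, "' not present", call. = FALSE)
  }
  if (is.null(target)) target <- setdiff(unique(ct$gene), reference)
  # technical replicates -> one CT per gene x biological replicate
  bio <- dplyr::summarise(
    dplyr::group_by(ct, .data$genotype, .data$treatment,
                    .data$biological_rep, .data$gene),
    ct = mean(.data$ct), .groups = "drop"
  )
  ref <- dplyr::filter(bio, .data$gene == reference)
  ref <- dplyr::rename(ref, ct_ref = "ct")
  ref$gene <- NULL
  out <- purrr::map_dfr(target, function(gn) {
    tgt <- dplyr::filter(bio, .data$gene == gn)
    joined <- dplyr::inner_join(
      tgt, ref, by = c("genotype", "treatment", "biological_rep"))
    missing_ref <- dplyr::anti_join(
      tgt, ref, by = c("genotype", "treatment", "biological_rep"))
    if (nrow(missing_ref) > 0) {
      stop("missing reference-gene rows for gene ", gn, call. = FALSE)
    }
    joined$dct <- joined$ct - joined$ct_ref
    per_trt <- dplyr::summarise(
      dplyr::group_by(joined, .data$genotype, .data$treatment),
      dct = mean(.data$dct), .groups = "drop"
    )
    wide <- tidyr::pivot_wider(per_trt, names_from = "treatment",
                               values_from = "dct")
    if (!all(c(treatment, calibrator) %in% names(wide))) {
      stop("gene ", gn, " lacks ", treatment, " and/or ", calibrator,
           " observations", call. = FALSE)
    }
    ddct <- wide[[treatment]] - wide[[calibrator]]
    tibble::tibble(genotype = wide$genotype, gene = gn,
                   delta_delta_ct = ddct, fold = 2^(-ddct))
  })
  call_direction(out, threshold)
}

#' Direction call from expression fold changes
#'
#' @param result Tibble with a `fold` column (e.g. from
#'   [ddct_fold_change()]), or a bare numeric vector of folds.
#' @param threshold Fold threshold (default 1.5).
#' @return The input with a `call` column: `"up"` if `fold > threshold`,
#'   `"down"` if `fold < 1/threshold`, otherwise `"nc"` (for a numeric
#'   input, the character vector of calls).
#' @export
call_direction <- function(result, threshold = 1.5) {
  stopifnot(threshold > 1)
  fold <- if (is.numeric(result)) result else result$fold
  stopifnot(all(fold > 0, na.rm = TRUE))
  call <- dplyr::case_when(
    fold > threshold ~ "up",
    fold < 1 / threshold ~ "down",
    TRUE ~ "nc"
  )
  if (is.numeric(result)) return(call)
  result$call <- call
  result
}
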