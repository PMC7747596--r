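# The lipid_dataset container: sample metadata, sample x analyte signal
# matrix, and a normalization state (raw signal vs percent of total).

.meta_cols <- c("sample_id", "genotype", "treatment", "year", "block",
                "replicate", "is_qc_pool")

#' Construct a lipid dataset
#'
#' @param values Numeric matrix (samples x analytes) with sample ids as row
#'   names and parseable lipid names as column names, or a wide data frame
#'   whose first column is `sample_id`.
#' @param meta Tibble of sample metadata with columns `sample_id`,
#'   `genotype`, `treatment` (`"AT"`/`"HT"`), `year`, `block`, `replicate`,
#'   `is_qc_pool`.  Quality-control pool samples may carry `NA` genotype and
#'   treatment.
#' @param unit `"signal_per_mg_dw"` (normalized mass-spectral signal per mg
#'   dry weight, 1.0 = signal of 1 nmol internal standard) or
#'   `"percent_of_total"`.
#' @return An object of class `lipid_dataset`.
#' @export
lipid_dataset <- function(values, meta,
                          unit = c("signal_per_mg_dw", "percent_of_total")) {
  unit <- match.arg(unit)
  if (is.data.frame(values)) {
    stopifnot(names(values)[1] == "sample_id")
    m <- as.matrix(values[, -1, drop = FALSE])
    rownames(m) <- as.character(values$sample_id)
    values <- m
  }
  stopifnot(is.matrix(values), is.numeric(values))
  meta <- tibble::as_tibble(meta)
  missing_cols <- setdiff(.meta_cols, names(meta))
  if (length(missing_cols) > 0) {
    stop("metadata lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicate sample_id in metadata: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]),
               collapse = ", "), call. = FALSE)
  }
  if (is.null(rownames(values))) rownames(values) <- meta$sample_id
  extra <- setdiff(rownames(values), meta$sample_id)
  if (length(extra) > 0) {
    stop("samples missing from metadata: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  meta <- meta[match(rownames(values), meta$sample_id), ]
  if (any(values < 0, na.rm = TRUE)) {
    stop("negative signal values are not allowed", call. = FALSE)
  }
  analytes <- parse_lipid_name(colnames(values))
  colnames(values) <- analytes$name
  out <- structure(
    list(values = values, meta = meta, analytes = analytes, unit = unit),
    class = "lipid_dataset"
  )
  if (unit == "percent_of_total") .check_percent_rows(out)
  out
}

.check_percent_rows <- function(ds) {
  keep <- !ds$meta$is_qc_pool
  totals <- rowSums(ds$values[keep, , drop = FALSE])
  if (any(abs(totals - 100) > 1e-6)) {
    bad <- rownames(ds$values)[keep][abs(totals - 100) > 1e-6]
    stop("percent_of_total rows must sum to 100; offending sample(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  invisible(ds)
}

#' @export
print.lipid_dataset <- function(x, ...) {
  cat("<lipid_dataset> ", nrow(x$values), " samples x ", ncol(x$values),
      " analytes [", x$unit, "]\n", sep = "")
  cat("  classes: ",
      paste(sort(unique(x$analytes$class)), collapse = ", "), "\n", sep = "")
  cat("  QC-pool samples: ", sum(x$meta$is_qc_pool), "\n", sep = "")
  invisible(x)
}

#' @export
dim.lipid_dataset <- function(x) dim(x$values)

#' Long tibble view of a lipid dataset
#'
#' @param x A `lipid_dataset`.
#' @param ... Unused.
#' @return Tibble with the sample metadata, `analyte`, `class`, and `value`
#'   (one row per sample x analyte).
#' @method tidy lipid_dataset
#' @export
tidy.lipid_dataset <- function(x, ...) {
  long <- tibble::as_tibble(x$values)
  long$sample_id <- rownames(x$values)
  long <- tidyr::pivot_longer(long, -"sample_id", names_to = "analyte",
                              values_to = "value")
  long <- dplyr::left_join(long, x$meta, by = "sample_id")
  long <- dplyr::left_join(
    long,
    dplyr::select(x$analytes, analyte = "name", "class"),
    by = "analyte"
  )
  dplyr::select(long, dplyr::all_of(.meta_cols), "analyte", "class", "value")
}

#' Read a wide lipid signal table plus sample metadata
#'
#' @param path CSV with first column `sample_id` and one column per analyte;
#'   headers must be parseable shorthand lipid names.
#' @param meta_path CSV of sample metadata keyed by `sample_id`.
#' @param unit Unit of the values, see [lipid_dataset()].
#' @return A `lipid_dataset`.
#' @export
read_lipid_csv <- function(path, meta_path,
                           unit = c("signal_per_mg_dw",
                                    "percent_of_total")) {
  values <- readr::read_csv(path, show_col_types = FALSE)
  if (names(values)[1] != "sample_id") {
    names(values)[1] <- "sample_id"
  }
  if (anyDuplicated(values$sample_id)) {
    stop("duplicate sample_id in ", path, ": ",
         paste(unique(values$sample_id[duplicated(values$sample_id)]),
               collapse = ", "), call. = FALSE)
  }
  headers <- names(values)[-1]
  ok <- vapply(headers, function(h) {
    !inherits(try(.parse_one(h), silent = TRUE), "try-error")
  }, logical(1))
  if (any(!ok)) {
    stop("unparseable analyte header(s): ",
         paste(headers[!ok], collapse = ", "), call. = FALSE)
  }
  meta <- readr::read_csv(meta_path, show_col_types = FALSE)
  meta$is_qc_pool <- as.logical(meta$is_qc_pool)
  lipid_dataset(values, meta, unit = match.arg(unit))
}

#' Write a lipid dataset to CSV
#'
#' @param ds A `lipid_dataset`.
#' @param path Output CSV for the wide value table.
#' @param meta_path Optional output CSV for the metadata.
#' @return `ds`, invisibly.
#' @export
write_lipid_csv <- function(ds, path, meta_path = NULL) {
  wide <- tibble::as_tibble(ds$values)
  wide <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(ds$values)),
                           wide)
  readr::write_csv(wide, path)
  if (!is.null(meta_path)) readr::write_csv(ds$meta, meta_path)
  invisible(ds)
}

#' Convert signal values to percent of total signal
#'
#' Each sample row is divided by its row total and multiplied by 100; the
#' dataset unit becomes `"percent_of_total"`.
#'
#' @param ds A `lipid_dataset` in signal units (re-normalizing an
#'   already-percent dataset, e.g. after subsetting analytes, is allowed).
#' @return A `lipid_dataset` in percent units.
#' @export
percent_of_total <- function(ds) {
  stopifnot(inherits(ds, "lipid_dataset"))
  totals <- rowSums(ds$values)
  if (any(totals <= 0)) {
    stop("zero total signal for sample(s): ",
         paste(rownames(ds$values)[totals <= 0], collapse = ", "),
         call. = FALSE)
  }
  ds$values <- sweep(ds$values, 1, totals, "/") * 100
  ds$unit <- "percent_of_total"
  ds
}

#' Subset the analytes of a dataset
#'
#' @param ds A `lipid_dataset`.
#' @param analytes Character vector of analyte names to keep (order
#'   preserved as in `ds`).
#' @return A `lipid_dataset` in the same unit. Percent datasets are left
#'   un-renormalized; call [percent_of_total()] to re-normalize.
#' @export
select_analytes <- function(ds, analytes) {
  stopifnot(inherits(ds, "lipid_dataset"))
  keep <- colnames(ds$values) %in% analytes
  if (!any(keep)) stop("no analytes left after subsetting", call. = FALSE)
  ds$values <- ds$values[, keep, drop = FALSE]
  ds$analytes <- ds$analytes[keep, ]
  ds
}

#' Quality-control filtering by LOD and QC-pool coefficient of variation
#'
#' An analyte is dropped when, in any year, (1) its mean signal across the
#' experimental samples falls below the limit of detection, or (2) its
#' coefficient of variation (sample standard deviation / mean) across the
#' quality-control pool injections exceeds `cov_max`.
#'
#' @param ds A `lipid_dataset` in signal units.  QC-pool rows may be included
#'   (flagged by `is_qc_pool`) or supplied separately via `qc_pool`.
#' @param qc_pool Optional separate `lipid_dataset` of QC-pool injections.
#' @param lod Limit of detection in normalized-signal units (default
#'   0.00005).
#' @param cov_max Maximum allowed QC coefficient of variation (default 0.3).
#' @return List with `dataset` (the input samples restricted to passing
#'   analytes, original analyte order preserved; internal QC rows ride along
#'   so filtering is idempotent) and `report` (tibble with
#'   one row per analyte x year: `analyte`, `year`, `mean_amount`, `cov`,
#'   `verdict`, `reason`).
#' @export
qc_filter <- function(ds, qc_pool = NULL, lod = 0.00005, cov_max = 0.3) {
  stopifnot(inherits(ds, "lipid_dataset"))
  if (ds$unit != "signal_per_mg_dw") {
    stop("qc_filter requires signal units, not ", ds$unit, call. = FALSE)
  }
  if (is.null(qc_pool)) {
    qc_idx <- ds$meta$is_qc_pool
    qc_values <- ds$values[qc_idx, , drop = FALSE]
    qc_meta <- ds$meta[qc_idx, ]
    exp_values <- ds$values[!qc_idx, , drop = FALSE]
    exp_meta <- ds$meta[!qc_idx, ]
  } else {
    stopifnot(inherits(qc_pool, "lipid_dataset"))
    stopifnot(identical(colnames(qc_pool$values), colnames(ds$values)))
    qc_values <- qc_pool$values
    qc_meta <- qc_pool$meta
    exp_values <- ds$values[!ds$meta$is_qc_pool, , drop = FALSE]
    exp_meta <- ds$meta[!ds$meta$is_qc_pool, ]
  }
  years <- sort(unique(exp_meta$year))
  report <- purrr::map_dfr(years, function(yr) {
    qc_rows <- qc_values[qc_meta$year == yr, , drop = FALSE]
    if (nrow(qc_rows) < 2) {
      stop("fewer than 2 QC-pool samples in year ", yr,
           ": coefficient of variation undefined", call. = FALSE)
    }
    exp_rows <- exp_values[exp_meta$year == yr, , drop = FALSE]
    mean_amount <- colMeans(exp_rows)
    qc_mean <- colMeans(qc_rows)
    qc_sd <- apply(qc_rows, 2, stats::sd)
    cov <- ifelse(qc_mean > 0, qc_sd / qc_mean, Inf)
    reason <- dplyr::case_when(
      mean_amount < lod ~ "below_LOD",
      cov > cov_max ~ "high_CoV",
      TRUE ~ "pass"
    )
    tibble::tibble(
      analyte = colnames(exp_values), year = yr,
      mean_amount = unname(mean_amount), cov = unname(cov),
      verdict = ifelse(reason == "pass", "pass", "drop"), reason = reason
    )
  })
  dropped <- unique(report$analyte[report$verdict == "drop"])
  keep <- setdiff(colnames(ds$values), dropped)
  # when QC rows ride along inside ds they are kept (restricted to passing
  # analytes) so that filtering is idempotent
  out_values <- if (is.null(qc_pool)) ds$values else exp_values
  out_meta <- if (is.null(qc_pool)) ds$meta else exp_meta
  filtered <- lipid_dataset(
    out_values[, colnames(out_values) %in% keep, drop = FALSE],
    out_meta, unit = ds$unit
  )
  list(dataset = filtered, report = report)
}
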