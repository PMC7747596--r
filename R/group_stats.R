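# Least-squares cell means under the factorial field design
# (treatment x genotype fixed, year and block-within-year as fixed blocking
# terms), AT-vs-HT tests, and Fisher's LSD compact letter display.

.design_formula <- function(data, response) {
  terms <- character(0)
  if (length(unique(data$genotype)) > 1 &&
      length(unique(data$treatment)) > 1) {
    terms <- c(terms, "genotype * treatment")
  } else if (length(unique(data$genotype)) > 1) {
    terms <- c(terms, "genotype")
  } else if (length(unique(data$treatment)) > 1) {
    terms <- c(terms, "treatment")
  }
  if (length(unique(data$.yb)) > 1) terms <- c(terms, ".yb")
  if (length(terms) == 0) terms <- "1"
  stats::reformulate(terms, response = response)
}

.cell_L <- function(fit, data, genotype, treatment) {
  # average the model-matrix rows over the year x block levels observed for
  # this genotype; this is the fixed-blocking approximation of a
  # design-adjusted (least-squares) mean
  yb_levels <- unique(data$.yb[data$genotype == genotype])
  newdata <- data.frame(
    genotype = factor(genotype, levels = levels(data$genotype)),
    treatment = factor(treatment, levels = levels(data$treatment)),
    .yb = factor(yb_levels, levels = levels(data$.yb))
  )
  mm <- stats::model.matrix(stats::delete.response(stats::terms(fit)),
                            newdata, xlev = fit$xlevels)
  colMeans(mm)
}

#' Fit least-squares cell means for a per-sample metric
#'
#' Fits `value ~ genotype * treatment + year:block` by ordinary least
#' squares (year and block-within-year as fixed blocking terms) and derives
#' the design-adjusted mean, standard error, and replicate count for every
#' genotype x treatment cell.  Genotypes observed in only a subset of years
#' are averaged over the blocking levels in which they actually occur.
#'
#' @param data Tibble with columns `genotype`, `treatment`, `year`, `block`,
#'   and the response.
#' @param response Name of the response column (default `"value"`).
#' @param alpha Significance level for the LSD machinery (default 0.05).
#' @return Object of class `cell_means`: use [tidy.cell_means()] for the
#'   cell table, [at_vs_ht_flags()] and [lsd_letters()] for comparisons.
#' @export
fit_cell_means <- function(data, response = "value", alpha = 0.05) {
  data <- tibble::as_tibble(data)
  stopifnot(all(c("genotype", "treatment", "year", "block",
                  response) %in% names(data)),
            alpha > 0, alpha < 1)
  data <- data[!is.na(data[[response]]), ]
  data$genotype <- factor(data$genotype)
  data$treatment <- factor(data$treatment)
  data$.yb <- factor(paste(data$year, data$block, sep = ":"))
  counts <- dplyr::count(data, .data$genotype, .data$treatment)
  cells <- counts[, c("genotype", "treatment")]
  if (nlevels(data$genotype) > 1 && nlevels(data$treatment) > 1) {
    full <- nlevels(data$genotype) * nlevels(data$treatment)
    if (nrow(cells) < full) {
      missing <- dplyr::anti_join(
        tidyr::expand_grid(genotype = levels(data$genotype),
                           treatment = levels(data$treatment)),
        dplyr::mutate(cells, genotype = as.character(.data$genotype),
                      treatment = as.character(.data$treatment)),
        by = c("genotype", "treatment"))
      stop("confounded design: no observations for cell(s) ",
           paste(paste(missing$genotype, missing$treatment, sep = ":"),
                 collapse = ", "), call. = FALSE)
    }
  }
  fml <- .design_formula(data, response)
  fit <- stats::lm(fml, data = data)
  b <- stats::coef(fit)
  ok <- !is.na(b)
  V <- stats::vcov(fit)           # rows/cols of estimable coefficients only
  Ls <- purrr::map2(as.character(cells$genotype),
                    as.character(cells$treatment),
                    ~ .cell_L(fit, data, .x, .y))
  est <- purrr::map_dbl(Ls, ~ sum(.x[ok] * b[ok]))
  se <- purrr::map_dbl(Ls, ~ sqrt(drop(t(.x[ok]) %*% V %*% .x[ok])))
  out <- dplyr::mutate(cells, lsmean = est, se = se, n = counts$n)
  structure(
    list(cells = out, L = Ls, fit = fit, vcov = V, ok = ok,
         sigma2 = stats::sigma(fit)^2, df = stats::df.residual(fit),
         alpha = alpha, data = data, response = response),
    class = "cell_means"
  )
}

#' @export
print.cell_means <- function(x, ...) {
  cat("<cell_means> response:", x$response, " residual df:", x$df, "\n")
  print(x$cells)
  invisible(x)
}

#' Tidy the cell-means table
#'
#' @param x A `cell_means` object.
#' @param ... Unused.
#' @return Tibble `genotype`, `treatment`, `lsmean`, `se`, `n`.
#' @method tidy cell_means
#' @export
tidy.cell_means <- function(x, ...) tibble::as_tibble(x$cells)

#' Model-level summary of a cell-means fit
#'
#' @param x A `cell_means` object.
#' @param ... Unused.
#' @return One-row tibble with `sigma`, `df_residual`, `r_squared`, `n`.
#' @method glance cell_means
#' @export
glance.cell_means <- function(x, ...) {
  tibble::tibble(sigma = sqrt(x$sigma2), df_residual = x$df,
                 r_squared = summary(x$fit)$r.squared,
                 n = nrow(x$data))
}

.contrast_test <- function(cm, L1, L2) {
  b <- stats::coef(cm$fit)
  Lc <- L1 - L2
  diff <- sum(Lc[cm$ok] * b[cm$ok])
  se <- sqrt(drop(t(Lc[cm$ok]) %*% cm$vcov %*% Lc[cm$ok]))
  tstat <- if (se > 0) diff / se else 0
  p <- 2 * stats::pt(-abs(tstat), cm$df)
  list(diff = diff, se = se, t = tstat, p = p)
}

#' Ambient vs heat significance flags per genotype
#'
#' Tests the AT-vs-HT least-squares-mean difference for each genotype with a
#' t test on the residual degrees of freedom (the per-comparison Fisher LSD
#' criterion; no multiplicity correction, optional Benjamini-Hochberg).
#'
#' @param cm A `cell_means` fit.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Tibble `genotype`, `diff` (AT - HT), `se`, `t`, `df`, `p_value`,
#'   `significant`, `direction` (`"up"`/`"down"`/`"ns"` for the heat
#'   response).
#' @export
at_vs_ht_flags <- function(cm, adjust = c("none", "BH")) {
  stopifnot(inherits(cm, "cell_means"))
  adjust <- match.arg(adjust)
  cells <- cm$cells
  genos <- unique(as.character(cells$genotype))
  res <- purrr::map_dfr(genos, function(g) {
    i_at <- which(cells$genotype == g & cells$treatment == "AT")
    i_ht <- which(cells$genotype == g & cells$treatment == "HT")
    if (length(i_at) != 1 || length(i_ht) != 1) {
      return(tibble::tibble(genotype = g, diff = NA_real_, se = NA_real_,
                            t = NA_real_, df = cm$df, p_value = NA_real_))
    }
    ct <- .contrast_test(cm, cm$L[[i_at]], cm$L[[i_ht]])
    tibble::tibble(genotype = g, diff = ct$diff, se = ct$se, t = ct$t,
                   df = cm$df, p_value = ct$p)
  })
  if (adjust == "BH") res$p_value <- stats::p.adjust(res$p_value, "BH")
  res$significant <- !is.na(res$p_value) & res$p_value < cm$alpha
  res$direction <- dplyr::case_when(
    res$significant & res$diff < 0 ~ "up",     # HT above AT
    res$significant & res$diff > 0 ~ "down",
    TRUE ~ "ns"
  )
  res
}

#' Fisher's LSD compact letter display
#'
#' Orders the levels by descending least-squares mean and assigns letters so
#' that two levels share a letter exactly when their difference is not
#' significant under the per-pair LSD criterion at the fit's alpha.
#'
#' @param cm A `cell_means` fit.
#' @param within Treatment level within which genotypes are compared.
#' @return Tibble `genotype`, `lsmean`, `letters`, sorted by descending mean.
#' @export
lsd_letters <- function(cm, within = "AT") {
  stopifnot(inherits(cm, "cell_means"))
  cells <- cm$cells
  idx <- which(cells$treatment == within)
  if (length(idx) < 2) stop("need at least 2 levels to letter",
                            call. = FALSE)
  ord <- idx[order(-cells$lsmean[idx])]
  k <- length(ord)
  sig <- matrix(FALSE, k, k)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      ct <- .contrast_test(cm, cm$L[[ord[i]]], cm$L[[ord[j]]])
      sig[i, j] <- sig[j, i] <- ct$p < cm$alpha
    }
  }
  # insert-and-absorb over means sorted descending: each maximal run of
  # mutually non-significant levels gets one letter
  runs <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && !any(sig[i:(j + 1), i:(j + 1)])) j <- j + 1
    runs[[length(runs) + 1]] <- i:j
  }
  # absorb runs contained in an earlier run
  keep <- !purrr::map_lgl(seq_along(runs), function(r) {
    any(purrr::map_lgl(runs[-r], ~ all(runs[[r]] %in% .x)))
  })
  runs <- runs[keep]
  labels <- character(k)
  for (r in seq_along(runs)) {
    labels[runs[[r]]] <- paste0(labels[runs[[r]]], letters[r])
  }
  tibble::tibble(genotype = as.character(cells$genotype[ord]),
                 lsmean = cells$lsmean[ord], letters = labels)
}

# pooled AT-vs-HT treatment contrast for one analyte/metric (used by the
# co-occurrence direction annotation)
.treatment_effect <- function(data, response = "value", alpha = 0.05) {
  cm <- fit_cell_means(data, response, alpha)
  # pooled contrast: average the genotype cell L-vectors per treatment
  cells <- cm$cells
  i_at <- which(cells$treatment == "AT")
  i_ht <- which(cells$treatment == "HT")
  if (length(i_at) == 0 || length(i_ht) == 0) {
    return(tibble::tibble(estimate = NA_real_, p_value = NA_real_))
  }
  L_at <- Reduce(`+`, cm$L[i_at]) / length(i_at)
  L_ht <- Reduce(`+`, cm$L[i_ht]) / length(i_ht)
  ct <- .contrast_test(cm, L_ht, L_at)   # estimate = HT - AT
  tibble::tibble(estimate = ct$diff, p_value = ct$p)
}
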