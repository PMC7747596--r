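# Co-occurrence analysis: Spearman correlation over samples, single-linkage
# hierarchical clustering on 1 - rho, threshold groups (connected components
# of the rho >= threshold graph), heat-response direction annotation, and
# Newick export.

#' Spearman correlation matrix over samples
#'
#' Pairwise Spearman rho across the (non-QC) samples, with average ranks for
#' ties.  Zero-variance analytes get `NA` rows/columns (they are excluded
#' from clustering) and are recorded in the `"excluded"` attribute.
#'
#' @param ds A `lipid_dataset` (or a samples x analytes numeric matrix).
#' @return Symmetric matrix of Spearman rho with unit diagonal.
#' @export
spearman_matrix <- function(ds) {
  values <- if (inherits(ds, "lipid_dataset")) {
    ds$values[!ds$meta$is_qc_pool, , drop = FALSE]
  } else {
    as.matrix(ds)
  }
  if (nrow(values) < 3) {
    stop("need at least 3 samples for a correlation matrix", call. = FALSE)
  }
  const <- apply(values, 2, function(v) stats::sd(v) == 0)
  rho <- suppressWarnings(stats::cor(values, method = "spearman"))
  rho[const, ] <- NA_real_
  rho[, const] <- NA_real_
  diag(rho) <- ifelse(const, NA_real_, 1)
  if (any(const)) {
    warning("zero-variance analyte(s) excluded from correlation: ",
            paste(colnames(values)[const], collapse = ", "))
  }
  attr(rho, "excluded") <- colnames(values)[const]
  rho
}

#' Single-linkage merge tree from a similarity matrix
#'
#' Agglomerates on the distance `d = 1 - rho` with single linkage (clusters
#' join at the maximum between-cluster rho).  `NA` rows (zero-variance
#' analytes) are dropped before clustering.
#'
#' @param rho Symmetric Spearman matrix from [spearman_matrix()].
#' @return Object of class `lipid_merge_tree`: the underlying `hclust`
#'   object plus a tidy merge table (`step`, `height`, `rho`).
#' @export
single_linkage_tree <- function(rho) {
  keep <- !apply(rho, 1, function(r) all(is.na(r)))
  rho <- rho[keep, keep, drop = FALSE]
  if (nrow(rho) < 2) stop("need at least 2 analytes", call. = FALSE)
  d <- stats::as.dist(1 - rho)
  hc <- stats::hclust(d, method = "single")
  merges <- tibble::tibble(step = seq_along(hc$height),
                           height = hc$height, rho = 1 - hc$height)
  structure(list(hclust = hc, merges = merges, labels = hc$labels),
            class = "lipid_merge_tree")
}

#' @export
print.lipid_merge_tree <- function(x, ...) {
  cat("<lipid_merge_tree> ", length(x$labels), " leaves, ",
      nrow(x$merges), " merges; linkage rho in [",
      signif(min(x$merges$rho), 3), ", ", signif(max(x$merges$rho), 3),
      "]\n", sep = "")
  invisible(x)
}

#' Extract co-occurring groups at a correlation threshold
#'
#' Groups are the connected components (of size >= 2) of the graph with an
#' edge wherever `rho >= threshold`; under single linkage this equals
#' cutting the merge tree at similarity = threshold.  Every member of a
#' group is therefore correlated with at least one other member at
#' `rho >= threshold`.
#'
#' @param rho Symmetric Spearman matrix.
#' @param threshold Similarity threshold (default 0.90).
#' @return List of character vectors (analyte names), ordered by first
#'   analyte index; singletons are not reported.
#' @export
extract_groups <- function(rho, threshold = 0.90) {
  labels <- colnames(rho)
  n <- ncol(rho)
  parent <- seq_len(n)
  find <- function(i) {
    root <- i
    while (parent[root] != root) root <- parent[root]
    root
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (!is.na(rho[i, j]) && rho[i, j] >= threshold) {
        ri <- find(i)
        rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  comps <- split(labels, roots)
  comps <- comps[vapply(comps, length, 1L) >= 2]
  comps <- comps[order(vapply(comps, function(g) match(g[1], labels), 1L))]
  unname(comps)
}

#' Annotate per-analyte heat-response directions
#'
#' For every analyte, tests the pooled AT-vs-HT contrast from the factorial
#' cell-means fit; `up`/`down` when significant at `alpha`, `ns` otherwise.
#'
#' @param ds A `lipid_dataset` (percent-of-total recommended).
#' @param alpha Significance level (default 0.05).
#' @return Tibble `analyte`, `estimate` (HT - AT), `p_value`, `direction`.
#' @export
annotate_directions <- function(ds, alpha = 0.05) {
  stopifnot(inherits(ds, "lipid_dataset"))
  long <- tidy(ds)
  long <- long[!long$is_qc_pool, ]
  purrr::map_dfr(unique(long$analyte), function(a) {
    sub <- long[long$analyte == a, ]
    eff <- .treatment_effect(sub, "value", alpha)
    dplyr::bind_cols(
      tibble::tibble(analyte = a), eff,
      tibble::tibble(direction = dplyr::case_when(
        is.na(eff$p_value) ~ "ns",
        eff$p_value < alpha & eff$estimate > 0 ~ "up",
        eff$p_value < alpha & eff$estimate < 0 ~ "down",
        TRUE ~ "ns"
      ))
    )
  })
}

#' Full co-occurrence analysis
#'
#' Runs [spearman_matrix()], [single_linkage_tree()], [extract_groups()],
#' and [annotate_directions()] and bundles the results.
#'
#' @inheritParams annotate_directions
#' @param threshold Group-extraction similarity threshold (default 0.90).
#' @return Object of class `cooccurrence_result` with elements `rho`,
#'   `tree`, `groups`, `directions`.
#' @export
cooccurrence <- function(ds, threshold = 0.90, alpha = 0.05) {
  rho <- spearman_matrix(ds)
  tree <- single_linkage_tree(rho)
  groups <- extract_groups(rho, threshold)
  directions <- annotate_directions(ds, alpha)
  structure(list(rho = rho, tree = tree, groups = groups,
                 directions = directions, threshold = threshold),
            class = "cooccurrence_result")
}

#' @export
print.cooccurrence_result <- function(x, ...) {
  cat("<cooccurrence_result> ", ncol(x$rho), " analytes, ",
      length(x$groups), " groups at rho >= ", x$threshold, "\n", sep = "")
  for (i in seq_along(x$groups)) {
    cat("  group ", i, ": ", paste(x$groups[[i]], collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Tidy the group membership of a co-occurrence result
#'
#' @param x A `cooccurrence_result`.
#' @param ... Unused.
#' @return Tibble `group`, `analyte`, `direction`.
#' @method tidy cooccurrence_result
#' @export
tidy.cooccurrence_result <- function(x, ...) {
  if (length(x$groups) == 0) {
    return(tibble::tibble(group = integer(0), analyte = character(0),
                          direction = character(0)))
  }
  out <- purrr::imap_dfr(x$groups, function(g, i) {
    tibble::tibble(group = i, analyte = g)
  })
  dplyr::left_join(out, dplyr::select(x$directions, "analyte", "direction"),
                   by = "analyte")
}

#' Export a merge tree as a Newick string
#'
#' Branch lengths derive from the `1 - rho` merge heights under the usual
#' ultrametric convention (each of two leaves joined at distance d sits
#' d/2 from the joint node).
#'
#' @param tree A `lipid_merge_tree`.
#' @param file Optional path; when given the string is also written there.
#' @return Newick string (invisibly when `file` is given).
#' @export
export_newick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "lipid_merge_tree"))
  phy <- ape::as.phylo(tree$hclust)
  txt <- ape::write.tree(phy)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}
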