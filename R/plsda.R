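# Two-class partial least squares discriminant analysis, NIPALS-style
# sequential extraction with X deflation, plus Wold's variable importance in
# projection (VIP).  Deterministic: the weight vector at each stage is
# X'y / ||X'y|| (no random initialization); component sign is fixed by
# forcing the largest-magnitude weight entry positive.

.plsda_xy <- function(x, y) {
  if (inherits(x, "lipid_dataset")) {
    ds <- x
    keep <- !ds$meta$is_qc_pool
    x <- ds$values[keep, , drop = FALSE]
    if (is.null(y)) y <- ds$meta$treatment[keep]
  }
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  list(x = x, y = y)
}

#' Fit a two-class PLS discriminant model
#'
#' Predictors are mean-centered (no unit-variance scaling by default,
#' matching analysis of signal tables that were not autoscaled); the class
#' label is coded 0/1 and centered.  Components are extracted sequentially:
#' `w_a = X'y / ||X'y||`, `t_a = X w_a`, `p_a = X' t_a / t_a' t_a`,
#' `q_a = y' t_a / t_a' t_a`, then X (and y) are deflated by the rank-one
#' fit.  The response sum of squares explained by component `a` is
#' `SS_a = q_a^2 t_a' t_a`.
#'
#' @param x Samples x analytes numeric matrix, or a `lipid_dataset` (QC-pool
#'   rows are dropped and `y` defaults to the treatment column).
#' @param y Class labels (factor/character/logical with exactly two levels,
#'   or numeric 0/1).  Ignored entry-wise where `NA`.
#' @param n_components Number of components A (default 2); must not exceed
#'   the rank of the centered predictor matrix.
#' @param scale Autoscale columns to unit variance before fitting (default
#'   `FALSE`).
#' @return Object of class `plsda_fit` with weights `W`, scores `T`,
#'   loadings `P`, response loadings `q`, explained response sum of squares
#'   `ss`, per-analyte `vip`, and the centering constants.
#' @export
fit_plsda <- function(x, y = NULL, n_components = 2, scale = FALSE) {
  xy <- .plsda_xy(x, y)
  x <- xy$x
  y <- xy$y
  if (is.null(colnames(x))) {
    colnames(x) <- paste0("V", seq_len(ncol(x)))
  }
  keep <- !is.na(y)
  x <- x[keep, , drop = FALSE]
  y <- y[keep]
  lv <- sort(unique(as.character(y)))
  if (length(lv) != 2) {
    stop("y must have exactly 2 classes, got ", length(lv), call. = FALSE)
  }
  y01 <- as.numeric(as.character(y) == lv[2])
  if (min(table(y01)) < 2) {
    stop("need at least 2 samples per class", call. = FALSE)
  }
  x_center <- colMeans(x)
  xc <- sweep(x, 2, x_center)
  x_scale <- rep(1, ncol(x))
  if (scale) {
    x_scale <- apply(x, 2, stats::sd)
    x_scale[x_scale == 0] <- 1
    xc <- sweep(xc, 2, x_scale, "/")
  }
  y_center <- mean(y01)
  yc <- y01 - y_center
  rk <- qr(xc)$rank
  if (n_components > rk) {
    stop("n_components (", n_components, ") exceeds the rank of the ",
         "centered predictor matrix (", rk, ")", call. = FALSE)
  }
  p <- ncol(xc)
  W <- P <- matrix(0, p, n_components,
                   dimnames = list(colnames(x), NULL))
  Tm <- matrix(0, nrow(xc), n_components,
               dimnames = list(rownames(x), NULL))
  q <- ss <- numeric(n_components)
  Xd <- xc
  yd <- yc
  for (a in seq_len(n_components)) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < .Machine$double.eps^0.5) {
      stop("no residual covariance between predictors and class at ",
           "component ", a, call. = FALSE)
    }
    w <- w / nw
    if (w[which.max(abs(w))] < 0) w <- -w   # sign convention
    t_a <- drop(Xd %*% w)
    tt <- sum(t_a^2)
    p_a <- drop(crossprod(Xd, t_a)) / tt
    q_a <- sum(yd * t_a) / tt
    Xd <- Xd - tcrossprod(t_a, p_a)
    yd <- yd - q_a * t_a
    W[, a] <- w
    P[, a] <- p_a
    Tm[, a] <- t_a
    q[a] <- q_a
    ss[a] <- q_a^2 * tt
  }
  model <- structure(
    list(W = W, P = P, T = Tm, q = q, ss = ss,
         x_center = x_center, x_scale = x_scale, y_center = y_center,
         levels = lv, y = y01, n_components = n_components,
         analytes = colnames(x), residual_x = Xd),
    class = "plsda_fit"
  )
  model$vip <- vip_scores(model)
  model
}

#' @export
print.plsda_fit <- function(x, ...) {
  cat("<plsda_fit> ", length(x$y), " samples x ", length(x$analytes),
      " analytes, A = ", x$n_components, "\n", sep = "")
  cat("  classes: ", paste(x$levels, collapse = " vs "), "\n", sep = "")
  cat("  explained response SS per component: ",
      paste(signif(x$ss / sum((x$y - mean(x$y))^2), 3), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Variable importance in projection
#'
#' Wold's VIP over the fitted components:
#' `VIP_j = sqrt(p * sum_a SS_a w_ja^2 / sum_a SS_a)` with `p` analytes, so
#' the mean squared VIP over analytes is exactly 1.
#'
#' @param model A `plsda_fit`.
#' @return Named numeric vector of VIP scores.
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "plsda_fit"))
  if (sum(model$ss) <= 0) {
    stop("no explained response variance: VIP undefined", call. = FALSE)
  }
  p <- nrow(model$W)
  w2 <- model$W^2
  vip <- sqrt(p * drop(w2 %*% model$ss) / sum(model$ss))
  stats::setNames(vip, model$analytes)
}

#' Top analytes by VIP
#'
#' @param model A `plsda_fit`.
#' @param k Number of analytes to return (default 15); values above the
#'   analyte count are truncated with a warning.  Ties are broken by analyte
#'   name.
#' @return Tibble `rank`, `analyte`, `vip`, descending by VIP.
#' @export
rank_top_k <- function(model, k = 15) {
  stopifnot(inherits(model, "plsda_fit"))
  vip <- model$vip
  if (k > length(vip)) {
    warning("k truncated to the number of analytes (", length(vip), ")")
    k <- length(vip)
  }
  ord <- order(-vip, names(vip))
  tibble::tibble(rank = seq_len(k),
                 analyte = names(vip)[ord][seq_len(k)],
                 vip = unname(vip[ord])[seq_len(k)])
}

#' Tidy a PLS-DA fit
#'
#' @param x A `plsda_fit`.
#' @param what `"vip"` (per-analyte VIP and rank), `"scores"` (per-sample
#'   component scores with class), `"weights"` or `"loadings"` (per analyte
#'   and component).
#' @param ... Unused.
#' @return A tibble.
#' @method tidy plsda_fit
#' @export
tidy.plsda_fit <- function(x, what = c("vip", "scores", "weights",
                                       "loadings"), ...) {
  what <- match.arg(what)
  switch(
    what,
    vip = {
      out <- tibble::tibble(analyte = x$analytes, vip = unname(x$vip))
      out$rank <- rank(-out$vip, ties.method = "first")
      dplyr::arrange(out, .data$rank)
    },
    scores = {
      out <- tibble::as_tibble(x$T, .name_repair = ~ paste0(
        "comp", seq_along(.x)))
      out$sample_id <- rownames(x$T) %||% as.character(seq_len(nrow(x$T)))
      out$class <- x$levels[x$y + 1]
      dplyr::select(out, "sample_id", "class", dplyr::everything())
    },
    weights = .mat_tidy(x$W, x$analytes, "weight"),
    loadings = .mat_tidy(x$P, x$analytes, "loading")
  )
}

.mat_tidy <- function(m, analytes, name) {
  out <- tibble::as_tibble(m, .name_repair = ~ paste0(
    "comp", seq_along(.x)))
  out$analyte <- analytes
  tidyr::pivot_longer(out, -"analyte", names_to = "component",
                      values_to = name)
}

#' Fit-level summary of a PLS-DA model
#'
#' @param x A `plsda_fit`.
#' @param ... Unused.
#' @return One-row tibble with sample/analyte counts, components, and the
#'   cumulative fraction of response sum of squares explained.
#' @method glance plsda_fit
#' @export
glance.plsda_fit <- function(x, ...) {
  ss_y <- sum((x$y - mean(x$y))^2)
  tibble::tibble(n = length(x$y), p = length(x$analytes),
                 n_components = x$n_components,
                 r2y = sum(x$ss) / ss_y)
}
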