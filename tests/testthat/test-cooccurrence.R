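test_that("Spearman matrix: identity, reversal, and the tied-rank formula", {
  x <- cbind(a = c(1, 2, 3, 4), b = c(4, 3, 2, 1), c = c(1, 3, 2, 4))
  meta <- toy_meta(paste0("S", 1:4))
  ds <- toy_dataset(x, c("PC(34:3)", "PC(34:2)", "PE(34:3)"), meta)
  rho <- spearman_matrix(ds)
  expect_equal(diag(rho), rep(1, 3), ignore_attr = TRUE)
  expect_equal(rho["PC(34:3)", "PC(34:2)"], -1)
  # (1,2,3,4) vs (1,3,2,4): rho = 1 - 6*2/(4*15) = 0.8
  expect_equal(rho["PC(34:3)", "PE(34:3)"], 0.8)
  expect_equal(rho, t(rho))
})

test_that("zero-variance analytes are excluded with a warning", {
  x <- cbind(c(1, 2, 3), c(5, 5, 5))
  ds <- toy_dataset(x, c("PC(34:3)", "PC(34:2)"), toy_meta(paste0("S", 1:3)))
  expect_warning(rho <- spearman_matrix(ds), "zero-variance.*PC\\(34:2\\)")
  expect_true(all(is.na(rho["PC(34:2)", ])))
  expect_equal(attr(rho, "excluded"), "PC(34:2)")
  expect_error(spearman_matrix(x[1:2, ]), "at least 3 samples")
})

test_that("two analytes merge once at their correlation", {
  rho <- matrix(c(1, 0.9, 0.9, 1), 2,
                dimnames = list(c("A", "B"), c("A", "B")))
  tree <- single_linkage_tree(rho)
  expect_equal(nrow(tree$merges), 1)
  expect_equal(tree$merges$rho, 0.9)
})

test_that("merge heights equal the brute-force single-linkage oracle", {
  for (seed in 1:10) {
    rho <- rand_rho(8, seed)
    tree <- single_linkage_tree(rho)
    oracle <- single_linkage_oracle(as.matrix(1 - rho))
    expect_equal(sort(tree$merges$height), oracle, tolerance = 1e-12)
  }
})

test_that("the merge-height profile is invariant to analyte input order", {
  rho <- rand_rho(8, 42)
  perm <- sample(8)
  t1 <- single_linkage_tree(rho)
  t2 <- single_linkage_tree(rho[perm, perm])
  expect_equal(sort(t1$merges$height), sort(t2$merges$height),
               tolerance = 1e-12)
  # single-linkage similarity is non-increasing along the merge sequence
  expect_true(all(diff(t1$merges$rho) < 1e-12))
})

test_that("groups are threshold-graph components and chain transitively", {
  rho <- matrix(1, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(extract_groups(rho), list(c("A", "B")))

  chain <- matrix(c(1, 0.95, 0.50,
                    0.95, 1, 0.92,
                    0.50, 0.92, 1), 3, byrow = TRUE,
                  dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expect_equal(extract_groups(chain), list(c("A", "B", "C")))
})

test_that("chained groups arise from sample vectors realizing the ranks", {
  # B tracks A closely, C tracks B closely, but A and C diverge
  a <- c(1, 2, 3, 4, 5, 6, 7, 8)
  b <- c(1, 2, 3, 4, 5, 6, 8, 7)    # rho(A,B) = 0.976
  c_ <- c(3, 2, 1, 4, 5, 6, 8, 7)   # rho(B,C) = 0.905, rho(A,C) = 0.881
  ds <- toy_dataset(cbind(a, b, c_),
                    c("PC(34:3)", "PC(34:2)", "PE(34:3)"),
                    toy_meta(paste0("S", 1:8)))
  rho <- spearman_matrix(ds)
  expect_gte(rho["PC(34:3)", "PC(34:2)"], 0.9)
  expect_gte(rho["PC(34:2)", "PE(34:3)"], 0.9)
  expect_lt(rho["PC(34:3)", "PE(34:3)"], 0.9)
  expect_equal(extract_groups(rho, 0.9),
               list(c("PC(34:3)", "PC(34:2)", "PE(34:3)")))
})

test_that("extracted groups equal thresholded-graph components (igraph
           oracle) and tree cutting, and are monotone in the threshold", {
  skip_if_not_installed("igraph")
  for (seed in 1:50) {
    rho <- rand_rho(10, seed)
    thr <- stats::runif(1, 0.2, 0.8)
    groups <- extract_groups(rho, thr)
    g <- igraph::graph_from_adjacency_matrix(
      (rho >= thr) * 1, mode = "undirected", diag = FALSE)
    comp <- igraph::components(g)
    oracle <- split(names(comp$membership), comp$membership)
    oracle <- unname(oracle[vapply(oracle, length, 1L) >= 2])
    expect_setequal(lapply(groups, sort), lapply(oracle, sort))

    # equivalence with cutting the single-linkage tree at the threshold
    tree <- single_linkage_tree(rho)
    cut <- stats::cutree(tree$hclust, h = 1 - thr + 1e-12)
    cut_groups <- split(names(cut), cut)
    cut_groups <- unname(cut_groups[vapply(cut_groups, length, 1L) >= 2])
    expect_setequal(lapply(groups, sort), lapply(cut_groups, sort))

    # raising the threshold never merges two previously separate groups
    tighter <- extract_groups(rho, thr + 0.1)
    for (tg in tighter) {
      containing <- Filter(function(g0) all(tg %in% g0), groups)
      expect_equal(length(containing), 1)
    }
  }
})

test_that("direction annotation recovers a planted increase and matches the
           sign of the mean difference", {
  meta <- factorial_meta()
  withr::local_seed(7)
  n <- nrow(meta)
  base <- exp(stats::rnorm(n, sd = 0.05))
  up <- base * ifelse(meta$treatment == "HT", 1.5, 1)    # planted +50%
  null1 <- exp(stats::rnorm(n, sd = 0.05))
  values <- cbind(up, null1)
  ds <- toy_dataset(values, c("TAG(52:3)", "PC(34:1)"), meta)
  dir <- annotate_directions(ds)
  expect_equal(dir$direction[dir$analyte == "TAG(52:3)"], "up")
  expect_gt(dir$estimate[dir$analyte == "TAG(52:3)"], 0)
  sig <- dir[dir$direction != "ns", ]
  expect_true(all(sign(sig$estimate) == ifelse(sig$direction == "up", 1, -1)))
})

test_that("direction annotation holds the type-I error near alpha", {
  meta <- factorial_meta()
  withr::local_seed(123)
  hits <- replicate(200, {
    ds <- toy_dataset(matrix(exp(stats::rnorm(nrow(meta), sd = 0.2))),
                      "PC(34:3)", meta)
    annotate_directions(ds)$direction != "ns"
  })
  expect_lt(mean(hits), 0.12)   # ~alpha = 0.05 within binomial noise
})

test_that("Newick export writes parseable ultrametric trees", {
  rho <- matrix(c(1, 0.9, 0.9, 1), 2,
                dimnames = list(c("A", "B"), c("A", "B")))
  tree <- single_linkage_tree(rho)
  expect_equal(export_newick(tree), "(A:0.05,B:0.05);")

  rho8 <- rand_rho(8, 3)
  tree8 <- single_linkage_tree(rho8)
  txt <- export_newick(tree8)
  phy <- ape::read.tree(text = txt)
  expect_equal(sort(phy$tip.label), sort(colnames(rho8)))
  f <- withr::local_tempfile(fileext = ".nwk")
  export_newick(tree8, f)
  expect_equal(readLines(f), txt)
})
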