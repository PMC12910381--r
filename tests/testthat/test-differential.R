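# PCA, clustering, Welch differential abundance, BH and volcano classes.

log2_fixture <- function(n = 20, seed = 71) {
  set.seed(seed)
  m <- matrix(stats::rnorm(n * 6, 20, 2), n, 6,
              dimnames = list(sprintf("P%02d", seq_len(n)), paste0("S", 1:6)))
  tiny_am(2^m)
}

test_that("PCA matches a brute-force eigendecomposition up to sign", {
  am <- log2_fixture()
  imp <- impute_qrilc(am, seed = 1)  # complete already; just log2-transforms
  p <- pca_samples(imp$matrix)
  expect_true(all(diff(p$var_explained) <= 1e-12))
  expect_equal(sum(p$var_explained), 1)
  brute <- pca_eigen_brute(am_values(imp$matrix))
  for (j in 1:3) {
    got <- p$scores[[paste0("PC", j)]]
    want <- brute$scores[, j]
    expect_true(max(abs(got - want)) < 1e-8 || max(abs(got + want)) < 1e-8)
  }
  expect_equal(p$var_explained[1:3], brute$var_explained[1:3], tolerance = 1e-10)

  # two identical samples separate nowhere
  m <- matrix(c(1, 2, 3, 1, 2, 3), 3, 2, dimnames = list(paste0("P", 1:3), c("S1", "S2")))
  p2 <- pca_samples(tiny_am(2^m))
  expect_equal(stats::sd(p2$scores$PC1), 0)

  withna <- tiny_am(matrix(c(1, NA, 2, 3), 2, 2,
                           dimnames = list(c("P1", "P2"), c("S1", "S2"))))
  expect_error(pca_samples(withna), "missing")
})

test_that("hierarchical clustering reproduces brute-force average linkage", {
  set.seed(81)
  for (i in 1:5) {
    v <- matrix(stats::rnorm(10 * 6, 20, 2), 10, 6,
                dimnames = list(sprintf("P%02d", 1:10), paste0("S", 1:6)))
    cl <- cluster_samples(tiny_am(v))
    d <- 1 - stats::cor(v)
    brute <- average_linkage_cophenetic(stats::as.dist(d))
    got <- as.matrix(stats::cophenetic(cl$hclust))
    expect_equal(unname(got), unname(brute), tolerance = 1e-10)
  }

  # duplicated sample merges first at height 0
  v <- matrix(stats::rnorm(30, 10, 1), 10, 3,
              dimnames = list(sprintf("P%02d", 1:10), c("S1", "S2", "S3")))
  v[, 2] <- v[, 1]
  cl <- cluster_samples(tiny_am(2^v))
  expect_equal(cl$merges$height[1], 0, tolerance = 1e-12)
  expect_setequal(c(-cl$merges$left[1], -cl$merges$right[1]), c(1, 2))

  # permutation of sample order leaves the tree unchanged up to relabeling
  perm <- c(3, 1, 2)
  cl2 <- cluster_samples(tiny_am(2^v[, perm]))
  c1 <- as.matrix(stats::cophenetic(cl$hclust))
  c2 <- as.matrix(stats::cophenetic(cl2$hclust))
  expect_equal(c1, c2[rownames(c1), colnames(c1)], tolerance = 1e-12)

  # constant sample handled with a warning
  v[, 3] <- 5
  expect_warning(cluster_samples(tiny_am(2^v)), "constant")
})

test_that("newick export writes a tree over the sample labels", {
  am <- log2_fixture()
  cl <- cluster_samples(am_log2(am))
  path <- tempfile(fileext = ".nwk")
  write_dendrogram_newick(cl, path)
  tree <- ape::read.tree(path)
  expect_setequal(tree$tip.label, am_samples(am))
})

test_that("Welch differential abundance and BH behave as defined", {
  st <- tiny_samples(paste0("S", 1:6), rep(c("T", "C"), each = 3))
  # identical groups -> zero fold change everywhere
  v <- matrix(stats::rnorm(30, 20, 1), 10, 3)
  m <- cbind(v, v)
  dimnames(m) <- list(sprintf("P%02d", 1:10), paste0("S", 1:6))
  da <- differential_abundance(tiny_am(2^m), st,
                               tibble::tibble(test_group = "T", control_group = "C"))
  expect_equal(da$log2fc, rep(0, 10))
  expect_true(all(da$p_adj >= da$p_raw - 1e-15))

  # exact difference with zero variance: fc 4, variance floor kicks in
  m2 <- rbind(PX = c(8, 8, 8, 4, 4, 4))
  colnames(m2) <- paste0("S", 1:6)
  da2 <- differential_abundance(tiny_am(m2, scale = "log2"), st,
                                tibble::tibble(test_group = "T", control_group = "C"))
  expect_equal(da2$log2fc, 4)
  expect_true(da2$var_floored)
  expect_lt(da2$p_raw, 1e-6)

  expect_error(
    differential_abundance(tiny_am(2^m), st,
                           tibble::tibble(test_group = "T", control_group = "Z")),
    "unknown group"
  )
  st1 <- tiny_samples(paste0("S", 1:6), c("T", rep("C", 5)))
  expect_error(
    differential_abundance(tiny_am(2^m), st1,
                           tibble::tibble(test_group = "T", control_group = "C")),
    "fewer than 2"
  )
})

test_that("BH adjustment equals the brute-force step-up on random vectors", {
  set.seed(91)
  for (i in 1:50) {
    p <- stats::runif(sample(3:40, 1))
    expect_equal(stats::p.adjust(p, "BH"), bh_brute(p), tolerance = 1e-12)
  }
  # monotone in p_raw
  p <- stats::runif(100)
  adj <- stats::p.adjust(p, "BH")
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
})

test_that("volcano classification applies inclusive default cutoffs", {
  res <- tibble::tibble(
    comparison = "T vs C",
    protein_id = paste0("P", 1:8),
    log2fc = c(2, 2, -1.0, -2, 0.5, 1.0, -0.99, 3),
    p_raw = rep(0.001, 8),
    p_adj = c(0.001, 0.5, 0.01, 0.005, 0.001, 0.01, 0.001, 0.011)
  )
  out <- classify_volcano(res)
  expect_equal(as.character(out$volcano_class),
               c("up",               # clear hit
                 "not_significant",  # large fc, weak p
                 "down",             # boundary fc -1 and boundary alpha, inclusive
                 "down",
                 "not_significant",  # small fc
                 "up",               # boundary fc +1, inclusive
                 "not_significant",  # just inside the fc window
                 "not_significant")) # p_adj just above alpha
  counts <- attr(out, "class_counts")
  expect_equal(counts$up, 2L)
  expect_equal(counts$down, 2L)
})
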