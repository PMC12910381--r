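# Generic QC metric suite.

qc_fixture <- function() {
  m <- matrix(c(
    10, 20, NA, 40,
    NA, 15, NA, 30,
    5, NA, NA, 25,
    8, 12, NA, 16
  ), nrow = 4, byrow = TRUE,
  dimnames = list(paste0("P", 1:4), paste0("S", 1:4)))
  tiny_am(m)
}

test_that("identification counts and missingness are complementary", {
  am <- qc_fixture()
  ids <- identification_counts(am)
  expect_equal(ids$n_identified, c(3, 3, 0, 4))
  miss <- missing_value_percentages(am)
  expect_equal(miss$missing_pct, c(25, 25, 100, 0))
  # conservation identity on random fixtures
  set.seed(11)
  for (i in 1:10) {
    m <- matrix(stats::runif(30, 1, 10), 6, 5,
                dimnames = list(paste0("P", 1:6), paste0("S", 1:5)))
    m[stats::runif(30) < 0.3] <- NA
    a <- tiny_am(m)
    expect_equal(missing_value_percentages(a)$missing_pct,
                 100 * (1 - identification_counts(a)$n_identified / 6))
  }
  empty <- tiny_am(matrix(numeric(), 0, 2, dimnames = list(NULL, c("S1", "S2"))))
  expect_error(missing_value_percentages(empty), "empty")
})

test_that("protein coverage histogram conserves the protein count", {
  am <- qc_fixture()
  cov <- protein_coverage(am)
  expect_equal(cov$per_protein$n_samples_detected, c(3, 2, 2, 3))
  expect_equal(sum(cov$histogram$n_proteins), 4L)
  expect_equal(cov$histogram$n_proteins[cov$histogram$k == 2], 2L)
})

test_that("shared identifications match brute-force set intersection", {
  am <- qc_fixture()
  sh <- shared_identifications(am)
  expect_equal(sh$overlap, t(sh$overlap))
  expect_equal(diag(sh$overlap), c(S1 = 3, S2 = 3, S3 = 0, S4 = 4))
  expect_equal(sh$jaccard["S3", "S3"], 1)  # both empty
  expect_equal(sh$jaccard["S1", "S3"], 0)
  set.seed(7)
  for (i in 1:10) {
    m <- matrix(stats::runif(40, 1, 5), 8, 5,
                dimnames = list(paste0("P", 1:8), paste0("S", 1:5)))
    m[stats::runif(40) < 0.4] <- NA
    a <- tiny_am(m)
    sh <- shared_identifications(a)
    det <- apply(!is.na(am_values(a)), 2L, which)
    det <- lapply(colnames(m), function(s) which(!is.na(m[, s])))
    for (s in 1:5) for (t in 1:5) {
      inter <- length(intersect(det[[s]], det[[t]]))
      uni <- length(union(det[[s]], det[[t]]))
      expect_equal(unname(sh$overlap[s, t]), inter)
      expect_equal(unname(sh$jaccard[s, t]), if (uni == 0) 1 else inter / uni)
    }
  }
})

test_that("common proteins honour the detection-fraction threshold", {
  am <- qc_fixture()
  expect_equal(common_proteins(am, 1)$protein_id, character())
  # 2 of 4 samples at min_fraction 0.5 is included (>= boundary)
  expect_setequal(common_proteins(am, 0.5)$protein_id, c("P1", "P2", "P3", "P4"))
  expect_setequal(common_proteins(am, 0.75)$protein_id, c("P1", "P4"))
  # monotone nonincreasing in min_fraction
  fr <- seq(0.1, 1, by = 0.1)
  ns <- vapply(fr, function(f) nrow(common_proteins(am, f)), integer(1L))
  expect_true(all(diff(ns) <= 0))
})

test_that("group CV follows the sd/mean definition and its invariances", {
  m <- matrix(c(100, 100, 1, 3), 2, 2, byrow = TRUE,
              dimnames = list(c("P1", "P2"), c("S1", "S2")))
  am <- tiny_am(m)
  st <- tiny_samples(c("S1", "S2"), c("A", "A"))
  cv <- group_cv(am, st)
  expect_equal(cv$cv[cv$protein_id == "P1"], 0)
  expect_equal(cv$cv[cv$protein_id == "P2"], sqrt(2) / 2, tolerance = 1e-12)

  # protein observed once in the group is skipped
  m2 <- rbind(m, P3 = c(5, NA))
  cv2 <- group_cv(tiny_am(m2), st)
  expect_false("P3" %in% cv2$protein_id)

  # scale invariance
  cv3 <- group_cv(tiny_am(m * 7), st)
  expect_equal(cv3$cv, cv$cv)

  st_small <- tiny_samples(c("S1", "S2"), c("A", "B"))
  expect_warning(expect_warning(group_cv(am, st_small), "fewer than 2"),
                 "fewer than 2")  # one warning per skipped singleton group
})

test_that("intensity summaries use observed values and type-7 quantiles", {
  m <- matrix(c(1, 2, 3, 4, 5, NA, NA, NA), 4, 2,
              dimnames = list(paste0("P", 1:4), c("S1", "S2")))
  s <- intensity_summary(tiny_am(m))
  expect_equal(s$median[s$sample_id == "S1"], 2.5)
  expect_equal(s$total[s$sample_id == "S1"], 10)
  expect_equal(s$median[s$sample_id == "S2"], 5)
  expect_equal(s$q1[s$sample_id == "S2"], 5)
  set.seed(21)
  m <- matrix(stats::rlnorm(50), 10, 5,
              dimnames = list(paste0("P", 1:10), paste0("S", 1:5)))
  s <- intensity_summary(tiny_am(m))
  for (j in 1:5) {
    expect_equal(s$q1[j], unname(stats::quantile(m[, j], 0.25)))
    expect_equal(s$q3[j], unname(stats::quantile(m[, j], 0.75)))
  }
})

test_that("metrics are invariant under row and column permutation", {
  set.seed(5)
  m <- matrix(stats::runif(40, 1, 9), 8, 5,
              dimnames = list(paste0("P", 1:8), paste0("S", 1:5)))
  m[stats::runif(40) < 0.25] <- NA
  am <- tiny_am(m)
  amp <- tiny_am(m[sample(8), sample(5)])
  a <- identification_counts(am); b <- identification_counts(amp)
  expect_equal(dplyr::arrange(a, sample_id), dplyr::arrange(b, sample_id))
  ca <- protein_coverage(am)$histogram; cb <- protein_coverage(amp)$histogram
  expect_equal(ca, cb)
})

test_that("qc_report bundles every metric and serializes to JSON", {
  am <- qc_fixture()
  st <- tiny_samples(paste0("S", 1:4), rep(c("A", "B"), each = 2))
  rep <- suppressWarnings(qc_report(am, st))
  expect_s3_class(rep, "qc_report")
  path <- tempfile(fileext = ".json")
  write_qc_report(rep, path)
  parsed <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(parsed$id_counts$n_identified, c(3, 3, 0, 4))
  expect_equal(sum(parsed$coverage_histogram$n_proteins), 4L)
})
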