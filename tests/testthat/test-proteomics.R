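# Consistency filtering, normalization and imputation.

test_that("consistency filter applies the at-least-two-thirds rule per group", {
  # two groups of 3; protein retained iff observed >= ceil(2/3 * 3) = 2 in a group
  m <- matrix(NA_real_, 3, 6,
              dimnames = list(paste0("P", 1:3), paste0("S", 1:6)))
  st <- tiny_samples(paste0("S", 1:6), rep(c("A", "B"), each = 3))
  m["P1", c("S1", "S2")] <- c(5, 6)        # 2 of 3 in A -> retained
  m["P2", c("S1", "S4")] <- c(5, 6)        # 1 of 3 in each -> dropped
  m["P3", c("S4", "S5", "S6")] <- c(1, 2, 3)  # complete in B -> retained
  res <- filter_by_consistency(tiny_am(m), st, 2 / 3)
  expect_setequal(res$matrix$protein_id, c("P1", "P3"))
  expect_equal(res$dropped_ids, "P2")

  # min_group_fraction = 1 keeps only proteins complete in some group
  res1 <- filter_by_consistency(tiny_am(m), st, 1)
  expect_equal(res1$matrix$protein_id, "P3")

  # monotone: lowering the fraction never removes a retained protein
  set.seed(31)
  for (i in 1:20) {
    mm <- matrix(stats::runif(24, 1, 9), 4, 6,
                 dimnames = list(paste0("P", 1:4), paste0("S", 1:6)))
    mm[stats::runif(24) < 0.5] <- NA
    hi <- filter_by_consistency(tiny_am(mm), st, 0.9)$matrix$protein_id
    lo <- filter_by_consistency(tiny_am(mm), st, 0.4)$matrix$protein_id
    expect_true(all(hi %in% lo))
  }
})

test_that("median normalization equalizes sample medians at the global median", {
  m <- matrix(c(5, 10, 20, 10, 20, 40), 3, 2,
              dimnames = list(paste0("P", 1:3), c("S1", "S2")))
  am <- tiny_am(m)
  out <- am_values(normalize_median(am))
  # medians 10 and 20, global median of all six values = 15
  expect_equal(unname(out[, "S1"]), c(5, 10, 20) * 1.5)
  expect_equal(unname(out[, "S2"]), c(10, 20, 40) * 0.75)
  expect_equal(unname(apply(out, 2, stats::median)), c(15, 15))

  # already-equal medians: identity
  same <- tiny_am(matrix(c(1, 2, 3, 3, 2, 1), 3, 2,
                         dimnames = list(paste0("P", 1:3), c("S1", "S2"))))
  expect_equal(am_values(normalize_median(same)), am_values(same))

  # missing cells untouched
  m[2, 1] <- NA
  out2 <- normalize_median(tiny_am(m))
  expect_true(is.na(am_values(out2)[2, 1]))

  allna <- tiny_am(matrix(c(1, 2, NA, NA), 2, 2,
                          dimnames = list(c("P1", "P2"), c("S1", "S2"))))
  expect_error(normalize_median(allna), "no observed values")
})

test_that("quantile normalization matches the brute-force rank/mean oracle", {
  # identical sorted values -> identity
  m <- matrix(c(1, 5, 9, 9, 1, 5), 3, 2,
              dimnames = list(paste0("P", 1:3), c("S1", "S2")))
  out <- am_values(normalize_quantile(tiny_am(m)))
  expect_equal(out, m)

  set.seed(41)
  for (i in 1:10) {
    mm <- matrix(stats::rlnorm(24, 3, 1), 6, 4,
                 dimnames = list(paste0("P", 1:6), paste0("S", 1:4)))
    got <- am_values(normalize_quantile(tiny_am(mm)))
    expect_equal(got, quantile_norm_brute(mm), tolerance = 1e-10)
    # defining property: all complete samples share sorted values
    sorted <- apply(got, 2, sort)
    expect_equal(sorted, sorted[, c(1, 1, 1, 1)], ignore_attr = TRUE)
  }
})

test_that("QRILC imputation fills left-censored values deterministically", {
  # complete matrix: unchanged (up to the log2 transform), empty mask
  m <- matrix(2^c(10, 11, 12, 13, 10.5, 11.5, 12.5, 13.5), 4, 2,
              dimnames = list(paste0("P", 1:4), c("S1", "S2")))
  res <- impute_qrilc(tiny_am(m), seed = 1)
  expect_equal(am_values(res$matrix), log2(m))
  expect_false(any(res$mask))

  # deterministic given seed; different seeds differ
  set.seed(51)
  mm <- matrix(2^stats::rnorm(200, 20, 1), 50, 4,
               dimnames = list(sprintf("P%02d", 1:50), paste0("S", 1:4)))
  mm[stats::runif(200) < 0.15] <- NA
  a <- impute_qrilc(tiny_am(mm), seed = 7)
  b <- impute_qrilc(tiny_am(mm), seed = 7)
  c <- impute_qrilc(tiny_am(mm), seed = 8)
  expect_identical(am_values(a$matrix), am_values(b$matrix))
  expect_false(identical(am_values(a$matrix), am_values(c$matrix)))
  expect_equal(a$mask, is.na(mm), ignore_attr = TRUE)

  # imputed values lie in each sample's low tail
  v <- am_values(a$matrix)
  for (s in colnames(v)) {
    imp <- v[a$mask[, s], s]
    obs <- log2(mm[!is.na(mm[, s]), s])
    if (length(imp)) expect_true(all(imp < stats::median(obs)))
  }

  few <- tiny_am(matrix(c(1, 2, 3, NA, 4, 5, 6, 7), 4, 2,
                        dimnames = list(paste0("P", 1:4), c("S1", "S2"))))
  expect_error(impute_qrilc(few, seed = 1), "fewer than 4 observed")
})

test_that("downshift imputation draws from the shifted normal", {
  set.seed(61)
  m <- matrix(2^stats::rnorm(400, 20, 1), 100, 4,
              dimnames = list(sprintf("P%03d", 1:100), paste0("S", 1:4)))
  am <- tiny_am(m)
  res0 <- impute_min_downshift(am, seed = 1)
  expect_false(any(res0$mask))

  m[1:30, 1] <- NA
  am <- tiny_am(m)
  # width = 0: deterministic constant fill at mean - shift*sd
  res <- impute_min_downshift(am, shift = 1.8, width = 0, seed = 1)
  v <- am_values(res$matrix)
  obs <- log2(m[31:100, 1])
  expect_equal(unname(v[1:30, 1]),
               rep(mean(obs) - 1.8 * stats::sd(obs), 30), tolerance = 1e-10)

  # over seeds, imputed mean approaches mean - 1.8 sd
  imps <- vapply(1:50, function(s) {
    mean(am_values(impute_min_downshift(am, seed = s)$matrix)[1:30, 1])
  }, double(1L))
  expect_equal(mean(imps), mean(obs) - 1.8 * stats::sd(obs), tolerance = 0.1)
})

test_that("group-mean imputation averages within the sample's group", {
  m <- rbind(
    P1 = 2^c(4, 6, NA, 8),
    P2 = 2^c(5, NA, NA, NA)
  )
  colnames(m) <- paste0("S", 1:4)
  st <- tiny_samples(paste0("S", 1:4), rep(c("A", "B"), each = 2))
  res <- impute_group_mean(tiny_am(m), st)
  v <- am_values(res$matrix)
  expect_equal(v["P1", "S3"], 8)  # group B mean of log2 values = 8
  expect_equal(v["P2", "S2"], 5)  # group A mean from the single observed value
  expect_true(all(is.na(v["P2", c("S3", "S4")])))  # group B has none -> flagged
  expect_equal(res$unimputable, "P2")

  complete <- tiny_am(matrix(2^c(1, 2, 3, 4), 2, 2,
                             dimnames = list(c("P1", "P2"), c("S1", "S2"))))
  resc <- impute_group_mean(complete, tiny_samples(c("S1", "S2"), c("A", "A")))
  expect_false(any(resc$mask))
})
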