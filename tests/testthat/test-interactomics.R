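# SAINT interop, CRAPome fold-change scoring, filtering, known-interaction
# mapping, MS-microscopy, enrichment, network export.

sc_fixture <- function() {
  counts <- rbind(
    PREY1 = c(10, 12, 0, 0, 0),
    PREY2 = c(6, 4, 5, 6, 4),
    PREY3 = c(0, 0, 2, 0, 3)
  )
  colnames(counts) <- c("B1_R1", "B1_R2", "C1", "C2", "C3")
  runs <- tibble::tibble(
    sample_id = colnames(counts),
    bait_uniprot = c("BAITX", "BAITX", NA, NA, NA),
    is_control = c(FALSE, FALSE, TRUE, TRUE, TRUE)
  )
  structure(list(counts = counts * 1.0, runs = runs), class = "sc_table")
}

test_that("spectral_counts builds the bait-run container and validates baits", {
  m <- matrix(c(3, NA, 2, 5), 2, 2,
              dimnames = list(c("PREY1", "PREY2"), c("B1_R1", "C1")))
  st <- tibble::tibble(sample_id = c("B1_R1", "C1"),
                       sample_group = c("bait", "control"),
                       bait_uniprot = c("BAITX", NA),
                       is_control = c(FALSE, TRUE),
                       acquisition_order = 1:2)
  sc <- spectral_counts(tiny_am(m, kind = "spectral_count"), st)
  expect_equal(sc$counts["PREY2", "B1_R1"], 0)  # missing -> zero count
  st$is_control <- FALSE
  st$bait_uniprot <- NA
  expect_error(spectral_counts(tiny_am(m, kind = "spectral_count"), st),
               "without a bait")
})

test_that("SAINT input files follow the three-file convention", {
  sc <- sc_fixture()
  outdir <- file.path(tempdir(), "saint_test")
  unlink(outdir, recursive = TRUE)
  paths <- write_saint_inputs(sc, outdir = outdir)
  inter <- readLines(paths[["interactions"]])
  # zero-count pairs omitted: PREY3 absent from bait runs
  expect_false(any(grepl("^B1_R1\tBAITX\tPREY3", inter)))
  expect_true("B1_R1\tBAITX\tPREY1\t10" %in% inter)
  baits <- readLines(paths[["baits"]])
  expect_true("B1_R1\tBAITX\tT" %in% baits)
  expect_true("C1\tC1\tC" %in% baits)
  preys <- readLines(paths[["preys"]])
  expect_equal(preys[1], "PREY1\t100\tPREY1")  # default length 100

  no_ctrl <- sc
  no_ctrl$runs$is_control <- FALSE
  no_ctrl$runs$bait_uniprot <- "BAITX"
  expect_error(write_saint_inputs(no_ctrl, outdir = outdir), "control")
})

test_that("SAINT output parsing validates required columns and ranges", {
  good <- write_lines_tmp(c("Bait\tPrey\tAvgP\tBFDR\tExtra",
                            "BAITX\tPREY1\t0.99\t0.01\tfoo",
                            "BAITX\tPREY2\t0.2\t0.4\tbar"))
  s <- read_saint_output(good)
  expect_equal(nrow(s), 2L)
  expect_equal(s$bfdr, c(0.01, 0.4))
  bad <- write_lines_tmp(c("Bait\tPrey\tAvgP", "B\tP\t0.5"))
  expect_error(read_saint_output(bad), "BFDR")
  oob <- write_lines_tmp(c("Bait\tPrey\tAvgP\tBFDR", "B\tP\t0.5\t1.4"))
  expect_error(read_saint_output(oob), "\\[0, 1\\]")
})

test_that("fold-change scores follow the CRAPome convention", {
  fc <- crapome_fold_change(sc_fixture())
  p1 <- fc[fc$prey == "PREY1", ]
  # absent from all controls, avg bait 11: fc_a = 11.1 / 0.1 = 111
  expect_equal(p1$avg_bait_count, 11)
  expect_equal(p1$fc_a, 11.1 / 0.1)
  expect_equal(p1$control_frequency, 0)
  p2 <- fc[fc$prey == "PREY2", ]
  expect_equal(p2$fc_a, (5 + 0.1) / (5 + 0.1))  # equal in bait and controls -> 1
  expect_equal(p2$control_frequency, 1)
  # PREY3 never seen in bait runs -> no record
  expect_false("PREY3" %in% fc$prey)

  # control permutation invariance and fc_b <= fc_a
  sc2 <- sc_fixture()
  sc2$counts <- sc2$counts[, c("B1_R1", "B1_R2", "C3", "C1", "C2")]
  sc2$runs <- sc2$runs[c(1, 2, 5, 3, 4), ]
  expect_equal(crapome_fold_change(sc2), fc)
  expect_true(all(fc$fc_b <= fc$fc_a + 1e-12))

  # top-k controls: PREY2 controls (5, 6, 4), top 2 -> 5.5
  fck <- crapome_fold_change(sc_fixture(), top_k = 2)
  expect_equal(fck$fc_b[fck$prey == "PREY2"], (5 + 0.1) / (5.5 + 0.1))
})

test_that("high-confidence filtering applies the enabled predicates", {
  fc <- crapome_fold_change(sc_fixture())
  rec <- filter_high_confidence(fc)
  expect_true(rec$passed[rec$prey == "PREY1"])   # fc_a 111, freq 0
  expect_false(rec$passed[rec$prey == "PREY2"])  # fc_a 1, freq 1

  saint <- tibble::tibble(bait = "BAITX", prey = c("PREY1", "PREY2"),
                          avg_p = c(0.99, 0.9), bfdr = c(0.2, 0.01))
  rec2 <- filter_high_confidence(fc, saint = saint)
  expect_false(rec2$passed[rec2$prey == "PREY1"])  # BFDR 0.2 fails despite FC
  expect_false(rec2$passed[rec2$prey == "PREY2"])  # BFDR ok but FC fails

  # monotone under threshold tightening
  loose <- filter_high_confidence(fc, fc_a_min = 1, control_freq_max = 1)
  tight <- filter_high_confidence(fc, fc_a_min = 50, control_freq_max = 0.2)
  expect_true(all(which(tight$passed) %in% which(loose$passed)))
})

test_that("known-interaction mapping is order-insensitive", {
  fc <- crapome_fold_change(sc_fixture())
  rec <- filter_high_confidence(fc)
  ref <- tibble::tibble(accession_a = "PREY1", accession_b = "BAITX")  # reversed
  out <- map_known_interactions(rec, ref)
  expect_true(out$records$known[out$records$prey == "PREY1"])
  expect_equal(out$known_fraction$known_fraction[out$known_fraction$bait == "BAITX"], 1)

  none <- map_known_interactions(rec, ref[0, ])
  expect_false(any(none$records$known))
  expect_true(all(none$known_fraction$known_fraction == 0))
})

test_that("MS-microscopy profiles normalize to a 0-100 scale", {
  rec <- tibble::tibble(
    bait = "BAITX", prey = c("A", "B", "C"),
    avg_bait_count = c(20, 10, 5), fc_a = 100, fc_b = 100,
    control_frequency = 0, n_control = 3, avg_p = NA_real_, bfdr = NA_real_,
    passed = c(TRUE, TRUE, FALSE)
  )
  markers <- tibble::tibble(localization = c("nucleus", "cytoplasm", "er"),
                            accession = c("A", "B", "Z"))
  prof <- ms_microscopy_profile(rec, markers)
  expect_equal(prof$score[prof$localization == "nucleus"], 100)   # raw 20
  expect_equal(prof$score[prof$localization == "cytoplasm"], 50)  # raw 10
  expect_equal(prof$score[prof$localization == "er"], 0)
  # scale invariance in the counts
  rec2 <- dplyr::mutate(rec, avg_bait_count = avg_bait_count * 13)
  expect_equal(ms_microscopy_profile(rec2, markers), prof)
  # no marker overlap -> all-zero row
  prof0 <- ms_microscopy_profile(dplyr::mutate(rec, prey = c("X", "Y", "W")), markers)
  expect_true(all(prof0$score == 0))
})

test_that("hypergeometric enrichment matches brute-force enumeration", {
  background <- paste0("G", 1:20)
  ann <- tibble::tibble(
    term = rep(c("T1", "T2", "T3", "T4"), times = c(20, 5, 8, 3)),
    accession = c(background, paste0("G", 1:5), paste0("G", 6:13), paste0("G", 14:16))
  )
  prey <- paste0("G", c(1:4, 14))
  res <- enrichment_hypergeometric(prey, ann, background)
  expect_equal(res$p[res$term == "T1"], 1)  # term = background
  t3 <- res[res$term == "T3", ]
  expect_equal(t3$n_overlap, 0L)
  expect_equal(t3$p, 1)  # P(overlap >= 0) = 1
  for (tm in c("T2", "T4")) {
    row <- res[res$term == tm, ]
    expect_equal(row$p,
                 hyper_tail_brute(row$n_overlap, row$n_term, 20, length(prey)),
                 tolerance = 1e-12)
  }
  expect_equal(res$p_adj, stats::p.adjust(res$p, "BH"), tolerance = 1e-12)
  expect_error(enrichment_hypergeometric(c("G1", "NOPE"), ann, background),
               "outside the background")
})

test_that("network export annotates roles and orders deterministically", {
  rec <- tibble::tibble(
    bait = c("B2", "B1", "B1"), prey = c("P1", "B2", "P2"),
    avg_bait_count = c(5, 7, 9), fc_a = 10, fc_b = 8, control_frequency = 0,
    n_control = 3, avg_p = NA_real_, bfdr = NA_real_, passed = c(TRUE, TRUE, FALSE)
  )
  net <- export_network(rec)
  expect_equal(net$edges$bait, c("B1", "B2"))  # lexicographic order
  expect_equal(net$nodes$role[net$nodes$id == "B2"], "both")
  expect_equal(net$nodes$role[net$nodes$id == "B1"], "bait")
  expect_equal(net$nodes$role[net$nodes$id == "P1"], "prey")

  empty <- export_network(dplyr::mutate(rec, passed = FALSE))
  expect_equal(nrow(empty$edges), 0L)
  expect_true(all(c("bait", "prey") %in% names(empty$edges)))
})
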