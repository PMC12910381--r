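# Deterministic synthetic-data generators. They produce every input the
# other modules consume, together with ground truth, so the whole system is
# testable without any download. All generators are pure functions of
# (parameters, seed).

#' Path to the bundled contaminant accession list
#' @return File path inside the installed package.
#' @export
bundled_contaminant_file <- function() {
  system.file("extdata", "contaminants.txt", package = "protflow", mustWork = TRUE)
}

#' Generate a synthetic whole-proteome dataset with ground truth
#'
#' Protein baselines are drawn from `Normal(20, 2)` on the log2 scale with
#' replicate noise `Normal(0, 0.25)`; a `de_fraction` of proteins is shifted
#' by `effect` log2 units (random sign) in the last group. Missingness is the
#' sum of a completely-at-random component (`mcar_rate`) and an
#' intensity-dependent (left-censoring) component: the censoring probability
#' rises logistically as a value falls below the 10th percentile of all log2
#' values, scaled by `mnar_strength`. A `contaminant_fraction` of non-shifted
#' proteins is relabeled with accessions from the bundled contaminant list.
#'
#' @param n_proteins,groups,reps Dataset dimensions (`groups * reps` samples).
#' @param de_fraction Fraction of proteins with a true shift in the last group.
#' @param effect Shift size in log2 units.
#' @param mnar_strength Maximum censoring probability for deeply low values.
#' @param mcar_rate Random missingness rate.
#' @param contaminant_fraction Fraction of proteins relabeled as contaminants.
#' @param seed Integer seed; regeneration with equal arguments is
#'   bit-identical.
#' @return List with `matrix` (linear-scale intensity [abundance_matrix()]),
#'   `samples` (sample table), `truth` (tibble `protein_id`, `de`,
#'   `contaminant`), and `params`.
#' @export
generate_proteomics <- function(n_proteins = 1000L, groups = 2L, reps = 4L,
                                de_fraction = 0.1, effect = 2.0,
                                mnar_strength = 0.5, mcar_rate = 0.02,
                                contaminant_fraction = 0.02, seed = 1L) {
  if (de_fraction < 0 || de_fraction > 1) stop("de_fraction must be in [0, 1]")
  stopifnot(groups >= 1L, reps >= 1L, mcar_rate >= 0, mcar_rate < 1,
            mnar_strength >= 0, mnar_strength <= 1)
  withr::with_seed(as.integer(seed), {
    group_names <- paste0("group", seq_len(groups))
    sample_ids <- as.vector(vapply(group_names, function(g) paste0(g, "_R", seq_len(reps)),
                                   character(reps)))
    sample_groups <- rep(group_names, each = reps)

    baseline <- stats::rnorm(n_proteins, 20, 2)
    n_de <- round(de_fraction * n_proteins)
    de_idx <- if (n_de > 0) sample.int(n_proteins, n_de) else integer()
    de_sign <- sample(c(-1, 1), n_de, replace = TRUE)
    shift <- numeric(n_proteins)
    shift[de_idx] <- de_sign * effect

    log2_vals <- matrix(baseline, n_proteins, length(sample_ids)) +
      matrix(stats::rnorm(n_proteins * length(sample_ids), 0, 0.25),
             n_proteins, length(sample_ids))
    last <- sample_groups == group_names[groups]
    log2_vals[, last] <- log2_vals[, last] + shift

    q10 <- stats::quantile(log2_vals, 0.10, names = FALSE)
    p_mnar <- mnar_strength * stats::plogis((q10 - log2_vals) / 0.5)
    miss <- matrix(stats::runif(length(log2_vals)) < p_mnar, n_proteins) |
      matrix(stats::runif(length(log2_vals)) < mcar_rate, n_proteins)

    ids <- sprintf("PROT%05d", seq_len(n_proteins))
    n_cont <- round(contaminant_fraction * n_proteins)
    cont_idx <- integer()
    if (n_cont > 0) {
      pool <- setdiff(seq_len(n_proteins), de_idx)
      cont_list <- read_contaminants(bundled_contaminant_file())
      n_cont <- min(n_cont, length(pool), length(cont_list))
      cont_idx <- sample(pool, n_cont)
      ids[cont_idx] <- sample(cont_list, n_cont)
    }

    vals <- 2^log2_vals
    vals[miss] <- NA_real_
    rownames(vals) <- ids
    colnames(vals) <- sample_ids
    am <- am_replace(
      new_abundance_matrix(tibble::tibble(protein_id = ids), "intensity", "linear"),
      vals
    )
    de_lab <- rep("null", n_proteins)
    de_lab[de_idx] <- ifelse(de_sign > 0, "up", "down")
    list(
      matrix = am,
      samples = tibble::tibble(sample_id = sample_ids, sample_group = sample_groups,
                               bait_uniprot = NA_character_, is_control = FALSE,
                               acquisition_order = seq_along(sample_ids)),
      truth = tibble::tibble(protein_id = ids, de = de_lab,
                             contaminant = seq_len(n_proteins) %in% cont_idx),
      params = list(n_proteins = n_proteins, groups = groups, reps = reps,
                    de_fraction = de_fraction, effect = effect,
                    mnar_strength = mnar_strength, mcar_rate = mcar_rate,
                    contaminant_fraction = contaminant_fraction, seed = as.integer(seed))
    )
  })
}

# negative-binomial counts with a floor on control presence
rnbinom_mu <- function(n, mu, dispersion) {
  stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Generate a synthetic AP-MS dataset with ground truth
#'
#' True preys follow a negative binomial (mean 10, dispersion 0.5) in their
#' own bait's runs and are absent everywhere else; background preys follow a
#' negative binomial (mean 5, dispersion 0.5) in every run, and each is
#' forced to be present in at least 80% of the control runs (zero control
#' cells beyond that allowance are bumped to a count of at least 1), the
#' regime in which control-frequency and fold-change filters are informative.
#'
#' @param n_baits Number of baits.
#' @param true_preys_per_bait True interactors planted per bait.
#' @param background_preys Number of promiscuous background preys.
#' @param n_controls Number of control runs.
#' @param reps Runs per bait.
#' @param seed Integer seed.
#' @return List with `sc` (an [spectral_counts()] table), `matrix`
#'   (spectral-count [abundance_matrix()]), `samples`, `truth` (tibble
#'   `bait`, `prey`, `label`), and `params`.
#' @export
generate_interactomics <- function(n_baits = 4L, true_preys_per_bait = 10L,
                                   background_preys = 200L, n_controls = 6L,
                                   reps = 2L, seed = 1L) {
  stopifnot(n_baits >= 1L, true_preys_per_bait >= 1L, background_preys >= 1L,
            reps >= 1L)
  withr::with_seed(as.integer(seed), {
    baits <- sprintf("BAIT%02d", seq_len(n_baits))
    bait_runs <- as.vector(vapply(baits, function(b) paste0(b, "_R", seq_len(reps)),
                                  character(reps)))
    ctrl_runs <- if (n_controls > 0) sprintf("CTRL%02d", seq_len(n_controls)) else character()
    run_ids <- c(bait_runs, ctrl_runs)
    run_bait <- c(rep(baits, each = reps), rep(NA_character_, length(ctrl_runs)))
    is_ctrl <- c(rep(FALSE, length(bait_runs)), rep(TRUE, length(ctrl_runs)))

    true_preys <- as.vector(vapply(seq_len(n_baits), function(i) {
      sprintf("TP%02d_%02d", i, seq_len(true_preys_per_bait))
    }, character(true_preys_per_bait)))
    bg_preys <- sprintf("BG%04d", seq_len(background_preys))
    preys <- c(true_preys, bg_preys)

    counts <- matrix(0L, length(preys), length(run_ids),
                     dimnames = list(preys, run_ids))
    for (i in seq_len(n_baits)) {
      rows <- true_preys[((i - 1) * true_preys_per_bait + 1):(i * true_preys_per_bait)]
      cols <- bait_runs[run_bait[seq_along(bait_runs)] == baits[i]]
      counts[rows, cols] <- rnbinom_mu(length(rows) * length(cols), mu = 10, dispersion = 0.5)
    }
    counts[bg_preys, ] <- rnbinom_mu(length(bg_preys) * length(run_ids),
                                     mu = 5, dispersion = 0.5)
    if (length(ctrl_runs)) {
      allowed_zero <- floor(0.2 * length(ctrl_runs))
      for (p in bg_preys) {
        zeros <- which(counts[p, ctrl_runs] == 0)
        excess <- length(zeros) - allowed_zero
        if (excess > 0) {
          fix <- sample(zeros, excess)
          counts[p, ctrl_runs[fix]] <- pmax(1L, rnbinom_mu(excess, mu = 5, dispersion = 0.5))
        }
      }
    }

    samples <- tibble::tibble(sample_id = run_ids,
                              sample_group = ifelse(is_ctrl, "control", run_bait),
                              bait_uniprot = run_bait, is_control = is_ctrl,
                              acquisition_order = seq_along(run_ids))
    m <- tibble::tibble(protein_id = preys)
    for (s in run_ids) m[[s]] <- as.numeric(counts[, s])
    am <- abundance_matrix(m, "spectral_count")
    truth <- tibble::tibble(
      bait = rep(baits, each = true_preys_per_bait),
      prey = true_preys, label = "true_interactor"
    )
    list(
      sc = structure(list(counts = counts * 1.0,
                          runs = samples[, c("sample_id", "bait_uniprot", "is_control")]),
                     class = "sc_table"),
      matrix = am, samples = samples, truth = truth,
      params = list(n_baits = n_baits, true_preys_per_bait = true_preys_per_bait,
                    background_preys = background_preys, n_controls = n_controls,
                    reps = reps, seed = as.integer(seed))
    )
  })
}

#' Generate a synthetic chromatogram run series
#'
#' Each TIC is the same sum of five Gaussian peaks plus a small baseline over
#' a 60-minute gradient; the whole trace of run `i` (of `n_runs`) is scaled
#' by `(1 - drift * i / n_runs)` times a small lognormal noise factor, and
#' acquisition timestamps are spaced hourly. The closed-form expected
#' last/first AUC ratio, `(1 - drift) / (1 - drift / n_runs)`, is attached as
#' attribute `expected_last_first_ratio`.
#'
#' @param n_runs Number of runs in the series.
#' @param drift Fractional intensity decay across the series, in \[0, 1\].
#' @param noise_sd Lognormal sd of the per-run amplitude noise.
#' @param seed Integer seed.
#' @return List of [chromatogram()] objects (with the ratio attribute).
#' @export
generate_chromatograms <- function(n_runs = 12L, drift = 0.0, noise_sd = 0.01,
                                   seed = 1L) {
  stopifnot(drift >= 0, drift <= 1, n_runs >= 1L)
  withr::with_seed(as.integer(seed), {
    t <- seq(0, 60, by = 0.1)
    centers <- stats::runif(5, 5, 55)
    widths <- stats::runif(5, 0.8, 2.5)
    amps <- stats::runif(5, 5e7, 2e8)
    base_tic <- rep(1e5, length(t))
    for (k in 1:5) base_tic <- base_tic + amps[k] * exp(-(t - centers[k])^2 / (2 * widths[k]^2))
    t0 <- as.POSIXct("2026-01-05 08:00:00", tz = "UTC")
    out <- lapply(seq_len(n_runs), function(i) {
      f <- (1 - drift * i / n_runs) * exp(stats::rnorm(1, 0, noise_sd))
      chromatogram(
        run_id = sprintf("RUN%03d", i),
        file_name = sprintf("run%03d.raw", i),
        acquisition_time = t0 + (i - 1) * 3600,
        time_points = t, tic = base_tic * f,
        metadata = list(instrument = "synthetic", series_index = i)
      )
    })
    attr(out, "expected_last_first_ratio") <- (1 - drift) / (1 - drift / n_runs)
    out
  })
}

#' Generate small reference tables and a synthetic image stack
#'
#' Produces, deterministically from the seed: a localization marker table
#' over four compartments, a known-interaction table containing a planted
#' subset of the interactomics generator's true pairs, an annotation table
#' (terms over the interactomics prey universe), and a 2-z x 3-channel
#' 64x64 synthetic image stack with a built-in colocalizing blob in channels
#' 1 and 2.
#'
#' @param seed Integer seed (also used for the paired interactomics dataset).
#' @return List with `markers`, `known_interactions`, `annotations`
#'   (tibbles), `image` (array `(z, channel, y, x)`), and `interactomics`
#'   (the paired [generate_interactomics()] result).
#' @export
generate_fixture_tables <- function(seed = 1L) {
  ia <- generate_interactomics(seed = seed)
  withr::with_seed(as.integer(seed) + 1000L, {
    locs <- c("nucleus", "cytoplasm", "mitochondrion", "plasma_membrane")
    preys <- rownames(ia$sc$counts)
    markers <- purrr::map_dfr(seq_along(locs), function(i) {
      tibble::tibble(localization = locs[i],
                     accession = sample(preys, 12L))
    })
    known <- ia$truth |>
      dplyr::slice_sample(prop = 0.5) |>
      dplyr::transmute(accession_a = .data$bait, accession_b = .data$prey)
    terms <- paste0("TERM", 1:6)
    annotations <- purrr::map_dfr(terms, function(tm) {
      tibble::tibble(term = tm, accession = sample(preys, sample(10:40, 1L)))
    })
    img <- array(stats::runif(2 * 3 * 64 * 64, 0, 0.1), dim = c(2, 3, 64, 64))
    yy <- matrix(rep(1:64, 64), 64); xx <- t(yy)
    blob <- exp(-((yy - 32)^2 + (xx - 32)^2) / (2 * 8^2))
    img[1, 1, , ] <- img[1, 1, , ] + 0.8 * blob
    img[1, 2, , ] <- img[1, 2, , ] + 0.6 * blob
    img[1, 3, , ] <- img[1, 3, , ] + 0.7 * exp(-((yy - 16)^2 + (xx - 48)^2) / (2 * 6^2))
    img[2, , , ] <- img[2, , , ] * 0.5
    img <- pmin(img, 1)
    list(markers = markers, known_interactions = known, annotations = annotations,
         image = img, interactomics = ia)
  })
}

#' Write a full synthetic fixture bundle to a directory
#'
#' Writes everything the workflows ingest: a generic intensity matrix and
#' sample table (proteomics), a spectral-count matrix and sample table
#' (interactomics), the contaminant list, marker/known-interaction/annotation
#' tables, chromatogram JSON documents, and a multi-page TIFF z-stack.
#'
#' @param dir Output directory.
#' @param seed Integer seed for every generator.
#' @return Named list of the paths written, invisibly.
#' @export
write_synthetic_bundle <- function(dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  prot <- generate_proteomics(seed = seed)
  fx <- generate_fixture_tables(seed = seed)
  ia <- fx$interactomics
  paths <- list(
    proteomics_matrix = file.path(dir, "proteomics_matrix.tsv"),
    proteomics_samples = file.path(dir, "proteomics_samples.tsv"),
    interactomics_matrix = file.path(dir, "interactomics_counts.tsv"),
    interactomics_samples = file.path(dir, "interactomics_samples.tsv"),
    contaminants = file.path(dir, "contaminants.txt"),
    markers = file.path(dir, "markers.tsv"),
    known_interactions = file.path(dir, "known_interactions.tsv"),
    annotations = file.path(dir, "annotations.tsv"),
    chromatogram_dir = file.path(dir, "chromatograms"),
    image = file.path(dir, "stack.tiff")
  )
  write_generic_matrix(prot$matrix, paths$proteomics_matrix)
  readr::write_tsv(prot$samples, paths$proteomics_samples)
  write_generic_matrix(ia$matrix, paths$interactomics_matrix)
  readr::write_tsv(ia$samples, paths$interactomics_samples)
  file.copy(bundled_contaminant_file(), paths$contaminants, overwrite = TRUE)
  readr::write_tsv(fx$markers, paths$markers)
  readr::write_tsv(fx$known_interactions, paths$known_interactions)
  readr::write_tsv(fx$annotations, paths$annotations)
  dir.create(paths$chromatogram_dir, showWarnings = FALSE)
  chroms <- generate_chromatograms(seed = seed)
  for (ch in chroms) {
    write_chromatogram_json(ch, file.path(paths$chromatogram_dir,
                                          paste0(ch$run_id, ".json")))
  }
  pages <- list()
  for (z in 1:2) for (ch in 1:3) pages[[length(pages) + 1L]] <- fx$image[z, ch, , ]
  tiff::writeTIFF(pages, paths$image, bits.per.sample = 16L)
  invisible(paths)
}
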