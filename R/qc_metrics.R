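# Generic QC metric suite computed for every submitted dataset: per-sample
# identification counts and missingness, per-protein coverage, pairwise shared
# identifications, commonly identified proteins, per-group CVs, and per-sample
# intensity summaries.

#' Per-sample protein identification counts
#' @param am An [abundance_matrix()].
#' @return Tibble with `sample_id`, `n_identified`.
#' @export
identification_counts <- function(am) {
  v <- am_values(am)
  tibble::tibble(sample_id = colnames(v), n_identified = unname(colSums(!is.na(v))))
}

#' Per-sample missing-value percentages
#' @inheritParams identification_counts
#' @return Tibble with `sample_id`, `missing_pct` in \[0, 100\].
#' @export
missing_value_percentages <- function(am) {
  v <- am_values(am)
  if (nrow(v) == 0L) stop("empty matrix: missing-value percentage undefined")
  tibble::tibble(sample_id = colnames(v),
                 missing_pct = unname(100 * colSums(is.na(v)) / nrow(v)))
}

#' Per-protein identification coverage
#'
#' For each protein, the number of samples in which it was identified, plus a
#' histogram (`k` samples -> number of proteins identified in exactly `k`
#' samples, `k = 0..n_samples`; bins sum to the protein count).
#'
#' @inheritParams identification_counts
#' @return List with tibbles `per_protein` (`protein_id`,
#'   `n_samples_detected`) and `histogram` (`k`, `n_proteins`).
#' @export
protein_coverage <- function(am) {
  v <- am_values(am)
  cov <- rowSums(!is.na(v))
  k <- 0:ncol(v)
  list(
    per_protein = tibble::tibble(protein_id = rownames(v), n_samples_detected = unname(cov)),
    histogram = tibble::tibble(k = k,
                               n_proteins = vapply(k, function(kk) sum(cov == kk), integer(1L)))
  )
}

#' Pairwise shared identifications
#'
#' Overlap counts (`|detected(s) .. detected(t)|`) and Jaccard indices between
#' the detection sets of every pair of samples. Jaccard is defined as 1 when
#' both sets are empty.
#'
#' @inheritParams identification_counts
#' @return List of two symmetric matrices, `overlap` and `jaccard`.
#' @export
shared_identifications <- function(am) {
  d <- !is.na(am_values(am))
  storage.mode(d) <- "double"
  overlap <- crossprod(d)
  counts <- colSums(d)
  union <- outer(counts, counts, "+") - overlap
  jaccard <- ifelse(union == 0, 1, overlap / union)
  dimnames(jaccard) <- dimnames(overlap)
  list(overlap = overlap, jaccard = jaccard)
}

#' Commonly identified proteins
#'
#' Proteins detected in at least `min_fraction` of the samples (default: all
#' of them), sorted by detection count then accession.
#'
#' @inheritParams identification_counts
#' @param min_fraction Detection-fraction threshold in (0, 1\].
#' @return Tibble with `protein_id`, `n_detected`.
#' @export
common_proteins <- function(am, min_fraction = 1) {
  stopifnot(min_fraction > 0, min_fraction <= 1)
  v <- am_values(am)
  n <- rowSums(!is.na(v))
  keep <- n >= min_fraction * ncol(v) - 1e-9
  tibble::tibble(protein_id = rownames(v)[keep], n_detected = unname(n[keep])) |>
    dplyr::arrange(dplyr::desc(.data$n_detected), .data$protein_id)
}

#' Per-group coefficients of variation
#'
#' CV = sample standard deviation / mean, computed on raw-scale values for
#' every protein with at least two observed values in the group. Groups with
#' fewer than two samples are skipped with a warning.
#'
#' @inheritParams identification_counts
#' @param samples A [read_sample_table()] tibble covering the matrix columns.
#' @return Tibble with `sample_group`, `protein_id`, `cv`.
#' @export
group_cv <- function(am, samples) {
  v <- am_values(am)
  groups <- split(samples$sample_id, samples$sample_group)
  out <- list()
  for (g in names(groups)) {
    ids <- intersect(groups[[g]], colnames(v))
    if (length(ids) < 2L) {
      warning("group '", g, "' has fewer than 2 samples; CV skipped")
      next
    }
    sub <- v[, ids, drop = FALSE]
    keep <- rowSums(!is.na(sub)) >= 2L
    if (!any(keep)) next
    sub <- sub[keep, , drop = FALSE]
    mu <- rowMeans(sub, na.rm = TRUE)
    sdv <- apply(sub, 1L, stats::sd, na.rm = TRUE)
    out[[g]] <- tibble::tibble(sample_group = g, protein_id = rownames(sub),
                               cv = unname(sdv / mu))
  }
  dplyr::bind_rows(out)
}

#' Per-sample intensity (or count) summaries
#'
#' Sum, median and quartiles of the observed values in each sample. Quantiles
#' use the linear-interpolation convention (`stats::quantile` type 7).
#'
#' @inheritParams identification_counts
#' @return Tibble with `sample_id`, `total`, `median`, `q1`, `q3`.
#' @export
intensity_summary <- function(am) {
  v <- am_values(am)
  purrr::map_dfr(colnames(v), function(s) {
    x <- v[, s]
    x <- x[!is.na(x)]
    q <- if (length(x)) stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
         else rep(NA_real_, 3L)
    tibble::tibble(sample_id = s, total = sum(x), median = q[2L], q1 = q[1L], q3 = q[3L])
  })
}

#' Full QC report
#'
#' Bundles every generic QC metric for one dataset. Use [write_qc_report()]
#' to serialize the bundle as a single JSON document, or the individual
#' tibbles for delimited export.
#'
#' @inheritParams group_cv
#' @param common_min_fraction Threshold for [common_proteins()].
#' @return List of class `qc_report`.
#' @export
qc_report <- function(am, samples, common_min_fraction = 1) {
  shared <- shared_identifications(am)
  cvs <- group_cv(am, samples)
  structure(list(
    id_counts = identification_counts(am),
    missing_pct = missing_value_percentages(am),
    coverage = protein_coverage(am),
    overlap = shared$overlap,
    jaccard = shared$jaccard,
    common_proteins = common_proteins(am, common_min_fraction),
    cv_by_group = cvs,
    cv_summary = if (nrow(cvs) > 0L) {
      dplyr::summarise(dplyr::group_by(cvs, .data$sample_group),
                       median_cv = stats::median(.data$cv), .groups = "drop")
    } else tibble::tibble(sample_group = character(), median_cv = double()),
    intensity_summary = intensity_summary(am)
  ), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d samples, %d proteins; median missing %.1f%%\n",
              nrow(x$id_counts), nrow(x$coverage$per_protein),
              stats::median(x$missing_pct$missing_pct)))
  invisible(x)
}

#' Serialize a QC report to JSON
#' @param report A [qc_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  obj <- list(
    id_counts = report$id_counts,
    missing_pct = report$missing_pct,
    coverage = report$coverage$per_protein,
    coverage_histogram = report$coverage$histogram,
    overlap = as.data.frame(report$overlap),
    jaccard = as.data.frame(report$jaccard),
    common_proteins = report$common_proteins,
    cv_by_group = report$cv_by_group,
    cv_summary = report$cv_summary,
    intensity_summary = report$intensity_summary
  )
  jsonlite::write_json(obj, path, dataframe = "columns", digits = NA, pretty = TRUE)
  invisible(path)
}
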